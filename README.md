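# ehrcleanr

Automated, clinical-knowledge-driven cleaning of numeric measurement and
laboratory records from Electronic Health Records (EHR).

Records exported from primary-care registries carry two families of
defects that distribution-based outlier screens handle badly:

* **value errors** — order-of-magnitude slips from extra or missing
  zeros (a blood pressure entered as `9` or `16,000`), outright
  implausible entries (`3000` mmHg), and meaningless tokens (`"NULL"`,
  `","`, `"na"`);
* **unit errors** — the same analyte reported in several valid units
  (creatinine in mg/dL, mmol/L, mg/L), misspelled units
  (`"mmol/LsOms"`), and junk unit tokens (`"??"`, `"77"`).

Because disease prevalence is low but real, the extreme values of sick
patients look exactly like errors to any method that works from the data
distribution. ehrcleanr instead cleans each variable against curated
clinical knowledge: a **Clinical Knowledge Database (CKD)** table that
stores, per variable, the admissible units with multiplicative
conversion rates to a standard unit, the **normal range** (reference
interval for healthy individuals) and the **extreme range**
(biologically plausible interval).

## The method

For one variable with spec `(units, rates, [n_min, n_max], [e_min, e_max])`
the pipeline runs four fixed stages:

1. **Preprocessing** — strip unexpected characters, coerce value tokens
   to numbers, turn meaningless tokens into `NA` with a reason code.
2. **Fuzzy unit repair** — score the raw unit `V` against every CKD unit
   `W` with a normalized Levenshtein similarity and keep the best
   candidate if its ratio clears a threshold (default 0.5), else the
   value becomes `NA`. The default score is the matching-blocks ratio
   `(|V| + |W| − Lev₂(V, W)) / (|V| + |W|)` with substitutions costing 2
   (equivalently `2·LCS/(|V|+|W|)`); the textbook normalization
   `1 − Lev(V, W)/max(|V|, |W|)` is selectable.
3. **Unit conversion** — multiply by the matched unit's rate so every
   value is in the standard unit.
4. **Range cleaning** — a value inside the extreme range is never
   touched (a genuinely sick patient is not "corrected"); a value
   outside it is shifted by the power of ten `10^k`, `|k| ≤ 6`, that
   brings it closest to the normal range, and kept only if the shifted
   value lands inside the extreme range — otherwise it becomes `NA` as a
   true outlier. Every surviving value is biologically plausible by
   construction.

Per-stage **quality-of-data** metrics are reported: completeness
(% missing), correctness (% inside the normal range) and plausibility
(% of non-missing values inside the extreme range).

## Worked example

```r
library(ehrcleanr)
ckd  <- load_ckd(system.file("extdata", "example_ckd.csv", package = "ehrcleanr"))
crea <- get_spec(ckd, "57139A.B")     # creatinine: standard unit Mg/dL,
                                      # normal 0.6-1.3, extreme 0.1-5
raw <- tibble::tibble(
  test_code = "57139A.B",
  num1 = c("0.1", "1.1", "90", "0.9", "NULL"),
  unit = c("mmol/LsOms", "mg/dL", "mg/dL", "qqqq", "mg/dL"))
out <- clean_variable(raw, crea)
out$records[, c("num1", "unit", "value_clean", "missing_reason",
                "exponent_applied", "unit_ratio")]
#> # A tibble: 5 × 6
#>   num1  unit       value_clean missing_reason    exponent_applied unit_ratio
#>   <chr> <chr>            <dbl> <chr>                        <int>      <dbl>
#> 1 0.1   mmol/LsOms        1.13 <NA>                             0       0.75
#> 2 1.1   mg/dL             1.1  <NA>                             0       1
#> 3 90    mg/dL             0.9  <NA>                            -2       1
#> 4 0.9   qqqq             NA    unmatched_unit                   0       0
#> 5 NULL  mg/dL            NA    meaningless_token                0       1
```

Row 1: the misspelled unit `mmol/LsOms` is repaired to `Mmol/L`
(similarity 0.75 ≥ 0.5) and the value converted at the creatinine rate
11.312 → 1.13 mg/dL. Row 3: 90 mg/dL is implausible; dividing by 100
lands it in the normal range (`exponent_applied = -2`). Row 4: `qqqq`
matches no unit (ratio 0) so the value is blanked. Row 5: `NULL` is a
meaningless value token.

```r
out$report
#> <qod_report> 57139A.B (Creatinine), n = 5
#>                stage n_total n_missing n_normal n_plausible pct_missing pct_normal pct_plausible
#>             original       5         0        1           1        0.00      20.00         20.00
#>  after_preprocessing       5         1        1           1       20.00      20.00         25.00
#>    after_unit_change       5         2        2           2       40.00      40.00         66.67
#>      after_all_steps       5         2        3           3       40.00      60.00        100.00
```

Completeness only degrades (nothing is imputed), correctness rises from
20% to 60%, and plausibility ends at 100% — the pipeline's structural
guarantee.

The same pipeline runs from the shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "ehrclean.R", package = "ehrcleanr"))')
Rscript "$CLI" clean --ckd ckd.csv --input raw.csv --variable 57139A.B \
        --out cleaned.csv --report report.csv
Rscript "$CLI" synth --ckd ckd.csv --variable 57139A.B --n 1000 --seed 7 \
        --out dirty.csv --truth-out truth.csv
```

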