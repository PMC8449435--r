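---
title: "Cleaning EHR measurements against clinical knowledge: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleaning EHR measurements against clinical knowledge: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrcleanr)
```

## Why knowledge-driven cleaning

Measurement and laboratory tables exported from routine care mix records
from many practices and laboratories collected over decades. Two things
make them hard to clean automatically with generic tools. First, the
errors are variable-specific: a creatinine of 90 is an obvious entry slip
in mg/dL and routine in µmol/L, and the mmol/L→mg/dL conversion factor
differs per analyte (18 for glucose, 11.312 for creatinine). Second, the
value distribution itself is contaminated: registries cover sick and
healthy patients alike, so distribution-based outlier detection flags
genuinely extreme patients as errors precisely when prevalence is low.

ehrcleanr therefore takes every cleaning decision from a curated
Clinical Knowledge Database (CKD) — per variable: the admissible units
with multiplicative rates into one standard unit, a *normal range*
(reference interval for healthy individuals) and an *extreme range*
(biologically plausible interval) — and none from the data distribution.
The package's structural guarantee is that after cleaning, every
surviving value lies inside the extreme range.

## The pipeline

Cleaning one variable runs four fixed stages
(`clean_variable()`); records are never dropped, only values blanked,
and every mutated cell carries provenance (reason code, matched unit,
similarity ratio, applied exponent).

### 1. Preprocessing

`coerce_numeric()` is a total function from raw tokens to numbers or
reasoned missing values. Tokens on the meaningless list (empty,
punctuation, `"null"`, `"na"`, ... — `default_meaningless_tokens()`,
extensible per run) or containing no digit become
`missing(meaningless_token)`. Otherwise every character outside
`0-9 . , + - space` is stripped and decimal/grouping marks are resolved:
with both `.` and `,` present the rightmost is the decimal separator;
a lone comma is decimal unless followed by exactly three trailing
digits (`"12,5"` → 12.5, `"16,000"` → 16000). Tokens with digits but no
unambiguous reading (`"1.2.3"`) become `missing(unparseable_number)`.
The rules are deterministic, never raise, and are idempotent through
rendering (parsing a printed cleaned value reproduces it exactly).
The mixed-convention rule reflects data entered under both continental
(comma-decimal) and anglophone conventions in the same table.

### 2. Fuzzy unit repair

`match_unit()` scores the raw unit token against every CKD unit of the
variable, case-insensitively on whitespace-normalized forms. The edit
distance is the standard Levenshtein dynamic program (implemented in
C++, per code point so `µmol/L` vs `mmol/L` is one substitution). Two
normalizations to `[0, 1]` are available (`similarity_ratio()`):

* `matching_blocks` (default): `(|V|+|W|−Lev₂)/(|V|+|W|)` where `Lev₂`
  charges substitutions 2, i.e. twice the longest common subsequence
  over the total length — the `ratio` of the difflib family;
* `printed_formula`: `1 − Lev/max(|V|,|W|)`.

The default is `matching_blocks` because it rewards long shared blocks:
a valid unit embedded in noise (`"mmol/LsOms"` → `"mmol/L"`, ratio 0.75
vs 0.60 under the plain formula) keeps a comfortable margin above the
acceptance threshold, which is what the unit-typo population looks like
in practice. The threshold (`unit_match_threshold`) defaults to 0.5: a
proposal must share at least half of its character mass with the raw
token. Below threshold the unit is deemed unrecognizable and the value
becomes `missing(unmatched_unit)` — repairing to a wrong unit would
silently rescale a value, which is worse than losing it.

Ties at equal ratio go to the smaller plain Levenshtein distance, then
to CKD order; specs store the standard unit first, so curated knowledge
wins residual ties. Comparison happens at full precision; the 2-decimal
scores are display only.

### 3. Unit conversion

A pure multiplication by the matched unit's `rate_to_standard`
(`standardize()`). Ranges are stored in the standard unit, so range
logic runs only after this stage. Affine transforms (temperature
scales) are out of scope: the CKD schema carries a single rate.

Empty unit tokens are governed by `empty_unit_policy`. The default
`assume_standard` keeps the value as already standard: in routine
extracts a blank unit overwhelmingly accompanies a value recorded in
the house standard unit, and blanking all of them would destroy far
more signal than it protects. `strict` (values with blank units become
missing) is available for conservative runs.

### 4. Range cleaning

`magnitude_correct()` implements the order-of-magnitude repair:

* values inside the extreme range are never shifted — even when outside
  the normal range they are legitimate extreme observations, and
  "correcting" them would corrupt exactly the patients a study cares
  about;
* an implausible value is shifted by `value · 10^k`,
  `k ∈ {−6, …, 6}\{0}`, choosing the `k` whose result is closest to the
  normal interval in Euclidean distance (0 when inside); the shift is
  kept only if the result lands inside the extreme range, otherwise the
  value becomes `missing(outlier)`.

Tie-breaks, applied in order: smaller distance, smaller `|k|`, negative
`k` (surplus trailing zeros are the archetypal keyboard slip, as in a
blood pressure `9050` for 90/50). The bound `|k| ≤ 6`
(`max_abs_exponent`) generously covers real extra/missing-zero errors
while refusing absurd rescues of values many orders of magnitude away.
Negative values for variables with a non-negative extreme range are
sign errors, not magnitude errors, and are removed without a shift
attempt; zero can never be rescued by a power of ten and falls out the
same way. The stage is idempotent — outputs are inside the extreme
range, which a second pass leaves untouched.

## Quality-of-data reporting

`stage_report()` tabulates, per stage: completeness as % missing
(the pipeline imputes nothing, so this is non-decreasing across
stages), correctness as % inside the normal range, and plausibility as
% of non-missing values inside the extreme range (100 after cleaning,
structurally). Two reporting policies were genuinely open and are
explicit knobs:

* the correctness denominator includes missing records by default
  (keeping completeness and correctness on the same base; a
  `non_missing` denominator is selectable);
* before unit conversion, a value is counted as normal only when its
  unit is already the standard unit — pre-conversion comparability is
  otherwise undefined. The report CSV carries this note in a comment
  line.

## Synthetic validation data

`generate_clean_records()` emits registry-shaped record tables (patient
and practice identifiers, dates, test codes, two value tokens, a unit
token) with values uniform inside the normal range. Uniform, not
Gaussian: range membership is all the pipeline inspects, and uniform
sampling maximizes boundary coverage per record. `corrupt_records()`
then injects at most one labelled corruption per record — unit typos
built from the same edit operations the matcher scores (so injected
distance is controllable), junk unit tokens, re-expression in an
alternate valid unit, `×10^k` magnitude slips, planted true outliers
verified by brute force to survive no power-of-ten rescue, and junk
value tokens — returning the ground truth per corrupted record.

What passing on this generator shows: the stages invert exactly the
error taxonomy they target, end-to-end, with known labels. What it does
not show: performance on real registries, where unit vocabularies are
larger and misspellings are not uniform over edit operations, where
blank units may hide non-standard units (the `assume_standard` policy
is then optimistic), and where errors correlate within patients and
practices. On variables whose extreme range spans more than one decade,
distinct exponents can both land inside the extreme range, so magnitude
repair is no longer uniquely invertible — the narrow-range (max/min
< 10) case is the one with a recovery guarantee, and the test suite
asserts exact recovery (relative tolerance 1e-9, floating-point
round-trip) only there.

## Numerical and degenerate-input choices

* The standard-unit rate must equal 1 within 1e-12, checked at load;
  exactly one unit per variable may carry rate 1.
* Similarity of two empty strings is defined as 1; an empty candidate
  list is an error (a valid CKD guarantees units).
* Unit-conversion round-trips (convert, divide back) are asserted at
  relative tolerance 1e-9.
* Cleaned values are rendered with the shortest decimal representation
  that round-trips the IEEE double, so re-cleaning printed output is a
  fixed point.
* Duplicate variable codes in a CKD are a hard error, never a merge;
  ranges are per variable, not per unit (unit rows beyond the first
  leave their range cells blank).
* The pipeline is deterministic end to end; identical input and
  configuration give byte-identical output files.

## Problem sizes in the test suite

The suite validates the edit distance exhaustively against a direct
transcription of its defining recurrence over all ~1.19 million string
pairs of length ≤ 6 on a three-letter alphabet (plus the memo-free
recursion on short strings and random pairs, and `utils::adist` as a
third independent check), and runs the end-to-end properties —
determinism, idempotence, 100% post-clean plausibility, monotone
completeness, exact recovery of injected `×10^k` errors — on synthetic
cohorts of 250–1,000 records per scenario with fixed seeds, sizes at
which every property is already fully exercised.

## Known limitations

* No longitudinal or within-patient consistency checks; each record is
  cleaned independently.
* No imputation, by design: the method only removes or rescales.
* Single multiplicative rate per unit; no affine or nonlinear
  conversions, no unit-grammar parsing.
* The meaningless-token list is a seed list, extensible per run, not a
  learned model.
* Fuzzy repair assumes the CKD unit list is complete for the variable;
  a valid-but-uncatalogued unit will be either mis-repaired or blanked.
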