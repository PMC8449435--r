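Package: ehrcleanr
Title: Clinical-Knowledge-Driven Cleaning of EHR Measurement Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Automated cleaning of numeric measurement and laboratory
    records from Electronic Health Records (EHR), driven by a curated
    Clinical Knowledge Database (CKD) of variable-specific rules. The
    pipeline repairs misspelled unit strings by Levenshtein-based fuzzy
    matching, converts values to a per-variable standard unit, corrects
    order-of-magnitude entry errors against reference ranges, replaces
    biologically implausible values with missing, and reports per-stage
    completeness, correctness and plausibility. Includes a synthetic
    dirty-record generator with labelled corruptions for end-to-end
    validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    readr,
    dplyr,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
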