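#' Pipeline run configuration
#'
#' Collects every tunable of the cleaning pipeline with its default. The
#' pipeline has no stochastic component; a configuration plus an input
#' determines the output byte for byte.
#'
#' @param value_columns Value-token column(s) to clean (first one is the
#'   primary value reported on). Default `"num1"`.
#' @param unit_column Unit-token column. Default `"unit"`.
#' @param test_code_column Column holding the variable/test code used for
#'   record extraction. Default `"test_code"`.
#' @param unit_match_threshold Fuzzy-match acceptance threshold in
#'   `(0, 1]`. Default 0.5.
#' @param similarity_method `"matching_blocks"` (default) or
#'   `"printed_formula"`, see [similarity_ratio()].
#' @param empty_unit_policy `"assume_standard"` (default) or `"strict"`,
#'   see [standardize()].
#' @param max_abs_exponent Magnitude-correction search bound, default 6.
#' @param meaningless_tokens Casefolded meaningless-token list.
#' @param correctness_denominator `"all"` or `"non_missing"`, see
#'   [correctness()].
#' @return A `run_config` list.
#' @export
run_config <- function(value_columns = "num1",
                       unit_column = "unit",
                       test_code_column = "test_code",
                       unit_match_threshold = 0.5,
                       similarity_method = c("matching_blocks", "printed_formula"),
                       empty_unit_policy = c("assume_standard", "strict"),
                       max_abs_exponent = 6,
                       meaningless_tokens = default_meaningless_tokens(),
                       correctness_denominator = c("all", "non_missing")) {
  similarity_method <- match.arg(similarity_method)
  empty_unit_policy <- match.arg(empty_unit_policy)
  correctness_denominator <- match.arg(correctness_denominator)
  if (!is.numeric(unit_match_threshold) ||
      unit_match_threshold <= 0 || unit_match_threshold > 1) {
    stop("unit_match_threshold must be in (0, 1]", call. = FALSE)
  }
  structure(list(
    value_columns = value_columns,
    unit_column = unit_column,
    test_code_column = test_code_column,
    unit_match_threshold = unit_match_threshold,
    similarity_method = similarity_method,
    empty_unit_policy = empty_unit_policy,
    max_abs_exponent = max_abs_exponent,
    meaningless_tokens = meaningless_tokens,
    correctness_denominator = correctness_denominator
  ), class = "run_config")
}

# Merge a YAML/JSON config file over the defaults.
load_run_config <- function(path) {
  opts <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(opts), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(run_config, opts)
}

#' Extract the records of one variable from a raw table
#'
#' Selects the rows whose test code equals the variable's code (exact
#' match after whitespace trimming), preserving order and duplicates. An
#' unknown code yields an empty table with a warning, not an error: a
#' registry extract may simply not contain a CKD variable.
#'
#' @param dataset Raw record tibble with a test-code column.
#' @param variable_code Code to extract.
#' @param test_code_column Name of the code column, default `"test_code"`.
#' @return Tibble of matching rows.
#' @export
extract_records <- function(dataset, variable_code, test_code_column = "test_code") {
  dataset <- as_tibble(dataset)
  if (!test_code_column %in% names(dataset)) {
    stop("input lacks column '", test_code_column, "'", call. = FALSE)
  }
  hit <- trimws(as.character(dataset[[test_code_column]])) == trimws(variable_code)
  hit[is.na(hit)] <- FALSE
  if (!any(hit)) {
    warning("no records with code '", trimws(variable_code), "'", call. = FALSE)
  }
  dataset[hit, , drop = FALSE]
}

#' Clean the records of one variable end to end
#'
#' Runs the four-stage pipeline on a record table that has already been
#' restricted to one variable: preprocessing ([preprocess_records()]),
#' fuzzy unit repair ([match_unit()]), conversion to the standard unit
#' ([standardize()]) and range cleaning ([magnitude_correct()]). Stage
#' snapshots feed the quality-of-data report.
#'
#' Rows are never dropped; a value that cannot be salvaged is blanked and
#' its `missing_reason` says at which stage and why. Each mutated cell
#' carries provenance: the matched unit and its similarity ratio, and the
#' power of ten applied.
#'
#' @param records Tibble of raw records for one variable (token columns
#'   as character).
#' @param spec The variable's [variable_spec()].
#' @param config A [run_config()].
#' @return List with `records` (input plus, for the primary value column:
#'   `value_clean`, `unit_clean`, `missing_reason`, `exponent_applied`,
#'   `unit_ratio`; additional value columns get suffixed variants) and
#'   `report` (a `qod_report`).
#' @export
#' @examples
#' ckd <- load_ckd(system.file("extdata", "example_ckd.csv", package = "ehrcleanr"))
#' raw <- tibble::tibble(
#'   test_code = "S00000069",
#'   num1 = c("120", "9", "16000", "3000", "NULL"),
#'   unit = c("mmHg", "mmHg", "mmHg", "mmHg", "mmHg"))
#' out <- clean_variable(raw, get_spec(ckd, "S00000069"))
#' out$records[, c("num1", "value_clean", "missing_reason", "exponent_applied")]
#' out$report
clean_variable <- function(records, spec, config = run_config()) {
  stopifnot(inherits(spec, "variable_spec"), inherits(config, "run_config"))
  records <- as_tibble(records)
  n <- nrow(records)
  pp <- preprocess_records(records, value_columns = config$value_columns,
                           unit_column = config$unit_column,
                           meaningless = config$meaningless_tokens)
  rec <- pp$records
  primary <- config$value_columns[1]

  snapshots <- comparable <- present <- list()
  out <- rec
  for (col in config$value_columns) {
    v_pp <- rec[[paste0(col, "_value")]]
    r_pp <- rec[[paste0(col, "_reason")]]
    std <- standardize_values(v_pp, r_pp, rec$unit_clean, spec,
                              policy = config$empty_unit_policy,
                              threshold = config$unit_match_threshold,
                              method = config$similarity_method)
    mc <- magnitude_correct(std$value, spec,
                            max_abs_exponent = config$max_abs_exponent)
    final_reason <- ifelse(!is.na(mc$reason), mc$reason, std$reason)

    sfx <- if (col == primary) "" else paste0("_", col)
    out[[paste0("value_clean", sfx)]] <- mc$value
    out[[paste0("missing_reason", sfx)]] <- final_reason
    out[[paste0("exponent_applied", sfx)]] <- mc$exponent_applied
    out[[paste0("unit_ratio", sfx)]] <- std$unit_ratio

    if (col == primary) {
      raw_tok <- records[[col]]
      is_std_unit <- norm_unit(rec$unit_clean) == norm_unit(spec$standard_unit)
      snapshots <- list(
        original = v_pp,
        after_preprocessing = v_pp,
        after_unit_change = std$value,
        after_all_steps = mc$value
      )
      # raw stage: a cell is missing only if genuinely empty; values are
      # range-comparable pre-conversion only when already in standard unit
      present <- list(original = !is.na(raw_tok) & nzchar(trimws(raw_tok)))
      comparable <- list(original = is_std_unit, after_preprocessing = is_std_unit)
    }
  }
  out$unit_clean <- ifelse(is.na(out[[paste0("value_clean", "")]]),
                           NA_character_, spec$standard_unit)
  report <- stage_report(snapshots, spec, comparable = comparable,
                         present = present)
  list(records = out, report = report)
}

#' Run the cleaning pipeline over a raw CSV, per variable
#'
#' Orchestrates the whole framework: loads the CKD, reads the raw table
#' (every column as character — the tokens are untrusted), and for each
#' requested variable extracts its records, cleans them and collects the
#' per-stage report. Writes the cleaned rows (original columns plus audit
#' columns) and a per-variable report table.
#'
#' @param ckd_path Path to the CKD file ([load_ckd()]).
#' @param input_path Path to the raw record CSV.
#' @param variable_codes Codes to clean, or `NULL` for every CKD code
#'   present in the input.
#' @param output_path,report_path Optional output CSVs.
#' @param config A [run_config()].
#' @param log Function receiving one structured message line per stage
#'   per variable (default `message`); `NULL` to silence.
#' @return List with `records` (cleaned rows of all requested variables,
#'   input order preserved), `reports` (named list of `qod_report`s) and
#'   `report_table` (wide per-variable tibble).
#' @export
run_pipeline <- function(ckd_path, input_path, variable_codes = NULL,
                         output_path = NULL, report_path = NULL,
                         config = run_config(), log = message) {
  ckd <- load_ckd(ckd_path)
  raw <- readr::read_csv(input_path,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  tc <- config$test_code_column
  if (!tc %in% names(raw)) {
    stop("input lacks column '", tc, "'", call. = FALSE)
  }
  if (is.null(variable_codes)) {
    variable_codes <- intersect(names(ckd$specs), unique(trimws(raw[[tc]])))
    if (length(variable_codes) == 0) {
      stop("no CKD variable codes present in input", call. = FALSE)
    }
  }
  say <- if (is.null(log)) function(...) invisible() else log
  raw$.row_id <- seq_len(nrow(raw))

  cleaned <- list(); reports <- list()
  for (code in variable_codes) {
    spec <- get_spec(ckd, code)
    recs <- suppressWarnings(extract_records(raw, code, test_code_column = tc))
    if (nrow(recs) == 0) {
      say(sprintf("[%s] no records found, skipping", code))
      next
    }
    res <- clean_variable(recs, spec, config = config)
    n_miss <- sum(is.na(res$records$value_clean))
    say(sprintf("[%s] stage=all n=%d missing=%d corrected=%d outliers=%d",
                code, nrow(recs), n_miss,
                sum(res$records$exponent_applied != 0),
                sum(res$records$missing_reason == "outlier", na.rm = TRUE)))
    cleaned[[code]] <- res$records
    reports[[code]] <- res$report
  }
  if (length(cleaned) == 0) stop("no variable produced any output", call. = FALSE)
  all_rows <- dplyr::bind_rows(cleaned)
  all_rows <- all_rows[order(all_rows$.row_id), , drop = FALSE]
  all_rows$.row_id <- NULL
  report_table <- dplyr::bind_rows(lapply(reports, report_row))
  if (!is.null(output_path)) {
    readr::write_csv(all_rows, output_path, na = "", progress = FALSE)
  }
  if (!is.null(report_path)) {
    writeLines(paste0("# pre-conversion correctness counts a value as normal only ",
                      "when its unit is already the standard unit"), report_path)
    readr::write_csv(report_table, report_path, na = "", append = TRUE,
                     col_names = TRUE, progress = FALSE)
  }
  list(records = all_rows, reports = reports, report_table = report_table)
}

#' Command-line entry point
#'
#' Thin argument-parsing layer over [run_pipeline()] (subcommand `clean`)
#' and the synthetic generator (subcommand `synth`, see
#' [generate_clean_records()] / [corrupt_records()]). Installed as the
#' `ehrclean.R` script under `inst/cli/`; call it as
#'
#' ```
#' Rscript $(Rscript -e 'cat(system.file("cli", "ehrclean.R", package = "ehrcleanr"))') \
#'   clean --ckd ckd.csv --input raw.csv --variable 57139A.B \
#'   --out cleaned.csv --report report.csv
#' ```
#'
#' @param args Character vector of command-line arguments (first element
#'   the subcommand).
#' @return Integer exit status, invisibly: 0 on success, 2 on usage or
#'   validation errors.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    message("usage: ehrclean.R <clean|synth> [options]; use --help per subcommand")
    invisible(2L)
  }
  if (length(args) == 0 || !args[1] %in% c("clean", "synth")) return(usage())
  sub <- args[1]; rest <- args[-1]
  status <- tryCatch({
    if (sub == "clean") cli_clean(rest) else cli_synth(rest)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}

cli_clean <- function(args) {
  spec <- list(
    optparse::make_option("--ckd", type = "character", help = "CKD CSV/JSON file"),
    optparse::make_option("--input", type = "character", help = "raw record CSV"),
    optparse::make_option("--variable", type = "character", default = NULL,
                          help = "comma-separated variable codes"),
    optparse::make_option("--all-variables", action = "store_true",
                          dest = "all_variables", default = FALSE,
                          help = "clean every CKD code present in the input"),
    optparse::make_option("--out", type = "character", default = NULL,
                          help = "cleaned record CSV"),
    optparse::make_option("--report", type = "character", default = NULL,
                          help = "per-variable QoD report CSV"),
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "YAML/JSON run configuration"),
    optparse::make_option("--threshold", type = "double", default = NULL,
                          help = "unit match threshold (default 0.5)"),
    optparse::make_option("--empty-unit-policy", type = "character",
                          dest = "empty_unit_policy", default = NULL,
                          help = "assume_standard | strict"),
    optparse::make_option("--value-columns", type = "character",
                          dest = "value_columns", default = NULL,
                          help = "comma-separated value columns (default num1)"),
    optparse::make_option("--quiet", action = "store_true", default = FALSE)
  )
  opt <- optparse::parse_args(optparse::OptionParser(option_list = spec,
                                                     prog = "ehrclean.R clean"),
                              args = args)
  if (is.null(opt$ckd) || is.null(opt$input)) {
    stop("--ckd and --input are required")
  }
  if (is.null(opt$variable) && !opt$all_variables) {
    stop("give --variable <codes> or --all-variables")
  }
  cfg <- if (!is.null(opt$config)) load_run_config(opt$config) else run_config()
  if (!is.null(opt$threshold)) cfg$unit_match_threshold <- opt$threshold
  if (!is.null(opt$empty_unit_policy)) {
    cfg$empty_unit_policy <- match.arg(opt$empty_unit_policy,
                                       c("assume_standard", "strict"))
  }
  if (!is.null(opt$value_columns)) {
    cfg$value_columns <- strsplit(opt$value_columns, ",", fixed = TRUE)[[1]]
  }
  codes <- if (!is.null(opt$variable)) {
    trimws(strsplit(opt$variable, ",", fixed = TRUE)[[1]])
  }
  res <- run_pipeline(opt$ckd, opt$input, variable_codes = codes,
                      output_path = opt$out, report_path = opt$report,
                      config = cfg,
                      log = if (opt$quiet) NULL else message)
  if (is.null(opt$out)) print(res$report_table)
  invisible(res)
}

cli_synth <- function(args) {
  spec <- list(
    optparse::make_option("--ckd", type = "character", help = "CKD CSV/JSON file"),
    optparse::make_option("--variable", type = "character", help = "variable code"),
    optparse::make_option("--n", type = "integer", default = 100L),
    optparse::make_option("--seed", type = "integer", default = NULL,
                          help = "RNG seed (required)"),
    optparse::make_option("--out", type = "character", help = "raw CSV to write"),
    optparse::make_option("--truth-out", type = "character", dest = "truth_out",
                          default = NULL, help = "ground-truth CSV to write"),
    optparse::make_option("--p-unit-typo", type = "double", dest = "p_unit_typo",
                          default = 0.05),
    optparse::make_option("--p-magnitude", type = "double", dest = "p_magnitude",
                          default = 0.05),
    optparse::make_option("--p-implausible", type = "double",
                          dest = "p_implausible", default = 0.02)
  )
  opt <- optparse::parse_args(optparse::OptionParser(option_list = spec,
                                                     prog = "ehrclean.R synth"),
                              args = args)
  if (is.null(opt$ckd) || is.null(opt$variable) || is.null(opt$out)) {
    stop("--ckd, --variable and --out are required")
  }
  if (is.null(opt$seed)) stop("--seed is required for reproducibility")
  ckd <- load_ckd(opt$ckd)
  vspec <- get_spec(ckd, opt$variable)
  clean <- generate_clean_records(vspec, opt$n, seed = opt$seed)
  cc <- corruption_config(p_unit_typo = opt$p_unit_typo,
                          p_magnitude_error = opt$p_magnitude,
                          p_implausible = opt$p_implausible,
                          seed = opt$seed + 1L)
  dirty <- corrupt_records(clean, vspec, cc)
  readr::write_csv(dirty$records, opt$out, na = "", progress = FALSE)
  if (!is.null(opt$truth_out)) {
    readr::write_csv(dirty$truth, opt$truth_out, na = "", progress = FALSE)
  }
  invisible(dirty)
}
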