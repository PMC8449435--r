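#' Completeness: percentage of missing values
#'
#' The completeness measure is reported as the percentage of missing
#' values (lower = more complete). The pipeline never imputes, so this
#' percentage can only grow from stage to stage.
#'
#' @param values Numeric vector (NA = missing). Must be non-empty.
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' completeness(c(1, 2, NA, 4))  # 25
completeness <- function(values) {
  if (length(values) == 0) stop("empty value list", call. = FALSE)
  100 * mean(is.na(values))
}

#' Correctness: percentage of values within the normal range
#'
#' @param values Numeric vector in the standard unit (NA = missing).
#' @param spec A [variable_spec()].
#' @param denominator `"all"` (default: missing values count in the
#'   denominator but never in the numerator, keeping correctness and
#'   completeness on the same base) or `"non_missing"`.
#' @return Percentage in `[0, 100]` (`NA` if `denominator =
#'   "non_missing"` and everything is missing).
#' @export
#' @examples
#' bp <- variable_spec("BP", "Blood pressure", "mmHg",
#'   units = data.frame(unit_label = "mmHg", rate_to_standard = 1),
#'   normal_range = c(60, 200), extreme_range = c(40, 260))
#' correctness(c(120, 80, 250, NA), bp)  # 50
correctness <- function(values, spec, denominator = c("all", "non_missing")) {
  denominator <- match.arg(denominator)
  if (length(values) == 0) stop("empty value list", call. = FALSE)
  n_normal <- sum(classify_range(values, spec) == "normal", na.rm = TRUE)
  den <- if (denominator == "all") length(values) else sum(!is.na(values))
  if (den == 0) return(NA_real_)
  100 * n_normal / den
}

#' Plausibility: percentage of non-missing values within the extreme range
#'
#' After full cleaning this is 100 by construction: anything outside the
#' biologically plausible range has been removed or corrected into it.
#'
#' @inheritParams correctness
#' @return Percentage of the non-missing values inside the extreme range;
#'   `NA` when every value is missing.
#' @export
#' @examples
#' bp <- variable_spec("BP", "Blood pressure", "mmHg",
#'   units = data.frame(unit_label = "mmHg", rate_to_standard = 1),
#'   normal_range = c(60, 200), extreme_range = c(40, 260))
#' plausibility(c(120, 3000, 250, NA, 90), bp)  # 75
plausibility <- function(values, spec) {
  if (length(values) == 0) stop("empty value list", call. = FALSE)
  n_obs <- sum(!is.na(values))
  if (n_obs == 0) return(NA_real_)
  cls <- classify_range(values, spec)
  100 * sum(cls %in% c("normal", "extreme_but_plausible")) / n_obs
}

qod_stage_names <- c("original", "after_preprocessing", "after_unit_change",
                     "after_all_steps")

# Per-stage counts. `present` overrides the missing definition (at the raw
# stage a cell holding an unparseable token is present, just not normal);
# `comparable` marks values whose unit allows range comparison (pre-
# conversion stages: only values already in the standard unit).
stage_stats <- function(values, spec, comparable = NULL, present = NULL) {
  n <- length(values)
  if (is.null(present)) present <- !is.na(values)
  if (is.null(comparable)) comparable <- rep(TRUE, n)
  cls <- classify_range(values, spec)
  usable <- !is.na(values) & comparable
  list(
    n_total = n,
    n_missing = sum(!present),
    n_normal = sum(usable & cls == "normal"),
    n_plausible = sum(usable & cls %in% c("normal", "extreme_but_plausible"))
  )
}

#' Assemble a per-stage quality-of-data report
#'
#' Takes one snapshot of the value vector after each pipeline stage and
#' tabulates completeness (% missing), correctness (% within the normal
#' range, over all records) and plausibility (% of non-missing values
#' within the extreme range) per stage.
#'
#' @param snapshots Named list of equal-length numeric vectors, one per
#'   stage, in pipeline order; canonical names are `original`,
#'   `after_preprocessing`, `after_unit_change`, `after_all_steps`.
#' @param spec A [variable_spec()].
#' @param comparable Optional named list of logical vectors flagging, for
#'   a stage, which values are expressed in the standard unit and hence
#'   comparable to the ranges (used for pre-conversion stages; values
#'   flagged `FALSE` count as not-normal and not-plausible).
#' @param present Optional named list of logical vectors overriding the
#'   missing definition for a stage (used for the raw stage, where an
#'   unparseable token is present but unusable).
#' @param variable_code,variable_name Identification carried into the
#'   report.
#' @return A `qod_report`: tibble with columns `stage`, `n_total`,
#'   `n_missing`, `n_normal`, `n_plausible`, `pct_missing`, `pct_normal`,
#'   `pct_plausible`.
#' @export
#' @examples
#' bp <- variable_spec("BP", "Blood pressure", "mmHg",
#'   units = data.frame(unit_label = "mmHg", rate_to_standard = 1),
#'   normal_range = c(60, 200), extreme_range = c(40, 260))
#' stage_report(list(original = c(120, 9, 3000),
#'                   after_all_steps = c(120, 90, NA)), bp)
stage_report <- function(snapshots, spec, comparable = list(), present = list(),
                         variable_code = spec$variable_code,
                         variable_name = spec$variable_name) {
  stopifnot(is.list(snapshots), length(snapshots) > 0, inherits(spec, "variable_spec"))
  lens <- lengths(snapshots)
  if (length(unique(lens)) != 1) {
    stop("inconsistent n_total across stages: ", paste(lens, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(names(snapshots), function(st) {
    s <- stage_stats(snapshots[[st]], spec,
                     comparable = comparable[[st]], present = present[[st]])
    tibble(stage = st, n_total = s$n_total, n_missing = s$n_missing,
           n_normal = s$n_normal, n_plausible = s$n_plausible)
  })
  rep <- dplyr::bind_rows(rows)
  rep$pct_missing <- 100 * rep$n_missing / rep$n_total
  rep$pct_normal <- 100 * rep$n_normal / rep$n_total
  n_obs <- rep$n_total - rep$n_missing
  rep$pct_plausible <- ifelse(n_obs > 0, 100 * rep$n_plausible / n_obs, NA_real_)
  structure(rep, class = c("qod_report", class(rep)),
            variable_code = variable_code, variable_name = variable_name)
}

#' @export
print.qod_report <- function(x, ...) {
  cat(sprintf("<qod_report> %s (%s), n = %d\n",
              attr(x, "variable_code"), attr(x, "variable_name"), x$n_total[1]))
  df <- as.data.frame(x)
  df$pct_missing <- sprintf("%.2f", df$pct_missing)
  df$pct_normal <- sprintf("%.2f", df$pct_normal)
  df$pct_plausible <- ifelse(is.na(df$pct_plausible), "-",
                             sprintf("%.2f", df$pct_plausible))
  print(df, row.names = FALSE)
  invisible(x)
}

# One wide CSV row per variable, mirroring the per-stage report layout.
report_row <- function(report) {
  pick <- function(stage, col) {
    i <- match(stage, report$stage)
    if (is.na(i)) NA_real_ else report[[col]][i]
  }
  tibble(
    variable_code = attr(report, "variable_code"),
    test_name = attr(report, "variable_name"),
    n_obs = report$n_total[1],
    miss_original_pct = pick("original", "pct_missing"),
    miss_preproc_pct = pick("after_preprocessing", "pct_missing"),
    miss_unit_pct = pick("after_unit_change", "pct_missing"),
    miss_final_pct = pick("after_all_steps", "pct_missing"),
    correct_original_pct = pick("original", "pct_normal"),
    correct_final_pct = pick("after_all_steps", "pct_normal")
  )
}
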