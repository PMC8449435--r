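#' Convert a value into the variable's standard unit
#'
#' Third pipeline stage. Given the (possibly repaired) unit of a record,
#' rescales the value by the CKD conversion rate into the standard unit:
#'
#' * matched unit accepted — value becomes `value * rate_to_standard`;
#' * empty unit token — under policy `"assume_standard"` (default) the
#'   value is taken to be already in the standard unit and kept; under
#'   `"strict"` it becomes missing with reason `unmatched_unit`;
#' * match rejected (unit present but below the fuzzy threshold) — the
#'   value becomes missing with reason `unmatched_unit`;
#' * missing input — passes through with its original reason.
#'
#' Conversion is a pure multiplication; the CKD schema carries a single
#' rate per unit, so affine transforms (temperature scales) are out of
#' scope.
#'
#' @param value Numeric scalar or `NA`.
#' @param match A `match_result` from [match_unit()], or `NULL`/`""` for a
#'   record whose unit token was empty.
#' @param spec The [variable_spec()].
#' @param policy Empty-unit policy, `"assume_standard"` or `"strict"`.
#' @param reason Reason code accompanying a missing `value` (kept as-is).
#' @return A `standardized_value`: list with `value` (number or `NA`),
#'   `unit` (the standard unit when the value is present), `source_unit`
#'   (matched unit the value came from, or `NA`) and `reason`.
#' @export
#' @examples
#' ckd <- load_ckd(system.file("extdata", "example_ckd.csv", package = "ehrcleanr"))
#' crea <- get_spec(ckd, "57139A.B")
#' m <- match_unit("mmol/L", crea)
#' standardize(1, m, crea)$value  # 11.312 mg/dL
standardize <- function(value, match, spec,
                        policy = c("assume_standard", "strict"),
                        reason = NA_character_) {
  policy <- match.arg(policy)
  stopifnot(inherits(spec, "variable_spec"))
  empty_unit <- is.null(match) ||
    (is.character(match) && !nzchar(collapse_ws(match)))
  if (!empty_unit && !inherits(match, "match_result")) {
    stop("`match` must be a match_result, NULL, or an empty string", call. = FALSE)
  }
  out <- function(v, unit, src, rsn) {
    structure(list(value = v, unit = unit, source_unit = src, reason = rsn),
              class = "standardized_value")
  }
  if (is.na(value)) {
    return(out(NA_real_, NA_character_, NA_character_, reason))
  }
  if (empty_unit) {
    if (policy == "assume_standard") {
      return(out(value, spec$standard_unit, spec$standard_unit, NA_character_))
    }
    return(out(NA_real_, NA_character_, NA_character_, "unmatched_unit"))
  }
  if (!match$accepted) {
    return(out(NA_real_, NA_character_, NA_character_, "unmatched_unit"))
  }
  rate <- rate_to_standard(spec, match$best_candidate)
  out(value * rate, spec$standard_unit, match$best_candidate, NA_character_)
}

# Vectorized standardization used by the pipeline: one fuzzy match per
# distinct unit token, then a rate lookup per record.
standardize_values <- function(values, reasons, units_clean, spec,
                               policy = "assume_standard", threshold = 0.5,
                               method = "matching_blocks") {
  n <- length(values)
  out_value <- values
  out_reason <- reasons
  matched_unit <- rep(NA_character_, n)
  ratio <- rep(NA_real_, n)

  distinct <- unique(units_clean[nzchar(units_clean)])
  matches <- lapply(distinct, match_unit, candidates = spec,
                    threshold = threshold, method = method)
  names(matches) <- distinct

  empty <- !nzchar(units_clean)
  if (policy == "strict") {
    newly <- empty & !is.na(out_value)
    out_value[newly] <- NA_real_
    out_reason[newly] <- "unmatched_unit"
  } else {
    matched_unit[empty & !is.na(out_value)] <- spec$standard_unit
  }
  for (u in distinct) {
    idx <- which(units_clean == u & !is.na(out_value))
    if (length(idx) == 0) {
      ratio[units_clean == u] <- matches[[u]]$ratio
      next
    }
    m <- matches[[u]]
    ratio[units_clean == u] <- m$ratio
    if (m$accepted) {
      out_value[idx] <- out_value[idx] * rate_to_standard(spec, m$best_candidate)
      matched_unit[idx] <- m$best_candidate
    } else {
      out_value[idx] <- NA_real_
      out_reason[idx] <- "unmatched_unit"
    }
  }
  tibble(value = out_value, reason = out_reason,
         matched_unit = matched_unit, unit_ratio = ratio)
}
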