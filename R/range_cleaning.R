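#' Classify a value against a variable's reference ranges
#'
#' `normal` inside the normal range (inclusive), `extreme_but_plausible`
#' inside the extreme range but outside the normal range, `implausible`
#' outside the extreme range. Ranges are in the standard unit, so values
#' must be standardized first.
#'
#' @param value Numeric vector (standard unit). `NA` classifies as `NA`.
#' @param spec A [variable_spec()].
#' @return Character vector over
#'   `{"normal", "extreme_but_plausible", "implausible"}`.
#' @export
#' @examples
#' ckd <- load_ckd(system.file("extdata", "example_ckd.csv", package = "ehrcleanr"))
#' classify_range(c(1.0, 0.2, -1), get_spec(ckd, "57139A.B"))
classify_range <- function(value, spec) {
  stopifnot(inherits(spec, "variable_spec"))
  nr <- spec$normal_range; er <- spec$extreme_range
  out <- rep(NA_character_, length(value))
  ok <- !is.na(value)
  out[ok] <- ifelse(value[ok] >= nr[1] & value[ok] <= nr[2], "normal",
             ifelse(value[ok] >= er[1] & value[ok] <= er[2],
                    "extreme_but_plausible", "implausible"))
  out
}

#' Correct order-of-magnitude errors and remove implausible values
#'
#' Fourth pipeline stage. Values inside the extreme (biologically
#' plausible) range are never touched — a patient with a genuinely extreme
#' result must not be "corrected". A value outside the extreme range is
#' assumed to be a data-entry slip with extra or missing zeros: the
#' power-of-ten shift `value * 10^k`, `k` in `-max_abs_exponent ...
#' max_abs_exponent` excluding 0, that brings it closest to the normal
#' range is applied. If even the best shift leaves the value outside the
#' extreme range, no power of ten can make it plausible and it becomes
#' missing with reason `outlier`.
#'
#' "Closest to the normal range" is the Euclidean distance to the normal
#' interval (zero when inside). Ties prefer the smaller `|k|`, then the
#' negative `k` (dividing away surplus zeros, the archetypal entry error).
#' Negative values for variables whose extreme range is non-negative are
#' sign errors, not magnitude errors, and become `outlier` without any
#' shift attempt. Missing input passes through untouched.
#'
#' The operation is idempotent: every non-missing output lies inside the
#' extreme range and is therefore left alone by a second pass.
#'
#' @param value Numeric vector in the standard unit (may contain `NA`).
#' @param spec A [variable_spec()].
#' @param max_abs_exponent Largest `|k|` searched (default 6).
#' @return Tibble with one row per input: `value` (corrected value or
#'   `NA`), `exponent_applied` (the `k` used, 0 when untouched),
#'   `range_class` (of the output value; `implausible` for removed
#'   values), `reason` (`"outlier"` where the value was removed).
#' @export
#' @examples
#' bp <- variable_spec("BP", "Blood pressure", "mmHg",
#'   units = data.frame(unit_label = "mmHg", rate_to_standard = 1),
#'   normal_range = c(60, 200), extreme_range = c(40, 260))
#' magnitude_correct(c(9, 16000, 3000, 113, 250), bp)
magnitude_correct <- function(value, spec, max_abs_exponent = 6) {
  stopifnot(inherits(spec, "variable_spec"),
            is.numeric(max_abs_exponent), max_abs_exponent >= 1)
  nr <- spec$normal_range; er <- spec$extreme_range
  ks <- setdiff(seq(-max_abs_exponent, max_abs_exponent), 0L)
  # tie order: distance, then |k|, then negative k first
  ks <- ks[order(abs(ks), ks)]

  n <- length(value)
  out_value <- as.numeric(value)
  exponent <- integer(n)
  reason <- rep(NA_character_, n)
  cls <- classify_range(value, spec)

  for (i in which(!is.na(value) & cls == "implausible")) {
    v <- value[i]
    if (v < 0 && er[1] >= 0) {     # sign error, not a magnitude error
      out_value[i] <- NA_real_
      reason[i] <- "outlier"
      next
    }
    shifted <- ifelse(ks > 0, v * 10^ks, v / 10^(-ks))
    dist <- pmax(0, nr[1] - shifted, shifted - nr[2])
    best <- which.min(dist)        # ks already in tie-break order
    if (shifted[best] >= er[1] && shifted[best] <= er[2]) {
      out_value[i] <- shifted[best]
      exponent[i] <- ks[best]
    } else {
      out_value[i] <- NA_real_
      reason[i] <- "outlier"
    }
  }
  tibble(value = out_value,
         exponent_applied = exponent,
         range_class = ifelse(is.na(out_value), cls, classify_range(out_value, spec)),
         reason = reason)
}
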