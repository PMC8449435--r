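#' Coerce untrusted value tokens to numbers
#'
#' Total, deterministic parsing of raw value cells. A token becomes a
#' finite number, or missing with a reason code:
#' * `originally_missing` — the cell was `NA` to begin with;
#' * `meaningless_token` — casefolded token is in the meaningless list
#'   (see [default_meaningless_tokens()]) or contains no digit;
#' * `unparseable_number` — digits are present but no unambiguous numeric
#'   reading exists (e.g. `"1.2.3"`).
#'
#' Parsing strips every character outside `0-9 . , + -` and space, then
#' resolves decimal/grouping marks: when both `.` and `,` occur the
#' rightmost one is the decimal separator and the other a grouping mark; a
#' lone `,` is a decimal separator unless it is followed by exactly three
#' trailing digits (so `"12,5"` is 12.5 but `"16,000"` is 16000, matching
#' how mixed Belgian/anglophone entry conventions appear in primary-care
#' extracts). Internal spaces group digits (`" 1 650 "` is 1650).
#'
#' @param tokens Character vector of raw value cells.
#' @param meaningless Casefolded tokens treated as "no information".
#' @return A tibble with one row per token: `value` (double, `NA` when
#'   missing) and `reason` (character reason code, `NA` when parsed).
#' @export
#' @examples
#' coerce_numeric(c("56.50", "NULL", " 1 650 ", "12,5", "16,000", "1.2.3"))
coerce_numeric <- function(tokens, meaningless = default_meaningless_tokens()) {
  tokens <- as.character(tokens)
  n <- length(tokens)
  value <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)

  is_orig_na <- is.na(tokens)
  reason[is_orig_na] <- "originally_missing"

  t_norm <- casefold(trimws(tokens))
  no_digit <- !is_orig_na & (t_norm %in% meaningless | !grepl("[0-9]", t_norm))
  reason[no_digit] <- "meaningless_token"

  todo <- which(!is_orig_na & !no_digit)
  for (i in todo) {
    v <- parse_numeric_token(t_norm[i])
    if (is.na(v)) reason[i] <- "unparseable_number" else value[i] <- v
  }
  tibble(value = value, reason = reason)
}

parse_numeric_token <- function(s) {
  s <- gsub("[^0-9.,+-]", "", s)  # spaces and junk act as grouping / noise
  sign <- 1
  if (grepl("^[+-]", s)) {
    if (substr(s, 1, 1) == "-") sign <- -1
    s <- substring(s, 2)
  }
  if (grepl("[+-]", s)) return(NA_real_)       # interior sign: ambiguous
  ndot <- nchar(gsub("[^.]", "", s))
  ncom <- nchar(gsub("[^,]", "", s))
  if (ndot > 0 && ncom > 0) {
    last_dot <- max(gregexpr(".", s, fixed = TRUE)[[1]])
    last_com <- max(gregexpr(",", s, fixed = TRUE)[[1]])
    if (last_dot > last_com) {                  # dot decimal, commas group
      if (ndot > 1) return(NA_real_)
      s <- gsub(",", "", s, fixed = TRUE)
    } else {                                    # comma decimal, dots group
      if (ncom > 1) return(NA_real_)
      s <- sub(",", ".", gsub(".", "", s, fixed = TRUE), fixed = TRUE)
    }
  } else if (ncom > 0) {
    if (ncom == 1) {
      if (grepl(",[0-9]{3}$", s)) {             # "16,000" style grouping
        s <- sub(",", "", s, fixed = TRUE)
      } else {
        s <- sub(",", ".", s, fixed = TRUE)     # "12,5" style decimal
      }
    } else if (grepl("^[0-9]{1,3}(,[0-9]{3})+$", s)) {
      s <- gsub(",", "", s, fixed = TRUE)
    } else {
      return(NA_real_)
    }
  } else if (ndot > 1) {
    return(NA_real_)
  }
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v) || !is.finite(v)) NA_real_ else sign * v
}

#' Normalize untrusted unit tokens
#'
#' Trims and collapses internal whitespace, preserving the original
#' casing. Tokens that carry no unit information — empty, all punctuation,
#' all digits, or in the meaningless list — come back as `""`; how an
#' empty unit is treated downstream is the `empty_unit_policy` of
#' [standardize()].
#'
#' @inheritParams coerce_numeric
#' @param tokens Character vector of raw unit cells.
#' @return Character vector of cleaned unit tokens (`""` = no unit).
#' @export
#' @examples
#' clean_unit_token(c(" mmol/L ", "??", "77", "NULL", "mg/dL"))
clean_unit_token <- function(tokens, meaningless = default_meaningless_tokens()) {
  out <- collapse_ws(ifelse(is.na(tokens), "", as.character(tokens)))
  bad <- casefold(out) %in% meaningless |
    !grepl("[[:alnum:]]", out) |       # all punctuation
    grepl("^[0-9]+$", out)             # all digits
  out[bad] <- ""
  out
}

#' Run the preprocessing stage over a record table
#'
#' First pipeline stage: applies [coerce_numeric()] to each configured
#' value column and [clean_unit_token()] to the unit column, and tallies
#' how many values became missing and why. No value is ever imputed, so
#' the number of non-missing values can only shrink.
#'
#' @param records Tibble/data.frame of raw records. Value and unit columns
#'   are read as character tokens; all other columns pass through.
#' @param value_columns Names of the value-token columns to parse
#'   (default `"num1"`).
#' @param unit_column Name of the unit-token column (default `"unit"`);
#'   `NULL` if the table has none.
#' @param meaningless Casefolded meaningless-token list.
#' @return A list with `records` (input plus, per value column `<col>`,
#'   `<col>_value` and `<col>_reason`, and `unit_clean`) and `counters`
#'   (list: `n_records`, per-column newly-missing counts by reason and
#'   `pct_newly_missing`).
#' @export
#' @examples
#' raw <- tibble::tibble(num1 = c("56.50", "na", "1 650", "7,5"),
#'                       unit = c("kg", "kg", "??", "kg"))
#' preprocess_records(raw)$counters
preprocess_records <- function(records, value_columns = "num1",
                               unit_column = "unit",
                               meaningless = default_meaningless_tokens()) {
  records <- as_tibble(records)
  missing_cols <- setdiff(c(value_columns, unit_column), names(records))
  if (length(missing_cols) > 0) {
    stop("input lacks column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(records)
  counters <- list(n_records = n, columns = list())
  for (col in value_columns) {
    parsed <- coerce_numeric(records[[col]], meaningless = meaningless)
    records[[paste0(col, "_value")]] <- parsed$value
    records[[paste0(col, "_reason")]] <- parsed$reason
    by_reason <- table(factor(parsed$reason, levels = c(
      "originally_missing", "meaningless_token", "unparseable_number")))
    counters$columns[[col]] <- list(
      newly_missing = as.list(by_reason),
      n_missing = sum(is.na(parsed$value)),
      pct_newly_missing = if (n > 0) 100 * sum(is.na(parsed$value)) / n else 0
    )
  }
  if (!is.null(unit_column)) {
    records$unit_clean <- clean_unit_token(records[[unit_column]], meaningless = meaningless)
    counters$n_units_blanked <-
      sum(!nzchar(records$unit_clean) &
            !is.na(records[[unit_column]]) & nzchar(trimws(records[[unit_column]])))
  }
  list(records = records, counters = counters)
}
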