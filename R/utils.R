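# Shared string helpers. Unit tokens are normalized in two layers:
# collapse_ws() is the display form (original casing kept), norm_unit()
# additionally casefolds and is the comparison form.

collapse_ws <- function(x) {
  x <- gsub("[[:space:]]+", " ", as.character(x))
  trimws(x)
}

norm_unit <- function(x) casefold(collapse_ws(x))

#' Default list of meaningless tokens
#'
#' Casefolded tokens that denote "no information" in value or unit cells of
#' raw EHR extracts (empty strings, stray punctuation, spelled-out NA/NULL
#' markers). The list is a seed, not an exhaustive enumeration; pass an
#' extended list to [preprocess_records()] or set `meaningless_tokens` in
#' [run_config()] to widen it for a given registry.
#'
#' @return Character vector of casefolded tokens.
#' @export
#' @examples
#' default_meaningless_tokens()
default_meaningless_tokens <- function() {
  c("", ",", ".", "n", "null", "na", "nan", "?", "??", "-")
}

# Render a double as a plain decimal token that coerce_numeric() parses
# back to the same double: shortest representation that round-trips.
render_value <- function(x) {
  render_one <- function(v) {
    if (is.na(v)) return(NA_character_)
    for (d in 1:17) {
      s <- format(v, scientific = FALSE, trim = TRUE, digits = d)
      if (!grepl("[eE]", s) && as.numeric(s) == v) return(s)
    }
    format(v, scientific = FALSE, trim = TRUE, digits = 17)
  }
  vapply(x, render_one, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
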