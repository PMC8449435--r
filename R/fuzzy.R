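#' Levenshtein edit distance
#'
#' Minimum number of single-character deletions, insertions and
#' substitutions turning `a` into `b`. Distances are computed per Unicode
#' code point. Vectorized with recycling.
#'
#' @param a,b Character vectors.
#' @return Integer vector of distances.
#' @export
#' @examples
#' levenshtein("kitten", "sitting")  # 3
#' levenshtein("ab", "")             # 2
levenshtein <- function(a, b) {
  edit_distance_cpp(enc2utf8(as.character(a)), enc2utf8(as.character(b)), 1L)
}

#' Normalized string similarity ratio
#'
#' Length-normalized Levenshtein similarity in `[0, 1]` (1 = identical,
#' 0 = nothing in common). Two normalizations are offered:
#'
#' * `"matching_blocks"` (default): `(|a| + |b| - d2) / (|a| + |b|)` where
#'   `d2` is the edit distance with substitutions costing 2 — equivalently
#'   twice the longest common subsequence over the total length. This is
#'   the `ratio` of the difflib/fuzzywuzzy family and is the package
#'   default for unit matching.
#' * `"printed_formula"`: `1 - d / max(|a|, |b|)` with `d` the plain
#'   Levenshtein distance — the textbook normalization.
#'
#' The two orderings mostly agree but the scores differ, e.g.
#' `similarity_ratio("mmol/LsOms", "mmol/L")` is 0.75 under
#' `matching_blocks` and 0.60 under `printed_formula`.
#'
#' Both are symmetric; a pair of empty strings has ratio 1.
#'
#' @param a,b Character vectors (recycled).
#' @param method Normalization, see above.
#' @return Numeric vector of ratios in `[0, 1]`.
#' @export
#' @examples
#' similarity_ratio("106/L", "X10exp6/L")             # 0.714...
#' similarity_ratio("106/L", "X10exp6/L", "printed_formula")
similarity_ratio <- function(a, b, method = c("matching_blocks", "printed_formula")) {
  method <- match.arg(method)
  a <- enc2utf8(as.character(a)); b <- enc2utf8(as.character(b))
  la <- utf8_length_cpp(a); lb <- utf8_length_cpp(b)
  n <- max(length(a), length(b))
  la <- rep_len(la, n); lb <- rep_len(lb, n)
  if (method == "matching_blocks") {
    d2 <- edit_distance_cpp(a, b, 2L)
    tot <- la + lb
    ifelse(tot == 0, 1, (tot - d2) / tot)
  } else {
    d1 <- edit_distance_cpp(a, b, 1L)
    mx <- pmax(la, lb)
    ifelse(mx == 0, 1, 1 - d1 / mx)
  }
}

#' Fuzzy-match a raw unit string against a variable's admissible units
#'
#' Scores the raw token against every candidate (case-insensitively, on
#' whitespace-normalized forms) and proposes the candidate with the
#' largest similarity ratio. The proposal is accepted when its ratio
#' reaches `threshold` (default 0.5); otherwise the unit is deemed
#' unrecognizable and the match is rejected — downstream this turns the
#' value into missing. An exact (normalized) match returns the stored
#' candidate unchanged with ratio 1.
#'
#' Ties at equal ratio go to the candidate with the smaller plain
#' Levenshtein distance, then to the earlier candidate in the list (specs
#' store the standard unit first, so it wins remaining ties).
#'
#' @param raw_unit One raw unit token.
#' @param candidates Non-empty character vector of admissible unit labels,
#'   or a [variable_spec()] (its unit labels are used).
#' @param threshold Acceptance threshold in `(0, 1]`, default 0.5.
#' @param method Similarity normalization, see [similarity_ratio()].
#' @return A `match_result`: list with `raw_unit`, `best_candidate`,
#'   `ratio`, `accepted`, `method`.
#' @export
#' @examples
#' match_unit("mmol/LsOms", c("mg/dL", "mmol/L"))   # accepted, ratio 0.75
#' match_unit("zzz", c("mg/dL", "mmol/L"))          # rejected
match_unit <- function(raw_unit, candidates, threshold = 0.5,
                       method = c("matching_blocks", "printed_formula")) {
  method <- match.arg(method)
  if (inherits(candidates, "variable_spec")) candidates <- candidates$units$unit_label
  candidates <- as.character(candidates)
  if (length(candidates) == 0) stop("no candidate units", call. = FALSE)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  stopifnot(length(raw_unit) == 1)
  raw_n <- norm_unit(raw_unit)
  cand_n <- norm_unit(candidates)

  exact <- match(raw_n, cand_n)
  if (!is.na(exact)) {
    return(new_match_result(raw_unit, candidates[exact], 1, TRUE, method))
  }
  ratios <- similarity_ratio(raw_n, cand_n, method = method)
  dists <- levenshtein(raw_n, cand_n)
  best <- order(-ratios, dists, seq_along(candidates))[1]
  new_match_result(raw_unit, candidates[best], ratios[best],
                   ratios[best] >= threshold, method)
}

new_match_result <- function(raw_unit, best_candidate, ratio, accepted, method) {
  structure(list(raw_unit = raw_unit, best_candidate = best_candidate,
                 ratio = ratio, accepted = accepted, method = method),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> '%s' -> %s (ratio %.2f, %s, %s)\n",
              x$raw_unit,
              if (is.null(x$best_candidate)) "NA" else sprintf("'%s'", x$best_candidate),
              x$ratio, if (x$accepted) "accepted" else "rejected", x$method))
  invisible(x)
}
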