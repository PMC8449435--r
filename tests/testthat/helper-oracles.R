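# Independent oracles for the string-distance primitives.

# Memo-free recursive edit distance, a direct transcription of the
# textbook recurrence: Lev(V, eps) = |V|, Lev(eps, W) = |W|, otherwise the
# minimum over deletion, insertion and substitution. Exponential on
# purpose — only for short strings.
lev_recursive <- function(a, b, sub_cost = 1L) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    min(rec(i - 1, j) + 1,                                   # deletion
        rec(i, j - 1) + 1,                                   # insertion
        rec(i - 1, j - 1) + (if (av[i] == bv[j]) 0 else sub_cost))
  }
  rec(length(av), length(bv))
}

# The same recurrence evaluated bottom-up and vectorised across many
# string pairs at once: all pairs share the DP table indexed by (i, j),
# with one table cell holding a vector over pairs. Independent of the
# package's per-pair C++ implementation.
lev_batch <- function(a, b, sub_cost = 1L) {
  stopifnot(length(a) == length(b))
  out <- integer(length(a))
  key <- paste(nchar(a), nchar(b))
  for (grp in split(seq_along(a), key)) {
    n <- nchar(a[grp[1]]); m <- nchar(b[grp[1]])
    ca <- if (n > 0) do.call(rbind, lapply(a[grp], utf8ToInt)) else NULL
    cb <- if (m > 0) do.call(rbind, lapply(b[grp], utf8ToInt)) else NULL
    prev <- matrix(rep(0:m, each = length(grp)), nrow = length(grp))
    if (m == 0) prev <- matrix(0L, nrow = length(grp), ncol = 1)
    for (i in seq_len(n)) {
      cur <- matrix(0L, nrow = length(grp), ncol = m + 1)
      cur[, 1] <- i
      for (j in seq_len(m)) {
        sub <- prev[, j] + ifelse(ca[, i] == cb[, j], 0L, sub_cost)
        cur[, j + 1] <- pmin(prev[, j + 1] + 1L, cur[, j] + 1L, sub)
      }
      prev <- cur
    }
    out[grp] <- prev[, m + 1]
  }
  out
}

# All strings of length 0..max_len over an alphabet.
all_strings <- function(alphabet, max_len) {
  out <- ""
  layer <- ""
  for (len in seq_len(max_len)) {
    layer <- as.vector(outer(layer, alphabet, paste0))
    out <- c(out, layer)
  }
  out
}
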