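test_that("edit distance matches the naive recursion on small exhaustive and random pairs", {
  # exhaustive over all strings of length <= 3 on a 3-letter alphabet,
  # against the memo-free recursive transcription of the recurrence
  strs <- all_strings(c("a", "b", "c"), 3)
  pairs <- expand.grid(a = strs, b = strs, stringsAsFactors = FALSE)
  got <- levenshtein(pairs$a, pairs$b)
  want <- mapply(lev_recursive, pairs$a, pairs$b)
  expect_equal(got, unname(want))

  # random longer pairs
  set.seed(1)
  ra <- replicate(200, paste(sample(letters[1:5], sample(0:7, 1), TRUE), collapse = ""))
  rb <- replicate(200, paste(sample(letters[1:5], sample(0:7, 1), TRUE), collapse = ""))
  expect_equal(levenshtein(ra, rb), unname(mapply(lev_recursive, ra, rb)))
})

test_that("edit distance agrees with utils::adist and handles multibyte units", {
  a <- c("kitten", "mmol/L", "106/L", "µmol/L", "", "ab")
  b <- c("sitting", "mmol/LsOms", "X10exp6/L", "mmol/L", "xy", "")
  expect_equal(levenshtein(a, b),
               as.integer(diag(utils::adist(a, b))))
  expect_equal(levenshtein("kitten", "sitting"), 3L)
  expect_equal(levenshtein("ab", ""), 2L)
  expect_equal(levenshtein("", "ab"), 2L)
  expect_equal(levenshtein("abc", "abc"), 0L)
  # per-character, not per-byte: one substitution despite multibyte micro
  expect_equal(levenshtein("µmol/L", "mmol/L"), 1L)
})

test_that("edit distance is a metric", {
  set.seed(7)
  words <- replicate(60, paste(sample(c("m", "o", "l", "/", "L", "g", "d"),
                                      sample(0:6, 1), TRUE), collapse = ""))
  x <- sample(words, 300, TRUE); y <- sample(words, 300, TRUE); z <- sample(words, 300, TRUE)
  dxy <- levenshtein(x, y); dyx <- levenshtein(y, x)
  dyz <- levenshtein(y, z); dxz <- levenshtein(x, z)
  expect_identical(dxy, dyx)                      # symmetry
  expect_true(all((dxy == 0) == (x == y)))        # identity of indiscernibles
  expect_true(all(dxz <= dxy + dyz))              # triangle inequality
})

test_that("similarity ratio reproduces the published unit-check scores", {
  expect_equal(round(similarity_ratio("106/L", "X10exp6/L"), 2), 0.71)
  expect_equal(round(similarity_ratio("mmol/LsOms", "mmol/L"), 2), 0.75)
  # the plain-formula normalization scores the same pairs lower
  expect_equal(similarity_ratio("mmol/LsOms", "mmol/L", "printed_formula"), 0.60)
  expect_equal(round(similarity_ratio("106/L", "X10exp6/L", "printed_formula"), 2), 0.56)
})

test_that("similarity ratio is a bounded symmetric similarity under both normalizations", {
  set.seed(11)
  a <- replicate(200, paste(sample(c(letters[1:6], "/", "%"), sample(0:8, 1), TRUE),
                            collapse = ""))
  b <- replicate(200, paste(sample(c(letters[1:6], "/", "%"), sample(0:8, 1), TRUE),
                            collapse = ""))
  for (m in c("matching_blocks", "printed_formula")) {
    r <- similarity_ratio(a, b, method = m)
    expect_true(all(r >= 0 & r <= 1))
    expect_equal(r, similarity_ratio(b, a, method = m))
    expect_true(all((r == 1) == (a == b)))
    expect_equal(similarity_ratio(a, a, method = m), rep(1, length(a)))
  }
  expect_equal(similarity_ratio("", ""), 1)
  # pure indel pair: matching-blocks charge is exactly the indel count
  expect_equal(similarity_ratio("abcd", "abXcd"), (4 + 5 - 1) / (4 + 5))
  # the normalizations coincide at the degenerate extremes: identical
  # strings (1) and equal-length strings with nothing in common (0)
  for (m in c("matching_blocks", "printed_formula")) {
    expect_equal(similarity_ratio("mg/dL", "mg/dL", method = m), 1)
    expect_equal(similarity_ratio("ab", "cd", method = m), 0)
  }
})

test_that("unit matching accepts typos above threshold and rejects junk", {
  crea <- creatinine_spec()
  m <- match_unit("mmol/LsOms", crea)
  expect_true(m$accepted)
  expect_equal(casefold(m$best_candidate), "mmol/l")
  expect_equal(round(m$ratio, 2), 0.75)

  exact <- match_unit("mmol/L", crea)
  expect_true(exact$accepted)
  expect_equal(exact$ratio, 1)
  expect_equal(exact$best_candidate, "Mmol/L")   # stored casing, unchanged value

  rej <- match_unit("zzz", c("mmol/L", "mg/dL"))
  expect_false(rej$accepted)
  expect_false(is.null(rej$best_candidate))      # best candidate kept for audit
  expect_lt(rej$ratio, 0.5)

  expect_error(match_unit("mmol/L", character()), "no candidate")
  expect_error(match_unit("mmol/L", "mmol/L", threshold = 0), "threshold")
})

test_that("threshold endpoints behave as accept-all / exact-only", {
  cands <- c("mmol/L", "mg/dL")
  # any positive similarity clears a vanishing threshold
  expect_true(match_unit("qqL", cands, threshold = 1e-9)$accepted)
  expect_false(match_unit("mmol/Lx", cands, threshold = 1)$accepted)
  expect_true(match_unit("MMOL/L", cands, threshold = 1)$accepted)  # exact after casefold
})

test_that("ties break on plain distance then candidate order", {
  # "abcxxx" and "axc" both score 2/3 against "abc" under matching
  # blocks, but "axc" is one plain edit away versus three: it must win
  # even though it is listed second
  expect_equal(similarity_ratio("abc", "abcxxx"), 2 / 3)
  expect_equal(similarity_ratio("abc", "axc"), 2 / 3)
  m <- match_unit("abc", c("abcxxx", "axc"), threshold = 0.5)
  expect_equal(m$best_candidate, "axc")

  # full tie (same ratio, same distance): earlier candidate wins, and
  # specs list the standard unit first
  m2 <- match_unit("mg/xL", c("mg/dL", "mg/aL"), threshold = 0.5)
  expect_equal(similarity_ratio("mg/xL", "mg/dL"),
               similarity_ratio("mg/xL", "mg/aL"))
  expect_equal(m2$best_candidate, "mg/dL")
})
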