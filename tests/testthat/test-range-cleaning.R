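test_that("range classification is inclusive and three-way", {
  crea <- creatinine_spec()
  expect_equal(classify_range(c(1.0, 0.2, -1, 0.6, 1.3, 0.1, 5, 5.01, NA), crea),
               c("normal", "extreme_but_plausible", "implausible",
                 "normal", "normal",                    # normal bounds inclusive
                 "extreme_but_plausible", "extreme_but_plausible",
                 "implausible", NA))
})

test_that("magnitude correction reproduces the blood-pressure worked examples", {
  bp <- bp_spec()
  out <- magnitude_correct(c(9, 16000, 3000, 113, 250, 0), bp)
  expect_equal(out$value, c(90, 160, NA, 113, 250, NA))
  expect_equal(out$exponent_applied, c(1, -2, 0, 0, 0, 0))
  expect_equal(out$reason, c(NA, NA, "outlier", NA, NA, "outlier"))
  expect_equal(out$range_class,
               c("normal", "normal", "implausible", "normal",
                 "extreme_but_plausible", "implausible"))
})

test_that("plausible values are never shifted and sign errors are not rescued", {
  bp <- bp_spec()
  # point-B protection: extreme-but-plausible stays untouched
  ex <- magnitude_correct(c(41, 259), bp)
  expect_equal(ex$value, c(41, 259))
  expect_equal(ex$exponent_applied, c(0, 0))
  # negative value against a non-negative extreme range: outlier, no shift
  neg <- magnitude_correct(-50, bp)
  expect_true(is.na(neg$value))
  expect_equal(neg$reason, "outlier")
  # missing input passes through
  expect_true(is.na(magnitude_correct(NA_real_, bp)$value))
})

test_that("every non-missing output lies in the extreme range and the pass is idempotent", {
  set.seed(5)
  ckd <- load_ckd(example_ckd_path())
  for (spec in ckd$specs) {
    er <- spec$extreme_range
    v <- c(runif(100, -er[2] * 10, er[2] * 1e4), 0,
           runif(20, spec$normal_range[1], spec$normal_range[2]))
    out <- magnitude_correct(v, spec)
    kept <- out$value[!is.na(out$value)]
    expect_true(all(kept >= er[1] & kept <= er[2]))
    # shifted values lie inside the extreme range by construction
    shifted <- out$value[out$exponent_applied != 0 & !is.na(out$value)]
    expect_true(all(shifted >= er[1] & shifted <= er[2]))
    again <- magnitude_correct(out$value, spec)
    expect_equal(again$value, out$value)
    expect_true(all(again$exponent_applied == 0))
  }
})

test_that("the chosen exponent matches a brute-force search with the stated tie-breaks", {
  brute <- function(v, spec, kmax = 6) {
    nr <- spec$normal_range; er <- spec$extreme_range
    cls <- classify_range(v, spec)
    if (is.na(v) || cls != "implausible") return(list(value = v, k = 0L))
    if (v < 0 && er[1] >= 0) return(list(value = NA_real_, k = 0L))
    grid <- expand.grid(k = setdiff(-kmax:kmax, 0))
    grid$shifted <- ifelse(grid$k > 0, v * 10^grid$k, v / 10^(-grid$k))
    grid$dist <- pmax(0, nr[1] - grid$shifted, grid$shifted - nr[2])
    grid <- grid[order(grid$dist, abs(grid$k), grid$k), ]
    best <- grid[1, ]
    if (best$shifted >= er[1] && best$shifted <= er[2]) {
      list(value = best$shifted, k = as.integer(best$k))
    } else {
      list(value = NA_real_, k = 0L)
    }
  }
  set.seed(17)
  ckd <- load_ckd(example_ckd_path())
  specs <- ckd$specs
  for (rep in 1:400) {
    spec <- specs[[sample(length(specs), 1)]]
    v <- sample(c(
      runif(1, -1e3, 1e6),
      runif(1, spec$extreme_range[1], spec$extreme_range[2]) *
        10^sample(-4:4, 1)), 1)
    got <- magnitude_correct(v, spec)
    want <- brute(v, spec)
    expect_equal(got$value, want$value, info = sprintf("%s v=%g", spec$variable_code, v))
    expect_equal(got$exponent_applied, want$k)
  }
})

test_that("injected powers of ten are uniquely invertible on narrow-range variables", {
  # extreme max/min < 10 means at most one exponent can land inside the
  # extreme range, so corruption by 10^k is always undone exactly
  hgb <- hgb_spec()
  expect_lt(hgb$extreme_range[2] / hgb$extreme_range[1], 10)
  set.seed(23)
  v <- runif(500, hgb$normal_range[1], hgb$normal_range[2])
  k <- sample(c(-2, -1, 1, 2), 500, replace = TRUE)
  corrupted <- ifelse(k > 0, v * 10^k, v / 10^(-k))
  out <- magnitude_correct(corrupted, hgb)
  expect_equal(out$value, v, tolerance = 1e-9)
  expect_equal(out$exponent_applied, as.integer(-k))
})
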