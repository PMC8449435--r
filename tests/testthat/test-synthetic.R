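test_that("clean record generation is reproducible and in-range", {
  crea <- creatinine_spec()
  a <- generate_clean_records(crea, 100, seed = 7)
  b <- generate_clean_records(crea, 100, seed = 7)
  expect_identical(a, b)
  values <- as.numeric(a$num1)
  expect_true(all(classify_range(values, crea) == "normal"))
  expect_true(all(a$unit == crea$standard_unit))
  expect_error(generate_clean_records(crea, 0, seed = 1), "positive")
  # a different seed gives different values
  expect_false(identical(a$num1, generate_clean_records(crea, 100, seed = 8)$num1))
})

test_that("zero corruption probabilities leave records untouched", {
  crea <- creatinine_spec()
  recs <- generate_clean_records(crea, 30, seed = 1)
  out <- corrupt_records(recs, crea, corruption_config(seed = 2))
  expect_identical(out$records, recs)
  expect_equal(nrow(out$truth), 0)
})

test_that("corruption assigns at most one labelled error per record, reproducibly", {
  crea <- creatinine_spec()
  recs <- generate_clean_records(crea, 400, seed = 3)
  cc <- corruption_config(p_unit_typo = 0.1, p_unit_meaningless = 0.1,
                          p_alternate_valid_unit = 0.1, p_magnitude_error = 0.1,
                          p_implausible = 0.1, p_meaningless_value = 0.1,
                          seed = 4)
  out1 <- corrupt_records(recs, crea, cc)
  out2 <- corrupt_records(recs, crea, cc)
  expect_identical(out1$records, out2$records)
  expect_identical(out1$truth, out2$truth)
  expect_false(anyDuplicated(out1$truth$row) > 0)
  expect_true(all(table(out1$truth$error_type) > 0))
  # labels tell the truth: magnitude rows carry an exponent, others do not
  mag <- out1$truth[out1$truth$error_type == "magnitude_error", ]
  expect_true(all(!is.na(mag$exponent)) && all(mag$exponent != 0))
  expect_true(all(is.na(out1$truth$exponent[out1$truth$error_type != "magnitude_error"])))
  expect_error(corruption_config(p_unit_typo = 0.9, p_magnitude_error = 0.4),
               "sum to at most 1")
})

test_that("implausible plants survive no power-of-ten rescue", {
  ckd <- load_ckd(example_ckd_path())
  for (spec in ckd$specs) {
    v <- ehrcleanr:::implausible_value(spec)
    ks <- -6:6
    shifted <- ifelse(ks >= 0, v * 10^ks, v / 10^(-ks))
    expect_true(all(shifted < spec$extreme_range[1] | shifted > spec$extreme_range[2]),
                info = spec$variable_code)
  }
})

test_that("the pipeline recovers truth from recoverable corruptions", {
  spec <- pressure_two_unit_spec()
  recs <- generate_clean_records(spec, 300, seed = 11)
  cc <- corruption_config(p_unit_typo = 0.15, p_alternate_valid_unit = 0.15,
                          p_magnitude_error = 0.2, seed = 12)
  dirty <- corrupt_records(recs, spec, cc)
  out <- clean_variable(dirty$records, spec)
  truth <- as.numeric(recs$num1)
  expect_equal(out$records$value_clean, truth, tolerance = 1e-9)
})

test_that("implausible and meaningless corruptions always end as reasoned missing", {
  crea <- creatinine_spec()
  recs <- generate_clean_records(crea, 200, seed = 21)
  cc <- corruption_config(p_implausible = 0.15, p_meaningless_value = 0.15, seed = 22)
  dirty <- corrupt_records(recs, crea, cc)
  out <- clean_variable(dirty$records, crea)
  truth <- dirty$truth
  implausible_rows <- truth$row[truth$error_type == "implausible"]
  junk_rows <- truth$row[truth$error_type == "meaningless_value"]
  expect_gt(length(implausible_rows), 0)
  expect_gt(length(junk_rows), 0)
  expect_true(all(out$records$missing_reason[implausible_rows] == "outlier"))
  expect_true(all(out$records$missing_reason[junk_rows] == "meaningless_token"))
  # everything that survives is biologically plausible
  expect_equal(out$report$pct_plausible[4], 100)
})
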