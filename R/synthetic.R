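#' Corruption configuration for the synthetic generator
#'
#' Probabilities of the error types observed in routinely collected
#' measurement data; each record receives at most one corruption
#' (assignment is mutually exclusive, so the probabilities must sum to at
#' most 1).
#'
#' @param p_unit_typo Misspelled unit: 1-2 random character edits.
#' @param p_unit_meaningless Unit replaced by a meaningless token
#'   (`"??"`, `"NULL"`, a bare digit, ...).
#' @param p_alternate_valid_unit Value re-expressed in a valid
#'   non-standard CKD unit, with that unit's label (no information loss —
#'   the pipeline must convert it back).
#' @param p_magnitude_error Value multiplied by `10^k` (entry slip with
#'   extra or missing zeros).
#' @param exponents,exponent_weights Distribution of the injected `k`
#'   (default uniform over plus/minus 1, 2, 3).
#' @param p_implausible Value replaced by one no power-of-ten shift can
#'   bring into the extreme range (a true outlier).
#' @param p_meaningless_value Value token replaced by `"NULL"`-like junk.
#' @param seed Integer RNG seed.
#' @return A `corruption_config` list.
#' @export
corruption_config <- function(p_unit_typo = 0,
                              p_unit_meaningless = 0,
                              p_alternate_valid_unit = 0,
                              p_magnitude_error = 0,
                              exponents = c(-3, -2, -1, 1, 2, 3),
                              exponent_weights = NULL,
                              p_implausible = 0,
                              p_meaningless_value = 0,
                              seed = 1L) {
  p <- c(p_unit_typo, p_unit_meaningless, p_alternate_valid_unit,
         p_magnitude_error, p_implausible, p_meaningless_value)
  if (any(p < 0) || any(p > 1) || sum(p) > 1) {
    stop("corruption probabilities must be in [0, 1] and sum to at most 1",
         call. = FALSE)
  }
  if (is.null(exponent_weights)) exponent_weights <- rep(1, length(exponents))
  stopifnot(length(exponent_weights) == length(exponents), all(exponents != 0))
  structure(list(
    p_unit_typo = p_unit_typo,
    p_unit_meaningless = p_unit_meaningless,
    p_alternate_valid_unit = p_alternate_valid_unit,
    p_magnitude_error = p_magnitude_error,
    exponents = exponents,
    exponent_weights = exponent_weights / sum(exponent_weights),
    p_implausible = p_implausible,
    p_meaningless_value = p_meaningless_value,
    seed = as.integer(seed)
  ), class = "corruption_config")
}

#' Generate clean single-variable records
#'
#' Emits a raw-record-shaped table (patient id, GP id, birth year, sex,
#' test code, date, year, test name, two value tokens, unit token) whose
#' primary values are drawn uniformly within the variable's normal range
#' and whose unit is the standard unit. Uniform sampling maximizes
#' boundary coverage; range membership is all the pipeline inspects, so
#' no attempt is made at a clinically realistic value distribution.
#' Values are rounded to 6 significant digits so the printed token parses
#' back to exactly the intended number.
#'
#' @param spec A [variable_spec()].
#' @param n Number of records (> 0).
#' @param seed Integer RNG seed; the same seed reproduces the same table.
#' @return Tibble of `n` raw records (all token columns character).
#' @export
#' @examples
#' bp <- variable_spec("BP", "Blood pressure", "mmHg",
#'   units = data.frame(unit_label = "mmHg", rate_to_standard = 1),
#'   normal_range = c(60, 200), extreme_range = c(40, 260))
#' generate_clean_records(bp, 3, seed = 7)
generate_clean_records <- function(spec, n, seed) {
  stopifnot(inherits(spec, "variable_spec"))
  if (!is.numeric(n) || n < 1) stop("n must be a positive count", call. = FALSE)
  n <- as.integer(n)
  withr_seed(seed, {
    values <- signif(runif(n, spec$normal_range[1], spec$normal_range[2]), 6)
    year <- sample(1994:2015, n, replace = TRUE)
    tibble(
      patient_id = as.character(sample(10000:99999, n, replace = TRUE)),
      gp_id = paste0("GP_", sample(1:120, n, replace = TRUE)),
      birth_year = as.character(sample(1920:2010, n, replace = TRUE)),
      sex = sample(c("F", "M"), n, replace = TRUE),
      test_code = spec$variable_code,
      date = sprintf("%02d/%02d/%d", sample(1:28, n, TRUE), sample(1:12, n, TRUE), year),
      year = as.character(year),
      test_name = spec$variable_name,
      num1 = render_value(values),
      num2 = "",
      unit = spec$standard_unit
    )
  })
}

# run expr under a local RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Inject labelled corruptions into clean records
#'
#' Applies at most one corruption per record according to the
#' probabilities in `config`, and returns the dirty table together with a
#' ground-truth label per corrupted record (true standard-unit value,
#' error type, injected exponent where applicable). With every
#' probability zero the records come back untouched and the label table
#' is empty.
#'
#' Corruption types: `unit_typo` applies 1-2 random character edits
#' (insertion, deletion, substitution — the same operation alphabet the
#' matcher scores) to the unit; `unit_meaningless` replaces the unit by a
#' junk token; `alternate_valid_unit` re-expresses the value in a valid
#' non-standard CKD unit (for a spec with a single unit this type
#' silently degrades to no corruption and no label); `magnitude_error`
#' multiplies the value by `10^k`; `implausible` plants a value that no
#' `10^k` shift (|k| up to 6) can bring into the extreme range;
#' `meaningless_value` replaces the value token with junk.
#'
#' @param records Clean records from [generate_clean_records()].
#' @param spec The [variable_spec()] the records belong to.
#' @param config A [corruption_config()].
#' @return List with `records` (dirty tibble, same shape and order) and
#'   `truth` (tibble: `row`, `true_value`, `error_type`, `exponent`).
#' @export
corrupt_records <- function(records, spec, config) {
  stopifnot(inherits(spec, "variable_spec"), inherits(config, "corruption_config"))
  records <- as_tibble(records)
  n <- nrow(records)
  types <- c("unit_typo", "unit_meaningless", "alternate_valid_unit",
             "magnitude_error", "implausible", "meaningless_value")
  probs <- c(config$p_unit_typo, config$p_unit_meaningless,
             config$p_alternate_valid_unit, config$p_magnitude_error,
             config$p_implausible, config$p_meaningless_value)
  alt_units <- spec$units$unit_label[
    norm_unit(spec$units$unit_label) != norm_unit(spec$standard_unit)]

  withr_seed(config$seed, {
    u <- runif(n)
    type_idx <- findInterval(u, cumsum(c(0, probs)))
    assigned <- ifelse(type_idx >= 1 & type_idx <= length(types),
                       types[pmin(pmax(type_idx, 1L), length(types))],
                       NA_character_)
    assigned[u >= sum(probs)] <- NA_character_

    truth_rows <- list()
    junk_units <- c("??", "NULL", "77", "1", "xx")
    junk_values <- c("NULL", "na", ",", "n", "-")

    for (i in which(!is.na(assigned))) {
      type <- assigned[i]
      true_value <- as.numeric(records$num1[i])
      exponent <- NA_integer_
      switch(type,
        unit_typo = {
          records$unit[i] <- typo_unit(records$unit[i], sample(1:2, 1))
        },
        unit_meaningless = {
          records$unit[i] <- sample(junk_units, 1)
        },
        alternate_valid_unit = {
          if (length(alt_units) == 0) {
            assigned[i] <- NA_character_
          } else {
            alt <- sample(alt_units, 1)
            rate <- rate_to_standard(spec, alt)
            records$num1[i] <- render_value(true_value / rate)
            records$unit[i] <- alt
          }
        },
        magnitude_error = {
          k <- sample(config$exponents, 1, prob = config$exponent_weights)
          exponent <- as.integer(k)
          shifted <- if (k > 0) true_value * 10^k else true_value / 10^(-k)
          records$num1[i] <- render_value(shifted)
        },
        implausible = {
          records$num1[i] <- render_value(implausible_value(spec))
        },
        meaningless_value = {
          records$num1[i] <- sample(junk_values, 1)
        }
      )
      if (!is.na(assigned[i])) {
        truth_rows[[length(truth_rows) + 1]] <- tibble(
          row = i, true_value = true_value, error_type = assigned[i],
          exponent = exponent)
      }
    }
    truth <- if (length(truth_rows) > 0) {
      dplyr::bind_rows(truth_rows)
    } else {
      tibble(row = integer(), true_value = numeric(),
             error_type = character(), exponent = integer())
    }
    list(records = records, truth = truth)
  })
}

# 1-2 random single-character edits over the characters seen in the label
typo_unit <- function(unit, n_edits) {
  chars <- strsplit(unit, "")[[1]]
  alphabet <- unique(c(chars, letters[1:10]))
  for (e in seq_len(n_edits)) {
    op <- sample(c("del", "ins", "sub"), 1)
    pos <- sample(seq_along(chars), 1)
    chars <- switch(op,
      del = if (length(chars) > 1) chars[-pos] else chars,
      ins = append(chars, sample(alphabet, 1), after = pos),
      sub = { chars[pos] <- sample(alphabet, 1); chars })
  }
  paste(chars, collapse = "")
}

# a value no 10^k shift (|k| <= 6) can bring into the extreme range,
# verified by brute force; falls back to a sign error when the range
# geometry leaves no positive gap
implausible_value <- function(spec, max_abs_exponent = 6) {
  er <- spec$extreme_range
  no_rescue <- function(v) {
    ks <- seq(-max_abs_exponent, max_abs_exponent)
    shifted <- ifelse(ks >= 0, v * 10^ks, v / 10^(-ks))
    all(shifted < er[1] | shifted > er[2])
  }
  mid <- sqrt(max(er[1], .Machine$double.eps) * er[2])
  candidates <- c(
    as.vector(outer(sqrt(10) * c(er[2], mid), 10^(0:3))),
    er[2] * 10^(max_abs_exponent + 1) * 1.5
  )
  for (v in candidates) if (no_rescue(v)) return(v)
  if (er[1] >= 0) return(-abs(er[2] + 1))
  stop("could not construct an implausible value for variable ",
       spec$variable_code, call. = FALSE)
}
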