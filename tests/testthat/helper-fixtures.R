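# Shared fixtures built in code.

example_ckd_path <- function() {
  system.file("extdata", "example_ckd.csv", package = "ehrcleanr")
}

example_raw_path <- function() {
  system.file("extdata", "example_raw_synthetic.csv", package = "ehrcleanr")
}

# Blood-pressure-like spec used throughout the range-cleaning tests.
bp_spec <- function() {
  variable_spec("S00000069", "Blood pressure", "mmHg",
                units = data.frame(unit_label = "mmHg", rate_to_standard = 1),
                normal_range = c(60, 200), extreme_range = c(40, 260))
}

# Narrow-range spec (extreme max/min < 10): the valid power-of-ten
# exponent is unique, so injected magnitude errors are exactly invertible.
hgb_spec <- function() {
  variable_spec("HGB", "Hemoglobin", "g/dL",
                units = data.frame(unit_label = c("g/dL", "g/L"),
                                   rate_to_standard = c(1, 0.1)),
                normal_range = c(12, 16), extreme_range = c(5, 25))
}

# Two well-separated units: a 1-2 character typo on either label cannot
# get closer to the other, so fuzzy repair is unambiguous.
pressure_two_unit_spec <- function() {
  variable_spec("PRES", "Pressure", "mmHg",
                units = data.frame(unit_label = c("mmHg", "kPa"),
                                   rate_to_standard = c(1, 7.5)),
                normal_range = c(60, 200), extreme_range = c(40, 260))
}

creatinine_spec <- function() {
  get_spec(load_ckd(example_ckd_path()), "57139A.B")
}
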