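#' Construct a variable specification
#'
#' A `variable_spec` is one entry of the Clinical Knowledge Database: the
#' curated cleaning rules for a single clinical variable. It carries the
#' admissible units with their multiplicative conversion rates into the
#' standard unit, the normal range (reference interval for healthy
#' individuals) and the extreme range (biologically plausible interval).
#' Both ranges are expressed in the standard unit, because range checks run
#' after unit conversion.
#'
#' @param variable_code Opaque identifier, e.g. `"57139A.B"`. Trimmed.
#' @param variable_name Display name, e.g. `"Creatinine"`.
#' @param standard_unit Unit string every value is converted into. Must
#'   appear in `units` with rate 1.
#' @param units Data frame with columns `unit_label` (character) and
#'   `rate_to_standard` (positive numeric): a value `v` recorded in
#'   `unit_label` equals `v * rate_to_standard` in the standard unit.
#' @param normal_range,extreme_range Numeric length-2 `c(min, max)` with
#'   `min < max`, in the standard unit. The normal range must lie within
#'   the extreme range.
#'
#' @return An object of class `variable_spec`. Units are stored with the
#'   standard unit first (this order breaks exact ties in fuzzy matching);
#'   labels keep their original casing for display but compare casefolded.
#' @export
#' @examples
#' bp <- variable_spec("S00000069", "Blood pressure", "mmHg",
#'   units = data.frame(unit_label = "mmHg", rate_to_standard = 1),
#'   normal_range = c(60, 200), extreme_range = c(40, 260))
#' bp
variable_spec <- function(variable_code, variable_name, standard_unit, units,
                          normal_range, extreme_range) {
  variable_code <- trimws(as.character(variable_code))
  units <- as_tibble(units)[, c("unit_label", "rate_to_standard")]
  units$unit_label <- collapse_ws(units$unit_label)
  units$rate_to_standard <- as.numeric(units$rate_to_standard)
  spec <- structure(
    list(
      variable_code = variable_code,
      variable_name = as.character(variable_name),
      standard_unit = collapse_ws(standard_unit),
      units = units,
      normal_range = as.numeric(normal_range),
      extreme_range = as.numeric(extreme_range)
    ),
    class = "variable_spec"
  )
  validate_spec(spec)
  # standard unit first, remaining units in given order
  is_std <- norm_unit(spec$units$unit_label) == norm_unit(spec$standard_unit)
  spec$units <- spec$units[order(!is_std), , drop = FALSE]
  spec
}

validate_spec <- function(spec) {
  code <- spec$variable_code
  fail <- function(msg) stop(sprintf("variable '%s': %s", code, msg), call. = FALSE)
  if (!nzchar(code)) stop("variable_code must be non-empty", call. = FALSE)
  u <- spec$units
  if (nrow(u) == 0) fail("no units defined")
  if (any(!nzchar(u$unit_label))) fail("empty unit label")
  if (any(is.na(u$rate_to_standard)) || any(u$rate_to_standard <= 0)) {
    fail("conversion rates must be positive numbers")
  }
  if (anyDuplicated(norm_unit(u$unit_label))) fail("duplicated unit label")
  std <- which(norm_unit(u$unit_label) == norm_unit(spec$standard_unit))
  if (length(std) != 1) fail("missing standard-unit row")
  if (abs(u$rate_to_standard[std] - 1) > 1e-12) {
    fail("standard unit must have conversion rate 1")
  }
  n_rate1 <- sum(abs(u$rate_to_standard - 1) <= 1e-12)
  if (n_rate1 != 1) fail("exactly one unit may have conversion rate 1")
  nr <- spec$normal_range; er <- spec$extreme_range
  if (length(nr) != 2 || anyNA(nr) || nr[1] >= nr[2]) fail("normal range must satisfy min < max")
  if (length(er) != 2 || anyNA(er) || er[1] >= er[2]) fail("extreme range must satisfy min < max")
  if (er[1] > nr[1] || nr[2] > er[2]) fail("normal range must lie within extreme range")
  invisible(spec)
}

#' @export
print.variable_spec <- function(x, ...) {
  cat(sprintf("<variable_spec> %s (%s)\n", x$variable_code, x$variable_name))
  cat(sprintf("  standard unit: %s\n", x$standard_unit))
  for (i in seq_len(nrow(x$units))) {
    cat(sprintf("  unit %-12s rate %g\n", x$units$unit_label[i], x$units$rate_to_standard[i]))
  }
  cat(sprintf("  normal range : [%g, %g]\n", x$normal_range[1], x$normal_range[2]))
  cat(sprintf("  extreme range: [%g, %g]\n", x$extreme_range[1], x$extreme_range[2]))
  invisible(x)
}

ckd_csv_columns <- c(
  "variable_code", "variable_name", "unit_label", "rate_to_standard",
  "standard_unit", "normal_min", "normal_max", "extreme_min", "extreme_max"
)

#' Load a Clinical Knowledge Database
#'
#' Reads a CKD file into a validated `ckd_table`. The CSV dialect has one
#' row per (variable, unit) with header
#' `variable_code, variable_name, unit_label, rate_to_standard,
#' standard_unit, normal_min, normal_max, extreme_min, extreme_max`;
#' range and standard-unit cells may be left blank on all but the first
#' row of a variable's block (they are read once per variable). The JSON
#' dialect is a list of spec objects (fields `variable_code`,
#' `variable_name`, `standard_unit`, `units` as a list of
#' `{unit_label, rate_to_standard}`, `normal_range` and `extreme_range`
#' as `{min, max}`), optionally wrapped in
#' `{provenance: ..., specs: [...]}`.
#'
#' A variable whose rows are split into non-adjacent blocks is rejected:
#' the CKD is curated clinical knowledge and a duplicated code is a
#' curation bug, not something to merge silently.
#'
#' @param path File path.
#' @param dialect `"csv"` or `"json"`; default guessed from the extension.
#' @return A `ckd_table`: list with `specs` (named list of
#'   [variable_spec()] objects) and `provenance` (free-text source note).
#' @seealso [write_ckd()], [get_spec()], [rate_to_standard()]
#' @export
#' @examples
#' ckd <- load_ckd(system.file("extdata", "example_ckd.csv", package = "ehrcleanr"))
#' ckd
#' get_spec(ckd, "57139A.B")
load_ckd <- function(path, dialect = c("auto", "csv", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop("CKD file not found: ", path, call. = FALSE)
  specs <- if (dialect == "csv") load_ckd_csv(path) else load_ckd_json(path)
  if (length(specs) == 0) stop("no variables in CKD file: ", path, call. = FALSE)
  new_ckd_table(specs, provenance = paste0("loaded from ", basename(path)))
}

new_ckd_table <- function(specs, provenance = "") {
  codes <- vapply(specs, function(s) s$variable_code, character(1))
  if (anyDuplicated(codes)) {
    stop("duplicate variable codes in CKD: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "), call. = FALSE)
  }
  structure(list(specs = setNames(specs, codes), provenance = provenance),
            class = "ckd_table")
}

load_ckd_csv <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!identical(names(tab), ckd_csv_columns)) {
    stop("CKD CSV header must be exactly: ",
         paste(ckd_csv_columns, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0) stop("no variables in CKD file: ", path, call. = FALSE)
  codes <- trimws(tab$variable_code)
  # non-contiguous repetition of a code = duplicate definition
  runs <- rle(codes)$values
  if (anyDuplicated(runs)) {
    stop("duplicate variable codes in CKD: ",
         paste(unique(runs[duplicated(runs)]), collapse = ", "), call. = FALSE)
  }
  first_filled <- function(x, code, what) {
    x <- x[!is.na(x) & nzchar(trimws(x))]
    if (length(x) == 0) {
      stop(sprintf("variable '%s': missing %s", code, what), call. = FALSE)
    }
    vals <- unique(trimws(x))
    if (length(vals) > 1) {
      stop(sprintf("variable '%s': conflicting %s values (%s)", code, what,
                   paste(vals, collapse = " / ")), call. = FALSE)
    }
    vals
  }
  lapply(split(seq_along(codes), factor(codes, levels = runs)), function(idx) {
    g <- tab[idx, ]
    code <- codes[idx[1]]
    variable_spec(
      variable_code = code,
      variable_name = first_filled(g$variable_name, code, "variable_name"),
      standard_unit = first_filled(g$standard_unit, code, "standard_unit"),
      units = tibble(unit_label = g$unit_label,
                     rate_to_standard = as.numeric(g$rate_to_standard)),
      normal_range = c(as.numeric(first_filled(g$normal_min, code, "normal_min")),
                       as.numeric(first_filled(g$normal_max, code, "normal_max"))),
      extreme_range = c(as.numeric(first_filled(g$extreme_min, code, "extreme_min")),
                        as.numeric(first_filled(g$extreme_max, code, "extreme_max")))
    )
  })
}

load_ckd_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.list(obj) && !is.null(obj$specs)) obj <- obj$specs
  if (length(obj) == 0) stop("no variables in CKD file: ", path, call. = FALSE)
  lapply(obj, function(s) {
    units <- do.call(rbind, lapply(s$units, function(u) {
      data.frame(unit_label = u$unit_label, rate_to_standard = u$rate_to_standard)
    }))
    variable_spec(
      variable_code = s$variable_code,
      variable_name = s$variable_name %||% s$variable_code,
      standard_unit = s$standard_unit,
      units = units,
      normal_range = c(s$normal_range$min, s$normal_range$max),
      extreme_range = c(s$extreme_range$min, s$extreme_range$max)
    )
  })
}

#' Write a Clinical Knowledge Database to disk
#'
#' Serializes a `ckd_table` in either dialect accepted by [load_ckd()];
#' loading the result yields an equivalent table (round-trip stability).
#' The CSV form writes ranges and the standard unit only on the first row
#' of each variable block, mirroring the layout the table is usually
#' curated in.
#'
#' @param ckd A `ckd_table`.
#' @param path Output file path.
#' @param dialect `"csv"` or `"json"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_ckd <- function(ckd, path, dialect = c("auto", "csv", "json")) {
  stopifnot(inherits(ckd, "ckd_table"))
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (dialect == "csv") {
    rows <- lapply(ckd$specs, function(s) {
      n <- nrow(s$units)
      blank_after_first <- function(x) c(x, rep(NA, n - 1))
      tibble(
        variable_code = rep(s$variable_code, n),
        variable_name = blank_after_first(s$variable_name),
        unit_label = s$units$unit_label,
        rate_to_standard = s$units$rate_to_standard,
        standard_unit = blank_after_first(s$standard_unit),
        normal_min = blank_after_first(s$normal_range[1]),
        normal_max = blank_after_first(s$normal_range[2]),
        extreme_min = blank_after_first(s$extreme_range[1]),
        extreme_max = blank_after_first(s$extreme_range[2])
      )
    })
    readr::write_csv(dplyr::bind_rows(rows), path, na = "", progress = FALSE)
  } else {
    specs <- lapply(unname(ckd$specs), function(s) {
      list(
        variable_code = s$variable_code,
        variable_name = s$variable_name,
        standard_unit = s$standard_unit,
        units = lapply(seq_len(nrow(s$units)), function(i) {
          list(unit_label = s$units$unit_label[i],
               rate_to_standard = s$units$rate_to_standard[i])
        }),
        normal_range = list(min = s$normal_range[1], max = s$normal_range[2]),
        extreme_range = list(min = s$extreme_range[1], max = s$extreme_range[2])
      )
    })
    jsonlite::write_json(list(provenance = ckd$provenance, specs = specs),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @export
print.ckd_table <- function(x, ...) {
  cat(sprintf("<ckd_table> %d variable(s)\n", length(x$specs)))
  for (s in x$specs) {
    cat(sprintf("  %-12s %-20s %d unit(s), normal [%g, %g], extreme [%g, %g]\n",
                s$variable_code, s$variable_name, nrow(s$units),
                s$normal_range[1], s$normal_range[2],
                s$extreme_range[1], s$extreme_range[2]))
  }
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Look up one variable's cleaning rules
#'
#' @param ckd A `ckd_table` from [load_ckd()].
#' @param variable_code Code to look up; surrounding whitespace is ignored.
#' @return The matching [variable_spec()].
#' @export
#' @examples
#' ckd <- load_ckd(system.file("extdata", "example_ckd.csv", package = "ehrcleanr"))
#' get_spec(ckd, " 57139A.B ")$variable_name
get_spec <- function(ckd, variable_code) {
  stopifnot(inherits(ckd, "ckd_table"))
  code <- trimws(variable_code)
  spec <- ckd$specs[[code]]
  if (is.null(spec)) {
    stop(sprintf("unknown variable code '%s' (CKD has: %s)", code,
                 paste(names(ckd$specs), collapse = ", ")), call. = FALSE)
  }
  spec
}

#' Conversion rate from a unit into the variable's standard unit
#'
#' Returns the multiplicative factor `r` such that a value recorded in
#' `unit_label` equals `value * r` in the standard unit. The standard unit
#' itself returns exactly 1. Lookup is case-insensitive on
#' whitespace-normalized labels.
#'
#' @param spec A [variable_spec()].
#' @param unit_label Unit string, one of the spec's units.
#' @return Positive numeric scalar.
#' @export
#' @examples
#' ckd <- load_ckd(system.file("extdata", "example_ckd.csv", package = "ehrcleanr"))
#' rate_to_standard(get_spec(ckd, "57139A.B"), "mmol/L")  # creatinine: 11.312
rate_to_standard <- function(spec, unit_label) {
  stopifnot(inherits(spec, "variable_spec"))
  i <- match(norm_unit(unit_label), norm_unit(spec$units$unit_label))
  if (is.na(i)) {
    stop(sprintf("unit '%s' is not a known unit of variable '%s'",
                 unit_label, spec$variable_code), call. = FALSE)
  }
  spec$units$rate_to_standard[i]
}
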