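#' Read and write admission-level registry tables
#'
#' The on-disk format is a UTF-8 CSV with a fixed header (one admission per
#' row, `.` decimal separator). Enumerated fields use lower-snake-case tokens
#' (`admission_type`: medical / urgent_surgery / elective_surgery;
#' `discharge_destination`: ward / other_icu / outside_hospital / died;
#' `diag_group`: CAP / sepsis / OHCA / other), flags are written as
#' TRUE/FALSE, and `readmitted_48h` is `NA` for admissions outside the
#' readmission risk set. `read_registry()` validates the table and reports
#' offending rows and columns; `write_registry()` then `read_registry()` is a
#' field-for-field identity.
#'
#' @param admissions Tibble of admissions, as produced by
#'   [simulate_registry()] (the `admissions` element).
#' @param path File path.
#' @return `write_registry()` returns `path` invisibly; `read_registry()`
#'   returns the validated admissions tibble.
#' @export
#' @examples
#' reg <- simulate_registry(registry_params(n_icus = 2, icu_sizes = c(5, 5)))
#' f <- tempfile(fileext = ".csv")
#' write_registry(reg$admissions, f)
#' identical(read_registry(f), reg$admissions)  # TRUE
write_registry <- function(admissions, path) {
  validate_admissions(admissions)
  readr::write_csv(admissions[, registry_columns()], path, na = "NA")
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  spec <- readr::cols(
    admission_id = readr::col_character(),
    icu_id = readr::col_character(),
    admission_type = readr::col_character(),
    diag_group = readr::col_character(),
    cardiac_surgery = readr::col_logical(),
    apache_excluded = readr::col_logical(),
    covariates_missing = readr::col_logical(),
    p_mort_raw = readr::col_double(),
    x1 = readr::col_double(), x2 = readr::col_double(),
    x3 = readr::col_double(), x4 = readr::col_double(),
    died_in_icu = readr::col_logical(),
    died_in_hospital = readr::col_logical(),
    discharge_destination = readr::col_character(),
    icu_los_days = readr::col_double(),
    readmitted_48h = readr::col_logical())
  adm <- readr::read_csv(path, col_types = spec, progress = FALSE)
  validate_admissions(adm)
}

validate_admissions <- function(adm) {
  missing_cols <- setdiff(registry_columns(), names(adm))
  if (length(missing_cols) > 0)
    abort_icubench(
      sprintf("Registry table is missing required column(s): %s.",
              paste(missing_cols, collapse = ", ")),
      "icubench_bad_registry")
  check_enum <- function(column, allowed) {
    bad <- which(!adm[[column]] %in% allowed)
    if (length(bad) > 0)
      abort_icubench(
        sprintf("Unknown token '%s' in column `%s` (first at row %d).",
                adm[[column]][bad[1]], column, bad[1]),
        "icubench_bad_registry")
  }
  check_enum("admission_type", admission_types)
  check_enum("diag_group", diag_groups)
  check_enum("discharge_destination", discharge_destinations)
  bad_los <- which(!(adm$icu_los_days > 0))
  if (length(bad_los) > 0)
    abort_icubench(
      sprintf("`icu_los_days` must be > 0 (violated first at row %d).",
              bad_los[1]),
      "icubench_bad_registry")
  bad_p <- which(!(adm$p_mort_raw > 0 & adm$p_mort_raw < 1))
  if (length(bad_p) > 0)
    abort_icubench(
      sprintf("`p_mort_raw` must lie in (0, 1) (violated first at row %d).",
              bad_p[1]),
      "icubench_bad_registry")
  bad_death <- which(adm$died_in_icu &
                       (!adm$died_in_hospital |
                          adm$discharge_destination != "died"))
  if (length(bad_death) > 0)
    abort_icubench(
      sprintf(paste0("ICU death implies in-hospital death and discharge ",
                     "destination 'died' (violated first at row %d)."),
              bad_death[1]),
      "icubench_bad_registry")
  adm
}
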