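#' Apply the admission exclusion cascade
#'
#' Builds the analysis cohort by removing, in order: cardiac-surgery
#' admissions, admissions excluded by the severity model's criteria,
#' admissions discharged to another ICU (their observed length of stay is
#' truncated), and admissions with missing model covariates. An admission
#' matching several rules is counted under the first matching rule, so the
#' exclusion log reads like a patient-flow diagram: counts sum exactly to
#' input minus retained.
#'
#' @param admissions Admissions tibble (see [read_registry()] for the
#'   column contract).
#' @return An object of class `icu_cohort`: a list with
#'   * `admissions`: the retained admissions tibble;
#'   * `exclusion_log`: tibble (`rule`, `n_excluded`) in application order;
#'   * `risk_set_ids`: `NULL` until [readmission_risk_set()] is applied.
#' @export
#' @examples
#' reg <- simulate_registry(registry_params(n_icus = 2, icu_sizes = c(50, 50)))
#' coh <- apply_exclusions(reg$admissions)
#' coh$exclusion_log
apply_exclusions <- function(admissions) {
  if (nrow(admissions) == 0)
    abort_icubench("Cannot build a cohort from an empty admission table.",
                   "icubench_empty_input")
  validate_admissions(admissions)
  rules <- list(
    cardiac_surgery = admissions$cardiac_surgery,
    apache_excluded = admissions$apache_excluded,
    transfer_other_icu = admissions$discharge_destination == "other_icu",
    covariates_missing = admissions$covariates_missing)
  claimed <- rep(FALSE, nrow(admissions))
  log <- purrr::imap(rules, function(hit, rule) {
    newly <- hit & !claimed
    claimed <<- claimed | hit
    tibble::tibble(rule = rule, n_excluded = sum(newly))
  })
  structure(
    list(admissions = admissions[!claimed, , drop = FALSE],
         exclusion_log = dplyr::bind_rows(log),
         risk_set_ids = NULL),
    class = "icu_cohort")
}

#' Construct the 48-hour readmission risk set
#'
#' Admissions are eligible for the readmission outcome only when the patient
#' survived the initial ICU stay and was discharged to a ward within the same
#' hospital; ICU deaths and discharges to a location outside the hospital are
#' not at risk of an observable 48-h ICU readmission.
#'
#' @param cohort An `icu_cohort` from [apply_exclusions()].
#' @return The cohort with `risk_set_ids` populated (possibly empty).
#' @export
readmission_risk_set <- function(cohort) {
  stopifnot(inherits(cohort, "icu_cohort"))
  adm <- cohort$admissions
  eligible <- !adm$died_in_icu & adm$discharge_destination == "ward"
  cohort$risk_set_ids <- adm$admission_id[eligible]
  cohort
}

#' Assign every retained admission to its report subgroups
#'
#' Each admission belongs to `all`, to exactly one admission-type subgroup
#' (medical / urgent_surgery / elective_surgery), to exactly one mortality
#' risk stratum based on the *recalibrated* death probability —
#' `risk_low` = [0, 0.3), `risk_medium` = [0.3, 0.7), `risk_high` = [0.7, 1],
#' boundary values falling in the upper stratum — and optionally to one
#' diagnostic subgroup (CAP / sepsis / OHCA).
#'
#' @param cohort An `icu_cohort`.
#' @param recalibrated_p Recalibrated death probability for every retained
#'   admission, in cohort row order (from [recalibrate_mortality()]).
#' @param cutpoints Risk-stratum boundaries, strictly increasing in (0, 1).
#' @return Long tibble (`admission_id`, `subgroup`), one row per membership.
#' @export
assign_subgroups <- function(cohort, recalibrated_p,
                             cutpoints = c(0.3, 0.7)) {
  stopifnot(inherits(cohort, "icu_cohort"))
  adm <- cohort$admissions
  if (length(recalibrated_p) != nrow(adm))
    abort_icubench(
      "`recalibrated_p` must have one value per retained admission.",
      "icubench_bad_probability")
  if (any(recalibrated_p < 0 | recalibrated_p > 1 | is.na(recalibrated_p)))
    abort_icubench("Recalibrated probabilities must lie in [0, 1].",
                   "icubench_bad_probability")
  stopifnot(length(cutpoints) == 2, diff(cutpoints) > 0,
            all(cutpoints > 0 & cutpoints < 1))
  stratum <- dplyr::case_when(
    recalibrated_p < cutpoints[1] ~ "risk_low",
    recalibrated_p < cutpoints[2] ~ "risk_medium",
    TRUE ~ "risk_high")
  dplyr::bind_rows(
    tibble::tibble(admission_id = adm$admission_id, subgroup = "all"),
    tibble::tibble(admission_id = adm$admission_id,
                   subgroup = adm$admission_type),
    tibble::tibble(admission_id = adm$admission_id, subgroup = stratum),
    tibble::tibble(admission_id = adm$admission_id,
                   subgroup = adm$diag_group) |>
      dplyr::filter(.data$subgroup != "other"))
}

#' @export
print.icu_cohort <- function(x, ...) {
  n_in <- nrow(x$admissions) + sum(x$exclusion_log$n_excluded)
  cat(sprintf("ICU cohort: %d of %d admissions retained (%.1f%%)\n",
              nrow(x$admissions), n_in, 100 * nrow(x$admissions) / n_in))
  for (i in seq_len(nrow(x$exclusion_log)))
    cat(sprintf("  excluded by %s: %d\n", x$exclusion_log$rule[i],
                x$exclusion_log$n_excluded[i]))
  if (!is.null(x$risk_set_ids))
    cat(sprintf("  readmission risk set: %d admissions\n",
                length(x$risk_set_ids)))
  invisible(x)
}

#' Export the exclusion log as JSON
#'
#' @param cohort An `icu_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(cohort, path) {
  stopifnot(inherits(cohort, "icu_cohort"))
  counts <- as.list(stats::setNames(cohort$exclusion_log$n_excluded,
                                    cohort$exclusion_log$rule))
  counts$retained <- nrow(cohort$admissions)
  jsonlite::write_json(counts, path, auto_unbox = TRUE)
  invisible(path)
}
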