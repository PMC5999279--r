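#' Fixed-effect case-mix models
#'
#' Step 1 of the two-step benchmarking procedure: three fixed-effect models
#' fitted once on the full cohort give every admission an expected outcome
#' under average unit performance. These expectations are reused unchanged in
#' every subgroup, so subgroup mixed models never refit the case-mix
#' adjustment on sparse data.
#'
#' * `recalibrate_mortality()` — logistic recalibration (intercept and slope)
#'   of the supplied severity-of-illness probability against observed
#'   in-hospital death: `death ~ qlogis(p_mort_raw)`.
#' * `fit_readmission_model()` — logistic regression of the 48-h readmission
#'   flag on first-24-hour covariates, fitted on the readmission risk set.
#' * `fit_los_model()` — ordinary least squares on `log(icu_los_days)`
#'   against the covariates; day-scale expectations are recovered with
#'   Duan's smearing factor (the mean of the exponentiated residuals), which
#'   is consistent without assuming normal log-scale errors.
#'
#' Each fit carries the model-performance metrics used for reporting: scaled
#' Brier score and C-statistic for the binary models, squared Pearson
#' correlation between predicted and observed day-scale length of stay for
#' the LOS model, and a 50-group calibration table for all three.
#'
#' @param cohort An `icu_cohort` (for `fit_readmission_model()` it must have
#'   been through [readmission_risk_set()]).
#' @param covariates Names of the covariate columns used by the readmission
#'   and LOS models (configurable; default the generator's `x1`--`x4`).
#' @param n_calibration_groups Groups in the calibration table.
#' @return An object of class `casemix_fit`: list with `outcome`, `link`,
#'   `coefficients`, `predictions` (tibble `admission_id`, `.pred` over the
#'   model's population), `metrics` (list `scaled_brier`, `c_statistic`,
#'   `r_squared`, `calibration_table`), and the underlying `model`.
#' @name casemix
NULL

#' @rdname casemix
#' @export
#' @examples
#' reg <- simulate_registry(registry_params(n_icus = 4,
#'                                          icu_sizes = rep(400, 4)))
#' coh <- readmission_risk_set(apply_exclusions(reg$admissions))
#' fit <- recalibrate_mortality(coh)
#' glance(fit)
recalibrate_mortality <- function(cohort, n_calibration_groups = 50) {
  stopifnot(inherits(cohort, "icu_cohort"))
  adm <- cohort$admissions
  lp <- logit(adm$p_mort_raw)
  if (stats::var(lp) == 0)
    abort_icubench(
      "Severity probability is constant: the recalibration slope is not identifiable.",
      "icubench_constant_covariate")
  fit <- stats::glm(adm$died_in_hospital ~ lp, family = stats::binomial())
  check_logistic_fit(fit, "mortality recalibration")
  new_casemix_fit("mortality", fit, adm$admission_id,
                  stats::fitted(fit), adm$died_in_hospital,
                  n_calibration_groups)
}

#' @rdname casemix
#' @export
fit_readmission_model <- function(cohort, covariates = paste0("x", 1:4),
                                  n_calibration_groups = 50) {
  stopifnot(inherits(cohort, "icu_cohort"))
  if (is.null(cohort$risk_set_ids))
    abort_icubench(
      "Run readmission_risk_set() before fitting the readmission model.",
      "icubench_no_risk_set")
  rs <- cohort$admissions[cohort$admissions$admission_id %in%
                            cohort$risk_set_ids, , drop = FALSE]
  if (nrow(rs) == 0)
    abort_icubench("The readmission risk set is empty.",
                   "icubench_empty_risk_set")
  form <- stats::reformulate(covariates, response = "readmitted_48h")
  fit <- stats::glm(form, data = rs, family = stats::binomial())
  check_logistic_fit(fit, "readmission model")
  new_casemix_fit("readmission", fit, rs$admission_id,
                  stats::fitted(fit), as.numeric(rs$readmitted_48h),
                  n_calibration_groups)
}

#' @rdname casemix
#' @export
fit_los_model <- function(cohort, covariates = paste0("x", 1:4),
                          n_calibration_groups = 50) {
  stopifnot(inherits(cohort, "icu_cohort"))
  adm <- cohort$admissions
  form <- stats::reformulate(covariates, response = "log(icu_los_days)")
  fit <- stats::lm(form, data = adm)
  smear <- mean(exp(stats::residuals(fit)))
  pred_days <- exp(stats::fitted(fit)) * smear
  out <- new_casemix_fit("los", fit, adm$admission_id, pred_days,
                         adm$icu_los_days, n_calibration_groups)
  out$smearing_factor <- smear
  out
}

check_logistic_fit <- function(fit, label) {
  if (!fit$converged)
    abort_icubench(sprintf("The %s did not converge.", label),
                   "icubench_nonconvergence")
  p <- stats::fitted(fit)
  if (all(p < 1e-10 | p > 1 - 1e-10))
    abort_icubench(
      sprintf("The %s is completely separated: all fitted probabilities are 0 or 1.",
              label),
      "icubench_separation")
  invisible(fit)
}

new_casemix_fit <- function(outcome, model, ids, pred, obs, n_groups) {
  metrics <- if (outcome == "los") {
    list(scaled_brier = NULL, c_statistic = NULL,
         r_squared = suppressWarnings(stats::cor(pred, obs)^2),
         calibration_table = calibration_groups(pred, obs, n_groups))
  } else {
    list(scaled_brier = scaled_brier(pred, obs),
         c_statistic = c_statistic(pred, obs),
         r_squared = NULL,
         calibration_table = calibration_groups(pred, obs, n_groups))
  }
  structure(
    list(outcome = outcome,
         link = if (outcome == "los") "log" else "logit",
         coefficients = stats::coef(model),
         predictions = tibble::tibble(admission_id = ids,
                                      .pred = unname(pred)),
         metrics = metrics,
         model = model),
    class = "casemix_fit")
}

#' @export
print.casemix_fit <- function(x, ...) {
  cat(sprintf("Case-mix model (%s, %s link): %d admissions\n",
              x$outcome, x$link, nrow(x$predictions)))
  if (x$outcome == "los")
    cat(sprintf("  R-squared (day scale): %.3f\n", x$metrics$r_squared))
  else
    cat(sprintf("  scaled Brier: %.3f, C-statistic: %.3f\n",
                x$metrics$scaled_brier, x$metrics$c_statistic))
  invisible(x)
}
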