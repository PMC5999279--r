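#' Parameters of the synthetic ICU registry generator
#'
#' Bundles every knob of the synthetic admission-level registry: number and
#' sizes of ICUs, the unit-level random-effect standard deviations for the
#' three outcomes (with their cross-outcome correlation), marginal targets for
#' the crude outcome rates, the length-of-stay baseline, exclusion-flag rates
#' and the subgroup mix. Defaults emulate a national ICU registry year:
#' 83 units of 205--2,282 admissions, crude in-hospital mortality 14.3%,
#' 48-hour readmission 2.4% among the risk set, right-skewed fractional-day
#' length of stay (median about 1.2 d, mean about 3.3 d) and an exclusion
#' cascade retaining about 82% of admissions.
#'
#' @param n_icus Number of ICUs.
#' @param icu_sizes Integer vector of admissions per ICU. If `NULL`, sizes are
#'   drawn uniformly from `icu_size_range` when the registry is simulated.
#' @param icu_size_range Length-2 integer range for random ICU sizes.
#' @param sd_mort,sd_readm Standard deviations of the unit random intercepts
#'   for in-hospital mortality and 48-h readmission, on the logit scale.
#' @param sd_los Standard deviation of the unit random intercept for ICU
#'   length of stay, in days (the unit effect is additive on the day scale).
#' @param effect_corr 3x3 correlation matrix of the unit effects, ordered
#'   (mortality, readmission, length of stay). Must be symmetric positive
#'   semi-definite with unit diagonal.
#' @param target_crude_mortality Target crude in-hospital mortality.
#' @param target_readmission_rate Target 48-h readmission rate in the risk set.
#' @param los_meanlog,los_sdlog Log-scale location and scale of the
#'   length-of-stay baseline (fractional days).
#' @param severity_sdlogit Spread of the severity-of-illness probability on
#'   the logit scale; larger values give a more right-skewed risk mix.
#' @param sd_severity_shift Standard deviation of an optional per-ICU shift of
#'   mean severity (logit scale); 0 means identical case mix in every unit.
#' @param exclusion_rates Named list of proportions for the exclusion-relevant
#'   fields: `cardiac_surgery`, `apache_excluded`, `transfer_other_icu`
#'   (probability that an ICU survivor is discharged to another ICU) and
#'   `covariates_missing`.
#' @param p_death_in_icu Probability that an in-hospital death occurs during
#'   the ICU stay (the rest die on the ward after ICU discharge).
#' @param p_outside_hospital Probability that an ICU survivor (not transferred)
#'   is discharged directly to a location outside the hospital.
#' @param admission_type_mix Named proportions over
#'   medical / urgent_surgery / elective_surgery.
#' @param diag_group_mix Named proportions over CAP / sepsis / OHCA / other.
#' @param beta_readm Coefficients of the four admission covariates in the
#'   readmission-generating logistic model (intercept is calibrated to
#'   `target_readmission_rate`).
#' @param beta_los Coefficients of the four admission covariates on the
#'   log length-of-stay scale.
#' @param seed Integer seed governing every random draw of the generator.
#'
#' @return An object of class `registry_params` (a validated named list).
#' @seealso [simulate_registry()]
#' @export
#' @examples
#' p <- registry_params(n_icus = 5, icu_sizes = rep(50, 5), seed = 1)
#' p$n_icus
registry_params <- function(n_icus = 83,
                            icu_sizes = NULL,
                            icu_size_range = c(205L, 2282L),
                            sd_mort = 0.2,
                            sd_readm = 0.3,
                            sd_los = 0.4,
                            effect_corr = diag(3),
                            target_crude_mortality = 0.143,
                            target_readmission_rate = 0.024,
                            los_meanlog = log(1.2),
                            los_sdlog = 1.39,
                            severity_sdlogit = 1.7,
                            sd_severity_shift = 0,
                            exclusion_rates = list(cardiac_surgery = 0.04,
                                                   apache_excluded = 0.10,
                                                   transfer_other_icu = 0.03,
                                                   covariates_missing = 0.02),
                            p_death_in_icu = 0.7,
                            p_outside_hospital = 0.10,
                            admission_type_mix = c(medical = 0.55,
                                                   urgent_surgery = 0.20,
                                                   elective_surgery = 0.25),
                            diag_group_mix = c(CAP = 0.05, sepsis = 0.08,
                                               OHCA = 0.04, other = 0.83),
                            beta_readm = c(0.30, -0.20, 0.15, 0),
                            beta_los = c(0.25, 0.15, 0, 0.10),
                            seed = 1L) {
  num <- as.numeric  # canonical double storage, so serialization round-trips
  params <- list(
    n_icus = as.integer(n_icus),
    icu_sizes = if (is.null(icu_sizes)) NULL else as.integer(icu_sizes),
    icu_size_range = as.integer(icu_size_range),
    sd_mort = num(sd_mort), sd_readm = num(sd_readm), sd_los = num(sd_los),
    effect_corr = if (is.matrix(effect_corr))
      matrix(num(effect_corr), nrow(effect_corr)) else effect_corr,
    target_crude_mortality = num(target_crude_mortality),
    target_readmission_rate = num(target_readmission_rate),
    los_meanlog = num(los_meanlog), los_sdlog = num(los_sdlog),
    severity_sdlogit = num(severity_sdlogit),
    sd_severity_shift = num(sd_severity_shift),
    exclusion_rates = lapply(exclusion_rates, num),
    p_death_in_icu = num(p_death_in_icu),
    p_outside_hospital = num(p_outside_hospital),
    admission_type_mix = stats::setNames(num(admission_type_mix),
                                         names(admission_type_mix)),
    diag_group_mix = stats::setNames(num(diag_group_mix),
                                     names(diag_group_mix)),
    beta_readm = num(beta_readm), beta_los = num(beta_los),
    seed = as.integer(seed))
  class(params) <- "registry_params"
  validate_registry_params(params)
}

validate_registry_params <- function(p) {
  stopifnot(is.list(p))
  if (!is.null(p$icu_sizes)) {
    if (length(p$icu_sizes) != p$n_icus)
      abort_icubench("`icu_sizes` must have length `n_icus`.",
                     "icubench_bad_params")
    if (length(p$icu_sizes) == 0L || any(p$icu_sizes < 1))
      abort_icubench("`icu_sizes` must be non-empty with every size >= 1.",
                     "icubench_bad_params")
  }
  if (p$n_icus < 1)
    abort_icubench("`n_icus` must be >= 1.", "icubench_bad_params")
  if (any(c(p$sd_mort, p$sd_readm, p$sd_los, p$sd_severity_shift) < 0))
    abort_icubench("Random-effect standard deviations must be >= 0.",
                   "icubench_bad_params")
  props <- c(p$target_crude_mortality, p$target_readmission_rate,
             unlist(p$exclusion_rates), p$p_death_in_icu,
             p$p_outside_hospital, p$admission_type_mix, p$diag_group_mix)
  if (any(props < 0 | props > 1))
    abort_icubench("All proportions must lie in [0, 1].",
                   "icubench_bad_params")
  C <- p$effect_corr
  if (!is.matrix(C) || !identical(dim(C), c(3L, 3L)) ||
      max(abs(C - t(C))) > 1e-12 || max(abs(diag(C) - 1)) > 1e-12)
    abort_icubench(
      "`effect_corr` must be a symmetric 3x3 matrix with unit diagonal.",
      "icubench_bad_corr")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    abort_icubench(
      sprintf("`effect_corr` is not positive semi-definite (min eigenvalue %.3g).",
              min(ev)),
      "icubench_bad_corr")
  for (nm in c("cardiac_surgery", "apache_excluded", "transfer_other_icu",
               "covariates_missing"))
    if (is.null(p$exclusion_rates[[nm]]))
      abort_icubench(sprintf("`exclusion_rates` is missing `%s`.", nm),
                     "icubench_bad_params")
  p
}

#' @export
print.registry_params <- function(x, ...) {
  sizes <- if (is.null(x$icu_sizes))
    sprintf("drawn from [%d, %d]", x$icu_size_range[1], x$icu_size_range[2])
  else sprintf("fixed (total %d)", sum(x$icu_sizes))
  cat("Synthetic ICU registry parameters\n")
  cat(sprintf("  ICUs: %d, sizes %s\n", x$n_icus, sizes))
  cat(sprintf("  unit-effect SDs (mort/readm logit, LOS days): %.2f / %.2f / %.2f\n",
              x$sd_mort, x$sd_readm, x$sd_los))
  cat(sprintf("  targets: crude mortality %.1f%%, risk-set readmission %.1f%%\n",
              100 * x$target_crude_mortality, 100 * x$target_readmission_rate))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Mean-matching location for a logit-normal distribution
#'
#' Finds `mu` such that `E[plogis(mu + sd * Z)] = target` for standard normal
#' `Z`, by Gauss--Hermite quadrature and root finding. Used to calibrate the
#' severity distribution and the readmission intercept of the generator so
#' marginal event rates hit their targets.
#'
#' @param target Target mean probability in (0, 1).
#' @param sd Standard deviation on the logit scale (>= 0).
#' @param nodes Number of Gauss--Hermite nodes.
#' @return The location `mu` (log-odds scale).
#' @export
#' @examples
#' mu <- calibrate_logit_normal(0.143, 1.7)
#' # mean of plogis(mu + 1.7 * Z) is ~0.143
calibrate_logit_normal <- function(target, sd, nodes = 40) {
  stopifnot(target > 0, target < 1, sd >= 0)
  if (sd == 0) return(logit(target))
  gh <- gauss_hermite_points(nodes)
  mean_p <- function(mu) sum(gh$w * invlogit(mu + sd * gh$x)) - target
  stats::uniroot(mean_p, interval = logit(target) + c(-1, 1) * (5 + 3 * sd),
                 tol = 1e-12)$root
}

# Gauss-Hermite rule rescaled for N(0,1) expectations: E f(Z) ~ sum w f(x).
# Golub-Welsch via the symmetric tridiagonal Jacobi matrix.
gauss_hermite_points <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  # physicists' rule: weights w_i = v_{1i}^2 * sqrt(pi); probabilists' scaling
  list(x = e$values * sqrt(2), w = e$vectors[1, ]^2)
}
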