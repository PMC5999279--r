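#' Simulate a synthetic admission-level ICU registry
#'
#' Generates a seeded registry of ICU admissions with known unit-level truth,
#' so that every downstream stage (exclusions, case-mix models, reliability
#' adjustment, associations) can be exercised and validated without access to
#' a real registry. Patients are nested in ICUs; each ICU carries a trivariate
#' normal random effect `(b_mort, b_readm, b_los)` with standard deviations
#' `sd_mort`, `sd_readm` (logit scale), `sd_los` (day scale) and correlation
#' `effect_corr`. Outcomes are drawn as:
#'
#' * in-hospital death: `Bernoulli(plogis(qlogis(p_mort_raw) + b_mort))`,
#'   with the severity probability `p_mort_raw` drawn logit-normally and its
#'   location calibrated so the realized crude mortality matches
#'   `target_crude_mortality`;
#' * 48-h readmission (ward survivors only):
#'   `Bernoulli(plogis(a0 + beta_readm . x + b_readm))`, with `a0` calibrated
#'   to `target_readmission_rate`;
#' * ICU length of stay: `exp(Normal(los_meanlog + beta_los . x, los_sdlog))
#'   + b_los`, truncated below at 0.02 days (about 30 minutes) — the unit
#'   effect is additive on the day scale, matching the linear mixed model
#'   used for the length-of-stay indicator.
#'
#' Deaths in hospital are split into ICU deaths (discharge destination
#' `died`) and later ward deaths; ICU survivors may be discharged to another
#' ICU, to a location outside the hospital, or to the ward. Only ward
#' discharges of ICU survivors form the readmission risk set, so eligibility
#' is structural, not flagged. Exclusion-relevant fields (cardiac surgery,
#' severity-model exclusion, missing covariates) are independent Bernoulli
#' flags.
#'
#' All draws derive from `params$seed` through one root generator in a fixed,
#' documented order (ICU sizes, unit effects, per-ICU severity shifts, then
#' admission-level columns), so identical parameters give bit-identical
#' output.
#'
#' @param params A [registry_params()] object.
#' @return A list of class `icu_registry` with elements
#'   * `admissions`: tibble, one row per admission (ids, subgroup labels,
#'     exclusion flags, severity `p_mort_raw`, covariates `x1`--`x4`,
#'     outcomes, discharge destination, `icu_los_days`, `readmitted_48h` —
#'     `NA` outside the risk set);
#'   * `truth`: tibble of per-ICU random effects `b_mort`, `b_readm`,
#'     `b_los` (ground truth for parameter-recovery checks only — the
#'     analysis pipeline never reads it);
#'   * `params`: the input parameters.
#' @export
#' @examples
#' reg <- simulate_registry(registry_params(n_icus = 3,
#'                                          icu_sizes = c(30, 40, 50),
#'                                          seed = 7))
#' nrow(reg$admissions)   # 120
#' reg$truth
simulate_registry <- function(params) {
  params <- validate_registry_params(params)
  p <- params
  set.seed(p$seed)

  # 1. unit sizes
  sizes <- p$icu_sizes %||%
    sample(seq(p$icu_size_range[1], p$icu_size_range[2]), p$n_icus,
           replace = TRUE)
  if (length(sizes) == 0L)
    abort_icubench("`icu_sizes` must be non-empty.", "icubench_bad_params")
  icu_ids <- sprintf("icu_%03d", seq_len(p$n_icus))
  n <- sum(sizes)

  # 2. unit random effects, jointly trivariate normal
  sds <- c(p$sd_mort, p$sd_readm, p$sd_los)
  Sigma <- diag(sds) %*% p$effect_corr %*% diag(sds)
  b <- rmvnorm_psd(p$n_icus, Sigma)
  truth <- tibble::tibble(icu_id = icu_ids, b_mort = b[, 1],
                          b_readm = b[, 2], b_los = b[, 3])

  # 3. optional per-ICU case-mix (severity) shift
  sev_shift <- if (p$sd_severity_shift > 0)
    stats::rnorm(p$n_icus, 0, p$sd_severity_shift) else rep(0, p$n_icus)

  # calibrated intercepts (deterministic given params)
  mu_sev <- calibrate_logit_normal(
    p$target_crude_mortality,
    sqrt(p$severity_sdlogit^2 + p$sd_mort^2 + p$sd_severity_shift^2))
  a0_readm <- calibrate_logit_normal(
    p$target_readmission_rate,
    sqrt(sum(p$beta_readm^2) + p$sd_readm^2))

  # 4. admission-level draws, one column at a time in fixed order
  icu_idx <- rep(seq_len(p$n_icus), times = sizes)
  adm <- tibble::tibble(
    admission_id = sprintf("adm_%06d", seq_len(n)),
    icu_id = icu_ids[icu_idx],
    admission_type = sample(names(p$admission_type_mix), n, replace = TRUE,
                            prob = p$admission_type_mix),
    diag_group = sample(names(p$diag_group_mix), n, replace = TRUE,
                        prob = p$diag_group_mix))
  X <- matrix(round(stats::rnorm(n * 4), 6), n, 4,
              dimnames = list(NULL, paste0("x", 1:4)))
  adm <- dplyr::bind_cols(adm, tibble::as_tibble(X))
  # recorded at finite precision, as a registry would; clamped inside (0, 1)
  adm$p_mort_raw <- pmin(pmax(round(
    invlogit(mu_sev + sev_shift[icu_idx] +
               p$severity_sdlogit * stats::rnorm(n)), 6), 1e-6), 1 - 1e-6)

  died_hosp <- stats::rbinom(n, 1, invlogit(logit(adm$p_mort_raw) +
                                              truth$b_mort[icu_idx])) == 1
  died_icu <- died_hosp & stats::runif(n) < p$p_death_in_icu
  u_dest <- stats::runif(n)
  dest <- dplyr::case_when(
    died_icu ~ "died",
    died_hosp ~ "ward",  # survived the ICU, died later on the ward
    u_dest < p$exclusion_rates$transfer_other_icu ~ "other_icu",
    u_dest < p$exclusion_rates$transfer_other_icu + p$p_outside_hospital ~
      "outside_hospital",
    TRUE ~ "ward")
  in_risk_set <- !died_icu & dest == "ward"
  eta_readm <- a0_readm + drop(X %*% p$beta_readm) + truth$b_readm[icu_idx]
  readm_draw <- stats::rbinom(n, 1, invlogit(eta_readm)) == 1
  # fractional days to 1e-4 d (~9 s), the resolution of admission timestamps
  los <- round(pmax(exp(stats::rnorm(n, p$los_meanlog +
                                       drop(X %*% p$beta_los),
                                     p$los_sdlog)) + truth$b_los[icu_idx],
                    0.02), 4)

  adm$died_in_icu <- died_icu
  adm$died_in_hospital <- died_hosp
  adm$discharge_destination <- dest
  adm$icu_los_days <- los
  adm$readmitted_48h <- ifelse(in_risk_set, readm_draw, NA)

  # 5. exclusion flags (missing-completely-at-random)
  adm$cardiac_surgery <- stats::runif(n) < p$exclusion_rates$cardiac_surgery
  adm$apache_excluded <- stats::runif(n) < p$exclusion_rates$apache_excluded
  adm$covariates_missing <- stats::runif(n) < p$exclusion_rates$covariates_missing

  adm <- adm[, registry_columns()]
  structure(list(admissions = adm, truth = truth, params = params),
            class = "icu_registry")
}

# column order of the registry table (also the CSV header)
registry_columns <- function() {
  c("admission_id", "icu_id", "admission_type", "diag_group",
    "cardiac_surgery", "apache_excluded", "covariates_missing",
    "p_mort_raw", paste0("x", 1:4),
    "died_in_icu", "died_in_hospital", "discharge_destination",
    "icu_los_days", "readmitted_48h")
}

# multivariate normal draw tolerant of semi-definite covariance
rmvnorm_psd <- function(n, Sigma) {
  e <- eigen(Sigma, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(Sigma))
  matrix(stats::rnorm(n * nrow(Sigma)), n) %*% t(L)
}

#' @export
print.icu_registry <- function(x, ...) {
  cat(sprintf("Synthetic ICU registry: %d admissions in %d ICUs (seed %d)\n",
              nrow(x$admissions), nrow(x$truth), x$params$seed))
  cat(sprintf("  crude in-hospital mortality: %.1f%%\n",
              100 * mean(x$admissions$died_in_hospital)))
  invisible(x)
}
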