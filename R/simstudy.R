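#' Single-replicate simulation studies of the benchmarking pipeline
#'
#' Lean building blocks for replicate experiments on the full pipeline.
#' Each call generates one registry from `params`, runs the exclusion
#' cascade and the cohort-level case-mix step, fits the reliability models
#' on the full cohort and returns scalar summaries, avoiding the per-subgroup
#' sweep so that hundreds of replicates stay affordable.
#'
#' `mortality_recovery_replicate()` targets parameter recovery: it returns
#' the estimated between-ICU SD of the mortality model and the Spearman
#' correlation between the true generated unit effects and the estimated
#' SMR.
#'
#' `indicator_pair_replicate()` targets the association analysis: it
#' computes the SMR and the SLOSR per ICU on the full cohort and returns
#' their Pearson correlation with its Student-t p-value (`NA` when either
#' indicator is constant, e.g. after a fully shrunk variance estimate of
#' zero), plus both estimated between-ICU SDs.
#'
#' @param params A [registry_params()] object (including the seed for this
#'   replicate).
#' @return A one-row tibble; see details above.
#' @export
mortality_recovery_replicate <- function(params) {
  reg <- simulate_registry(params)
  cohort <- readmission_risk_set(apply_exclusions(reg$admissions))
  cm <- recalibrate_mortality(cohort)
  fit <- fit_binary_shrinkage(cohort$admissions$died_in_hospital,
                              cm$predictions$.pred,
                              cohort$admissions$icu_id)
  smr <- standardized_ratio_binary(fit)
  joined <- dplyr::inner_join(smr, reg$truth, by = "icu_id")
  tibble::tibble(
    sigma_b_hat = fit$sigma_b,
    spearman_smr = if (stats::sd(joined$ratio) == 0) NA_real_ else
      stats::cor(joined$b_mort, joined$ratio, method = "spearman"))
}

#' @rdname mortality_recovery_replicate
#' @export
indicator_pair_replicate <- function(params) {
  reg <- simulate_registry(params)
  cohort <- readmission_risk_set(apply_exclusions(reg$admissions))
  adm <- cohort$admissions
  cm <- recalibrate_mortality(cohort)
  fit_m <- fit_binary_shrinkage(adm$died_in_hospital, cm$predictions$.pred,
                                adm$icu_id)
  los <- fit_los_model(cohort)
  fit_l <- fit_gaussian_shrinkage(adm$icu_los_days, los$predictions$.pred,
                                  adm$icu_id)
  smr <- standardized_ratio_binary(fit_m)
  slosr <- standardized_ratio_los(fit_l)
  joined <- dplyr::inner_join(smr, slosr, by = "icu_id",
                              suffix = c("_smr", "_slosr"))
  degenerate <- stats::sd(joined$ratio_smr) == 0 ||
    stats::sd(joined$ratio_slosr) == 0
  if (degenerate) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- pearson_with_p(joined$ratio_smr, joined$ratio_slosr)
    r <- ct$r; p <- ct$p
  }
  tibble::tibble(r = r, p = p, sigma_b_mort = fit_m$sigma_b,
                 sigma_b_los = fit_l$sigma_b)
}
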