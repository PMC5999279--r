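#' Pipeline configuration
#'
#' Collects every setting of the end-to-end benchmarking run: the registry
#' source (generator parameters or a CSV path), covariate lists for the
#' readmission and length-of-stay models, risk-stratum cutpoints, the number
#' of calibration groups, the significance level, and whether reliability
#' adjustment is applied. Serializable to YAML/JSON.
#'
#' @param registry Either a [registry_params()] object (the registry is
#'   simulated) or a single file path to an admission-level CSV.
#' @param covariates_readmission,covariates_los Covariate column names for
#'   the two developed case-mix models.
#' @param risk_cutpoints Mortality-probability boundaries of the risk strata.
#' @param n_calibration_groups Calibration-table groups (default 50).
#' @param alpha Significance level for association tests (default 0.01).
#' @param reliability_adjustment Apply empirical-Bayes shrinkage (default
#'   `TRUE`); `FALSE` reproduces the unadjusted sensitivity analysis.
#' @param output_dir Directory for the output bundle, or `NULL` to skip
#'   writing files.
#' @param seed Seed for the simulated registry (ignored when `registry` is
#'   a path; overrides the seed inside `registry` when given).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(registry = registry_params(),
                            covariates_readmission = paste0("x", 1:4),
                            covariates_los = paste0("x", 1:4),
                            risk_cutpoints = c(0.3, 0.7),
                            n_calibration_groups = 50,
                            alpha = 0.01,
                            reliability_adjustment = TRUE,
                            output_dir = NULL,
                            seed = NULL) {
  stopifnot(length(risk_cutpoints) == 2, diff(risk_cutpoints) > 0,
            all(risk_cutpoints > 0 & risk_cutpoints < 1),
            alpha > 0, alpha < 1)
  if (inherits(registry, "registry_params") && !is.null(seed)) {
    registry$seed <- as.integer(seed)
  }
  structure(
    list(registry = registry,
         covariates_readmission = covariates_readmission,
         covariates_los = covariates_los,
         risk_cutpoints = risk_cutpoints,
         n_calibration_groups = n_calibration_groups,
         alpha = alpha,
         reliability_adjustment = reliability_adjustment,
         output_dir = output_dir),
    class = "pipeline_config")
}

#' Run the full benchmarking pipeline
#'
#' Orchestrates simulate/load, the exclusion cascade and risk set, the three
#' cohort-level case-mix models, subgroup assignment on the recalibrated
#' mortality probability, per-subgroup reliability adjustment, the benchmark
#' summary table and the pairwise association analysis (Pearson primary,
#' Spearman sensitivity). A diagnostic block correlates each crude per-ICU
#' outcome with its standardized ratio in the full cohort. When
#' `config$output_dir` is set, the bundle (registry CSV if simulated,
#' exclusion log, model metrics, indicator and association tables, scatter
#' exports and a run manifest) is written there; identical configuration and
#' seed reproduce the bundle exactly.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of class `icu_benchmark` with elements
#'   `cohort`, `casemix`, `subgroups`, `indicators`, `table1`,
#'   `associations` (Pearson), `associations_spearman`,
#'   `crude_vs_adjusted`, `truth` (when simulated), `config`.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(registry_params(n_icus = 10,
#'                                        icu_sizes = rep(300, 10),
#'                                        seed = 42))
#' bench <- run_pipeline(cfg)
#' bench$table1
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  simulated <- inherits(config$registry, "registry_params")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("Pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   class = "icubench_pipeline_error", parent = e)
    })
  }

  if (simulated) {
    reg <- stage("simulate", simulate_registry(config$registry))
    admissions <- reg$admissions
    truth <- reg$truth
  } else {
    admissions <- stage("read_registry", read_registry(config$registry))
    truth <- NULL
  }

  cohort <- stage("cohort", readmission_risk_set(apply_exclusions(admissions)))
  fits <- stage("casemix", list(
    mortality = recalibrate_mortality(cohort, config$n_calibration_groups),
    readmission = fit_readmission_model(cohort,
                                        config$covariates_readmission,
                                        config$n_calibration_groups),
    los = fit_los_model(cohort, config$covariates_los,
                        config$n_calibration_groups)))
  subgroups <- stage("subgroups",
                     assign_subgroups(cohort, fits$mortality$predictions$.pred,
                                      config$risk_cutpoints))
  indicators <- stage("reliability",
                      compute_indicator_table(cohort, subgroups, fits,
                                              config$reliability_adjustment))
  table1 <- stage("report", summarize_table1(cohort, subgroups, indicators))
  assoc <- stage("association",
                 pairwise_indicator_associations(indicators, "pearson",
                                                 config$alpha))
  assoc_sp <- stage("association",
                    pairwise_indicator_associations(indicators, "spearman",
                                                    config$alpha))
  crude_vs_adj <- stage("diagnostics",
                        crude_vs_adjusted(cohort, indicators))

  result <- structure(
    list(cohort = cohort, casemix = fits, subgroups = subgroups,
         indicators = indicators, table1 = table1,
         associations = assoc, associations_spearman = assoc_sp,
         crude_vs_adjusted = crude_vs_adj,
         truth = truth, config = config),
    class = "icu_benchmark")

  if (!is.null(config$output_dir))
    stage("write_bundle", write_bundle(result, admissions, simulated))
  invisible(result)
}

# crude per-ICU outcome vs its standardized ratio, full cohort (diagnostic)
crude_vs_adjusted <- function(cohort, indicators) {
  adm <- cohort$admissions
  rs <- adm[adm$admission_id %in% cohort$risk_set_ids, , drop = FALSE]
  crude <- dplyr::full_join(
    adm |> dplyr::group_by(.data$icu_id) |>
      dplyr::summarise(crude_mortality = mean(.data$died_in_hospital),
                       mean_los = mean(.data$icu_los_days),
                       .groups = "drop"),
    rs |> dplyr::group_by(.data$icu_id) |>
      dplyr::summarise(crude_readmission = mean(.data$readmitted_48h),
                       .groups = "drop"),
    by = "icu_id")
  ind <- indicators[indicators$subgroup == "all", , drop = FALSE]
  dat <- dplyr::inner_join(crude, ind, by = "icu_id")
  one <- function(x, y, label) {
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(NULL)
    ct <- pearson_with_p(x[ok], y[ok])
    tibble::tibble(comparison = label, r = ct$r, p = ct$p, n_icus = ct$n)
  }
  dplyr::bind_rows(
    one(dat$crude_mortality, dat$SMR, "crude_mortality_vs_SMR"),
    one(dat$crude_readmission, dat$SRR, "crude_readmission_vs_SRR"),
    one(dat$mean_los, dat$SLOSR, "mean_los_vs_SLOSR"))
}

write_bundle <- function(result, admissions, simulated) {
  dir <- result$config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (simulated)
    write_registry(admissions, file.path(dir, "registry.csv"))
  write_exclusion_log(result$cohort, file.path(dir, "exclusion_log.json"))
  metrics <- purrr::map(result$casemix, function(f) {
    m <- f$metrics
    list(outcome = f$outcome, link = f$link,
         coefficients = as.list(f$coefficients),
         scaled_brier = m$scaled_brier, c_statistic = m$c_statistic,
         r_squared = m$r_squared)
  })
  jsonlite::write_json(metrics, file.path(dir, "casemix_metrics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (nm in names(result$casemix))
    readr::write_csv(result$casemix[[nm]]$metrics$calibration_table,
                     file.path(dir, sprintf("calibration_%s.csv", nm)))
  write_indicator_table(result$indicators,
                        file.path(dir, "indicator_table.csv"))
  readr::write_csv(result$table1, file.path(dir, "table1_summary.csv"),
                   na = "NA")
  readr::write_csv(result$associations,
                   file.path(dir, "associations_pearson.csv"))
  readr::write_csv(result$associations_spearman,
                   file.path(dir, "associations_spearman.csv"))
  readr::write_csv(association_report(result$associations),
                   file.path(dir, "association_report.csv"), na = "NA")
  for (pr in c("SMR-SRR", "SMR-SLOSR", "SLOSR-SRR"))
    readr::write_csv(scatter_export(result$indicators, pr, "all"),
                     file.path(dir, sprintf("scatter_%s_all.csv",
                                            gsub("-", "_", pr))))
  if (!is.null(result$crude_vs_adjusted))
    readr::write_csv(result$crude_vs_adjusted,
                     file.path(dir, "crude_vs_adjusted.csv"))
  cfg <- result$config
  manifest <- list(
    package_version = as.character(utils::packageVersion("icubench")),
    r_version = as.character(getRversion()),
    simulated = simulated,
    seed = if (simulated) cfg$registry$seed else NULL,
    config_hash = rlang::hash(cfg),
    alpha = cfg$alpha,
    reliability_adjustment = cfg$reliability_adjustment,
    n_admissions_input = nrow(admissions),
    n_retained = nrow(result$cohort$admissions),
    n_risk_set = length(result$cohort$risk_set_ids))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' @export
print.icu_benchmark <- function(x, ...) {
  cat("ICU benchmark run\n")
  print(x$cohort)
  cat(sprintf("  indicator table: %d ICUs x %d subgroups\n",
              length(unique(x$indicators$icu_id)),
              length(unique(x$indicators$subgroup))))
  sig <- x$associations[x$associations$significant, , drop = FALSE]
  cat(sprintf("  significant associations (alpha = %g): %d of %d\n",
              x$config$alpha, nrow(sig), nrow(x$associations)))
  invisible(x)
}
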