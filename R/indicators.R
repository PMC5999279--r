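#' Per-ICU quality indicators by subgroup
#'
#' Runs the reliability-adjustment step for every subgroup and outcome and
#' assembles the benchmark table: one row per (ICU, subgroup) with the
#' standardized mortality ratio (SMR), standardized 48-h readmission ratio
#' (SRR, computed on the readmission risk set) and standardized
#' length-of-stay ratio (SLOSR), plus the underlying admission counts. The
#' case-mix expectations come from the cohort-level fixed models and are
#' reused unchanged within each subgroup; the crude rate / mean that anchors
#' each ratio is subgroup-specific, so a unit performing exactly as expected
#' scores 1 in every subgroup.
#'
#' Cells whose mixed model cannot be fitted (e.g. a subgroup with
#' single-class outcomes or a single ICU) are reported as missing, with the
#' failure recorded in the `failures` attribute; other cells are unaffected.
#' An ICU with no admissions in a subgroup gets a missing indicator, never
#' the shrunk value 1, so "no data" and "average performance" stay
#' distinguishable.
#'
#' @param cohort An `icu_cohort` that has been through
#'   [readmission_risk_set()].
#' @param subgroup_assignment Long tibble from [assign_subgroups()].
#' @param fits Named list of `casemix_fit`s: `mortality`, `readmission`,
#'   `los`.
#' @param reliability_adjustment If `FALSE`, skip the mixed models and report
#'   raw observed/expected ratios per ICU (sensitivity analysis).
#' @return Tibble (`icu_id`, `subgroup`, `SMR`, `SRR`, `SLOSR`,
#'   `n_mortality`, `n_risk_set`, `n_los`) of class `indicator_table`, with
#'   attribute `failures` (tibble of skipped cells, possibly empty).
#' @export
compute_indicator_table <- function(cohort, subgroup_assignment, fits,
                                    reliability_adjustment = TRUE) {
  stopifnot(inherits(cohort, "icu_cohort"))
  if (is.null(cohort$risk_set_ids))
    abort_icubench("Run readmission_risk_set() on the cohort first.",
                   "icubench_no_risk_set")
  for (nm in c("mortality", "readmission", "los"))
    if (!inherits(fits[[nm]], "casemix_fit"))
      abort_icubench(sprintf("`fits` must contain a casemix_fit named '%s'.",
                             nm),
                     "icubench_bad_fits")
  adm <- cohort$admissions
  all_icus <- sort(unique(adm$icu_id))
  subgroups <- intersect(subgroup_levels,
                         unique(subgroup_assignment$subgroup))
  failures <- list()

  one_cell <- function(dat, obs, pred, subgroup, outcome) {
    # returns tibble(icu_id, ratio, n) or NULL on recorded failure
    res <- tryCatch({
      if (!reliability_adjustment) {
        raw_ratio(obs, pred, dat$icu_id, outcome)
      } else if (outcome == "los") {
        standardized_ratio_los(
          fit_gaussian_shrinkage(obs, pred, dat$icu_id, subgroup))
      } else {
        standardized_ratio_binary(
          fit_binary_shrinkage(obs, pred, dat$icu_id, subgroup, outcome))
      }
    }, icubench_error = function(e) {
      failures[[length(failures) + 1]] <<-
        tibble::tibble(subgroup = subgroup, outcome = outcome,
                       message = conditionMessage(e))
      NULL
    })
    res
  }

  rows <- purrr::map(subgroups, function(sg) {
    ids <- subgroup_assignment$admission_id[subgroup_assignment$subgroup == sg]
    sub <- adm[adm$admission_id %in% ids, , drop = FALSE]
    out <- tibble::tibble(icu_id = all_icus, subgroup = sg,
                          SMR = NA_real_, SRR = NA_real_, SLOSR = NA_real_,
                          n_mortality = 0L, n_risk_set = 0L, n_los = 0L)
    if (nrow(sub) == 0) return(out)

    mort <- dplyr::inner_join(sub, fits$mortality$predictions,
                              by = "admission_id")
    cnt <- table(factor(mort$icu_id, levels = all_icus))
    out$n_mortality <- out$n_los <- as.integer(cnt[out$icu_id])
    cell <- one_cell(mort, mort$died_in_hospital, mort$.pred, sg, "mortality")
    if (!is.null(cell))
      out$SMR[match(cell$icu_id, out$icu_id)] <- cell$ratio

    los <- dplyr::inner_join(sub, fits$los$predictions, by = "admission_id")
    cell <- one_cell(los, los$icu_los_days, los$.pred, sg, "los")
    if (!is.null(cell))
      out$SLOSR[match(cell$icu_id, out$icu_id)] <- cell$ratio

    rs <- sub[sub$admission_id %in% cohort$risk_set_ids, , drop = FALSE]
    rs <- dplyr::inner_join(rs, fits$readmission$predictions,
                            by = "admission_id")
    cnt <- table(factor(rs$icu_id, levels = all_icus))
    out$n_risk_set <- as.integer(cnt[out$icu_id])
    if (nrow(rs) > 0) {
      cell <- one_cell(rs, rs$readmitted_48h, rs$.pred, sg, "readmission")
      if (!is.null(cell))
        out$SRR[match(cell$icu_id, out$icu_id)] <- cell$ratio
    }
    # units without admissions in this subgroup keep NA, not the shrunk 1
    out$SMR[out$n_mortality == 0L] <- NA_real_
    out$SLOSR[out$n_los == 0L] <- NA_real_
    out$SRR[out$n_risk_set == 0L] <- NA_real_
    out
  })
  res <- dplyr::bind_rows(rows)
  attr(res, "failures") <- if (length(failures) > 0)
    dplyr::bind_rows(failures)
  else tibble::tibble(subgroup = character(), outcome = character(),
                      message = character())
  class(res) <- c("indicator_table", class(res))
  res
}

# unadjusted observed/expected ratios (reliability adjustment disabled)
raw_ratio <- function(obs, pred, icu_ids, outcome) {
  obs <- as.numeric(obs)
  tibble::tibble(icu_id = icu_ids, obs = obs, pred = pred) |>
    dplyr::group_by(.data$icu_id) |>
    dplyr::summarise(ratio = sum(.data$obs) / sum(.data$pred),
                     n = dplyr::n(), .groups = "drop")
}

#' Write an indicator table as a long CSV
#'
#' One row per (ICU, subgroup, indicator): columns `icu_id`, `subgroup`,
#' `indicator`, `value`, `n`.
#'
#' @param table An `indicator_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_indicator_table <- function(table, path) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(table),
    cols = dplyr::all_of(indicator_names),
    names_to = "indicator", values_to = "value") |>
    dplyr::mutate(n = dplyr::case_when(
      .data$indicator == "SMR" ~ .data$n_mortality,
      .data$indicator == "SRR" ~ .data$n_risk_set,
      TRUE ~ .data$n_los)) |>
    dplyr::select("icu_id", "subgroup", "indicator", "value", "n")
  readr::write_csv(long, path, na = "NA")
  invisible(path)
}

#' Benchmark report: crude outcomes and indicator ranges by subgroup
#'
#' Summarises, per subgroup: the crude in-hospital mortality rate and 48-h
#' readmission rate (each with the min--max over ICUs), the median ICU
#' length of stay (with the min--max of per-ICU medians), and the min--max
#' over ICUs of the three standardized ratios.
#'
#' @param cohort An `icu_cohort` with its risk set.
#' @param subgroup_assignment Long tibble from [assign_subgroups()].
#' @param indicator_table From [compute_indicator_table()].
#' @return One tibble row per subgroup.
#' @export
summarize_table1 <- function(cohort, subgroup_assignment, indicator_table) {
  adm <- cohort$admissions
  rs_ids <- cohort$risk_set_ids
  subgroups <- intersect(subgroup_levels,
                         unique(subgroup_assignment$subgroup))
  rng <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) c(NA_real_, NA_real_) else range(x)
  }
  purrr::map_dfr(subgroups, function(sg) {
    ids <- subgroup_assignment$admission_id[subgroup_assignment$subgroup == sg]
    sub <- adm[adm$admission_id %in% ids, , drop = FALSE]
    rs <- sub[sub$admission_id %in% rs_ids, , drop = FALSE]
    by_icu <- sub |> dplyr::group_by(.data$icu_id) |>
      dplyr::summarise(mort = mean(.data$died_in_hospital),
                       med_los = stats::median(.data$icu_los_days),
                       .groups = "drop")
    readm_by_icu <- rs |> dplyr::group_by(.data$icu_id) |>
      dplyr::summarise(readm = mean(.data$readmitted_48h), .groups = "drop")
    ind <- indicator_table[indicator_table$subgroup == sg, , drop = FALSE]
    mr <- rng(by_icu$mort); rr <- rng(readm_by_icu$readm)
    lr <- rng(by_icu$med_los)
    smr <- rng(ind$SMR); srr <- rng(ind$SRR); slosr <- rng(ind$SLOSR)
    tibble::tibble(
      subgroup = sg, n_admissions = nrow(sub), n_risk_set = nrow(rs),
      crude_mortality_pct = 100 * mean(sub$died_in_hospital),
      crude_mortality_min_pct = 100 * mr[1],
      crude_mortality_max_pct = 100 * mr[2],
      smr_min = smr[1], smr_max = smr[2],
      crude_readmission_pct = 100 * mean(rs$readmitted_48h),
      crude_readmission_min_pct = 100 * rr[1],
      crude_readmission_max_pct = 100 * rr[2],
      srr_min = srr[1], srr_max = srr[2],
      median_los_days = stats::median(sub$icu_los_days),
      median_los_min_days = lr[1], median_los_max_days = lr[2],
      slosr_min = slosr[1], slosr_max = slosr[2])
  })
}
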