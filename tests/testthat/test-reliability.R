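make_shrinkage_fit <- function(u, rate, outcome = "mortality",
                               n = rep(100L, length(u))) {
  structure(list(outcome = outcome, subgroup = "all", sigma_b = 0.3,
                 sigma_e = if (outcome == "los") 1 else NULL,
                 beta = c(0, 1), u = u, overall_rate = rate,
                 n_per_icu = stats::setNames(as.table(n), names(u))),
            class = "shrinkage_fit")
}

test_that("posterior unit intercepts match the dense matrix-algebra oracle", {
  set.seed(12)
  for (i in 1:5) {
    n_icu <- sample(3:8, 1)
    n_i <- sample(1:15, n_icu, replace = TRUE)
    icu <- rep(sprintf("u%d", seq_len(n_icu)), times = n_i)
    r <- rnorm(length(icu), 0, 2)
    sb <- runif(1, 0.1, 2); se <- runif(1, 0.5, 3)
    expect_equal(gaussian_blup(r, icu, sb, se),
                 blup_matrix_oracle(r, icu, sb, se), tolerance = 1e-10)
  }
})

test_that("scalar shrinkage law holds exactly at fixed variance components", {
  # one unit, n = 4, mean residual 2, variances (1, 4): u = 0.5 * 2 = 1
  u <- gaussian_blup(rep(2, 4), rep("a", 4), sigma_b = 1, sigma_e = 2)
  expect_equal(unname(u), 1, tolerance = 1e-12)
  # shrink_i * mean residual, across many random configurations
  set.seed(33)
  for (i in 1:5) {
    n_i <- sample(1:30, 4)
    icu <- rep(letters[1:4], times = n_i)
    r <- rnorm(length(icu))
    sb <- runif(1, 0.2, 1.5); se <- runif(1, 0.5, 2)
    mbar <- tapply(r, icu, mean)
    shrink <- sb^2 / (sb^2 + se^2 / n_i)
    expect_equal(unname(gaussian_blup(r, icu, sb, se)),
                 as.numeric(shrink * mbar), tolerance = 1e-10)
  }
})

test_that("shrinkage pulls small units harder and vanishing units to ratio 1", {
  m <- 1.5  # identical mean residual, increasing unit size
  u_by_n <- vapply(c(1, 2, 5, 200, 20000),
                   function(n) unname(gaussian_blup(rep(m, n), rep("a", n),
                                                    0.5, 2)),
                   numeric(1))
  expect_true(all(diff(u_by_n) > 0))       # |u| grows with n toward m
  expect_lt(abs(u_by_n[5] - m), 0.01)      # large unit: u -> m
  expect_lt(u_by_n[1], 0.1)                # tiny unit: u -> 0, ratio -> 1
  fit <- make_shrinkage_fit(c(a = u_by_n[1]), rate = 3.3, outcome = "los")
  expect_lt(abs(standardized_ratio_los(fit)$ratio - 1), 0.05)
  expect_equal(unname(gaussian_blup(rnorm(10), rep("a", 10), 0, 1)), 0)
})

test_that("standardized binary ratio follows the inverse-logit construction", {
  fit <- make_shrinkage_fit(c(a = 0, b = 0.5, c = -20), rate = 0.143)
  ratios <- standardized_ratio_binary(fit)$ratio
  expect_equal(ratios[1], 1)
  expect_equal(ratios[2], plogis(qlogis(0.143) + 0.5) / 0.143)
  expect_equal(ratios[2], 1.51, tolerance = 0.005)
  expect_lt(ratios[3], 1e-6)  # u -> -inf drives the ratio to 0
  expect_error(
    standardized_ratio_binary(make_shrinkage_fit(c(a = 0), rate = 0)),
    class = "icubench_degenerate_rate")
})

test_that("standardized LOS ratio is additive on the day scale", {
  fit <- make_shrinkage_fit(c(a = 0, b = 0.33), rate = 3.3, outcome = "los")
  ratios <- standardized_ratio_los(fit)$ratio
  expect_equal(ratios[1], 1)
  expect_equal(ratios[2], 1.1, tolerance = 1e-12)
  fit <- make_shrinkage_fit(c(a = -3.3), rate = 3.3, outcome = "los")
  expect_equal(standardized_ratio_los(fit)$ratio, 0)
  fit <- make_shrinkage_fit(c(a = -4), rate = 3.3, outcome = "los")
  expect_warning(r <- standardized_ratio_los(fit), "floored")
  expect_equal(r$ratio, 0)
  expect_error(
    standardized_ratio_los(make_shrinkage_fit(c(a = 0), rate = 0,
                                              outcome = "los")),
    class = "icubench_degenerate_rate")
})

test_that("binary mixed model recovers a null between-unit variance", {
  p <- registry_params(n_icus = 83, icu_sizes = rep(500L, 83),
                       sd_mort = 0, sd_readm = 0, sd_los = 0, seed = 71)
  coh <- quick_cohort(p)$cohort
  cm <- recalibrate_mortality(coh)
  fit <- fit_binary_shrinkage(coh$admissions$died_in_hospital,
                              cm$predictions$.pred, coh$admissions$icu_id)
  expect_lt(fit$sigma_b, 0.05)
  expect_lt(max(abs(fit$u)), 0.05)
  # with all u ~ 0 every standardized ratio sits at 1
  expect_true(all(abs(standardized_ratio_binary(fit)$ratio - 1) < 0.05))
})

test_that("Laplace marginal likelihood agrees with quadrature and lme4", {
  for (fx in mixed_fixtures()) {
    dat <- data.frame(y = fx$y, lp = qlogis(fx$p), icu = fx$icu)
    m <- suppressMessages(
      lme4::glmer(y ~ lp + (1 | icu), data = dat, family = binomial()))
    beta <- lme4::fixef(m)
    sigma <- max(sqrt(unname(unlist(lme4::VarCorr(m)))), 1e-6)
    ll_lap <- binary_marginal_loglik(fx$y, fx$p, fx$icu, beta, sigma,
                                     "laplace")
    ll_agq <- binary_marginal_loglik(fx$y, fx$p, fx$icu, beta, sigma,
                                     "agq", 40)
    expect_lt(abs(ll_lap - ll_agq), 1e-3)             # quadrature oracle
    expect_lt(abs(ll_lap - as.numeric(logLik(m))), 1e-4)  # lme4 cross-check
    # and at a fixed representative parameter point
    expect_lt(abs(
      binary_marginal_loglik(fx$y, fx$p, fx$icu, c(0, 1), 0.3, "laplace") -
      binary_marginal_loglik(fx$y, fx$p, fx$icu, c(0, 1), 0.3, "agq", 40)),
      1e-3)
  }
})

test_that("Gaussian mixed model intercepts coincide with lme4 conditional modes", {
  set.seed(9)
  icu <- rep(sprintf("u%d", 1:10), times = sample(20:60, 10, replace = TRUE))
  pred <- rexp(length(icu), 1 / 3)
  y <- 0.5 + 0.9 * pred + rep(rnorm(10, 0, 0.6), times = table(icu)[unique(icu)]) +
    rnorm(length(icu), 0, 2)
  fit <- fit_gaussian_shrinkage(y, pred, icu)
  modes <- lme4::ranef(fit$model)$icu[["(Intercept)"]]
  names(modes) <- rownames(lme4::ranef(fit$model)$icu)
  expect_equal(fit$u, modes[names(fit$u)], tolerance = 1e-6)
  expect_error(fit_gaussian_shrinkage(y[icu == "u1"], pred[icu == "u1"],
                                      icu[icu == "u1"]),
               class = "icubench_single_icu")
})

test_that("degenerate binary subgroups fail with explicit conditions", {
  expect_error(fit_binary_shrinkage(rep(1, 10), runif(10), rep("a", 10)),
               class = "icubench_single_class")
  expect_error(fit_binary_shrinkage(numeric(0), numeric(0), character(0)),
               class = "icubench_empty_subgroup")
})

test_that("indicator table covers every ICU-subgroup cell with honest missingness", {
  p <- small_params(seed = 23)
  res <- quick_cohort(p)
  coh <- res$cohort
  fits <- list(mortality = recalibrate_mortality(coh),
               readmission = fit_readmission_model(coh),
               los = fit_los_model(coh))
  sg <- assign_subgroups(coh, fits$mortality$predictions$.pred)
  tab <- suppressWarnings(compute_indicator_table(coh, sg, fits))
  subgroups <- unique(sg$subgroup)
  icus <- unique(coh$admissions$icu_id)
  expect_equal(nrow(tab), length(icus) * length(subgroups))
  # a cell with no admissions is missing, never the shrunk value 1
  empty <- tab[tab$n_mortality == 0, ]
  if (nrow(empty) > 0) expect_true(all(is.na(empty$SMR)))
  expect_true(all(is.na(tab$SRR[tab$n_risk_set == 0])))
  # counts agree with the cohort
  all_row <- tab[tab$subgroup == "all", ]
  expect_equal(sum(all_row$n_mortality), nrow(coh$admissions))
  expect_equal(sum(all_row$n_risk_set), length(coh$risk_set_ids))
  # failures are recorded per cell, not fatal
  expect_s3_class(attr(tab, "failures"), "tbl_df")
  # long CSV export has one row per (icu, subgroup, indicator)
  f <- withr::local_tempfile(fileext = ".csv")
  write_indicator_table(tab, f)
  long <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(nrow(long), nrow(tab) * 3)
})

test_that("disabling reliability adjustment yields raw observed/expected ratios", {
  res <- quick_cohort(small_params(seed = 29))
  coh <- res$cohort
  fits <- list(mortality = recalibrate_mortality(coh),
               readmission = fit_readmission_model(coh),
               los = fit_los_model(coh))
  sg <- assign_subgroups(coh, fits$mortality$predictions$.pred)
  raw <- suppressWarnings(
    compute_indicator_table(coh, sg, fits, reliability_adjustment = FALSE))
  adm <- dplyr::inner_join(coh$admissions, fits$mortality$predictions,
                           by = "admission_id")
  one_icu <- adm[adm$icu_id == adm$icu_id[1], ]
  expected <- sum(one_icu$died_in_hospital) / sum(one_icu$.pred)
  got <- raw$SMR[raw$subgroup == "all" & raw$icu_id == one_icu$icu_id[1]]
  expect_equal(got, expected)
})
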