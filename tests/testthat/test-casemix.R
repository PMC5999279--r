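# Parameter-recovery checks run the generator with unit effects switched
# off, so the fixed-effect models see data drawn exactly from their own
# model class and must recover the generating coefficients.

no_effects_params <- function(n_total, seed, ...) {
  registry_params(n_icus = 10, icu_sizes = rep(n_total %/% 10L, 10),
                  sd_mort = 0, sd_readm = 0, sd_los = 0, seed = seed, ...)
}

test_that("mortality recalibration recovers identity on well-calibrated data", {
  coh <- quick_cohort(no_effects_params(50000L, seed = 41))$cohort
  fit <- recalibrate_mortality(coh)
  expect_lt(abs(fit$coefficients[1]), 0.05)      # intercept near 0
  expect_lt(abs(fit$coefficients[2] - 1), 0.05)  # slope near 1
  expect_true(all(fit$predictions$.pred > 0 & fit$predictions$.pred < 1))
  # positive slope makes recalibration strictly monotone in raw severity
  ord <- order(coh$admissions$p_mort_raw)
  expect_true(all(diff(fit$predictions$.pred[ord]) >= 0))
})

test_that("constant severity is rejected as unidentifiable", {
  fx <- exclusion_fixture()
  fx$p_mort_raw <- 0.5
  coh <- apply_exclusions(fx)
  expect_error(recalibrate_mortality(coh),
               class = "icubench_constant_covariate")
})

test_that("readmission model recovers generating coefficients and the null", {
  # sharp recovery case: strong effects, elevated event rate
  p <- no_effects_params(100000L, seed = 43,
                         beta_readm = c(0.5, -0.4, 0.3, 0),
                         target_readmission_rate = 0.2)
  coh <- quick_cohort(p)$cohort
  fit <- fit_readmission_model(coh)
  est <- fit$coefficients[paste0("x", 1:3)]
  expect_true(all(abs(est - c(0.5, -0.4, 0.3)) / c(0.5, 0.4, 0.3) < 0.10))
  se4 <- summary(fit$model)$coefficients["x4", "Std. Error"]
  expect_lt(abs(fit$coefficients["x4"]), 3 * se4)
  # score-equation identity: fitted probabilities sum to observed events
  rs <- coh$admissions[coh$admissions$admission_id %in% coh$risk_set_ids, ]
  expect_equal(sum(fit$predictions$.pred), sum(rs$readmitted_48h))
  expect_true(all(fit$predictions$.pred > 0 & fit$predictions$.pred < 1))
  # the model population is exactly the risk set
  expect_setequal(fit$predictions$admission_id, coh$risk_set_ids)
})

test_that("readmission model demands a constructed risk set", {
  coh <- apply_exclusions(exclusion_fixture())
  expect_error(fit_readmission_model(coh), class = "icubench_no_risk_set")
})

test_that("LOS model recovers log-scale coefficients with smearing back-transform", {
  p <- no_effects_params(50000L, seed = 47, beta_los = c(0.5, -0.4, 0.3, 0))
  coh <- quick_cohort(p)$cohort
  fit <- fit_los_model(coh)
  est <- fit$coefficients[paste0("x", 1:3)]
  expect_true(all(abs(est - c(0.5, -0.4, 0.3)) / c(0.5, 0.4, 0.3) < 0.10))
  expect_true(all(fit$predictions$.pred > 0))
  expect_gt(fit$smearing_factor, 1)  # Jensen: mean(exp(resid)) > exp(0)
  # day-scale R^2 equals the squared two-pass Pearson correlation
  obs <- coh$admissions$icu_los_days
  pr <- fit$predictions$.pred
  r2 <- (sum((pr - mean(pr)) * (obs - mean(obs))) /
           sqrt(sum((pr - mean(pr))^2) * sum((obs - mean(obs))^2)))^2
  expect_equal(fit$metrics$r_squared, r2)
})

test_that("constant LOS with an intercept-only model predicts the constant", {
  fx <- exclusion_fixture()
  fx$icu_los_days <- 2.5
  coh <- apply_exclusions(fx)
  fit <- fit_los_model(coh, covariates = "1", n_calibration_groups = 2)
  expect_equal(fit$predictions$.pred, rep(2.5, nrow(coh$admissions)))
})

test_that("doubling every LOS doubles every prediction", {
  coh <- quick_cohort(small_params(seed = 13))$cohort
  fit1 <- fit_los_model(coh)
  coh2 <- coh
  coh2$admissions$icu_los_days <- 2 * coh2$admissions$icu_los_days
  fit2 <- fit_los_model(coh2)
  expect_equal(fit2$predictions$.pred, 2 * fit1$predictions$.pred)
})

test_that("logistic fits attain the brute-force likelihood maximum on tiny data", {
  set.seed(6)
  for (i in 1:5) {
    n <- sample(10:30, 1)
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.3 + 0.8 * x))
    if (length(unique(y)) < 2) next
    m <- suppressWarnings(stats::glm(y ~ x, family = binomial()))
    eta <- stats::fitted(m)
    ll_glm <- sum(y * log(eta) + (1 - y) * log(1 - eta))
    ll_oracle <- bruteforce_logistic_loglik(y, x)
    expect_lt(abs(ll_glm - ll_oracle), 1e-6)
  }
})

test_that("binary model metrics populate the expected slots", {
  coh <- quick_cohort(small_params(seed = 19))$cohort
  fit <- recalibrate_mortality(coh)
  expect_null(fit$metrics$r_squared)
  expect_true(is.numeric(fit$metrics$scaled_brier))
  expect_true(fit$metrics$c_statistic >= 0 && fit$metrics$c_statistic <= 1)
  expect_equal(sum(fit$metrics$calibration_table$n), nrow(coh$admissions))
  g <- glance(fit)
  expect_equal(g$c_statistic, fit$metrics$c_statistic)
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
})
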