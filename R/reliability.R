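#' Reliability adjustment via random-intercept mixed models
#'
#' Step 2 of the two-step benchmarking procedure. Within a subgroup, the
#' observed outcome is regressed on the case-mix expectation from the
#' cohort-level fixed model, with a random intercept per ICU:
#'
#' * binary outcomes (mortality, readmission): logistic mixed model with
#'   fixed part `intercept + slope * qlogis(pred)`, fitted by Laplace
#'   approximation of the marginal likelihood;
#' * length of stay: linear mixed model on the day scale with fixed part
#'   `intercept + slope * pred`, variance components by REML.
#'
#' The empirical-Bayes unit intercepts `u` are posterior modes (binary) or
#' posterior means / BLUPs (Gaussian). Because the posterior shrinks unit
#' deviations toward 0 in proportion to their imprecision, the standardized
#' ratios derived from `u` shrink small, unreliable units toward 1.
#'
#' @param obs Outcome vector: 0/1/logical for the binary model, length of
#'   stay in fractional days for the Gaussian model.
#' @param pred Case-mix expectation per admission, from the cohort-level
#'   fixed model (probability for binary outcomes, days for LOS).
#' @param icu_ids Unit identifier per admission.
#' @param subgroup Label carried into the result (bookkeeping only).
#' @return An object of class `shrinkage_fit`: list with `outcome`,
#'   `subgroup`, `sigma_b` (between-ICU SD), `sigma_e` (Gaussian only),
#'   `beta` (fixed effects), `u` (named per-ICU empirical-Bayes intercept),
#'   `overall_rate` (subgroup crude rate, or mean LOS in days), `n_per_icu`,
#'   and the underlying lme4 `model`.
#' @name shrinkage
NULL

glmer_fast_control <- function() {
  lme4::glmerControl(optimizer = "nloptwrap", calc.derivs = FALSE)
}

#' @rdname shrinkage
#' @param outcome Label for the binary outcome (`"mortality"` or
#'   `"readmission"`).
#' @export
fit_binary_shrinkage <- function(obs, pred, icu_ids, subgroup = "all",
                                 outcome = "mortality") {
  obs <- as.numeric(obs)
  stopifnot(length(obs) == length(pred), length(obs) == length(icu_ids))
  if (length(obs) == 0)
    abort_icubench("Empty subgroup.", "icubench_empty_subgroup")
  if (all(obs == 1) || all(obs == 0))
    abort_icubench(
      sprintf("Subgroup '%s' has single-class outcomes; the logistic mixed model is not identifiable.",
              subgroup),
      "icubench_single_class")
  dat <- data.frame(y = obs, lp = logit(pred), icu = factor(icu_ids))
  fit <- tryCatch(
    lme4::glmer(y ~ lp + (1 | icu), data = dat, family = stats::binomial(),
                control = glmer_fast_control()),
    error = function(e) abort_icubench(
      sprintf("Logistic mixed model failed to converge in subgroup '%s': %s",
              subgroup, conditionMessage(e)),
      "icubench_nonconvergence"))
  u <- lme4::ranef(fit)$icu[["(Intercept)"]]
  names(u) <- rownames(lme4::ranef(fit)$icu)
  structure(
    list(outcome = outcome, subgroup = subgroup,
         sigma_b = sqrt(unname(unlist(lme4::VarCorr(fit)))),
         sigma_e = NULL,
         beta = lme4::fixef(fit),
         u = u,
         overall_rate = mean(obs),
         n_per_icu = table(factor(icu_ids)),
         model = fit),
    class = "shrinkage_fit")
}

#' @rdname shrinkage
#' @export
fit_gaussian_shrinkage <- function(obs, pred, icu_ids, subgroup = "all") {
  stopifnot(length(obs) == length(pred), length(obs) == length(icu_ids))
  if (length(obs) == 0)
    abort_icubench("Empty subgroup.", "icubench_empty_subgroup")
  icu <- factor(icu_ids)
  if (nlevels(icu) < 2)
    abort_icubench(
      sprintf("Subgroup '%s' covers a single ICU; the between-ICU variance is not identifiable.",
              subgroup),
      "icubench_single_icu")
  dat <- data.frame(y = obs, pred = pred, icu = icu)
  fit <- suppressMessages(
    lme4::lmer(y ~ pred + (1 | icu), data = dat, REML = TRUE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_b <- vc$sdcor[vc$grp == "icu"]
  sigma_e <- vc$sdcor[vc$grp == "Residual"]
  beta <- lme4::fixef(fit)
  resid_fixed <- obs - (beta[1] + beta[2] * pred)
  u <- gaussian_blup(resid_fixed, icu, sigma_b, sigma_e)
  structure(
    list(outcome = "los", subgroup = subgroup,
         sigma_b = sigma_b, sigma_e = sigma_e, beta = beta, u = u,
         overall_rate = mean(obs),
         n_per_icu = table(icu),
         model = fit),
    class = "shrinkage_fit")
}

#' Posterior-mean unit intercepts in the Gaussian model
#'
#' Computes the best linear unbiased predictors of the per-unit intercepts
#' given fixed variance components, from the fixed-part residuals. Uses the
#' general mixed-model identity
#' `u = sigma_b^2 Z' V^{-1} r` with `V = sigma_b^2 Z Z' + sigma_e^2 I`,
#' evaluated through the Woodbury identity so it runs in linear time. For a
#' random-intercept model this reduces to the scalar shrinkage law
#' `u_i = shrink_i * mean(r_i)` with
#' `shrink_i = sigma_b^2 / (sigma_b^2 + sigma_e^2 / n_i)`.
#'
#' @param resid Fixed-part residuals, one per observation.
#' @param icu_ids Unit identifier per observation.
#' @param sigma_b Between-unit standard deviation.
#' @param sigma_e Residual standard deviation.
#' @return Named vector of unit intercepts (one per unit present).
#' @export
gaussian_blup <- function(resid, icu_ids, sigma_b, sigma_e) {
  stopifnot(sigma_b >= 0, sigma_e > 0)
  icu <- factor(icu_ids)
  if (sigma_b == 0)
    return(stats::setNames(rep(0, nlevels(icu)), levels(icu)))
  zr <- as.numeric(tapply(resid, icu, sum))          # Z'r
  n_i <- as.numeric(table(icu))                      # diag(Z'Z)
  # Woodbury: u = (sb^2/se^2) (Z'r - Z'Z (se^2/sb^2 I + Z'Z)^{-1} Z'r)
  inner <- zr / (sigma_e^2 / sigma_b^2 + n_i)
  u <- (sigma_b^2 / sigma_e^2) * (zr - n_i * inner)
  stats::setNames(u, levels(icu))
}

#' Marginal log-likelihood of the binary random-intercept model
#'
#' Evaluates, at given parameter values, the marginal log-likelihood of the
#' logistic random-intercept model (fixed part `beta[1] + beta[2] *
#' qlogis(pred)`, unit intercepts integrated over `N(0, sigma_b^2)`), either
#' by the Laplace approximation or by adaptive Gauss--Hermite quadrature
#' centred and scaled at the per-unit posterior mode. The quadrature version
#' at 40 nodes serves as a near-exact reference for validating the Laplace
#' approximation on small problems.
#'
#' @inheritParams fit_binary_shrinkage
#' @param beta Fixed-effect coefficients (intercept, slope on the log-odds
#'   of the prediction).
#' @param sigma_b Between-unit SD of the random intercept.
#' @param method `"laplace"` or `"agq"`.
#' @param nodes Number of quadrature nodes for `"agq"`.
#' @return The marginal log-likelihood (a scalar).
#' @export
binary_marginal_loglik <- function(obs, pred, icu_ids, beta, sigma_b,
                                   method = c("laplace", "agq"),
                                   nodes = 40) {
  method <- match.arg(method)
  obs <- as.numeric(obs)
  eta0 <- beta[1] + beta[2] * logit(pred)
  icu <- factor(icu_ids)
  gh <- if (method == "agq") gauss_hermite_points(nodes)
  total <- 0
  for (lev in levels(icu)) {
    idx <- icu == lev
    y <- obs[idx]; e0 <- eta0[idx]
    # log integrand h(u) = sum_j [y eta - log(1+exp(eta))] + log phi(u; 0, sigma_b^2)
    h <- function(u) sum(y * (e0 + u) - log1p(exp(e0 + u))) +
      stats::dnorm(u, 0, sigma_b, log = TRUE)
    # Newton for the mode
    u <- 0
    for (it in 1:50) {
      p <- invlogit(e0 + u)
      g <- sum(y - p) - u / sigma_b^2
      H <- -sum(p * (1 - p)) - 1 / sigma_b^2
      step <- g / H
      u <- u - step
      if (abs(step) < 1e-12) break
    }
    p <- invlogit(e0 + u)
    H <- -sum(p * (1 - p)) - 1 / sigma_b^2
    if (method == "laplace") {
      total <- total + h(u) + 0.5 * log(2 * pi) - 0.5 * log(-H)
    } else {
      s <- 1 / sqrt(-H)
      lognum <- vapply(gh$x, function(z) h(u + s * z) -
                         stats::dnorm(z, log = TRUE), numeric(1))
      m <- max(lognum)
      total <- total + m + log(sum(gh$w * exp(lognum - m))) + log(s)
    }
  }
  total
}

#' Standardized ratios from a shrinkage fit
#'
#' Converts per-ICU empirical-Bayes intercepts into reliability-adjusted
#' standardized ratios. For binary outcomes the unit intercept is added to
#' the log-odds of the subgroup crude rate and mapped back through the
#' inverse logit, then divided by the crude rate (used identically for the
#' SMR and, on the risk set, the SRR). For length of stay the unit intercept
#' (days) is added to the subgroup mean LOS and divided by that mean. In
#' both cases `u = 0` maps to a ratio of exactly 1, and as a unit's
#' admission count shrinks to zero its ratio is pulled to 1.
#'
#' @param fit A `shrinkage_fit`.
#' @return Tibble (`icu_id`, `ratio`, `n`).
#' @name standardized_ratio
NULL

#' @rdname standardized_ratio
#' @export
standardized_ratio_binary <- function(fit) {
  stopifnot(inherits(fit, "shrinkage_fit"))
  rate <- fit$overall_rate
  if (rate <= 0 || rate >= 1)
    abort_icubench(
      sprintf("Overall rate is %.3f; standardized ratios need a rate strictly inside (0, 1).",
              rate),
      "icubench_degenerate_rate")
  tibble::tibble(
    icu_id = names(fit$u),
    ratio = invlogit(logit(rate) + unname(fit$u)) / rate,
    n = as.integer(fit$n_per_icu[names(fit$u)]))
}

#' @rdname standardized_ratio
#' @export
standardized_ratio_los <- function(fit) {
  stopifnot(inherits(fit, "shrinkage_fit"))
  mean_los <- fit$overall_rate
  if (mean_los <= 0)
    abort_icubench("Mean length of stay must be positive.",
                   "icubench_degenerate_rate")
  ratio <- (mean_los + unname(fit$u)) / mean_los
  if (any(ratio < 0)) {
    warning("Some adjusted mean lengths of stay were negative; ratios floored at 0.",
            call. = FALSE)
    ratio <- pmax(ratio, 0)
  }
  tibble::tibble(icu_id = names(fit$u), ratio = ratio,
                 n = as.integer(fit$n_per_icu[names(fit$u)]))
}

#' @export
print.shrinkage_fit <- function(x, ...) {
  cat(sprintf("Random-intercept fit (%s, subgroup '%s'): %d ICUs, %d admissions\n",
              x$outcome, x$subgroup, length(x$u), sum(x$n_per_icu)))
  cat(sprintf("  between-ICU SD: %.4f; overall %s: %.4f\n", x$sigma_b,
              if (x$outcome == "los") "mean LOS (days)" else "rate",
              x$overall_rate))
  invisible(x)
}
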