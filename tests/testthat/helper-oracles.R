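# Independent oracles used across the suite. These deliberately use naive
# brute-force routes (all-pairs enumeration, grid/simplex maximization,
# dense matrix algebra, permutation resampling) so they share no code with
# the implementation they check.

# concordance by explicit enumeration of every (event, non-event) pair
allpairs_cstat <- function(pred, obs) {
  obs <- as.numeric(obs)
  pos <- pred[obs == 1]
  neg <- pred[obs == 0]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  total / (length(pos) * length(neg))
}

# maximized Bernoulli log-likelihood for a 1-covariate logistic model,
# by Nelder-Mead from several starts
bruteforce_logistic_loglik <- function(y, x) {
  nll <- function(b) {
    eta <- b[1] + b[2] * x
    -sum(y * eta - log1p(exp(eta)))
  }
  best <- Inf
  for (start in list(c(0, 0), c(-1, 1), c(1, -1), c(0, 2))) {
    o <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  -best
}

# posterior-mean unit intercepts through the dense n x n covariance solve
blup_matrix_oracle <- function(resid, icu_ids, sigma_b, sigma_e) {
  icu <- factor(icu_ids)
  Z <- stats::model.matrix(~ icu - 1)
  V <- sigma_b^2 * Z %*% t(Z) + sigma_e^2 * diag(length(resid))
  u <- sigma_b^2 * t(Z) %*% solve(V, resid)
  stats::setNames(as.numeric(u), levels(icu))
}

# two-sided permutation p-value for the Pearson correlation
perm_pvalue_pearson <- function(x, y, n_perm = 1e5, seed = 99) {
  set.seed(seed)
  r_obs <- stats::cor(x, y)
  perms <- replicate(n_perm, stats::cor(x, sample(y)))
  mean(abs(perms) >= abs(r_obs) - 1e-12)
}

# registry small enough for fast unit tests
small_params <- function(seed = 101, ...) {
  registry_params(n_icus = 6, icu_sizes = rep(150L, 6), seed = seed, ...)
}

# lean pipeline fragment: registry -> cohort + recalibrated mortality fit
quick_cohort <- function(params) {
  reg <- simulate_registry(params)
  cohort <- readmission_risk_set(apply_exclusions(reg$admissions))
  list(reg = reg, cohort = cohort)
}
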