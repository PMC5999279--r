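#' Scaled Brier score
#'
#' `1 - Brier / Brier_ref`, where the reference model predicts the event
#' prevalence for every subject. 1 means perfect prediction, 0 means no
#' better than prevalence; negative values are possible for models worse
#' than the prevalence.
#'
#' @param pred Predicted event probabilities.
#' @param obs Binary outcomes (0/1 or logical).
#' @return A single number `<= 1`.
#' @export
#' @examples
#' scaled_brier(c(0.8, 0.2, 0.6, 0.4), c(1, 0, 1, 0))  # 0.6
scaled_brier <- function(pred, obs) {
  obs <- as.numeric(obs)
  stopifnot(length(pred) == length(obs))
  ybar <- mean(obs)
  if (ybar == 0 || ybar == 1)
    abort_icubench(
      "Scaled Brier score undefined: outcomes are single-class, the reference Brier score is zero.",
      "icubench_single_class")
  1 - mean((pred - obs)^2) / (ybar * (1 - ybar))
}

#' Concordance index (C-statistic)
#'
#' Fraction of (event, non-event) pairs in which the event received the
#' higher prediction, counting tied predictions as half. Computed via mean
#' ranks (Wilcoxon identity), so it scales to large cohorts; equal to the
#' all-pairs enumeration.
#'
#' @inheritParams scaled_brier
#' @return A number in [0, 1].
#' @export
#' @examples
#' c_statistic(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))  # 0.75
c_statistic <- function(pred, obs) {
  obs <- as.numeric(obs)
  stopifnot(length(pred) == length(obs))
  n1 <- sum(obs == 1); n0 <- sum(obs == 0)
  if (n1 == 0 || n0 == 0)
    abort_icubench(
      "C-statistic undefined: outcomes are single-class.",
      "icubench_single_class")
  r <- rank(pred)  # average ranks give ties half credit
  (sum(r[obs == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Calibration table over equally sized prediction groups
#'
#' Sorts subjects by predicted value (stable, ties broken by input order),
#' splits them into `n_groups` contiguous groups whose sizes differ by at
#' most one (any remainder goes to the last groups), and reports per group
#' the size and the mean predicted and observed outcome. Comparing the two
#' columns assesses calibration-in-the-mean across the risk spectrum.
#'
#' @inheritParams scaled_brier
#' @param obs Observed outcomes (binary or continuous).
#' @param n_groups Number of groups (default 50).
#' @return Tibble (`group`, `n`, `mean_predicted`, `mean_observed`).
#' @export
calibration_groups <- function(pred, obs, n_groups = 50) {
  obs <- as.numeric(obs)
  n <- length(pred)
  stopifnot(length(obs) == n)
  if (n < n_groups)
    abort_icubench(
      sprintf("Need at least %d observations for %d calibration groups, got %d.",
              n_groups, n_groups, n),
      "icubench_too_few")
  ord <- order(pred, seq_len(n))
  base <- n %/% n_groups
  sizes <- rep(base, n_groups)
  extra <- n - base * n_groups
  if (extra > 0)
    sizes[(n_groups - extra + 1):n_groups] <- base + 1
  grp <- rep(seq_len(n_groups), times = sizes)
  tibble::tibble(
    group = seq_len(n_groups),
    n = sizes,
    mean_predicted = as.numeric(tapply(pred[ord], grp, mean)),
    mean_observed = as.numeric(tapply(obs[ord], grp, mean)))
}
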