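#' Correlation with Student-t p-value
#'
#' `pearson_with_p()` computes the sample Pearson correlation and its
#' two-sided p-value from the exact t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' `spearman_with_p()` applies the same transform to the Pearson correlation
#' of average ranks (ties receive mean ranks), the large-sample
#' approximation appropriate at typical unit counts; for tiny samples
#' (`n <= 10`) an exact permutation p-value over all orderings is available.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, neither constant.
#' @param exact For `spearman_with_p()`: compute the p-value by full
#'   permutation enumeration (only allowed for `n <= 10`).
#' @return Tibble with columns `r`, `p`, `n`.
#' @export
#' @examples
#' pearson_with_p(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
pearson_with_p <- function(x, y) {
  check_corr_input(x, y)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' @rdname pearson_with_p
#' @export
spearman_with_p <- function(x, y, exact = FALSE) {
  check_corr_input(x, y)
  n <- length(x)
  rho <- stats::cor(rank(x), rank(y))
  if (exact) {
    if (n > 10)
      abort_icubench("Exact permutation p-values are limited to n <= 10.",
                     "icubench_too_large")
    rx <- rank(x)
    perms <- permutations_of(n)
    ry <- rank(y)
    null_rho <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  } else {
    p <- t_transform_p(rho, n)
  }
  tibble::tibble(r = rho, p = p, n = n)
}

t_transform_p <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

check_corr_input <- function(x, y) {
  if (length(x) != length(y))
    abort_icubench("`x` and `y` must have equal length.",
                   "icubench_bad_input")
  if (length(x) < 3)
    abort_icubench("Correlation requires at least 3 observations.",
                   "icubench_too_few")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    abort_icubench("Correlation undefined for constant input.",
                   "icubench_constant_input")
  invisible(NULL)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

indicator_pairs <- list(c("SMR", "SRR"), c("SMR", "SLOSR"), c("SLOSR", "SRR"))

#' Pairwise unit-level associations between quality indicators
#'
#' For every subgroup in the indicator table and each indicator pair
#' (SMR--SRR, SMR--SLOSR, SLOSR--SRR), computes the correlation across ICUs
#' contributing both indicators (pairwise-complete deletion) and flags
#' significance at `alpha`. Subgroup-pair cells with fewer than 3 complete
#' ICUs are omitted with a warning.
#'
#' @param table An `indicator_table` from [compute_indicator_table()].
#' @param method `"pearson"` (primary analysis) or `"spearman"`
#'   (rank-based sensitivity analysis).
#' @param alpha Significance level (default 0.01).
#' @return Tibble (`subgroup`, `pair`, `method`, `r`, `p`, `n_icus`,
#'   `significant`), ordered subgroup-major in report order.
#' @export
pairwise_indicator_associations <- function(table,
                                            method = c("pearson", "spearman"),
                                            alpha = 0.01) {
  method <- match.arg(method)
  stopifnot(alpha > 0, alpha < 1)
  corr_fun <- if (method == "pearson") pearson_with_p else spearman_with_p
  subgroups <- intersect(subgroup_levels, unique(table$subgroup))
  res <- purrr::map_dfr(subgroups, function(sg) {
    sub <- table[table$subgroup == sg, , drop = FALSE]
    purrr::map_dfr(indicator_pairs, function(pr) {
      x <- sub[[pr[1]]]; y <- sub[[pr[2]]]
      ok <- stats::complete.cases(x, y)
      pair_label <- paste(pr, collapse = "-")
      if (sum(ok) < 3) {
        warning(sprintf(
          "Subgroup '%s', pair %s: fewer than 3 ICUs with both indicators; omitted.",
          sg, pair_label), call. = FALSE)
        return(NULL)
      }
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        # a fully shrunk (sigma_b = 0) subgroup fit makes an indicator constant
        warning(sprintf(
          "Subgroup '%s', pair %s: an indicator is constant across ICUs; omitted.",
          sg, pair_label), call. = FALSE)
        return(NULL)
      }
      ct <- corr_fun(x[ok], y[ok])
      tibble::tibble(subgroup = sg, pair = pair_label, method = method,
                     r = ct$r, p = ct$p, n_icus = ct$n,
                     significant = ct$p < alpha)
    })
  })
  res
}

#' Export indicator pairs for a scatter plot panel
#'
#' Returns one point per ICU with both indicators present in the given
#' subgroup: coordinates, the ICU identifier and its admission count.
#'
#' @param table An `indicator_table`.
#' @param pair One of `"SMR-SRR"`, `"SMR-SLOSR"`, `"SLOSR-SRR"`.
#' @param subgroup A subgroup present in the table.
#' @return Tibble (`x`, `y`, `icu_id`, `n`); `x` is the first indicator of
#'   the pair.
#' @export
scatter_export <- function(table, pair, subgroup) {
  known_pairs <- vapply(indicator_pairs, paste, "", collapse = "-")
  if (!pair %in% known_pairs)
    abort_icubench(sprintf("Unknown indicator pair '%s'.", pair),
                   "icubench_bad_pair")
  if (!subgroup %in% table$subgroup)
    abort_icubench(sprintf("Subgroup '%s' is not in the indicator table.",
                           subgroup),
                   "icubench_bad_subgroup")
  parts <- strsplit(pair, "-", fixed = TRUE)[[1]]
  sub <- table[table$subgroup == subgroup, , drop = FALSE]
  n <- dplyr::case_when(parts[1] == "SMR" ~ sub$n_mortality,
                        parts[1] == "SRR" ~ sub$n_risk_set,
                        TRUE ~ sub$n_los)
  out <- tibble::tibble(x = sub[[parts[1]]], y = sub[[parts[2]]],
                        icu_id = sub$icu_id, n = n)
  out[stats::complete.cases(out$x, out$y), , drop = FALSE]
}

#' Table of associations in report shape
#'
#' Pivots the long association results into the report layout: one row per
#' subgroup, coefficient and p-value columns per indicator pair.
#'
#' @param associations Output of [pairwise_indicator_associations()].
#' @return Wide tibble, one row per subgroup.
#' @export
association_report <- function(associations) {
  tidyr::pivot_wider(
    dplyr::select(associations, "subgroup", "pair", "r", "p"),
    names_from = "pair", values_from = c("r", "p"),
    names_glue = "{pair}_{.value}")
}
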