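#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a case-mix model fit
#'
#' @param x A `casemix_fit`.
#' @param ... Unused.
#' @return One tibble row per coefficient (`term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`).
#' @method tidy casemix_fit
#' @export
tidy.casemix_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @rdname tidy.casemix_fit
#' @return For `glance()`: a one-row tibble of model-performance metrics
#'   (`outcome`, `n`, `scaled_brier`, `c_statistic`, `r_squared`).
#' @method glance casemix_fit
#' @export
glance.casemix_fit <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(outcome = x$outcome, n = nrow(x$predictions),
                 scaled_brier = m$scaled_brier %||% NA_real_,
                 c_statistic = m$c_statistic %||% NA_real_,
                 r_squared = m$r_squared %||% NA_real_)
}

#' Tidy a reliability-adjustment fit
#'
#' @param x A `shrinkage_fit`.
#' @param ... Unused.
#' @return One tibble row per ICU (`icu_id`, `u`, `n`).
#' @method tidy shrinkage_fit
#' @export
tidy.shrinkage_fit <- function(x, ...) {
  tibble::tibble(icu_id = names(x$u), u = unname(x$u),
                 n = as.integer(x$n_per_icu[names(x$u)]))
}

#' @rdname tidy.shrinkage_fit
#' @return For `glance()`: one row with `outcome`, `subgroup`, `sigma_b`,
#'   `sigma_e`, the fixed effects and the subgroup overall rate / mean.
#' @method glance shrinkage_fit
#' @export
glance.shrinkage_fit <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, subgroup = x$subgroup,
                 sigma_b = x$sigma_b, sigma_e = x$sigma_e %||% NA_real_,
                 intercept = unname(x$beta[1]), slope = unname(x$beta[2]),
                 overall_rate = x$overall_rate,
                 n_icus = length(x$u), n = sum(x$n_per_icu))
}
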