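#' Logit and inverse-logit
#'
#' Thin wrappers over [stats::qlogis()] and [stats::plogis()] used throughout
#' the package to move between probability and log-odds scales.
#'
#' @param p Probabilities in (0, 1).
#' @param x Log-odds.
#' @return Numeric vector.
#' @keywords internal
#' @name logit
NULL

#' @rdname logit
logit <- function(p) stats::qlogis(p)

#' @rdname logit
invlogit <- function(x) stats::plogis(x)

# abort with a class so callers can test error conditions precisely
abort_icubench <- function(message, class) {
  rlang::abort(message, class = c(class, "icubench_error"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

admission_types <- c("medical", "urgent_surgery", "elective_surgery")
diag_groups <- c("CAP", "sepsis", "OHCA", "other")
discharge_destinations <- c("ward", "other_icu", "outside_hospital", "died")
risk_strata <- c("risk_low", "risk_medium", "risk_high")
indicator_names <- c("SMR", "SRR", "SLOSR")

# canonical subgroup order used in report tables
subgroup_levels <- c("all", "CAP", "sepsis", "OHCA",
                     "medical", "urgent_surgery", "elective_surgery",
                     "risk_low", "risk_medium", "risk_high")
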