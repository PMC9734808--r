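## Incidence rate ratios: exp of a Poisson log-mean coefficient, with the
## conventional percentage reading ((IRR - 1) * 100% above one,
## (1 - IRR) * 100% below one).

#' Incidence rate ratio of a Poisson coefficient
#'
#' @param coefficient Poisson log-mean coefficient(s).
#' @return `exp(coefficient)`.
#' @export
irr <- function(coefficient) exp(coefficient)

#' Percentage interpretation of an incidence rate ratio
#'
#' A unit covariate increase multiplies the expected count by the IRR; the
#' conventional reading is a `(IRR - 1) * 100` percent increase when the IRR
#' exceeds one and a `(1 - IRR) * 100` percent decrease otherwise.
#'
#' @param irr incidence rate ratio(s).
#' @return named-free numeric vector of percentages (always non-negative;
#'   see `direction`).
#' @export
irr_pct <- function(irr) ifelse(irr >= 1, (irr - 1) * 100, (1 - irr) * 100)

#' Per-regime incidence rate ratio table for a fitted switching model
#'
#' Exponentiates both regimes' coefficients and attaches significance stars
#' carried over from the coefficient z-tests (the IRR is significant exactly
#' when its log is).
#'
#' @param fit an `esc_fit` with standard errors.
#' @param digits rounding for the displayed IRRs (default 3, the usual table
#'   convention).
#' @return data frame with one row per outcome covariate (plus intercept):
#'   IRR and stars for the treated and untreated regimes, and the percent
#'   interpretation of each IRR.
#' @export
irr_table <- function(fit, digits = 3) {
  stopifnot(inherits(fit, "esc_fit"))
  if (is.null(fit$coef_table)) stop("fit carries no standard errors")
  tab <- fit$coef_table
  vars <- colnames(fit$frame$X)
  pick <- function(prefix) tab[match(paste0(prefix, vars), tab$parameter), ]
  t1 <- pick("beta1."); t0 <- pick("beta0.")
  data.frame(variable = vars,
             irr_treated = round(irr(t1$estimate), digits),
             stars_treated = t1$stars,
             pct_treated = round(irr_pct(irr(t1$estimate)), 1),
             irr_control = round(irr(t0$estimate), digits),
             stars_control = t0$stars,
             pct_control = round(irr_pct(irr(t0$estimate)), 1))
}
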