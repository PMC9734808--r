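## Counterfactual expected outcomes and treatment effects. For regime j and
## conditioning treatment status T (s = 2T - 1):
##   E(Y_j | X, T) = exp(X'beta_j + sigma_j^2 / 2)
##                   * Phi{ s (rho_j sigma_j + Z'alpha) } / Phi{ s Z'alpha }
## evaluated in log space so deep-tail selection indices never divide by an
## underflowed normal probability. ATT averages E(Y1|X,1) - E(Y0|X,1) over
## the treated; ATU averages E(Y1|X,0) - E(Y0|X,0) over the untreated.

eo_core <- function(params, X, Z, regime, conditioning) {
  nat <- esc_natural(params)
  beta <- if (regime == 1) params$beta1 else params$beta0
  sigma <- if (regime == 1) nat[["sigma1"]] else nat[["sigma0"]]
  rho <- if (regime == 1) nat[["rho1"]] else nat[["rho0"]]
  s <- 2 * conditioning - 1
  idx <- drop(Z %*% params$alpha)
  exp(drop(X %*% beta) + sigma^2 / 2 +
        pnorm(s * (rho * sigma + idx), log.p = TRUE) -
        pnorm(s * idx, log.p = TRUE))
}

#' Conditional expected outcome under a chosen regime
#'
#' Model-implied expected count had the households in `data` occupied
#' `regime`, conditional on their actual (or hypothesised) treatment status
#' `conditioning`. With `regime != conditioning` this is a counterfactual
#' mean; with `rho = 0` the selection correction cancels and the value
#' reduces to `exp(X'beta_j + sigma_j^2 / 2)`.
#'
#' @param fit an `esc_fit` (or an [esc_params()] combined with `data` whose
#'   roles match `fit$frame`).
#' @param data data frame of households; defaults to the fitting data.
#' @param regime outcome regime, 1 (treated equation) or 0.
#' @param conditioning treatment status conditioned on, 1 or 0.
#' @return numeric vector of expected counts, one per row of `data`.
#' @export
expected_outcome <- function(fit, data = NULL, regime = 1, conditioning = 1) {
  stopifnot(inherits(fit, "esc_fit"), regime %in% c(0, 1),
            conditioning %in% c(0, 1))
  fr <- fit$frame
  if (is.null(data)) {
    X <- fr$X; Z <- fr$Z
  } else {
    f2 <- esc_frame(cbind(data,
                          if (!fr$outcome %in% names(data))
                            setNames(data.frame(0L), fr$outcome)),
                    fr$outcome,
                    fr$treatment, fr$covariates, fr$iv)
    X <- f2$X; Z <- f2$Z
  }
  eo_core(fit$params, X, Z, regime, conditioning)
}

new_effect <- function(effect, mu1, mu0, n_group, se = NA_real_) {
  point <- mean(mu1) - mean(mu0)
  baseline <- mean(mu0)  # regime-0 mean within the group
  factual <- if (effect == "ATT") mu1 else mu0
  counterfactual <- if (effect == "ATT") mu0 else mu1
  structure(list(effect = effect, point = point,
                 pct_change = pct_change(point, baseline),
                 mean_factual = mean(factual),
                 mean_counterfactual = mean(counterfactual),
                 sd_factual = if (length(factual) > 1) sd(factual) else 0,
                 sd_counterfactual = if (length(counterfactual) > 1)
                   sd(counterfactual) else 0,
                 sd_effects = if (length(mu1) > 1) sd(mu1 - mu0) else 0,
                 se = se, n_group = n_group),
            class = "esc_effect")
}

#' Treatment effect from group mean outcomes
#'
#' Builds an effect summary directly from a group's two regime means (e.g.
#' values printed in a results table): the point effect is the regime-1 mean
#' minus the regime-0 mean and the percent change divides by the regime-0
#' mean within the group — the counterfactual mean for the treated group,
#' the factual mean for the untreated group.
#'
#' @param mean_y1 mean expected outcome under the treated regime.
#' @param mean_y0 mean expected outcome under the untreated regime.
#' @param effect `"ATT"` or `"ATU"`.
#' @param n_group group size (optional).
#' @return an `esc_effect`.
#' @export
effect_from_means <- function(mean_y1, mean_y0, effect = c("ATT", "ATU"),
                              n_group = NA_integer_) {
  effect <- match.arg(effect)
  new_effect(effect, mean_y1, mean_y0, n_group)
}

#' Average treatment effect on the treated (ATT)
#'
#' Averages, over treated households, the gap between the factual expected
#' outcome `E(Y1 | X, T = 1)` and the counterfactual `E(Y0 | X, T = 1)`.
#' The percent change is relative to the counterfactual mean.
#'
#' @inheritParams expected_outcome
#' @return an `esc_effect`.
#' @export
att <- function(fit, data = NULL) {
  fr <- fit$frame
  tr <- if (is.null(data)) fr$tr else data[[fr$treatment]]
  if (!any(tr == 1)) stop("no treated rows: ATT undefined")
  keep <- tr == 1
  mu1 <- expected_outcome(fit, data, regime = 1, conditioning = 1)[keep]
  mu0 <- expected_outcome(fit, data, regime = 0, conditioning = 1)[keep]
  new_effect("ATT", mu1, mu0, sum(keep))
}

#' Average treatment effect on the untreated (ATU)
#'
#' Averages, over untreated households, the gap between the counterfactual
#' `E(Y1 | X, T = 0)` and the factual `E(Y0 | X, T = 0)`. The percent change
#' is relative to the factual untreated mean.
#'
#' @inheritParams expected_outcome
#' @return an `esc_effect`.
#' @export
atu <- function(fit, data = NULL) {
  fr <- fit$frame
  tr <- if (is.null(data)) fr$tr else data[[fr$treatment]]
  if (!any(tr == 0)) stop("no untreated rows: ATU undefined")
  keep <- tr == 0
  mu1 <- expected_outcome(fit, data, regime = 1, conditioning = 0)[keep]
  mu0 <- expected_outcome(fit, data, regime = 0, conditioning = 0)[keep]
  new_effect("ATU", mu1, mu0, sum(keep))
}

#' Standard errors for ATT and ATU
#'
#' Nonparametric household bootstrap (resample rows, refit from the original
#' estimate, recompute both effects; the SE is the SD over replicates) or a
#' parametric alternative that draws parameter vectors from the asymptotic
#' normal of the fit without refitting.
#'
#' @param fit a converged `esc_fit` with robust covariance (needed for
#'   `method = "parametric"`).
#' @param B number of replicates; fewer than 100 triggers a warning.
#' @param seed integer seed; identical seed and `B` reproduce the SEs.
#' @param method `"bootstrap"` (refits) or `"parametric"` (draws).
#' @return list with `ATT` and `ATU` (`esc_effect`s carrying `se`),
#'   the replicate matrix, and the number of failed replicates.
#' @export
effect_se <- function(fit, B = 200, seed = 1,
                      method = c("bootstrap", "parametric")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "esc_fit"), B >= 2)
  if (B < 100) warning("B < 100 replicates: standard errors will be noisy")
  fr <- fit$frame
  reps <- matrix(NA_real_, B, 2, dimnames = list(NULL, c("ATT", "ATU")))
  set.seed(seed)
  if (method == "bootstrap") {
    dat <- as.data.frame(cbind(fr$X[, -1, drop = FALSE], fr$Z[, fr$iv,
                                                              drop = FALSE]))
    dat[[fr$outcome]] <- fr$Y
    dat[[fr$treatment]] <- fr$tr
    failed <- 0
    for (b in seq_len(B)) {
      idx <- sample.int(nrow(dat), replace = TRUE)
      rb <- tryCatch({
        ## replicate fits use a relaxed gradient tolerance: resampling noise
        ## dwarfs optimiser noise at the default tolerance
        fb <- suppressWarnings(
          fit_esc(dat[idx, , drop = FALSE], fr$outcome, fr$treatment,
                  fr$covariates, fr$iv, nodes = fit$nodes,
                  tol = max(fit$tol, 1e-4), start = fit$params, se = FALSE,
                  optimizer = fit$optimizer))
        ## accept replicates at the optimiser's own stopping rule: near the
        ## sigma boundary the strict gradient criterion can be unattainable
        ## while the optimum is located to far better than resampling noise
        if (!fb$converged && fb$opt_convergence != 0) NULL
        else c(att(fb)$point, atu(fb)$point)
      }, error = function(e) NULL)
      if (is.null(rb)) failed <- failed + 1 else reps[b, ] <- rb
    }
    if (failed > 0.2 * B)
      stop("bootstrap aborted: ", failed, " of ", B,
           " replicates failed to converge")
  } else {
    if (is.null(fit$vcov_robust))
      stop("parametric draws need the fit's robust covariance")
    V <- fit$vcov_robust
    e <- eigen((V + t(V)) / 2, symmetric = TRUE)
    L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(V))
    thetas <- matrix(rnorm(B * nrow(V)), B) %*% t(L)
    keep1 <- fr$tr == 1; keep0 <- fr$tr == 0
    for (b in seq_len(B)) {
      th <- fit$theta
      th[fit$free] <- th[fit$free] + thetas[b, ]
      pb <- unpack_theta(th, fr)
      reps[b, 1] <- mean(eo_core(pb, fr$X, fr$Z, 1, 1)[keep1] -
                           eo_core(pb, fr$X, fr$Z, 0, 1)[keep1])
      reps[b, 2] <- mean(eo_core(pb, fr$X, fr$Z, 1, 0)[keep0] -
                           eo_core(pb, fr$X, fr$Z, 0, 0)[keep0])
    }
    failed <- 0
  }
  se <- apply(reps, 2, sd, na.rm = TRUE)
  a1 <- att(fit); a1$se <- se[["ATT"]]
  a0 <- atu(fit); a0$se <- se[["ATU"]]
  list(ATT = a1, ATU = a0, replicates = reps, n_failed = failed,
       method = method)
}

#' @export
print.esc_effect <- function(x, ...) {
  cat(sprintf("%s: %.4f (%.2f%%)  [factual %.4f, counterfactual %.4f, n = %s]\n",
              x$effect, x$point, x$pct_change, x$mean_factual,
              x$mean_counterfactual, x$n_group))
  if (is.finite(x$se)) cat(sprintf("  SE = %.4f\n", x$se))
  invisible(x)
}
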