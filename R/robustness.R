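## Robustness toolkit: the instrument falsification test (relevance in the
## selection probit, exclusion in the untreated outcome equation), a
## single-equation Poisson model with an endogenous binary treatment
## (treatment dummy inside X, one shared heterogeneity term correlated with
## the selection error), and inverse-probability-weighted regression
## adjustment (IPWRA) for the ATT.

#' Falsification test of the instrumental variable
#'
#' A valid instrument must predict treatment (relevance: z-test of the IV in
#' a probit of the treatment on Z) while being excludable from the outcome
#' process (exclusion: z-test of the IV added to a Poisson-lognormal
#' regression of the outcome on X, among untreated households, where the
#' outcome is untouched by the treatment).
#'
#' @inheritParams esc_loglik
#' @param relevance_p relevance passes when the IV's selection p-value is
#'   below this threshold (default 0.01).
#' @param exclusion_p exclusion passes when the IV's outcome p-value among
#'   the untreated exceeds this threshold (default 0.10).
#' @param nodes quadrature order for the outcome regression.
#' @return object of class `esc_falsification` with the two z-statistics and
#'   p-values, the thresholds, and `verdict` (`"pass"`/`"fail"`, `NA` when
#'   the exclusion test is undefined because the IV is constant among the
#'   untreated).
#' @export
falsification_test <- function(data, outcome = "dds", treatment = "ofs",
                               covariates = default_covariates(),
                               iv = "peer_online",
                               relevance_p = 0.01, exclusion_p = 0.10,
                               nodes = 16) {
  stopifnot(length(iv) == 1)
  fr <- esc_frame(data, outcome, treatment, covariates, iv)
  if (!any(fr$tr == 0)) stop("untreated arm is empty")
  Zd <- as.data.frame(fr$Z[, -1, drop = FALSE])
  Zd$.tr <- fr$tr
  pr <- suppressWarnings(glm(.tr ~ ., data = Zd, family = binomial("probit")))
  prt <- summary(pr)$coefficients
  rel_z <- prt[iv, "z value"]
  rel_p <- prt[iv, "Pr(>|z|)"]

  idx0 <- fr$tr == 0
  iv0 <- fr$Z[idx0, iv]
  if (var(iv0) == 0) {
    warning("IV is constant among the untreated: exclusion test undefined")
    excl_z <- NA_real_; excl_p <- NA_real_
    verdict <- NA_character_
  } else {
    X0 <- cbind(fr$X[idx0, , drop = FALSE], fr$Z[idx0, iv, drop = FALSE])
    pf <- pln_fit(fr$Y[idx0], X0, nodes = nodes)
    row <- pf$table[pf$table$parameter == iv, ]
    excl_z <- row$z; excl_p <- row$p_value
    verdict <- if (rel_p < relevance_p && excl_p > exclusion_p) "pass"
               else "fail"
  }
  structure(list(iv = iv, iv_relevance_z = rel_z, iv_relevance_p = rel_p,
                 iv_exclusion_z = excl_z, iv_exclusion_p = excl_p,
                 relevance_threshold = relevance_p,
                 exclusion_threshold = exclusion_p, verdict = verdict),
            class = "esc_falsification")
}

#' @export
print.esc_falsification <- function(x, ...) {
  cat("IV falsification test for '", x$iv, "'\n", sep = "")
  cat(sprintf("  relevance (selection probit): z = %.2f, p = %.3g (need p < %g)\n",
              x$iv_relevance_z, x$iv_relevance_p, x$relevance_threshold))
  cat(sprintf("  exclusion (untreated outcome): z = %.2f, p = %.3g (need p > %g)\n",
              x$iv_exclusion_z, x$iv_exclusion_p, x$exclusion_threshold))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

## ---- endogenous-treatment Poisson (single outcome equation) ----------------

#' Poisson regression with an endogenous binary treatment
#'
#' A single count equation with the treatment dummy among the regressors,
#' `log E(Y | X, T, eta) = X'beta + tau T + eta`, whose lognormal
#' heterogeneity `eta = sigma u` is correlated (`rho`) with the probit
#' selection error — the one-equation counterpart of [fit_esc()], estimated
#' with the same quadrature machinery and a single `(sigma, rho)` pair.
#'
#' @inheritParams fit_esc
#' @param fix optional named numeric vector pinning parameters (e.g.
#'   `c(arho = 0)` for the exogenous-treatment restriction, under which the
#'   model factorises into a probit plus a pooled Poisson-lognormal
#'   regression with a treatment dummy).
#' @return object of class `prete_fit`: coefficient table (sandwich SEs),
#'   `treatment_coef`, `pct_effect` (`(exp(tau) - 1) * 100`), `loglik`,
#'   convergence metadata.
#' @export
fit_prete <- function(data, outcome = "dds", treatment = "ofs",
                      covariates = default_covariates(), iv = "peer_online",
                      nodes = 32, tol = 1e-6, max_iter = 500, se = TRUE,
                      fix = NULL) {
  fr <- esc_frame(data, outcome, treatment, covariates, iv)
  if (!any(fr$tr == 1) || !any(fr$tr == 0)) stop("both arms must be non-empty")
  Xt <- cbind(fr$X, treatment = fr$tr)
  check_full_rank(Xt, "outcome")
  check_full_rank(fr$Z, "selection")
  pz <- ncol(fr$Z); px <- ncol(Xt)
  pr <- suppressWarnings(glm.fit(fr$Z, fr$tr, family = binomial("probit")))
  po <- suppressWarnings(glm.fit(Xt, fr$Y, family = poisson()))
  theta0 <- setNames(c(pmin(pmax(coef(pr), -20), 20),
                       pmin(pmax(coef(po), -20), 20), log(0.5), 0),
                     c(paste0("alpha.", colnames(fr$Z)),
                       paste0("beta.", colnames(Xt)), "ln_sigma", "arho"))
  gh <- gh_rule(nodes)
  core <- function(th, want_scores = FALSE) {
    alpha <- th[seq_len(pz)]
    beta <- th[pz + seq_len(px)]
    sigma <- exp(th[[pz + px + 1]])
    rho <- tanh(th[[pz + px + 2]])
    n <- length(fr$Y)
    ll <- numeric(n)
    scores <- if (want_scores) matrix(0, n, length(th),
                                      dimnames = list(NULL, names(th)))
    for (j in c(1L, 0L)) {
      idx <- which(fr$tr == j)
      if (!length(idx)) next
      arm <- arm_loglik(fr$Y[idx], Xt[idx, , drop = FALSE],
                        fr$Z[idx, , drop = FALSE], 2 * j - 1, beta, alpha,
                        sigma, rho, gh, want_scores = want_scores)
      ll[idx] <- arm$ll
      if (want_scores) {
        scores[idx, seq_len(pz)] <- fr$Z[idx, , drop = FALSE] * arm$g_c
        scores[idx, pz + seq_len(px)] <- Xt[idx, , drop = FALSE] * arm$g_mu
        scores[idx, pz + px + 1] <- arm$g_lnsig
        scores[idx, pz + px + 2] <- arm$g_arho
      }
    }
    out <- list(loglik = sum(fr$w * ll), per_obs = ll)
    if (want_scores) {
      out$scores <- scores * fr$w
      out$grad <- colSums(out$scores)
    }
    out
  }
  free <- rep(TRUE, length(theta0))
  if (!is.null(fix)) {
    unknown <- setdiff(names(fix), names(theta0))
    if (length(unknown))
      stop("fix refers to unknown parameter(s): ",
           paste(unknown, collapse = ", "))
    theta0[names(fix)] <- fix
    free[match(names(fix), names(theta0))] <- FALSE
  }
  res <- run_mle(theta0, free, core, max_iter = max_iter)
  final <- core(res$theta, want_scores = TRUE)
  score_norm <- max(abs(final$grad[free]))
  tau <- res$theta[[pz + px]]
  out <- list(theta = res$theta, loglik = final$loglik,
              treatment_coef = tau, pct_effect = (exp(tau) - 1) * 100,
              sigma = exp(res$theta[[pz + px + 1]]),
              rho = tanh(res$theta[[pz + px + 2]]),
              score_norm = score_norm,
              converged = score_norm < tol * (1 + abs(final$loglik)),
              nodes = nodes, n = length(fr$Y))
  if (se) {
    gfree <- function(par) {
      th <- res$theta; th[free] <- par
      core(th, want_scores = TRUE)$grad[free]
    }
    H <- grad_hessian(gfree, res$theta[free])
    S <- crossprod(final$scores[, free, drop = FALSE] / sqrt(fr$w))
    bread <- neg_inverse(H)
    Vf <- bread %*% S %*% bread
    Vf <- (Vf + t(Vf)) / 2
    nmf <- names(res$theta)[free]
    dimnames(Vf) <- list(nmf, nmf)
    V <- matrix(NA_real_, length(res$theta), length(res$theta),
                dimnames = list(names(res$theta), names(res$theta)))
    V[nmf, nmf] <- Vf
    sev <- setNames(rep(NA_real_, length(res$theta)), names(res$theta))
    sev[free] <- sqrt(pmax(diag(Vf), 0))
    tab <- data.frame(parameter = names(res$theta),
                      estimate = unname(res$theta), se = unname(sev))
    tab$z <- tab$estimate / tab$se
    tab$p_value <- 2 * pnorm(-abs(tab$z))
    tab$stars <- p_stars(tab$p_value)
    out$vcov <- V
    out$table <- tab
    out$treatment_se <- sev[[pz + px]]
  }
  structure(out, class = "prete_fit")
}

#' @export
print.prete_fit <- function(x, ...) {
  cat("Endogenous-treatment Poisson model (single equation)\n")
  cat(sprintf("  n = %d  loglik = %.3f  converged: %s\n", x$n, x$loglik,
              x$converged))
  cat(sprintf("  treatment coefficient = %.4f (implied %%%.2f)  sigma = %.4g  rho = %.3f\n",
              x$treatment_coef, x$pct_effect, x$sigma, x$rho))
  invisible(x)
}

## ---- IPWRA -----------------------------------------------------------------

#' Inverse-probability-weighted regression adjustment for the ATT
#'
#' Doubly robust estimator addressing selection on observables: a probit
#' propensity model on Z, ATT weights (1 for the treated, `p/(1-p)` for
#' controls), arm-specific weighted Poisson regressions of the outcome on X,
#' and the ATT as the mean difference of both arms' fitted means over the
#' treated. Unlike [fit_esc()], no allowance is made for unobserved
#' selection.
#'
#' @inheritParams esc_loglik
#' @param trim propensity trimming bounds; rows outside are dropped with a
#'   warning when more than 10 percent go.
#' @return an `esc_effect` (with `weights` and `n_trimmed` attributes).
#' @export
ipwra_att <- function(data, outcome = "dds", treatment = "ofs",
                      covariates = default_covariates(), iv = "peer_online",
                      trim = c(0.01, 0.99)) {
  fr <- esc_frame(data, outcome, treatment, covariates, iv)
  pr <- suppressWarnings(glm.fit(fr$Z, fr$tr, family = binomial("probit")))
  p <- pr$fitted.values
  keep <- p >= trim[1] & p <= trim[2]
  n_trim <- sum(!keep)
  if (n_trim > 0.1 * length(p))
    warning("propensity trimming removed ", n_trim, " of ", length(p), " rows")
  Y <- fr$Y[keep]; X <- fr$X[keep, , drop = FALSE]
  tr <- fr$tr[keep]; p <- p[keep]
  w <- ifelse(tr == 1, 1, p / (1 - p))
  fit1 <- suppressWarnings(glm.fit(X[tr == 1, , drop = FALSE], Y[tr == 1],
                                   weights = w[tr == 1], family = poisson()))
  fit0 <- suppressWarnings(glm.fit(X[tr == 0, , drop = FALSE], Y[tr == 0],
                                   weights = w[tr == 0], family = poisson()))
  Xt <- X[tr == 1, , drop = FALSE]
  mu1 <- exp(drop(Xt %*% coef(fit1)))
  mu0 <- exp(drop(Xt %*% coef(fit0)))
  eff <- new_effect("ATT", mu1, mu0, sum(tr == 1))
  attr(eff, "weights") <- w
  attr(eff, "kept") <- keep
  attr(eff, "n_trimmed") <- n_trim
  eff
}
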