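## Poisson-lognormal regression: a single count equation whose log-mean
## carries normal heterogeneity, log E(Y | X, eta) = X'beta + eta,
## eta ~ N(0, sigma^2), estimated by Gauss-Hermite maximum likelihood.
## This is the rho = 0 margin of the switching model and is kept as an
## independent one-dimensional mixture routine: it backs the falsification
## test's outcome regression and serves as the factorisation oracle for the
## joint likelihood.

#' Poisson-lognormal log-likelihood
#'
#' @param beta named coefficient vector (first element the intercept,
#'   matching the columns of `X`).
#' @param ln_sigma log heterogeneity SD.
#' @param Y non-negative integer counts.
#' @param X design matrix including the intercept column.
#' @param nodes quadrature order.
#' @param weights optional positive weights.
#' @return list with `loglik` and per-observation `contributions`.
#' @export
pln_loglik <- function(beta, ln_sigma, Y, X, nodes = 32, weights = NULL) {
  w <- weights %||% rep(1, length(Y))
  parts <- pln_parts(Y, X, beta, exp(ln_sigma), gh_rule(nodes))
  list(loglik = sum(w * parts$ll), contributions = parts$ll)
}

#' Fit a Poisson-lognormal regression by maximum likelihood
#'
#' @inheritParams pln_loglik
#' @param start optional list with `beta` and `ln_sigma` starting values
#'   (defaults to a plain Poisson fit and `ln 0.5`).
#' @param max_iter optimiser iteration cap.
#' @return object of class `pln_fit`: `beta`, `ln_sigma`, `sigma`, `loglik`,
#'   observed-information `vcov`, coefficient `table` with z-tests, and
#'   convergence metadata.
#' @export
pln_fit <- function(Y, X, nodes = 32, weights = NULL, start = NULL,
                    max_iter = 500) {
  stopifnot(all(Y >= 0), all(Y == round(Y)), nrow(X) == length(Y))
  w <- weights %||% rep(1, length(Y))
  check_full_rank(X, "outcome")
  if (is.null(start)) {
    g <- suppressWarnings(glm.fit(X, Y, weights = w, family = poisson()))
    start <- list(beta = pmin(pmax(coef(g), -20), 20), ln_sigma = log(0.5))
  }
  theta0 <- c(start$beta, ln_sigma = start$ln_sigma)
  gh <- gh_rule(nodes)
  p <- ncol(X)
  core <- function(th, want_scores = FALSE) {
    parts <- pln_parts(Y, X, th[seq_len(p)], exp(th[p + 1]), gh,
                       want_scores = want_scores)
    out <- list(loglik = sum(w * parts$ll), per_obs = parts$ll)
    if (want_scores) {
      out$scores <- cbind(X * parts$g_mu, parts$g_lnsig) * w
      out$grad <- colSums(out$scores)
    }
    out
  }
  res <- run_mle(theta0, rep(TRUE, p + 1), core, max_iter = max_iter)
  final <- core(res$theta, want_scores = TRUE)
  gfun <- function(th) core(th, want_scores = TRUE)$grad
  H <- grad_hessian(gfun, res$theta)
  S <- crossprod(final$scores / sqrt(w))
  bread <- neg_inverse(H)
  V <- bread %*% S %*% bread
  V <- (V + t(V)) / 2
  nm <- c(colnames(X), "ln_sigma")
  dimnames(V) <- list(nm, nm)
  se <- sqrt(pmax(diag(V), 0))
  est <- setNames(res$theta, nm)
  tab <- data.frame(parameter = nm, estimate = unname(est), se = unname(se))
  tab$z <- tab$estimate / tab$se
  tab$p_value <- 2 * pnorm(-abs(tab$z))
  tab$stars <- p_stars(tab$p_value)
  structure(list(beta = est[seq_len(p)], ln_sigma = est[[p + 1]],
                 sigma = exp(est[[p + 1]]), loglik = final$loglik,
                 vcov = V, table = tab, score_norm = max(abs(final$grad)),
                 converged = res$opt$convergence == 0 ||
                   max(abs(final$grad)) < 1e-4 * (1 + abs(final$loglik)),
                 nodes = nodes, n = length(Y)),
            class = "pln_fit")
}

#' @export
print.pln_fit <- function(x, ...) {
  cat("Poisson-lognormal regression (Gauss-Hermite", x$nodes, "nodes)\n")
  cat(sprintf("  n = %d   loglik = %.3f   sigma = %.4g   converged: %s\n",
              x$n, x$loglik, x$sigma, x$converged))
  print(x$table, row.names = FALSE)
  invisible(x)
}

## Probit log-likelihood on a fixed design (used by factorisation oracles).
probit_loglik <- function(alpha, tr, Z, weights = NULL) {
  w <- weights %||% rep(1, length(tr))
  sum(w * pnorm((2 * tr - 1) * drop(Z %*% alpha), log.p = TRUE))
}
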