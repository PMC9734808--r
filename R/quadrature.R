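## Gauss-Hermite machinery shared by the switching model, the single-equation
## endogenous-treatment Poisson model and the Poisson-lognormal regression.
## The mixing integral over eta ~ N(0, sigma^2) is standardised as
## eta = sqrt(2) * sigma * u, giving sum_k w_k f(sqrt(2) sigma u_k) / sqrt(pi)
## over the Hermite nodes u_k.

.gh_cache <- new.env(parent = emptyenv())

gh_rule <- function(nodes) {
  stopifnot(nodes >= 2)
  key <- as.character(nodes)
  if (is.null(.gh_cache[[key]])) {
    r <- pracma::gaussHermite(nodes)
    .gh_cache[[key]] <- list(u = r$x, lw = log(r$w) - 0.5 * log(pi))
  }
  .gh_cache[[key]]
}

## Per-observation log-likelihood (and score pieces) for one arm of the
## switching likelihood:
##   l_i = log int Pois(Y_i | exp(X_i'beta + eta))
##             * Phi{ s (Z_i'alpha + rho eta / sigma) / sqrt(1 - rho^2) }
##             * N(eta; 0, sigma^2) d eta,      s = 2T - 1.
## Scores returned on the (beta, alpha, ln sigma, atanh rho) scale as the
## per-observation multipliers g_mu (for X beta), g_c (for Z alpha), g_lnsig,
## g_arho; the caller assembles full score rows.
arm_loglik <- function(Y, X, Z, s, beta, alpha, sigma, rho, gh,
                       want_scores = FALSE) {
  n <- length(Y)
  u <- gh$u; lw <- gh$lw
  mu <- drop(X %*% beta)
  cc <- drop(Z %*% alpha)
  r <- sqrt(1 - rho^2)
  lin <- outer(mu, sqrt(2) * sigma * u, "+")          # n x K log-means
  lam <- exp(lin)
  A <- Y * lin - lam - lgamma(Y + 1)                  # Poisson log-kernel
  m <- outer(cc, sqrt(2) * rho * u, "+") / r
  B <- pnorm(s * m, log.p = TRUE)
  a <- sweep(A + B, 2, lw, "+")
  ll <- row_logsumexp(a)
  out <- list(ll = ll)
  if (want_scores) {
    P <- exp(a - ll)                                  # node posteriors, rows sum to 1
    resid <- Y - lam
    U <- matrix(u, n, length(u), byrow = TRUE)
    ratio <- exp(dnorm(m, log = TRUE) - B)            # phi(m) / Phi(s m)
    dm <- (sqrt(2) * U + m * rho / r) / r             # d m / d rho
    out$g_mu <- rowSums(P * resid)
    out$g_c <- (s / r) * rowSums(P * ratio)
    out$g_lnsig <- sqrt(2) * sigma * rowSums(P * resid * U)
    out$g_arho <- s * (1 - rho^2) * rowSums(P * ratio * dm)
  }
  out
}

## Poisson-lognormal kernel without the selection factor (the rho = 0 /
## single-equation mixture). Same parameterisation conventions.
pln_parts <- function(Y, X, beta, sigma, gh, want_scores = FALSE) {
  n <- length(Y)
  u <- gh$u
  mu <- drop(X %*% beta)
  lin <- outer(mu, sqrt(2) * sigma * u, "+")
  lam <- exp(lin)
  a <- sweep(Y * lin - lam - lgamma(Y + 1), 2, gh$lw, "+")
  ll <- row_logsumexp(a)
  out <- list(ll = ll)
  if (want_scores) {
    P <- exp(a - ll)
    U <- matrix(u, n, length(u), byrow = TRUE)
    out$g_mu <- rowSums(P * (Y - lam))
    out$g_lnsig <- sqrt(2) * sigma * rowSums(P * (Y - lam) * U)
  }
  out
}

## Numerical Hessian of a total log-likelihood by central differences of an
## analytic gradient function g(theta); step 1e-5 * (1 + |theta_k|).
grad_hessian <- function(gfun, theta) {
  p <- length(theta)
  H <- matrix(0, p, p)
  for (k in seq_len(p)) {
    h <- 1e-5 * (1 + abs(theta[k]))
    up <- theta; up[k] <- up[k] + h
    dn <- theta; dn[k] <- dn[k] - h
    H[, k] <- (gfun(up) - gfun(dn)) / (2 * h)
  }
  (H + t(H)) / 2
}

## Solve for the sandwich bread; fall back to an eigen pseudo-inverse when
## the Hessian is numerically singular.
neg_inverse <- function(H) {
  out <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(out) || any(!is.finite(out))) {
    warning("singular Hessian: using pseudo-inverse")
    e <- eigen(-(H + t(H)) / 2, symmetric = TRUE)
    pos <- e$values > max(abs(e$values)) * 1e-10
    out <- e$vectors[, pos, drop = FALSE] %*%
      (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
  }
  out
}
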