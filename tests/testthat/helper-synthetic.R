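## Shared fixtures: small generator configurations (one continuous covariate
## plus the instrument) that keep optimisation fast, and brute-force
## Monte-Carlo oracles kept deliberately independent of the package's
## quadrature code paths.

small_spec <- function() {
  list(x1 = list(type = "normal", mean = 0, sd = 1),
       peer_online = list(type = "bernoulli", p = 0.5))
}

small_config <- function(n, seed = NULL, sigma1 = 0.3, sigma0 = 0.25,
                         rho1 = -0.5, rho0 = -0.4, a_iv = 1.0,
                         b1 = c("(Intercept)" = 1.9, x1 = 0.10),
                         b0 = c("(Intercept)" = 1.7, x1 = 0.08), ...) {
  esc_config(n = n,
             alpha = c("(Intercept)" = -0.8, x1 = 0.5, peer_online = a_iv),
             beta1 = b1, beta0 = b0,
             sigma1 = sigma1, sigma0 = sigma0, rho1 = rho1, rho0 = rho0,
             covariate_spec = small_spec(), seed = seed, ...)
}

small_fit_args <- function() {
  list(outcome = "dds", treatment = "ofs", covariates = "x1",
       iv = "peer_online")
}

fit_small <- function(data, nodes = 16, ...) {
  fit_esc(data, outcome = "dds", treatment = "ofs", covariates = "x1",
          iv = "peer_online", nodes = nodes, ...)
}

## Monte-Carlo estimate of one observation's joint likelihood
##   E_u[ Pois(y | exp(xb + sigma u)) * Phi(s (za + rho u) / sqrt(1-rho^2)) ]
## with u standard normal; returns the log value and the MC standard error
## of the log (delta method).
mc_joint_loglik_row <- function(y, xb, za, s, sigma, rho, n_draws, u = NULL) {
  if (is.null(u)) u <- rnorm(n_draws)
  g <- dpois(y, exp(xb + sigma * u)) *
    pnorm(s * (za + rho * u) / sqrt(1 - rho^2))
  m <- mean(g)
  list(log = log(m), se_log = sd(g) / (sqrt(length(g)) * m))
}

## Monte-Carlo conditional expectation E[exp(xb + sigma u) | s (za + eps) > 0]
## with corr(eps, u) = rho, by joint-normal simulation.
mc_expected_outcome <- function(xb, za, s, sigma, rho, n_draws) {
  eps <- rnorm(n_draws)
  u <- rho * eps + sqrt(1 - rho^2) * rnorm(n_draws)
  keep <- s * (za + eps) > 0
  vals <- exp(xb + sigma * u[keep])
  list(mean = mean(vals), se = sd(vals) / sqrt(sum(keep)))
}
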