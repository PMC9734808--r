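test_that("starting values are sensible under an exogenous DGP", {
  cfg <- small_config(4000, seed = 3, rho1 = 0, rho0 = 0)
  truth <- generate_population(cfg)
  sv <- starting_values(truth$data, outcome = "dds", treatment = "ofs",
                        covariates = "x1", iv = "peer_online")
  ## probit/Poisson starts are consistent here: crude 3-SE style bound
  expect_lt(abs(sv$beta1[["(Intercept)"]] - 1.9), 0.15)
  expect_lt(abs(sv$beta0[["(Intercept)"]] - 1.7), 0.15)
  expect_lt(abs(sv$alpha[["peer_online"]] - 1.0), 0.25)
  expect_equal(sv$arho1, 0)
  expect_equal(sv$ln_sigma1, log(0.5))
})

test_that("degenerate and ill-posed inputs are rejected informatively", {
  d <- data.frame(dds = rpois(50, 3), ofs = 1, x1 = rnorm(50),
                  peer_online = rbinom(50, 1, .5))
  expect_error(starting_values(d, covariates = "x1"), "control arm")
  d2 <- data.frame(dds = rpois(50, 3), ofs = rbinom(50, 1, .5),
                   x1 = rnorm(50), peer_online = rbinom(50, 1, .5))
  d2$x2 <- 2 * d2$x1
  expect_error(starting_values(d2, covariates = c("x1", "x2")), "collinear")
  ## an all-zero arm still yields finite (floored) starts
  d3 <- data.frame(dds = c(rpois(40, 4), rep(0, 40)),
                   ofs = rep(c(1, 0), each = 40), x1 = rnorm(80),
                   peer_online = rbinom(80, 1, .5))
  sv3 <- starting_values(d3, covariates = "x1")
  expect_true(all(is.finite(unlist(sv3))))
  expect_gte(sv3$beta0[["(Intercept)"]], -20)
})

test_that("with rho = 0 the joint likelihood factorises into probit + mixture", {
  cfg <- small_config(300, seed = 19)
  truth <- generate_population(cfg)
  fr <- switchcount:::esc_frame(truth$data, "dds", "ofs", "x1", "peer_online")
  p <- esc_params(alpha = c("(Intercept)" = -0.6, x1 = 0.4, peer_online = 0.9),
                  beta1 = c("(Intercept)" = 1.8, x1 = 0.12),
                  beta0 = c("(Intercept)" = 1.6, x1 = 0.05),
                  ln_sigma1 = log(0.4), ln_sigma0 = log(0.3),
                  arho1 = 0, arho0 = 0)
  joint <- esc_loglik(p, truth$data, covariates = "x1", nodes = 48)$loglik
  probit <- switchcount:::probit_loglik(p$alpha, fr$tr, fr$Z)
  i1 <- fr$tr == 1; i0 <- fr$tr == 0
  mix <- pln_loglik(p$beta1, p$ln_sigma1, fr$Y[i1], fr$X[i1, , drop = FALSE],
                    nodes = 48)$loglik +
    pln_loglik(p$beta0, p$ln_sigma0, fr$Y[i0], fr$X[i0, , drop = FALSE],
               nodes = 48)$loglik
  expect_equal(joint, probit + mix, tolerance = 1e-6 / abs(joint))
})

test_that("as sigma degenerates the likelihood reduces to probit + plain Poisson", {
  cfg <- small_config(250, seed = 29)
  truth <- generate_population(cfg)
  fr <- switchcount:::esc_frame(truth$data, "dds", "ofs", "x1", "peer_online")
  p <- esc_params(alpha = c("(Intercept)" = -0.5, x1 = 0.3, peer_online = 1.1),
                  beta1 = c("(Intercept)" = 1.9, x1 = 0.1),
                  beta0 = c("(Intercept)" = 1.7, x1 = 0.08),
                  ln_sigma1 = log(1e-8), ln_sigma0 = log(1e-8),
                  arho1 = 0, arho0 = 0)
  joint <- esc_loglik(p, truth$data, covariates = "x1", nodes = 32)$loglik
  probit <- switchcount:::probit_loglik(p$alpha, fr$tr, fr$Z)
  pois <- sum(dpois(fr$Y[fr$tr == 1],
                    exp(drop(fr$X[fr$tr == 1, ] %*% p$beta1)), log = TRUE)) +
    sum(dpois(fr$Y[fr$tr == 0],
              exp(drop(fr$X[fr$tr == 0, ] %*% p$beta0)), log = TRUE))
  expect_equal(joint, probit + pois, tolerance = 1e-6 / abs(joint))
})

test_that("quadrature agrees with brute-force Monte-Carlo integration", {
  cfg <- small_config(20, seed = 37, sigma1 = 0.5, sigma0 = 0.45,
                      rho1 = -0.6, rho0 = 0.3)
  truth <- generate_population(cfg)
  p <- config_params(cfg)
  fr <- switchcount:::esc_frame(truth$data, "dds", "ofs", "x1", "peer_online")
  gh <- esc_loglik(p, truth$data, covariates = "x1", nodes = 48)$contributions
  set.seed(99)
  u <- rnorm(2e5)
  nat <- esc_natural(p)
  total_gap <- 0; total_var <- 0
  for (i in seq_along(fr$Y)) {
    j <- fr$tr[i]
    mc <- mc_joint_loglik_row(
      fr$Y[i], drop(fr$X[i, ] %*% (if (j == 1) p$beta1 else p$beta0)),
      drop(fr$Z[i, ] %*% p$alpha), 2 * j - 1,
      if (j == 1) nat[["sigma1"]] else nat[["sigma0"]],
      if (j == 1) nat[["rho1"]] else nat[["rho0"]], u = u)
    total_gap <- total_gap + (gh[i] - mc$log)
    total_var <- total_var + mc$se_log^2
  }
  expect_lt(abs(total_gap), 3 * sqrt(total_var))
})

test_that("the likelihood is invariant to covariate re-centring", {
  cfg <- small_config(200, seed = 41)
  truth <- generate_population(cfg)
  p <- config_params(cfg)
  base <- esc_loglik(p, truth$data, covariates = "x1")$loglik
  shifted <- truth$data
  shifted$x1 <- shifted$x1 + 2
  p2 <- p
  p2$alpha[["(Intercept)"]] <- p$alpha[["(Intercept)"]] - 2 * p$alpha[["x1"]]
  p2$beta1[["(Intercept)"]] <- p$beta1[["(Intercept)"]] - 2 * p$beta1[["x1"]]
  p2$beta0[["(Intercept)"]] <- p$beta0[["(Intercept)"]] - 2 * p$beta0[["x1"]]
  expect_equal(esc_loglik(p2, shifted, covariates = "x1")$loglik, base,
               tolerance = 1e-8 / abs(base))
})

test_that("joint probabilities over (T, Y) sum to one", {
  ## fixed covariate row; sum the joint likelihood over both arms and
  ## y = 0..500 at moderate log-means
  p <- esc_params(alpha = c("(Intercept)" = -0.4, x1 = 0.5, peer_online = 1),
                  beta1 = c("(Intercept)" = 1.6, x1 = 0.1),
                  beta0 = c("(Intercept)" = 1.4, x1 = -0.1),
                  ln_sigma1 = log(0.4), ln_sigma0 = log(0.3),
                  arho1 = atanh(-0.7), arho0 = atanh(0.4))
  ymax <- 500
  total <- 0
  for (tr in c(1, 0)) {
    d <- data.frame(dds = 0:ymax, ofs = tr, x1 = 0.3, peer_online = 1)
    total <- total +
      sum(exp(esc_loglik(p, d, covariates = "x1", nodes = 64)$contributions))
  }
  expect_equal(total, 1, tolerance = 1e-6)
})

test_that("fitting recovers a well-identified small model and is deterministic", {
  cfg <- small_config(4000, seed = 47, sigma1 = 0.35, sigma0 = 0.3,
                      rho1 = -0.6, rho0 = -0.5)
  truth <- generate_population(cfg)
  fit <- fit_small(truth$data, nodes = 16)
  expect_true(fit$converged)
  theta_true <- switchcount:::pack_params(config_params(cfg), fit$frame)
  dev <- abs(fit$theta - theta_true) / fit$se[names(fit$theta)]
  expect_true(all(dev < 3.5))
  ## per-observation quadrature gap at the doubled order is negligible
  expect_lt(fit$quad_gap, 1e-4)
  ## deterministic optimiser: identical refits bit for bit
  fit2 <- fit_small(truth$data, nodes = 16)
  expect_identical(fit$theta, fit2$theta)
  expect_identical(fit$loglik, fit2$loglik)
})

test_that("a rho-zero DGP yields correlation estimates near zero", {
  cfg <- small_config(5000, seed = 53, rho1 = 0, rho0 = 0,
                      sigma1 = 0.3, sigma0 = 0.3)
  truth <- generate_population(cfg)
  fit <- fit_small(truth$data, nodes = 16)
  expect_true(fit$converged)
  expect_lt(abs(fit$theta[["arho1"]]) / fit$se[["arho1"]], 3)
  expect_lt(abs(fit$theta[["arho0"]]) / fit$se[["arho0"]], 3)
})

test_that("freeing rho never lowers the maximised likelihood", {
  cfg <- small_config(1500, seed = 59, rho1 = -0.6, rho0 = -0.5)
  truth <- generate_population(cfg)
  free <- fit_small(truth$data, nodes = 12, se = FALSE)
  pinned <- fit_small(truth$data, nodes = 12, se = FALSE,
                      fix = c(arho1 = 0, arho0 = 0))
  expect_gte(free$loglik, pinned$loglik - 1e-6)
})

test_that("robust and model-based standard errors agree under independence", {
  ## with rho = 0 and a correctly specified mixture the information equality
  ## makes sandwich and inverse-Hessian SEs comparable
  cfg <- small_config(3000, seed = 61, rho1 = 0, rho0 = 0,
                      sigma1 = 0.4, sigma0 = 0.35)
  truth <- generate_population(cfg)
  fit <- fit_small(truth$data, nodes = 16)
  fr <- fit$frame
  gfun <- function(th) switchcount:::esc_loglik_core(th, fr, fit$nodes,
                                                     want_scores = TRUE)$grad
  H <- switchcount:::grad_hessian(gfun, fit$theta)
  se_hess <- sqrt(diag(switchcount:::neg_inverse(H)))
  comp <- c("alpha.peer_online", "beta1.(Intercept)", "beta0.(Intercept)",
            "beta1.x1", "beta0.x1")
  idx <- match(comp, names(fit$theta))
  expect_true(all(abs(fit$se[comp] / se_hess[idx] - 1) < 0.2))
})

test_that("doubling observation weights scales the loglik and shrinks SEs by sqrt(2)", {
  cfg <- small_config(1200, seed = 67)
  truth <- generate_population(cfg)
  args <- small_fit_args()
  f1 <- fit_esc(truth$data, args$outcome, args$treatment, args$covariates,
                args$iv, nodes = 12, start = config_params(cfg))
  f2 <- fit_esc(truth$data, args$outcome, args$treatment, args$covariates,
                args$iv, nodes = 12, start = config_params(cfg),
                weights = rep(2, nrow(truth$data)))
  expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 1e-6)
  comp <- grep("^(alpha|beta)", names(f1$theta), value = TRUE)
  expect_equal(unname(f2$se[comp] * sqrt(2)), unname(f1$se[comp]),
               tolerance = 0.02)
})

test_that("incidence rate ratios exponentiate coefficients with the percent reading", {
  expect_equal(irr(0.011), exp(0.011))
  expect_equal(round(irr(0.011), 3), 1.011)
  expect_equal(round(irr_pct(irr(0.011)), 1), 1.1)
  expect_equal(round(irr(-0.329), 3), 0.720)
  expect_equal(round(irr_pct(irr(-0.026)), 1), 2.6)
  expect_equal(irr(0), 1)
  expect_equal(irr_pct(1), 0)
})

test_that("irr_table reports both regimes on the fitted model", {
  cfg <- small_config(2500, seed = 71)
  truth <- generate_population(cfg)
  fit <- fit_small(truth$data, nodes = 12)
  tab <- irr_table(fit)
  expect_equal(tab$variable, c("(Intercept)", "x1"))
  expect_equal(tab$irr_treated,
               round(exp(fit$params$beta1), 3), ignore_attr = TRUE)
  expect_equal(tab$irr_control,
               round(exp(fit$params$beta0), 3), ignore_attr = TRUE)
})
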