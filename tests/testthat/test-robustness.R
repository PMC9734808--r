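test_that("the falsification test passes on an exclusion-valid DGP", {
  ## rho = 0 keeps the untreated outcome free of selection-induced
  ## association with the instrument (with strong unobserved selection and
  ## sizeable heterogeneity, exclusion-style tests can reject even valid
  ## instruments through the truncation of the selection error). Under the
  ## null the exclusion p-value is uniform, so the verdict is checked over
  ## replicates rather than on a single draw.
  verdicts <- vapply(113:118, function(s) {
    truth <- generate_population(small_config(2500, seed = s,
                                              rho1 = 0, rho0 = 0))
    res <- falsification_test(truth$data, covariates = "x1", nodes = 12)
    expect_lt(res$iv_relevance_p, 0.01)
    res$verdict
  }, character(1))
  expect_gte(sum(verdicts == "pass"), 4)  # each passes w.p. 0.9 by design
})

test_that("an instrument leaking into the outcome fails on exclusion", {
  cfg <- esc_config(
    n = 8000,
    alpha = c("(Intercept)" = -0.8, x1 = 0.5, peer_online = 1.0),
    beta1 = c("(Intercept)" = 1.9, x1 = 0.10, peer_online = 0.1),
    beta0 = c("(Intercept)" = 1.7, x1 = 0.08, peer_online = 0.1),
    sigma1 = 0.3, sigma0 = 0.25, rho1 = -0.5, rho0 = -0.4,
    covariate_spec = small_spec(), seed = 127)
  truth <- generate_population(cfg)
  ## the IV sits inside the outcome equations, so Z = X: the test is run
  ## declaring it as the would-be instrument
  res <- falsification_test(truth$data, covariates = "x1", nodes = 12)
  expect_lt(res$iv_exclusion_p, 0.10)
  expect_equal(res$verdict, "fail")
})

test_that("an irrelevant instrument fails on relevance", {
  cfg <- small_config(4000, seed = 131, a_iv = 0, rho1 = 0, rho0 = 0)
  truth <- generate_population(cfg)
  res <- falsification_test(truth$data, covariates = "x1", nodes = 12)
  expect_gt(res$iv_relevance_p, 0.01)
  expect_equal(res$verdict, "fail")
})

test_that("a constant instrument among the untreated is flagged", {
  cfg <- small_config(400, seed = 137)
  truth <- generate_population(cfg)
  d <- truth$data
  d$peer_online[d$ofs == 0] <- 0
  expect_warning(res <- falsification_test(d, covariates = "x1", nodes = 12),
                 "constant")
  expect_true(is.na(res$verdict))
})

test_that("the single-equation endogenous-treatment model matches a constrained switch", {
  ## with shared beta/sigma/rho and a zero treatment coefficient, the
  ## one-equation likelihood equals the switching likelihood evaluated at
  ## beta1 = beta0
  cfg <- small_config(600, seed = 139)
  truth <- generate_population(cfg)
  p <- esc_params(alpha = c("(Intercept)" = -0.7, x1 = 0.4, peer_online = 1.0),
                  beta1 = c("(Intercept)" = 1.8, x1 = 0.1),
                  beta0 = c("(Intercept)" = 1.8, x1 = 0.1),
                  ln_sigma1 = log(0.35), ln_sigma0 = log(0.35),
                  arho1 = atanh(-0.5), arho0 = atanh(-0.5))
  ll_esc <- esc_loglik(p, truth$data, covariates = "x1", nodes = 24)$loglik
  ## evaluate the one-equation likelihood at the matching parameters by a
  ## single-iteration fit started there with the treatment effect pinned
  fr <- switchcount:::esc_frame(truth$data, "dds", "ofs", "x1", "peer_online")
  gh <- switchcount:::gh_rule(24)
  Xt <- cbind(fr$X, treatment = fr$tr)
  ll_prete <- 0
  for (j in c(1, 0)) {
    idx <- fr$tr == j
    ll_prete <- ll_prete + sum(switchcount:::arm_loglik(
      fr$Y[idx], Xt[idx, , drop = FALSE], fr$Z[idx, , drop = FALSE],
      2 * j - 1, c(p$beta1, treatment = 0), p$alpha, 0.35, -0.5, gh)$ll)
  }
  expect_equal(ll_esc, ll_prete, tolerance = 1e-10)
})

test_that("the one-equation model recovers a homogeneous treatment effect", {
  tau <- 0.25
  cfg <- esc_config(
    n = 6000,
    alpha = c("(Intercept)" = -0.6, x1 = 0.5, peer_online = 1.0),
    beta1 = c("(Intercept)" = 1.6 + tau, x1 = 0.1),
    beta0 = c("(Intercept)" = 1.6, x1 = 0.1),
    sigma1 = 0.3, sigma0 = 0.3, rho1 = -0.5, rho0 = -0.5, rho_cross = 0.999,
    covariate_spec = small_spec(), seed = 149)
  truth <- generate_population(cfg)
  pf <- fit_prete(truth$data, covariates = "x1", nodes = 16)
  expect_true(pf$converged)
  expect_lt(abs(pf$treatment_coef - tau) / pf$treatment_se, 3)
  expect_gt(pf$pct_effect, 0)
})

test_that("with rho = 0 the one-equation model matches a pooled mixture fit", {
  cfg <- small_config(3000, seed = 151, rho1 = 0, rho0 = 0,
                      b1 = c("(Intercept)" = 1.9, x1 = 0.1),
                      b0 = c("(Intercept)" = 1.7, x1 = 0.1),
                      sigma1 = 0.35, sigma0 = 0.35)
  truth <- generate_population(cfg)
  ## with the correlation pinned at zero the model factorises exactly into
  ## a probit plus a pooled mixture regression with a treatment dummy
  pf <- fit_prete(truth$data, covariates = "x1", nodes = 16,
                  fix = c(arho = 0))
  fr <- switchcount:::esc_frame(truth$data, "dds", "ofs", "x1", "peer_online")
  Xt <- cbind(fr$X, treatment = fr$tr)
  pl <- pln_fit(fr$Y, Xt, nodes = 16)
  nm <- paste0("beta.", colnames(Xt))
  expect_equal(unname(pf$theta[nm]), unname(pl$beta), tolerance = 1e-3)
  ## and the freely estimated correlation stays near zero
  pf_free <- fit_prete(truth$data, covariates = "x1", nodes = 16, se = FALSE)
  expect_lt(abs(pf_free$rho), 0.2)
})

test_that("IPWRA reduces to the naive difference under random treatment", {
  cfg <- small_config(8000, seed = 157, a_iv = 0.0, rho1 = 0, rho0 = 0)
  cfg$alpha[["x1"]] <- 0
  truth <- generate_population(cfg)
  eff <- ipwra_att(truth$data, covariates = "x1")
  naive <- mean(truth$data$dds[truth$data$ofs == 1]) -
    mean(truth$data$dds[truth$data$ofs == 0])
  expect_lt(abs(eff$point - naive), 0.1)
})

test_that("IPWRA is consistent under selection on observables only", {
  cfg <- small_config(20000, seed = 163, rho1 = 0, rho0 = 0,
                      sigma1 = 0.3, sigma0 = 0.3)
  truth <- generate_population(cfg)
  eff <- ipwra_att(truth$data, covariates = "x1")
  oracle <- true_effects(truth)[["ATT"]]
  n1 <- sum(truth$data$ofs == 1)
  se <- sd((truth$y1 - truth$y0)[truth$data$ofs == 1]) / sqrt(n1)
  expect_lt(abs(eff$point - oracle), 4 * se)
  expect_true(all(attr(eff, "weights") >= 0))
})

test_that("IPWRA reweighting balances covariates across arms", {
  cfg <- small_config(15000, seed = 167)
  truth <- generate_population(cfg)
  eff <- ipwra_att(truth$data, covariates = "x1")
  kept <- attr(eff, "kept")
  w <- attr(eff, "weights")
  tr <- truth$data$ofs[kept]
  x <- truth$data$x1[kept]
  m1 <- weighted.mean(x[tr == 1], w[tr == 1])
  m0 <- weighted.mean(x[tr == 0], w[tr == 0])
  expect_lt(abs(m1 - m0), 0.06)
})
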