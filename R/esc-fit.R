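## Full-information maximum likelihood for the endogenous switching count
## model: probit selection T = 1{Z'alpha + eps > 0} jointly with two Poisson
## outcome regimes log E(Y_j | X, eta_j) = X'beta_j + eta_j, where
## eta_j = sigma_j u_j and corr(eps, u_j) = rho_j. Estimation is on the
## unconstrained scale (ln sigma_j, atanh rho_j); the mixing integral is
## evaluated by Gauss-Hermite quadrature in log space.

## ---- model frame -----------------------------------------------------------

esc_frame <- function(data, outcome, treatment, covariates, iv,
                      weights = NULL) {
  need <- c(outcome, treatment, covariates, iv)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("data is missing column(s): ", paste(miss, collapse = ", "))
  Y <- data[[outcome]]
  tr <- data[[treatment]]
  if (!all(tr %in% c(0, 1))) stop("treatment column must be binary 0/1")
  if (any(!is.finite(Y)) || any(Y < 0) || any(Y != round(Y)))
    stop("outcome must be a non-negative integer count")
  for (v in c(covariates, iv))
    if (!is.numeric(data[[v]]))
      stop("covariate '", v, "' must be numeric")
  if (length(iv) == 0)
    warning("no exclusion restriction: Z equals X, the model is identified ",
            "only by functional form")
  X <- cbind("(Intercept)" = 1, as.matrix(data[covariates]))
  Z <- cbind("(Intercept)" = 1, as.matrix(data[c(covariates, iv)]))
  w <- weights %||% rep(1, length(Y))
  stopifnot(length(w) == length(Y), all(w > 0))
  list(Y = as.numeric(Y), tr = as.integer(tr), X = X, Z = Z, w = w,
       outcome = outcome, treatment = treatment,
       covariates = covariates, iv = iv)
}

theta_names <- function(fr) {
  c(paste0("alpha.", colnames(fr$Z)),
    paste0("beta1.", colnames(fr$X)),
    paste0("beta0.", colnames(fr$X)),
    "ln_sigma1", "ln_sigma0", "arho1", "arho0")
}

pack_params <- function(params, fr) {
  setNames(c(params$alpha, params$beta1, params$beta0,
             params$ln_sigma1, params$ln_sigma0,
             params$arho1, params$arho0),
           theta_names(fr))
}

unpack_theta <- function(theta, fr) {
  pz <- ncol(fr$Z); px <- ncol(fr$X)
  esc_params(
    alpha = setNames(theta[seq_len(pz)], colnames(fr$Z)),
    beta1 = setNames(theta[pz + seq_len(px)], colnames(fr$X)),
    beta0 = setNames(theta[pz + px + seq_len(px)], colnames(fr$X)),
    ln_sigma1 = theta[[pz + 2 * px + 1]],
    ln_sigma0 = theta[[pz + 2 * px + 2]],
    arho1 = theta[[pz + 2 * px + 3]],
    arho0 = theta[[pz + 2 * px + 4]])
}

#' Parameter vector of the endogenous switching count model
#'
#' Collects the full parameter vector on the unconstrained optimisation
#' scale: selection coefficients, the two regimes' log-mean coefficients,
#' log heterogeneity SDs and atanh-transformed correlations.
#'
#' @param alpha named selection coefficients (including intercept).
#' @param beta1,beta0 named regime coefficients (including intercept).
#' @param ln_sigma1,ln_sigma0 log of the heterogeneity SDs.
#' @param arho1,arho0 atanh of the error correlations.
#' @return an object of class `esc_params`.
#' @export
esc_params <- function(alpha, beta1, beta0, ln_sigma1, ln_sigma0,
                       arho1, arho0) {
  stopifnot(all(is.finite(c(alpha, beta1, beta0, ln_sigma1, ln_sigma0,
                            arho1, arho0))))
  structure(list(alpha = alpha, beta1 = beta1, beta0 = beta0,
                 ln_sigma1 = ln_sigma1, ln_sigma0 = ln_sigma0,
                 arho1 = arho1, arho0 = arho0),
            class = "esc_params")
}

#' Natural-scale heterogeneity parameters
#'
#' @param params an [esc_params()].
#' @return named vector `sigma1`, `sigma0`, `rho1`, `rho0`.
#' @export
esc_natural <- function(params) {
  c(sigma1 = exp(params$ln_sigma1), sigma0 = exp(params$ln_sigma0),
    rho1 = tanh(params$arho1), rho0 = tanh(params$arho0))
}

#' Convert generator truth to an `esc_params`
#'
#' @param config an [esc_config()]; its coefficients and natural-scale
#'   `sigma`/`rho` are mapped onto the estimation scale.
#' @return an `esc_params`.
#' @export
config_params <- function(config) {
  stopifnot(inherits(config, "esc_config"))
  esc_params(alpha = config$alpha, beta1 = config$beta1, beta0 = config$beta0,
             ln_sigma1 = log(config$sigma1), ln_sigma0 = log(config$sigma0),
             arho1 = atanh(config$rho1), arho0 = atanh(config$rho0))
}

## ---- likelihood ------------------------------------------------------------

esc_loglik_core <- function(theta, fr, nodes, want_scores = FALSE) {
  p <- unpack_theta(theta, fr)
  gh <- gh_rule(nodes)
  nat <- esc_natural(p)
  n <- length(fr$Y)
  ll <- numeric(n)
  scores <- if (want_scores) matrix(0, n, length(theta),
                                    dimnames = list(NULL, names(theta)))
  pz <- ncol(fr$Z); px <- ncol(fr$X)
  for (j in c(1L, 0L)) {
    idx <- which(fr$tr == j)
    if (!length(idx)) next
    s <- 2 * j - 1
    beta <- if (j == 1) p$beta1 else p$beta0
    sigma <- if (j == 1) nat[["sigma1"]] else nat[["sigma0"]]
    rho <- if (j == 1) nat[["rho1"]] else nat[["rho0"]]
    arm <- arm_loglik(fr$Y[idx], fr$X[idx, , drop = FALSE],
                      fr$Z[idx, , drop = FALSE], s, beta, p$alpha,
                      sigma, rho, gh, want_scores = want_scores)
    ll[idx] <- arm$ll
    if (want_scores) {
      scores[idx, seq_len(pz)] <- fr$Z[idx, , drop = FALSE] * arm$g_c
      bcols <- if (j == 1) pz + seq_len(px) else pz + px + seq_len(px)
      scores[idx, bcols] <- fr$X[idx, , drop = FALSE] * arm$g_mu
      scores[idx, pz + 2 * px + (2 - j)] <- arm$g_lnsig
      scores[idx, pz + 2 * px + (4 - j)] <- arm$g_arho
    }
  }
  out <- list(per_obs = ll, loglik = sum(fr$w * ll))
  if (want_scores) {
    out$scores <- scores * fr$w
    out$grad <- colSums(out$scores)
  }
  out
}

#' Joint log-likelihood of the endogenous switching count model
#'
#' Evaluates, for each household, the log of the joint probability of its
#' observed count and treatment status: the Poisson kernel of the occupied
#' regime mixed over the lognormal heterogeneity and weighted by the probit
#' selection factor, integrated by Gauss-Hermite quadrature with log-sum-exp
#' stabilisation.
#'
#' @param params an [esc_params()].
#' @param data household-level data frame.
#' @param outcome,treatment,covariates,iv column roles.
#' @param nodes quadrature order (>= 8).
#' @param weights optional positive observation weights.
#' @return list with `loglik` (weighted sum) and `contributions`
#'   (per-observation log-likelihood values).
#' @export
esc_loglik <- function(params, data, outcome = "dds", treatment = "ofs",
                       covariates = default_covariates(),
                       iv = "peer_online", nodes = 32, weights = NULL) {
  stopifnot(inherits(params, "esc_params"), nodes >= 8)
  fr <- esc_frame(data, outcome, treatment, covariates, iv, weights)
  theta <- pack_params(params, fr)
  res <- esc_loglik_core(theta, fr, nodes)
  bad <- which(!is.finite(res$per_obs))
  if (length(bad))
    stop("non-finite likelihood contribution at row(s) ",
         paste(head(bad, 5), collapse = ", "),
         " (sigma1 = ", signif(exp(params$ln_sigma1), 4),
         ", rho1 = ", signif(tanh(params$arho1), 4), ")")
  list(loglik = res$loglik, contributions = res$per_obs)
}

## ---- starting values -------------------------------------------------------

check_full_rank <- function(M, label) {
  q <- qr(M)
  if (q$rank < ncol(M)) {
    dep <- colnames(M)[q$pivot[(q$rank + 1):ncol(M)]]
    stop(label, " design matrix is rank deficient; collinear column(s): ",
         paste(dep, collapse = ", "))
  }
}

#' Starting values for the switching-model optimiser
#'
#' A probit of treatment on Z for the selection coefficients, arm-restricted
#' Poisson regressions of the count on X for each regime, `ln sigma = ln 0.5`
#' and zero correlations. Coefficients are clamped to \[-20, 20\] so a
#' degenerate arm (all-zero counts) still yields finite starts.
#'
#' @inheritParams esc_loglik
#' @return an [esc_params()].
#' @export
starting_values <- function(data, outcome = "dds", treatment = "ofs",
                            covariates = default_covariates(),
                            iv = "peer_online", weights = NULL) {
  fr <- esc_frame(data, outcome, treatment, covariates, iv, weights)
  if (!any(fr$tr == 1)) stop("treated arm is empty")
  if (!any(fr$tr == 0)) stop("control arm is empty")
  check_full_rank(fr$X, "outcome")
  check_full_rank(fr$Z, "selection")
  clamp <- function(b) pmin(pmax(b, -20), 20)
  pr <- suppressWarnings(glm.fit(fr$Z, fr$tr, weights = fr$w,
                                 family = binomial("probit")))
  arm_pois <- function(j) {
    idx <- fr$tr == j
    fit <- suppressWarnings(glm.fit(fr$X[idx, , drop = FALSE], fr$Y[idx],
                                    weights = fr$w[idx], family = poisson()))
    clamp(setNames(coef(fit), colnames(fr$X)))
  }
  esc_params(alpha = clamp(setNames(coef(pr), colnames(fr$Z))),
             beta1 = arm_pois(1L), beta0 = arm_pois(0L),
             ln_sigma1 = log(0.5), ln_sigma0 = log(0.5),
             arho1 = 0, arho0 = 0)
}

## ---- optimisation ----------------------------------------------------------

## Minimise the negative log-likelihood over the free coordinates, memoising
## the last evaluation so optim's paired fn/gr calls cost one pass.
run_mle <- function(theta0, free, core, method = "BFGS", max_iter = 500) {
  cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    key <- paste(par, collapse = ",")
    if (!identical(cache$key, key)) {
      th <- theta0
      th[free] <- par
      cache$val <- core(th, want_scores = TRUE)
      cache$key <- key
    }
    cache$val
  }
  fn <- function(par) {
    v <- evaluate(par)
    if (!is.finite(v$loglik)) return(1e10)
    -v$loglik
  }
  gr <- function(par) {
    v <- evaluate(par)
    if (!is.finite(v$loglik) || any(!is.finite(v$grad[free])))
      return(rep(0, length(par)))
    -v$grad[free]
  }
  opt <- optim(theta0[free], fn, gr, method = method,
               control = list(maxit = max_iter, reltol = 1e-12))
  if (method == "BFGS" && opt$convergence > 1)
    opt <- optim(opt$par, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = max_iter))
  theta <- theta0
  theta[free] <- opt$par
  list(theta = theta, opt = opt)
}

#' Fit the endogenous switching count model by maximum likelihood
#'
#' Jointly estimates the probit selection equation and the two correlated
#' Poisson-lognormal outcome regimes by quasi-Newton maximisation of the
#' Gauss-Hermite likelihood on the unconstrained parameter scale, with
#' sandwich (robust) standard errors.
#'
#' @inheritParams esc_loglik
#' @param nodes quadrature order (default 32); adequacy at the optimum is
#'   checked by re-evaluating the log-likelihood at `2 * nodes`.
#' @param tol convergence requires the gradient max-norm to be below
#'   `tol * (1 + |loglik|)`.
#' @param max_iter optimiser iteration cap per round.
#' @param start optional [esc_params()] starting values (defaults to
#'   [starting_values()]).
#' @param fix optional named numeric vector pinning parameters at fixed
#'   values during optimisation, e.g. `c(arho1 = 0, arho0 = 0)` for the
#'   exogenous-selection null.
#' @param se compute the robust covariance (default `TRUE`).
#' @param optimizer `"BFGS"` (default) or `"L-BFGS-B"`.
#' @return an object of class `esc_fit`: `params`, `loglik`, `converged`,
#'   `score_norm`, `quad_gap` (per-observation log-likelihood change at the
#'   doubled quadrature order), robust covariance and coefficient table when
#'   `se = TRUE`, group sizes, and the stored model frame.
#' @export
fit_esc <- function(data, outcome = "dds", treatment = "ofs",
                    covariates = default_covariates(), iv = "peer_online",
                    weights = NULL, nodes = 32, tol = 1e-6, max_iter = 500,
                    start = NULL, fix = NULL, se = TRUE,
                    optimizer = c("BFGS", "L-BFGS-B")) {
  optimizer <- match.arg(optimizer)
  stopifnot(nodes >= 8)
  fr <- esc_frame(data, outcome, treatment, covariates, iv, weights)
  start <- start %||% starting_values(data, outcome, treatment, covariates,
                                      iv, weights)
  theta0 <- pack_params(start, fr)
  free <- rep(TRUE, length(theta0))
  if (!is.null(fix)) {
    unknown <- setdiff(names(fix), names(theta0))
    if (length(unknown))
      stop("fix refers to unknown parameter(s): ",
           paste(unknown, collapse = ", "))
    theta0[names(fix)] <- fix
    free[match(names(fix), names(theta0))] <- FALSE
  }
  core <- function(th, want_scores = FALSE)
    esc_loglik_core(th, fr, nodes, want_scores)

  ## coarse pre-optimisation at 8 nodes: the integrand is smooth in the
  ## heterogeneity, so a low-order rule brings the parameters close before
  ## the full-order polish (deterministic; final convergence is always
  ## assessed at the requested order)
  if (nodes >= 16) {
    core8 <- function(th, want_scores = FALSE)
      esc_loglik_core(th, fr, 8, want_scores)
    theta0 <- run_mle(theta0, free, core8, method = optimizer,
                      max_iter = max_iter)$theta
  }
  res <- run_mle(theta0, free, core, method = optimizer, max_iter = max_iter)
  final <- core(res$theta, want_scores = TRUE)
  score_norm <- max(abs(final$grad[free]))
  converged <- is.finite(final$loglik) &&
    score_norm < tol * (1 + abs(final$loglik))
  ## one polish round if the gradient is not yet small enough
  if (!converged) {
    res <- run_mle(res$theta, free, core, method = optimizer,
                   max_iter = max_iter)
    final <- core(res$theta, want_scores = TRUE)
    score_norm <- max(abs(final$grad[free]))
    converged <- is.finite(final$loglik) &&
      score_norm < tol * (1 + abs(final$loglik))
  }
  params <- unpack_theta(res$theta, fr)
  nat <- esc_natural(params)
  if (max(abs(nat[c("rho1", "rho0")])) > 0.995)
    warning("estimated |rho| exceeds 0.995: correlation at the boundary")
  quad_gap <- abs(esc_loglik_core(res$theta, fr, 2 * nodes)$loglik -
                    final$loglik) / length(fr$Y)
  fit <- structure(list(
    params = params, theta = res$theta, free = free, loglik = final$loglik,
    per_obs = final$per_obs, converged = converged, score_norm = score_norm,
    quad_gap = quad_gap, nodes = nodes, tol = tol,
    n = length(fr$Y), n_treated = sum(fr$tr == 1),
    n_control = sum(fr$tr == 0), optimizer = optimizer,
    opt_convergence = res$opt$convergence, frame = fr, fix = fix),
    class = "esc_fit")
  if (se) {
    rs <- robust_se(fit)
    fit$vcov_robust <- rs$vcov
    fit$se <- rs$se
    fit$coef_table <- rs$table
  }
  fit
}

#' Sandwich (robust) covariance of a fitted switching model
#'
#' Computes `H^{-1} S H^{-1}` with `H` the Hessian of the log-likelihood
#' (central finite differences of the analytic gradient, step
#' `1e-5 * (1 + |theta|)`) and `S` the outer product of the per-observation
#' analytic score vectors, plus delta-method standard errors for
#' `sigma_j = exp(ln sigma_j)` and `rho_j = tanh(arho_j)`.
#'
#' @param fit an `esc_fit`.
#' @return list with `vcov` (free-parameter covariance), `se` (named vector)
#'   and `table` (coefficient table with natural-scale rows for sigma/rho).
#' @export
robust_se <- function(fit) {
  stopifnot(inherits(fit, "esc_fit"))
  fr <- fit$frame
  free <- fit$free
  core <- function(th, want_scores = FALSE)
    esc_loglik_core(th, fr, fit$nodes, want_scores)
  gfun <- function(th) core(th, want_scores = TRUE)$grad[free]
  gfree <- function(par) {
    th <- fit$theta; th[free] <- par
    gfun(th)
  }
  H <- grad_hessian(gfree, fit$theta[free])
  ## frequency-weight convention: the meat is sum_i w_i s_i s_i', so that
  ## doubling all weights doubles H and S consistently
  sc <- core(fit$theta, want_scores = TRUE)$scores[, free, drop = FALSE]
  S <- crossprod(sc / sqrt(fr$w))
  bread <- neg_inverse(H)
  V <- bread %*% S %*% bread
  V <- (V + t(V)) / 2
  dimnames(V) <- list(names(fit$theta)[free], names(fit$theta)[free])
  se <- setNames(rep(NA_real_, length(fit$theta)), names(fit$theta))
  se[free] <- sqrt(pmax(diag(V), 0))
  est <- fit$theta
  tab <- data.frame(parameter = names(est), estimate = unname(est),
                    se = unname(se))
  ## natural-scale sigma/rho via the delta method
  nat <- esc_natural(fit$params)
  extra <- data.frame(
    parameter = c("sigma1", "sigma0", "rho1", "rho0"),
    estimate = unname(nat),
    se = unname(c(se["ln_sigma1"] * nat[["sigma1"]],
                  se["ln_sigma0"] * nat[["sigma0"]],
                  se["arho1"] * (1 - nat[["rho1"]]^2),
                  se["arho0"] * (1 - nat[["rho0"]]^2))))
  tab <- rbind(tab, extra)
  tab$z <- tab$estimate / tab$se
  tab$p_value <- 2 * pnorm(-abs(tab$z))
  tab$stars <- p_stars(tab$p_value)
  list(vcov = V, se = se, table = tab)
}

#' @export
print.esc_fit <- function(x, digits = 3, ...) {
  cat("Endogenous switching count model (FIML, Gauss-Hermite ", x$nodes,
      " nodes)\n", sep = "")
  cat(sprintf("  n = %d (treated %d, control %d)   loglik = %.3f\n",
              x$n, x$n_treated, x$n_control, x$loglik))
  cat(sprintf("  converged: %s   score max-norm = %.2e   quad gap/obs = %.2e\n",
              x$converged, x$score_norm, x$quad_gap))
  nat <- esc_natural(x$params)
  cat(sprintf("  sigma1 = %.4g  sigma0 = %.4g  rho1 = %.3f  rho0 = %.3f\n",
              nat[["sigma1"]], nat[["sigma0"]], nat[["rho1"]], nat[["rho0"]]))
  if (!is.null(x$coef_table)) {
    tab <- x$coef_table
    tab$estimate <- round(tab$estimate, digits)
    tab$se <- round(tab$se, digits)
    tab$z <- round(tab$z, 2)
    print(tab, row.names = FALSE)
  }
  invisible(x)
}
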