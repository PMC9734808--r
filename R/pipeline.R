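## End-to-end orchestration: validate a survey table, run descriptives, fit
## the switching model, compute effects and robustness checks, and write a
## reproducible report directory. Configuration is a plain list (or a YAML
## file with the same structure); all randomness flows from its single seed.

#' Validate a household survey table
#'
#' Drops rows failing the survey's cleaning rules and reports counts per
#' rule: missing values in any role variable, households below the minimum
#' size, and (when intake records are supplied) households with any
#' per-capita intake above the cap.
#'
#' @param data raw household table.
#' @param roles list with `outcome`, `treatment`, `iv` and `covariates`
#'   column names (all must exist in `data`).
#' @param rules list of cleaning rules: `min_household_size` (default 1;
#'   applied when a `household_size` column exists) and `intake_cap` in
#'   g/day (default 5000).
#' @param intake optional long intake records (see [compute_dds()]) with
#'   household ids matching `data$household_id`.
#' @return list with `data` (survivors) and `report` (data frame of rule,
#'   dropped count).
#' @export
validate_survey <- function(data, roles,
                            rules = list(min_household_size = 1,
                                         intake_cap = 5000),
                            intake = NULL) {
  need <- unlist(roles[c("outcome", "treatment", "iv", "covariates")],
                 use.names = FALSE)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("required column(s) missing from data: ", paste(miss, collapse = ", "))
  if (anyDuplicated(c(roles$outcome, roles$treatment, roles$iv)))
    stop("outcome, treatment and iv roles must be distinct columns")
  report <- data.frame(rule = character(), dropped = integer())
  note <- function(rule, n) rbind(report, data.frame(rule = rule, dropped = n))

  keep <- complete.cases(data[need])
  report <- note("missing_role_variable", sum(!keep))
  data <- data[keep, , drop = FALSE]

  min_hh <- rules$min_household_size %||% 1
  if ("household_size" %in% names(data)) {
    keep <- data$household_size >= min_hh
    report <- note("household_size_below_minimum", sum(!keep))
    data <- data[keep, , drop = FALSE]
  }

  if (!is.null(intake) && "household_id" %in% names(data)) {
    cap <- rules$intake_cap %||% 5000
    over <- unique(intake$household_id[
      intake$grams_per_capita_per_day > cap])
    keep <- !(data$household_id %in% over)
    report <- note("intake_above_cap", sum(!keep))
    data <- data[keep, , drop = FALSE]
  }
  list(data = data, report = report)
}

read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config$roles <- config$roles %||% list()
  config$roles$outcome <- config$roles$outcome %||% "dds"
  config$roles$treatment <- config$roles$treatment %||% "ofs"
  config$roles$iv <- config$roles$iv %||% "peer_online"
  config$roles$covariates <- config$roles$covariates %||% default_covariates()
  config$options <- config$options %||% list()
  o <- config$options
  config$options <- list(nodes = o$nodes %||% 32, tol = o$tol %||% 1e-6,
                         bootstrap = o$bootstrap %||% 0,
                         seed = o$seed %||% 1,
                         prete = o$prete %||% TRUE,
                         ipwra = o$ipwra %||% TRUE,
                         falsification = o$falsification %||% TRUE)
  config$validation <- config$validation %||% list()
  if (is.null(config$data)) stop("config must name a 'data' CSV path")
  if (is.null(config$outdir)) stop("config must name an 'outdir'")
  config
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
}

effect_row <- function(e) {
  data.frame(effect = e$effect, mean_factual = e$mean_factual,
             mean_counterfactual = e$mean_counterfactual, point = e$point,
             pct_change = e$pct_change, se = e$se,
             sd_effects = e$sd_effects, n_group = e$n_group)
}

#' Run the full analysis pipeline
#'
#' Reads the survey CSV, validates it, writes descriptive tables (summary
#' statistics, food-group table when intake records are given, treated vs
#' control mean differences), fits the endogenous switching count model,
#' writes the coefficient and IRR tables, ATT/ATU effects (bootstrap SEs
#' when `options$bootstrap > 0`), the IV falsification test and the
#' robustness estimators, plus a machine-readable `summary.json` and a run
#' log. Identical config and seed give byte-identical `summary.json`.
#'
#' @param config list or YAML path with fields `data` (CSV path), optional
#'   `intake` (CSV path), `outdir`, `roles` (outcome/treatment/iv/
#'   covariates), `options` (nodes, tol, bootstrap, seed, prete, ipwra,
#'   falsification) and `validation` rules.
#' @return invisibly, a list with the fitted objects and the paths written.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  roles <- cfg$roles; opts <- cfg$options
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$outdir, f)
  t0 <- Sys.time()
  stages <- list()
  tick <- function(name, expr) {
    s <- Sys.time()
    v <- force(expr)
    stages[[name]] <<- round(as.numeric(Sys.time() - s, units = "secs"), 3)
    message(sprintf("[%s] done in %.1fs", name, stages[[name]]))
    v
  }

  data <- read.csv(cfg$data)
  intake <- if (!is.null(cfg$intake)) read.csv(cfg$intake)
  val <- tick("validate",
              validate_survey(data, roles, cfg$validation, intake))
  data <- val$data
  write_json_file(list(n_in = nrow(data) + sum(val$report$dropped),
                       n_kept = nrow(data),
                       dropped = val$report), out("validation.json"))

  vars <- c(roles$outcome, roles$treatment, roles$covariates, roles$iv)
  desc <- data.frame(variable = vars,
                     mean = vapply(vars, function(v) mean(data[[v]]), 0),
                     sd = vapply(vars, function(v) sd(data[[v]]), 0))
  write.csv(desc, out("descriptives.csv"), row.names = FALSE)

  if (!is.null(intake)) {
    write.csv(summarize_groups(intake, nrow(data)),
              out("food_groups.csv"), row.names = FALSE)
  }
  write.csv(group_mean_differences(data, roles$treatment,
                                   c(roles$outcome, roles$covariates,
                                     roles$iv)),
            out("mean_differences.csv"), row.names = FALSE)

  set.seed(opts$seed)
  fit <- tick("fit_esc",
              fit_esc(data, roles$outcome, roles$treatment, roles$covariates,
                      roles$iv, nodes = opts$nodes, tol = opts$tol))
  write.csv(fit$coef_table, out("coefficients.csv"), row.names = FALSE)
  write.csv(irr_table(fit), out("irr.csv"), row.names = FALSE)
  nat <- esc_natural(fit$params)
  write_json_file(list(loglik = fit$loglik, converged = fit$converged,
                       score_norm = fit$score_norm, nodes = fit$nodes,
                       n = fit$n, n_treated = fit$n_treated,
                       params = lapply(fit$params, as.list),
                       natural = as.list(nat)),
                  out("fit.json"))

  effects <- tick("effects", {
    if (opts$bootstrap > 0)
      effect_se(fit, B = opts$bootstrap, seed = opts$seed,
                method = "bootstrap")[c("ATT", "ATU")]
    else list(ATT = att(fit), ATU = atu(fit))
  })
  write.csv(rbind(effect_row(effects$ATT), effect_row(effects$ATU)),
            out("effects.csv"), row.names = FALSE)

  fals <- prete <- ipw <- NULL
  if (isTRUE(opts$falsification)) {
    fals <- tick("falsification",
                 falsification_test(data, roles$outcome, roles$treatment,
                                    roles$covariates, roles$iv))
    write_json_file(unclass(fals), out("falsification.json"))
  }
  if (isTRUE(opts$prete)) {
    prete <- tick("prete",
                  fit_prete(data, roles$outcome, roles$treatment,
                            roles$covariates, roles$iv, nodes = opts$nodes))
    write_json_file(list(treatment_coef = prete$treatment_coef,
                         treatment_se = prete$treatment_se,
                         pct_effect = prete$pct_effect, sigma = prete$sigma,
                         rho = prete$rho, loglik = prete$loglik,
                         converged = prete$converged),
                    out("prete.json"))
  }
  if (isTRUE(opts$ipwra)) {
    ipw <- tick("ipwra",
                ipwra_att(data, roles$outcome, roles$treatment,
                          roles$covariates, roles$iv))
    write_json_file(c(unclass(ipw)[c("effect", "point", "pct_change",
                                     "mean_factual", "mean_counterfactual",
                                     "n_group")],
                      list(n_trimmed = attr(ipw, "n_trimmed"))),
                    out("ipwra.json"))
  }

  summary <- list(
    n = fit$n, n_treated = fit$n_treated, n_control = fit$n_control,
    loglik = fit$loglik, converged = fit$converged,
    sigma1 = nat[["sigma1"]], sigma0 = nat[["sigma0"]],
    rho1 = nat[["rho1"]], rho0 = nat[["rho0"]],
    att = list(point = effects$ATT$point,
               pct_change = effects$ATT$pct_change,
               se = effects$ATT$se),
    atu = list(point = effects$ATU$point,
               pct_change = effects$ATU$pct_change,
               se = effects$ATU$se),
    falsification_verdict = if (!is.null(fals)) fals$verdict,
    prete_pct_effect = if (!is.null(prete)) prete$pct_effect,
    ipwra_att = if (!is.null(ipw)) ipw$point,
    seed = opts$seed)
  write_json_file(summary, out("summary.json"))
  write_json_file(list(seed = opts$seed,
                       package_version = as.character(packageVersion("switchcount")),
                       r_version = R.version.string,
                       started = format(t0, "%Y-%m-%d %H:%M:%S"),
                       stage_seconds = stages),
                  out("run_log.json"))
  invisible(list(fit = fit, effects = effects, falsification = fals,
                 prete = prete, ipwra = ipw, outdir = cfg$outdir,
                 summary = summary))
}
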