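---
title: "Endogenous switching regression for count outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Endogenous switching regression for count outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchcount)
```

## The problem

Households choose for themselves whether to adopt a behaviour — here, the
motivating application is online food shopping among rural households — and
we want the causal effect of that choice on a bounded count outcome, the
household dietary diversity score (DDS): the number of distinct food groups,
out of a canonical list of 12, consumed over a 72-hour recall window.
Adopters differ systematically from non-adopters in both observed
characteristics (age, education, asset ownership) and unobserved ones
(technology affinity, motivation), so a naive comparison of group means
confounds selection with treatment.

`switchcount` implements an endogenous switching model for counts that
addresses both sources of selection bias by full-information maximum
likelihood (FIML), together with the surrounding toolkit: DDS construction
from long-format intake records, counterfactual treatment effects,
incidence-rate-ratio reporting, an instrument falsification test, two
robustness estimators, and a synthetic survey generator that carries both
potential outcomes so every stage can be validated against a known truth.

## The model

A probit selection equation drives the treatment indicator:

$$T_i = 1\{Z_i'\alpha + \varepsilon_i > 0\}, \qquad
  \varepsilon_i \sim N(0, 1),$$

where $Z$ contains the outcome covariates $X$ plus at least one excluded
instrument. Each treatment regime $j \in \{1, 0\}$ has its own Poisson
outcome process with lognormal heterogeneity:

$$Y_{ji} \mid X_i, \eta_{ji} \sim
  \mathrm{Poisson}\{\exp(X_i'\beta_j + \eta_{ji})\}, \qquad
  \eta_{ji} = \sigma_j u_{ji},\; u_{ji} \sim N(0,1),$$

with $\mathrm{corr}(\varepsilon_i, u_{ji}) = \rho_j$. Only the occupied
regime is observed. The joint probability of an observation integrates the
Poisson kernel against the heterogeneity, tilted by the selection
probability:

$$f_j(Y_i, T_i \mid X_i, Z_i) = \int
  f_j(Y_i \mid X_i, \eta)\,
  \Phi\!\left\{\frac{(2T_i - 1)(Z_i'\alpha + \rho_j \eta / \sigma_j)}
       {\sqrt{1 - \rho_j^2}}\right\} \phi_{\sigma_j}(\eta)\, d\eta ,$$

where $\phi_{\sigma}$ is the $N(0, \sigma^2)$ density (the mixing density
interpretation is the one consistent with $\sigma_j$ entering the
counterfactual mean formula separately). A statistically significant
$\hat\rho_j$ diagnoses selection on unobservables. Counterfactual expected
outcomes follow in closed form:

$$E(Y_j \mid X, T) = \exp(X'\beta_j + \sigma_j^2/2)\,
  \frac{\Phi\{(2T-1)(\rho_j\sigma_j + Z'\alpha)\}}
       {\Phi\{(2T-1) Z'\alpha\}},$$

and the average treatment effect on the treated (ATT) averages
$E(Y_1|X,T{=}1) - E(Y_0|X,T{=}1)$ over treated households; the ATU is the
analogue over untreated households. Percent changes divide by the
regime-0 mean within the group (the counterfactual mean for the ATT, the
factual mean for the ATU) — the convention that reproduces the published
worked examples this package's acceptance checks use.

## Numerical strategy

* **Quadrature.** The one-dimensional mixing integral is evaluated by
  non-adaptive Gauss–Hermite quadrature after standardising
  $\eta = \sqrt{2}\sigma u$; the default order is 32 nodes. All node-level
  terms are assembled in log space with log-sum-exp stabilisation, and
  $\Phi$ is always evaluated through `pnorm(log.p = TRUE)` so deep-tail
  selection indices never underflow to $0/0$. At the fitted optimum the
  log-likelihood is re-evaluated at twice the order; the per-observation
  change is stored as `quad_gap` (typically $<10^{-6}$).
* **Parameterisation.** Optimisation runs unconstrained over
  $(\alpha, \beta_1, \beta_0, \ln\sigma_1, \ln\sigma_0,
  \mathrm{atanh}\,\rho_1, \mathrm{atanh}\,\rho_0)$, keeping
  $\sigma_j > 0$ and $|\rho_j| < 1$ without box constraints. Results are
  reported on both scales.
* **Optimiser.** BFGS with analytic gradients (the per-observation score
  of the quadrature likelihood is available in closed form given the node
  posteriors), with an L-BFGS-B fallback. For orders of 16 and above a
  coarse 8-node pre-optimisation supplies the starting point; the final
  convergence check — gradient max-norm below
  $\mathrm{tol}\cdot(1 + |\ell|)$ — is always performed at the requested
  order. Starting values come from a probit of $T$ on $Z$ and
  arm-restricted Poisson fits, with $\ln\sigma_j = \ln 0.5$,
  $\rho_j = 0$; all coefficients are clamped to $[-20, 20]$ so degenerate
  arms (all-zero counts) still start finite. Refits on identical data are
  bit-identical.
* **Standard errors.** Sandwich covariance $H^{-1} S H^{-1}$ with $S$ the
  outer product of analytic per-observation scores (frequency-weight
  convention $\sum_i w_i s_i s_i'$) and $H$ a central-finite-difference
  Hessian of the analytic gradient, step $10^{-5}(1 + |\theta_k|)$;
  singular Hessians fall back to an eigenvalue pseudo-inverse with a
  warning. $\sigma_j$ and $\rho_j$ get delta-method SEs on the natural
  scale; $\rho_j$'s significance is assessed by a z-test on the atanh
  scale.
* **Effect uncertainty.** A nonparametric household bootstrap (resample
  rows, refit warm-started from the full-sample estimate, recompute both
  effects) is the default; a parametric alternative draws parameter
  vectors from the asymptotic normal without refitting. Replicate fits
  accept the optimiser's own stopping rule with a relaxed gradient
  tolerance — near the $\sigma$ boundary the strict criterion can be
  unattainable on a sharp ridge although the optimum is located far more
  precisely than resampling noise. Both the SE of the effect and the SD of
  the per-household effects are reported, since published tables do not
  always say which of the two their parentheses contain.

## Behaviour near $\sigma = 0$

The reference configuration (below) has $\ln\sigma_1 = -5.8$ and
$\ln\sigma_0 = -6.6$: heterogeneity SDs of order $10^{-3}$ against Poisson
means around 7. Data carry essentially no information distinguishing such
values from zero — the likelihood gain of the fitted heterogeneity block
over $\sigma_j = 0$ is a couple of log-likelihood units at $n = 20{,}000$.
Three practical consequences, all deliberate behaviour:

1. $\hat\sigma_j^2$ behaves like a variance component at the boundary of
   its parameter space: its sampling distribution is approximately
   $\max\{0, N(0, \tau^2)\}$, so $\hat\sigma_j$ may collapse to numerical
   zero or sit at a small positive value (up to roughly $0.05$–$0.1$ here)
   with no contradiction. Wald intervals on the $\ln\sigma$ scale are not
   valid in this regime; recovery should be judged on the variance scale
   or through the identified product $\rho_j\sigma_j$ that enters the
   counterfactual means.
2. When $\hat\sigma_j$ collapses, $\rho_j$ is unidentified (it enters the
   likelihood only through $\rho_j\eta/\sigma_j$ weighted by a degenerate
   mixture) and its sign is arbitrary; the fit warns when $|\hat\rho_j|$
   exceeds 0.995 and the Hessian may need the pseudo-inverse.
3. Treatment effects are essentially unaffected: the ATT/ATU depend on the
   block only through $\sigma_j^2/2$ and $\rho_j\sigma_j$, both
   recovered to within a few times $10^{-2}$ in absolute terms.

## The synthetic survey generator

`generate_population()` draws covariates from per-variable marginals,
a trivariate normal error vector, both potential outcomes, and the
selection indicator, returning the observable survey table together with
the oracle ($y_1$, $y_0$, latent draws). Design choices:

* **Marginals, not joints.** The calibration source reports only means and
  SDs, so covariates are independent by default; honesty about what is
  known beats an invented correlation structure. The default marginals
  reproduce the survey table: truncated normals for age (18–95),
  education (0–22) and household size ($\geq 1$) whose *truncated* mean
  and SD are moment-matched to the targets (plain truncation would shift
  education's mean by about 0.3 years); lognormals matched in mean and SD
  for the skewed non-negative variables (land size, distances); Bernoulli
  indicators; a four-level province factor expanded into exhaustive,
  mutually exclusive dummies with Sichuan as reference; and a Bernoulli
  (0.59) instrument: whether relatives or friends shop online.
* **Calibrated adoption share.** The selection slopes are the reference
  estimates (instrument coefficient 1.328); the intercept is calibrated by
  root-finding so the population mean of $\Phi(Z'\alpha)$ equals the
  observed adoption share 0.18 (`calibrate_selection_intercept()`, fixed
  internal Monte-Carlo draw, deterministic).
* **Error joint.** Only $\mathrm{corr}(\varepsilon, u_j)$ is ever
  identified — the two regimes are never jointly observed. The generator
  uses the one-factor construction
  $u_j = \rho_j \varepsilon + \sqrt{1 - \rho_j^2}\, v_j$ with independent
  $v_j$, giving $\mathrm{corr}(u_1, u_0) = \rho_1\rho_0$; `rho_cross`
  overrides it (validated for positive definiteness).
* **Unbounded counts.** The estimator assumes Poisson support, so counts
  are not capped at 12 by default; `cap12 = TRUE` exists for realism
  experiments. With the reference parameters the generated DDS mean is
  6.57 and the share of counts above 12 is negligible.

What the generator does *not* emulate: village/county clustering, the
two-step recall protocol, item-level intake joint with the household
covariates, and covariate correlations. Passing tests therefore certify
the estimator under the model's own assumptions — they cannot certify
robustness to misspecifications real surveys may carry.

A worked example:

```{r example, eval = FALSE}
cfg <- default_config(n = 947, seed = 1)
truth <- generate_population(cfg)
mean(truth$data$ofs)        # adoption share ~ 0.18
true_effects(truth)         # oracle ATT / ATU

fit <- fit_esc(truth$data)  # FIML, 32-node quadrature
att(fit); atu(fit)          # model-based effects
irr_table(fit)              # per-regime incidence rate ratios
falsification_test(truth$data)
```

## Dietary diversity construction

`compute_dds()` counts the distinct food groups with positive intake per
household (each group once, zero-gram records ignored), and
`summarize_groups()` reports per-group participation and mean per-capita
intake. Mean intake uses the **all-household** denominator (non-consumers
contribute zero); the source tables do not state which convention they
use, and this one is flagged here as the package's choice. The intake
simulator draws per-group consumption independently at calibrated
participation rates — a useful property follows: the implied mean DDS is
the sum of the participation probabilities ($\approx 6.57$ at the default
profile), matching the survey's reported mean, which suggests independence
across groups is not a bad approximation at the mean.

## Instrument falsification and robustness estimators

The falsification test checks **relevance** (z-test of the instrument in
the selection probit, threshold $p < 0.01$) and **exclusion** (z-test of
the instrument added to a Poisson-lognormal regression of the outcome on
$X$ among untreated households, threshold $p > 0.10$); thresholds are
configurable and the exact recipe is this package's documented choice —
published applications typically cite the procedure without printing it.
One caveat the tests document: when $\sigma_j \rho_j$ is large, truncation
of the selection error induces a genuine association between a *valid*
instrument and the untreated outcome, so the exclusion check over-rejects;
with the reference configuration's tiny $\sigma_j$ the issue is
negligible.

Two alternative estimators serve as robustness checks. `fit_prete()` is
the single-equation counterpart — one outcome equation with a treatment
dummy and a single correlated heterogeneity term — estimated with the same
quadrature machinery; with $\rho$ pinned at zero it factorises exactly
into a probit plus a pooled Poisson-lognormal regression, which the tests
verify. `ipwra_att()` is inverse-probability-weighted regression
adjustment with ATT weights ($1$ for treated, $p/(1-p)$ for controls),
propensity trimming to $[0.01, 0.99]$, and arm-specific weighted Poisson
regressions; it is consistent only under selection on observables, and the
tests demonstrate both that regime (matching the oracle when $\rho_j = 0$)
and its limitation under unobserved selection.

## Problem sizes used in validation

The test-suite sizes are the package's validation design: likelihood
correctness against $10^6$-draw Monte-Carlo integration on 50 households;
parameter recovery at $n = 20{,}000$ from the reference configuration;
formula-vs-oracle effect checks on five configurations (including
$\rho_j = 0$ and strongly negative $\rho_j$) at $n = 2\times 10^5$;
generator calibration at $n = 10^4$; falsification size and power at
$n = 5{,}000$ / $n = 20{,}000$ with a $0.1$ instrument leak. Monte-Carlo
comparisons use pre-stated 3–4 SE bands (wider where several checks run
simultaneously).

## Known limitations

* The likelihood treats households as independent; survey clustering and
  stratification are not modelled (no design-based variance correction).
* Only Poisson kernels are implemented — no negative-binomial or
  zero-inflated variants, and only a binary treatment.
* The bounded support of a diversity score (0–12) is approximated by
  unbounded Poisson regimes, as in the source model; for outcomes near the
  ceiling this approximation deteriorates.
* Near-boundary heterogeneity is reported faithfully but, as described
  above, $\ln\sigma_j$ and $\rho_j$ should not be over-interpreted when
  $\hat\sigma_j$ is tiny.
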