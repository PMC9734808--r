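# switchcount

Endogenous switching regression for count outcomes, with treatment-effect
estimation and a calibrated synthetic survey generator.

## What problem this solves

Households *choose* whether to adopt a behaviour — the motivating
application is online food shopping in rural household surveys — and the
outcome of interest is a count: the household dietary diversity score
(DDS), the number of distinct food groups (out of 12) consumed over a
72-hour recall window. Because adopters differ from non-adopters in both
observed and unobserved ways, naive group comparisons confound selection
with treatment. This package is for applied econometricians and
nutrition/epidemiology researchers who need the selection-corrected
answer.

The core model couples a probit selection equation with two
regime-specific Poisson outcome equations whose lognormal heterogeneity is
correlated with the selection error:

    T_i = 1{ Z_i'α + ε_i > 0 },                     ε ~ N(0, 1)
    Y_ji | X_i, η_ji ~ Poisson( exp(X_i'β_j + η_ji) ),   j = 1 (treated), 0
    η_ji = σ_j u_ji,   corr(ε_i, u_ji) = ρ_j

Everything is estimated jointly by full-information maximum likelihood;
the mixing integral is evaluated by Gauss–Hermite quadrature (32 nodes by
default) in log space with analytic gradients, and inference uses
sandwich (robust) standard errors. A significant ρ̂_j diagnoses selection
on unobservables. Counterfactual expected outcomes

    E(Y_j | X, T) = exp(X'β_j + σ_j²/2) · Φ{(2T−1)(ρ_jσ_j + Z'α)} / Φ{(2T−1)Z'α}

give the average treatment effects on the treated (ATT) and untreated
(ATU), with percent changes relative to the group's regime-0 mean.

Around the core sit: DDS construction from long intake records
(`compute_dds`, `summarize_groups`, `group_mean_differences`),
incidence-rate-ratio tables (`irr_table`), an instrument falsification
test (`falsification_test`), robustness estimators (`fit_prete`,
`ipwra_att`), a pipeline driver (`run_pipeline`), and a synthetic survey
generator (`default_config`, `generate_population`) whose defaults are
calibrated to published survey marginals — adoption share 0.18,
instrument: whether relatives or friends shop online — and which retains
both potential outcomes per household as an oracle for validation.

## Worked example

```r
library(switchcount)

cfg   <- default_config(n = 5000, seed = 1)   # survey-calibrated generator
truth <- generate_population(cfg)
mean(truth$data$ofs)        # 0.1802  — adoption share near the 0.18 target
true_effects(truth)         # oracle: ATT 0.216, ATU 0.426

fit <- fit_esc(truth$data)  # FIML, 32-node Gauss–Hermite
att(fit)
#> ATT: 0.4045 (6.15%)  [factual 6.9799, counterfactual 6.5755, n = 901]
effect_se(fit, B = 400, seed = 1, method = "parametric")$ATT
#> ATT: 0.4045 (6.15%)  SE = 0.6159

falsification_test(truth$data)
#> relevance (selection probit): z = 21.47, p = 2.9e-102 (need p < 0.01)
#> exclusion (untreated outcome): z = 1.33, p = 0.182    (need p > 0.1)
#> verdict: pass

irr_table(fit)[c(4, 7), c("variable", "irr_treated", "irr_control")]
#>    variable irr_treated irr_control
#> 4 education       1.011       1.007
#> 7      oven       1.079       1.028
```

Reading the output: treated households average 6.98 food groups; the model
puts their counterfactual (non-shopping) mean at 6.58, an ATT of 0.40
(+6.2%), consistent with the generator's oracle ATT of 0.22 well within
the SE of 0.62. The education IRRs say one extra year of schooling scales
the expected DDS by 1.011 among shoppers (a 1.1% increase). The
falsification test confirms the instrument predicts adoption but not the
outcome among non-adopters.

The methods vignette (`vignettes/endogenous-switching-counts.Rmd`) details
the likelihood, the numerical choices, the generator's calibration, and
the model's behaviour when the heterogeneity SDs approach zero.

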