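# idmaft

Parametric Weibull accelerated failure time (AFT) illness-death models for
semi-competing risks data.

## The problem

In cohort studies a disease of interest (the non-terminal event) can be
censored by death (the terminal event), but not vice versa: a diagnosed
participant remains under observation until death. On top of this
semi-competing structure, three observation features are the rule when age
is the time scale: participants enter the study late (left truncation at
the entry age), the disease onset is only known to lie between two
follow-up visits (interval censoring), and death is right-censored at the
study end.

`idmaft` models such data with a three-state illness-death model — healthy,
diseased, dead — fitting one Weibull AFT regression per transition:
incidence *i*, mortality without disease *m0*, mortality after diagnosis
*m1*. For transition *p*,

    log T = X'beta_p + kappa_p^{-1} epsilon + u_p,

i.e. T is Weibull with scale `exp(X'beta_p + u_p)` and shape `kappa_p`.
Covariates act multiplicatively on the event **age**: `exp(beta)` is an
acceleration factor, and `exp(-kappa * beta)` the equivalent hazard ratio.
A per-subject normal random-effect vector `u` links the three submodels
(shared scalar "HomVar", structured trivariate "HetVar", or none) and is
integrated out of the likelihood by non-adaptive Gauss–Hermite quadrature
(2 nodes per dimension by default). The likelihood handles all four
observed-data cases (diagnosed × died) with left truncation at entry and
midpoint truncation of the post-diagnosis death age.

The package is aimed at biostatisticians analysing disease-incidence
cohorts (dementia, diabetes, ...) who want effects on the age scale rather
than hazard ratios, plus the machinery to validate the estimator by
simulation: a calibrated cohort generator, a scenario catalogue, and a
replicate-study harness computing median bias, MSE, coverage and
convergence rates.

## A worked example

```r
library(idmaft)

sim <- simulate_idm(idm_scenario("E65_S", 500), seed = 1)
sim
#> Synthetic illness-death cohort 'E65_S': 479 retained of 500 drawn
#> 
#>   I  II III  IV 
#> 101   4 276  98 

fit <- fit_idm(~ sex, sim$data, structure = "homvar")
fit
#> Weibull AFT illness-death model (homvar random effects)
#>   n = 479 subjects, 10 free parameters, 2 quadrature points/dim
#>   logLik = -1829.981   AIC = 3680.0   BIC = 3721.7   converged: TRUE
#> 
#>                     Estimate Std. Error
#> beta_i.(Intercept)    4.6175     0.0275
#> beta_i.sex            0.0570     0.0356
#> beta_m0.(Intercept)   4.4864     0.0082
#> beta_m0.sex          -0.0231     0.0120
#> beta_m1.(Intercept)   4.2132     0.0576
#> beta_m1.sex          -0.1120     0.0351
#> kappa_i               6.0045     0.8577
#> kappa_m0             10.1103     0.6016
#> kappa_m1              6.8937     1.2674
#> s2                    0.0000     0.0000

effect_table(fit)[, c("transition", "term", "beta", "af", "hr")]
#>   transition term        beta        af        hr
#> 1          i  sex  0.05698013 1.0586348 0.7102512
#> 2         m0  sex -0.02309707 0.9771676 1.2630361
#> 3         m1  sex -0.11196103 0.8940791 2.1637203
```

The `beta` column is the AFT coefficient (log-age scale), `af = exp(beta)`
the acceleration factor — in this simulated cohort males reach disease
onset at 1.06 times the female age and die (without disease) at 0.98 times
the female age — and `hr = exp(-kappa*beta)` the corresponding hazard
ratio. At n = 479 the estimates sit within about two standard errors of
the generator truth (0.03, −0.04, −0.08 for the three sex effects).
`profile_summaries()` converts a fit into mean/median event ages per
covariate profile, and `median_survival_difference()` reports how many
years of median lifetime a diagnosis costs for a given profile.

The data generator follows the cohort emulation used in the shipped
simulation study: trivariate normal random effects (variances 0.008237,
0.000714, 0.000063, one covariance 0.000115), sex ~ Bernoulli(0.4),
Weibull event ages calibrated so the reference-profile means are 95
(onset), 85 (death without disease) and 65 or 80 (death after diagnosis)
years, entry U(55,60), censoring U(85,95) or U(95,105), visit half-widths
U(0,3). `scenario_catalogue()` lists the 12 shipped settings;
`run_study()` executes scenario × structure × replicate grids and
summarises them into bias/MSE/coverage tables.

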