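---
title: "Weibull AFT illness-death models for semi-competing risks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weibull AFT illness-death models for semi-competing risks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idmaft)
```

## The model

Cohort studies that follow participants for a disease of interest face a
*semi-competing risks* structure: death can censor the disease onset, but a
diagnosed participant remains observable until death. `idmaft` models this
with a three-state illness-death model — healthy, diseased, dead — and one
Weibull accelerated failure time (AFT) regression per transition, on the
age scale:

* incidence *i*: age at disease onset \(T_1\),
* mortality without disease *m0*: age at death for undiagnosed subjects
  \(T_2\),
* mortality after diagnosis *m1*: age at death given onset at \(T_1\).

Each transition \(p \in \{i, m0, m1\}\) has
\(\log T = X^\top\beta_p + \kappa_p^{-1}\,\varepsilon + u_p\) with a
standard extreme-value error, i.e. \(T\) is Weibull with scale
\(\eta_p = \exp(X^\top\beta_p + u_p)\) and shape \(\kappa_p\),
\(S_p(t) = \exp\{-(t/\eta_p)^{\kappa_p}\}\). Covariates multiply the event
*age*: \(\exp(\beta)\) is an acceleration factor (AF), and for the Weibull
the same coefficient converts to a proportional-hazards hazard ratio
\(\mathrm{HR} = \exp(-\kappa\beta) = \mathrm{AF}^{-\kappa}\), so a negative
coefficient (earlier event) yields HR > 1. A note on conventions: some
presentations of the AFT model call the error multiplier a "scale"
parameter; every population formula used here (mean
\(\eta\,\Gamma(1+1/\kappa)\), median \(\eta(\log 2)^{1/\kappa}\)) requires
\(\kappa\) to be the Weibull *shape*, and the package uses that convention
throughout.

The per-subject random-effect vector \(u = (u_i, u_{m0}, u_{m1})\) is
normal with mean zero and either a shared scalar effect (`homvar`: one
variance \(s^2\), the same draw added to all three linear predictors), a
structured trivariate effect (`hetvar`: three variances plus
\(c_{i,m1}\) and \(c_{m0,m1}\); the incidence/death-without-disease
covariance is fixed at zero because death before any disease is taken to
be unrelated to the disease process), or no effect at all (`none`).

## Observed data and likelihood

Each subject contributes the tuple (entry age \(L\), diagnosis interval
\([T_l, T_r]\), last age \(Y_2 = \min(T_2, C)\), indicators
\(\delta_1, \delta_2\), covariates). Age is the time scale, so everyone is
left-truncated at study entry: the likelihood conditions on being healthy
and alive at \(L\) through the divisor \(S_i(L)\,S_{m0}(L)\). Disease
onset is interval-censored between the last disease-free visit and the
first visit with diagnosis; death is right-censored at \(C\). The four
cases (diagnosed × died) contribute, conditionally on \(u\):

| case | \(\delta_1\) | \(\delta_2\) | contribution |
|------|------|------|-------------------------------------------------------|
| I    | 1 | 1 | \([S_i(T_l)-S_i(T_r)]\; S_{m0}(T_r)\; f_{m1}(Y_2) \,/\, [S_i(L) S_{m0}(L) S_{m1}(T_m)]\) |
| II   | 1 | 0 | as I with \(S_{m1}(Y_2)\) in place of \(f_{m1}(Y_2)\) |
| III  | 0 | 1 | \(S_i(Y_2)\, f_{m0}(Y_2) \,/\, [S_i(L) S_{m0}(L)]\) |
| IV   | 0 | 0 | \(S_i(Y_2)\, S_{m0}(Y_2) \,/\, [S_i(L) S_{m0}(L)]\) |

The model is Markov: the post-diagnosis death hazard depends only on
current age, so \(S_{m1}(t_2 \mid t_1) = S_{m1}(t_2)/S_{m1}(t_1)\). Because
the onset age inside the interval is unknown, the *m1* distribution is
left-truncated at the interval midpoint \(T_m\) by default
(`tm_trunc = "midpoint"`); truncation at the right bound is available.
Wide visit intervals make the midpoint markedly less biased than the right
bound when visits are far apart.

Two numerical points matter here and are the package's own choices:

* **All survival terms are evaluated in log space**
  (\(\log S = -\exp\{\kappa(\log t - \log\eta)\}\)) and the interval
  probability as `log1p(-exp(...))`; at ages 55–105 with shapes near 10 the
  plain products underflow double precision.
* **The truncation age of the *m1* factor is capped at the observed last
  age, \(\min(T_m, Y_2)\).** The generator draws visit intervals around the
  true onset, so \(T_m\) (even \(T_r\)) can fall after an early death. An
  uncapped \(f_{m1}(Y_2)/S_{m1}(T_m)\) with \(T_m > Y_2\) exceeds the
  hazard, and the marginal likelihood becomes *unbounded* in
  \((\kappa_{m1}, s^2_{m1})\) — uncapped heterogeneous-variance fits
  diverged in exactly this way. Truncating a death-age law beyond the
  observed death is incoherent; with the cap such a subject contributes the
  hazard \(h_{m1}(Y_2)\) and the likelihood is bounded again.

The marginal likelihood integrates the product of contributions over \(u\)
by **non-adaptive Gauss–Hermite quadrature** (default 2 nodes per
dimension, the estimation default throughout; configurable upward).
Standard-normal nodes are rescaled by a symmetric eigenvalue square root of
the covariance so that zero variances degrade gracefully to a single node,
and the per-subject node mixture is combined by log-sum-exp. With two
nodes per dimension the `hetvar` grid has \(2^3 = 8\) points, exactly the
configuration used for all shipped simulation results.

## Estimation

`fit_idm()` maximises the marginal log-likelihood with `nlminb` (a PORT
quasi-Newton method with box constraints) over an unconstrained
parameterisation: coefficients natural, shapes log, variances log,
covariances as atanh-correlations (the correlation pair is kept inside the
positive semi-definite disc). Convergence is declared on relative function
change below 1e-8 (with a capped restart verifying stalls flagged by the
optimiser); the iteration cap is 500.

Warm starts are staged through the nested structures: three univariate
transition factor fits (interval-/right-censored truncated Weibull
likelihoods) start the no-random-effects model, its optimum starts
`homvar`, and the `homvar` optimum starts `hetvar`, combined with a coarse
grid search over random-effect variance initial values
\(\{10^{-6}, 10^{-4}, 10^{-2}\}\). Small initial variances are recommended.
Staging also enforces the nesting order of the maximised likelihoods: if a
richer structure ends below its parent, the parent solution with the extra
variance at its boundary is adopted.

Standard errors come from central finite differences of the marginal
log-likelihood at the maximiser (a pseudo-inverse with a flag when the
information matrix is near-singular — variance components on the boundary
routinely produce this), delta-method-transformed to the natural scale.
`effect_table()` reports \(\beta\), AF and HR with 95% Wald intervals; the
AF interval is the exponentiated coefficient interval, the HR interval uses
the delta method on \(\kappa\beta\) (the source tables are consistent with
the former; for the HR no propagation rule is stated, so the delta method
is adopted and documented here). `profile_summaries()` turns fits into
per-profile mean/median event ages with delta-method intervals, and
`median_survival_difference()` contrasts the two mortality medians — the
years of life a diagnosis costs for a covariate profile. These are
summaries of the latent Weibull laws: what a cohort observed from birth to
extinction would show, not the truncated, censored sample averages.

## The synthetic-data generator

`simulate_idm()` implements the cohort emulation used for all shipped
results:

1. \(u \sim N_3(0, \Sigma_{gen})\) with variances
   \(\sigma^2_i = 0.008237\), \(\sigma^2_{m0} = 0.000714\),
   \(\sigma^2_{m1} = 0.000063\) and the single covariance
   \(c_{i,m1} = 0.000115\) (the generator covariance differs deliberately
   from the fitted `hetvar` structure, which also frees \(c_{m0,m1}\));
2. sex \(\sim\) Bernoulli(0.4);
3. \(t_1\) and a disease-free death age from the *i* and *m0* Weibull
   submodels;
4. if \(t_1\) is the earlier event, the death age is redrawn from the *m1*
   submodel truncated at \(t_1\) by closed-form inversion
   \(t_2 = (t_1^{\kappa} - \eta^{\kappa}\log(1-U))^{1/\kappa}\);
5. entry \(L \sim U(55, 60)\) and censoring \(C \sim U(85,95)\) (early) or
   \(U(95,105)\) (late); subjects with \(L \ge \min(t_1, t_2)\) are
   deleted (left truncation);
6. a subject is diagnosed (\(\delta_1 = 1\)) when the onset precedes death
   and censoring, \(l < t_1 < \min(t_2, c)\); the visit interval is then
   built from two independent \(U(0,3)\) half-widths,
   \(t_l = \max(t_1 - U_1,\, l)\), \(t_r = t_1 + U_2\) (visits at most six
   years apart; the left bound never precedes study entry; the right bound
   may fall after death — see the truncation cap above).

The diagnosis indicator deserves a note: defining it from the latent onset
(step 6) rather than from the interval's right bound is what the
observation process implies — diagnosis status is decided by the disease
course, after which the surrounding visit ages are located. Defining
\(\delta_1\) by \(t_r < \min(t_2, c)\) instead misclassifies roughly half
of the diseased subjects when post-diagnosis survival is short
(\(E_{m1} = 65\)), and parameter recovery collapses; this package uses the
latent-onset definition.

**Calibration.** True shapes are \(\kappa_i = 7.0\), \(\kappa_{m0} =
10.8\), \(\kappa_{m1} = 8.1\), back-solved from the published
dementia-cohort coefficient/AF/HR triples via
\(\kappa = -\log(\mathrm{HR})/\beta\); sex effects are \(0.03\), \(-0.04\),
\(-0.08\) on the log-age scale. Intercepts are calibrated so the reference
(female) profile mean, *conditional on a zero random effect*, hits
\(E_i = 95\), \(E_{m0} = 85\), \(E_{m1} \in \{65, 80\}\) years through
\(E = e^{\beta_0}\Gamma(1 + 1/\kappa)\); the marginal mean over the random
effect is then \(E\,e^{\sigma^2/2}\) (about 95.4 years for incidence). The
calibration targets are stated for the event-age distributions without
saying whether they are reference-profile or sex-marginal means; the
reference-profile reading keeps the closed form exact and is adopted.

`scenario_catalogue()` ships the 12 settings crossing early/late
censoring, \(E_{m1} = 65/80\) and initial sizes 2400/1200/500. What the
generator does *not* emulate: covariate-dependent visit schedules,
non-uniform entry or censoring laws, more than one binary covariate in the
shipped scenarios (the fitting engine accepts arbitrary designs), or
measurement error in ages. Passing tests on these data therefore
demonstrate internal consistency of model, likelihood and estimator under
the stated mechanism — not robustness to real-cohort features such as
informative censoring or irregular visits.

## The simulation-study harness

`run_study()` executes scenario × structure × replicate grids;
`run_replicate()` is deterministic given (base seed, replicate index), with
per-replicate seeds spaced by a fixed prime so any execution order yields
identical archives. Metrics per parameter: median bias, MSE, empirical
coverage of 95% Wald intervals, and the convergence count; metrics are
computed over converged replicates only, with the convergence rate
reported alongside. Truths for derived Weibull mean/median summaries come
from the true parameters through the same closed forms.

Shipped checks use 100 replicates per cell (the headline study sizes here
are 100-replicate versions of 1000-replicate tables; medians and coverage
at 100 replicates carry Monte-Carlo noise of roughly ±0.03 on a coverage
proportion). The `hetvar` variance components frequently sit at or near
their boundary in these fits — the same behaviour the source analysis
reports — so their bias rows are reported but not meaningful; regression
coefficients and shapes are the evaluable quantities.

## Known limitations

* Shape parameters are estimated with visible bias under heavy censoring
  (their likelihood information comes from a narrow age window); regression
  coefficients are robust. This mirrors the published simulation tables.
* The `hetvar` random-effect variances are weakly identified at these
  magnitudes; expect boundary estimates and flagged standard errors.
* Only Weibull transition distributions are implemented; Gompertz or
  log-normal alternatives are out of scope here.
* Time-dependent covariates and covariate-dependent visit processes are
  not supported.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_idm(idm_scenario("E65_S", 500), seed = 1)
fit <- fit_idm(~ sex, sim$data, structure = "homvar")
fit
effect_table(fit)
profile_summaries(fit, data.frame(profile = c("female", "male"),
                                  sex = c(0, 1)))
median_survival_difference(fit, data.frame(sex = 1))
```
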