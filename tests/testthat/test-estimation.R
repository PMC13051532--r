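# Fast shared fits for the estimation tests (module-level fixtures).
sim_small <- simulate_idm(idm_scenario("E65_S", 500), seed = 101)
fit_none <- fit_idm(~ sex, sim_small$data, structure = "none")
fit_hom <- fit_idm(~ sex, sim_small$data, structure = "homvar")

test_that("univariate warm-start fits recover known distributions", {
  set.seed(61)
  # exponential, no truncation/censoring: MLE scale = mean of observations
  y <- rexp(3000, rate = 1 / 8)
  d <- idm_data(data.frame(entry_age = 0, t_left = NA, t_right = NA,
                           t_mid = NA, last_age = y, delta1 = 0, delta2 = 1,
                           sex = 0))
  tp <- fit_univariate("m0", d)
  expect_close(exp(tp$beta[1]), mean(y), 3 * mean(y) / sqrt(3000))
  expect_close(tp$kappa, 1, 0.05)
  # Weibull sample, kappa = 8, scale = 95: shape within 10%
  y <- rweibull(2000, shape = 8, scale = 95)
  d <- idm_data(data.frame(entry_age = 0, t_left = NA, t_right = NA,
                           t_mid = NA, last_age = y, delta1 = 0, delta2 = 1,
                           sex = 0))
  tp <- fit_univariate("m0", d)
  expect_close(tp$kappa / 8, 1, 0.1)
  expect_close(exp(tp$beta[1]) / 95, 1, 0.02)
  # fully censored data: no events, fallback with warning
  d2 <- idm_data(data.frame(entry_age = 0, t_left = NA, t_right = NA,
                            t_mid = NA, last_age = y, delta1 = 0,
                            delta2 = 0, sex = 0))
  expect_warning(fit_univariate("m0", d2), "no informative events")
})

test_that("fit without random effects recovers a zero-variance truth", {
  p0 <- true_params_dementia(65)
  p0$re <- re_hetvar(0, 0, 0)
  sim <- simulate_idm(idm_scenario("norand", 2400, true_params = p0),
                      seed = 51)
  fit <- fit_idm(~ sex, sim$data, structure = "none", se = FALSE)
  expect_true(fit$converged)
  tru <- scenario_truth(idm_scenario("norand", 2400, true_params = p0),
                        "none")
  bet <- grep("^beta", names(tru))
  # one replicate: allow ~2 sampling standard errors around the truth
  expect_true(all(abs(fit$estimate[bet] - tru[bet]) < 0.1))
})

test_that("information criteria follow their defining formulas", {
  expect_equal(fit_hom$aic, -2 * fit_hom$loglik + 2 * fit_hom$n_free)
  expect_equal(fit_hom$bic,
               -2 * fit_hom$loglik + log(fit_hom$n_subjects) * fit_hom$n_free)
  expect_equal(fit_hom$n_free, 10L)  # 6 betas + 3 shapes + 1 variance
  expect_equal(fit_none$n_free, 9L)
  # arithmetic sanity on the formulas themselves
  expect_equal(-2 * (-100) + 2 * 5, 210)
  expect_close(-2 * (-100) + 5 * log(100), 223.03, 0.005)
})

test_that("Wald intervals are standard", {
  expect_equal(wald_ci(0, 1)[1, ], c(lower = -1, upper = 1) * qnorm(0.975))
  expect_equal(wald_ci(3.2, 0), cbind(lower = 3.2, upper = 3.2))
  expect_error(wald_ci(0, -1), "non-negative")
  ci <- wald_ci(0.5, 0.2, level = 0.9)
  expect_close(ci[1, "lower"], 0.5 - qnorm(0.95) * 0.2, 1e-12)
})

test_that("nested random-effect structures order the likelihood", {
  f_het <- fit_idm(~ sex, sim_small$data, structure = "hetvar", se = FALSE)
  expect_gte(f_het$loglik, fit_hom$loglik - 1e-4)
  expect_gte(fit_hom$loglik, fit_none$loglik - 1e-4)
  # tiny shared variance: homvar collapses onto the no-RE fit
  expect_lt(fit_hom$loglik - fit_none$loglik, 0.5 + 1e-6)
})

test_that("refitting from the maximiser leaves the likelihood unchanged", {
  refit <- fit_idm(~ sex, sim_small$data, structure = "homvar",
                   start = fit_hom$params, se = FALSE)
  expect_lt(abs(refit$loglik - fit_hom$loglik), 1e-6)
})

test_that("effect table carries coherent AFT, AF and HR columns", {
  tab <- effect_table(fit_hom)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$transition, c("i", "m0", "m1"))
  expect_equal(tab$af, acceleration_factor(tab$beta))
  kaps <- fit_hom$estimate[paste0("kappa_", tab$transition)]
  expect_equal(tab$hr, unname(hazard_ratio(tab$beta, kaps)))
  # AF interval is the exponentiated coefficient interval
  expect_equal(tab$af_lower, exp(tab$beta_lower))
  expect_equal(tab$af_upper, exp(tab$beta_upper))
  expect_true(all(tab$beta_lower <= tab$beta, tab$beta <= tab$beta_upper))
  expect_true(all(tab$hr_lower <= tab$hr, tab$hr <= tab$hr_upper))
})

test_that("profile summaries respect the Weibull mean/median identity", {
  prof <- data.frame(profile = c("female", "male"), sex = c(0, 1))
  ps <- profile_summaries(fit_hom, prof)
  expect_equal(nrow(ps), 6L)
  for (r in seq_len(nrow(ps))) {
    kap <- fit_hom$estimate[paste0("kappa_", ps$transition[r])]
    expect_close(ps$median[r] / ps$mean[r],
                 log(2)^(1 / kap) / gamma(1 + 1 / kap), 1e-10)
  }
  expect_true(all(ps$mean_lower <= ps$mean & ps$mean <= ps$mean_upper))
  # kappa = 1 sanity via the closed forms used in the summaries
  expect_equal(wb_median(log(10), 1) / wb_mean(log(10), 1), log(2))
})

test_that("median survival difference matches the profile summaries", {
  prof <- data.frame(sex = 1)
  msd <- median_survival_difference(fit_hom, prof)
  ps <- profile_summaries(fit_hom, prof)
  direct <- ps$median[ps$transition == "m0"] -
    ps$median[ps$transition == "m1"]
  expect_close(msd[["difference"]], direct, 1e-10)
  expect_lte(msd[["lower"]], msd[["difference"]])
  expect_gte(msd[["upper"]], msd[["difference"]])
})
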