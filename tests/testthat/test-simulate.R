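test_that("intercept calibration reproduces the target reference means", {
  for (Em1 in c(65, 80)) {
    p <- true_params_dementia(Em1)
    expect_close(wb_mean(p$inc$beta[1], p$inc$kappa), 95, 1e-10)
    expect_close(wb_mean(p$mort0$beta[1], p$mort0$kappa), 85, 1e-10)
    expect_close(wb_mean(p$mort1$beta[1], p$mort1$kappa), Em1, 1e-10)
  }
})

test_that("scenario catalogue and validation behave", {
  cat_ <- scenario_catalogue()
  expect_length(cat_, 12)
  expect_setequal(names(cat_)[1:3], c("E65_L", "E65_M", "E65_S"))
  expect_equal(cat_$L80_S$n_initial, 500L)
  expect_equal(cat_$L65_M$censor, c(95, 105))
  expect_error(idm_scenario("bad", 100, censor = c(40, 50)),
               "censoring bounds")
  expect_error(idm_scenario("bad", 0), "positive")
})

test_that("latent draws match their configured laws", {
  sc <- idm_scenario("big", 1e5, sex_prob = 0.4)
  set.seed(21)
  lat <- draw_latent(1e5, sc)
  # sex prevalence within 3 binomial sigmas
  expect_close(mean(lat$sex), 0.4, 3 * sqrt(0.4 * 0.6 / 1e5))
  # random-effect variances near their targets
  expect_close(var(lat$u_i), 0.008237, 3e-4)
  expect_close(cov(lat$u_i, lat$u_m1), 0.000115, 1e-4)
  expect_close(cov(lat$u_i, lat$u_m0), 0, 1e-4)
  # onset-age mean for the reference profile: the random effect multiplies
  # the scale by exp(u), so the marginal mean is 95 * E[exp(u_i)]
  ref <- lat$sex == 0
  target <- 95 * exp(0.008237 / 2)
  se <- sd(lat$t1[ref]) / sqrt(sum(ref))
  expect_close(mean(lat$t1[ref]), target, 3 * se)
  # zero-variance scenario produces identically zero effects
  p0 <- true_params_dementia(65)
  p0$re <- re_hetvar(0, 0, 0)
  sc0 <- idm_scenario("zero", 100, true_params = p0)
  lat0 <- draw_latent(100, sc0)
  expect_true(all(lat0[, c("u_i", "u_m0", "u_m1")] == 0))
})

test_that("post-diagnosis death ages follow the truncated conditional law", {
  p <- true_params_dementia(65)
  sc1 <- exp(p$mort1$beta[1])
  kap <- p$mort1$kappa
  expect_close(draw_death_after_diagnosis(70, sc1, kap, U = 1e-12), 70,
               1e-6)
  # exponential inversion special case
  expect_close(draw_death_after_diagnosis(1e-12, 10, 1, U = 0.5),
               -10 * log(0.5), 1e-6)
  set.seed(31)
  t1 <- 75
  t2 <- draw_death_after_diagnosis(rep(t1, 1e5), sc1, kap)
  expect_true(all(t2 > t1))
  # KS distance against S(t)/S(t1)
  cdf <- function(t) 1 - wb_surv_cond(t, t1, sc1, kap)
  emp <- ecdf(t2)
  grid <- quantile(t2, seq(0.001, 0.999, length.out = 500))
  expect_lt(max(abs(emp(grid) - cdf(grid))), 0.01)
})

test_that("observation process enforces truncation and interval geometry", {
  sim <- simulate_idm(idm_scenario("E65_L", 2400), seed = 2)
  d <- sim$data; tr <- sim$truth
  # left truncation: every retained subject entered before both event ages
  expect_true(all(tr$entry < pmin(tr$t1, tr$t2)))
  expect_true(all(d$entry_age == tr$entry))
  # diagnosed subjects bracket the true onset
  d1 <- d$delta1 == 1
  expect_true(all(d$t_left[d1] <= tr$t1[d1]))
  expect_true(all(tr$t1[d1] <= d$t_right[d1]))
  expect_true(all(d$t_left[d1] >= d$entry_age[d1]))
  # diagnosis requires onset before death and censoring
  expect_true(all(tr$t1[d1] < pmin(tr$t2, tr$censor)[d1]))
  expect_true(all(!d1 | tr$diseased))
  # undiagnosed normalisation
  expect_true(all(d$t_left[!d1] == d$last_age[!d1]))
  expect_true(all(is.infinite(d$t_right[!d1])))
  # death indicator
  expect_equal(d$delta2, as.integer(tr$t2 < tr$censor))
  expect_equal(d$last_age, pmin(tr$t2, tr$censor))
  # all four cases occur
  expect_true(all(sim$case_counts > 0))
})

test_that("generation is seed-reproducible, bitwise on serialised text", {
  s1 <- simulate_idm(idm_scenario("E65_S", 500), seed = 77)
  s2 <- simulate_idm(idm_scenario("E65_S", 500), seed = 77)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_idm_data(s1$data, f1); write_idm_data(s2$data, f2)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- simulate_idm(idm_scenario("E65_S", 500), seed = 78)
  expect_false(identical(s1$data$last_age, s3$data$last_age))
})

test_that("late censoring strictly reduces the censored fraction", {
  early <- simulate_idm(idm_scenario("E65_L", 2400, censor = c(85, 95)),
                        seed = 12)
  late <- simulate_idm(idm_scenario("L65_L", 2400, censor = c(95, 105)),
                       seed = 12)
  expect_lt(mean(late$data$delta2 == 0), mean(early$data$delta2 == 0))
})
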