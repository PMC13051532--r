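test_that("subjects are classified into the four observed-data cases", {
  d <- tiny_cohort()
  expect_equal(as.character(case_of(d)), c("I", "II", "III", "IV"))
})

test_that("dataset validation catches malformed records", {
  df <- as.data.frame(tiny_cohort())
  bad <- df; bad$last_age[3] <- bad$entry_age[3]
  expect_error(idm_data(bad), "last_age")
  bad <- df; bad$delta1[1] <- 2
  expect_error(idm_data(bad), "delta1")
  bad <- df; bad$t_right[1] <- bad$t_left[1]
  expect_error(idm_data(bad), "t_left < t_right")
  # left bound before entry is clamped, not rejected
  cl <- df; cl$t_left[1] <- cl$entry_age[1] - 5
  cl$t_mid[1] <- (cl$t_left[1] + cl$t_right[1]) / 2
  expect_warning(out <- idm_data(cl), "clamped")
  expect_equal(out$t_left[1], out$entry_age[1])
})

test_that("closed-form exponential case III contribution is reproduced", {
  # kappa = 1, all beta = 0 (scale 1), L = 1, Y2 = 2: the contribution is
  # S_i(2) f_m0(2) / (S_i(1) S_m0(1)) = e^{-2} e^{-2} / (e^{-1} e^{-1})
  d <- idm_data(data.frame(entry_age = 1, t_left = NA, t_right = NA,
                           t_mid = NA, last_age = 2, delta1 = 0,
                           delta2 = 1, sex = 0))
  p <- idm_params(transition_params(c(0, 0), 1), transition_params(c(0, 0), 1),
                  transition_params(c(0, 0), 1))
  expect_close(log_contribution(d, p), -2, 1e-12)
})

test_that("case I contribution equals the product of its six factors", {
  set.seed(11)
  for (i in 1:20) {
    l <- runif(1, 50, 60)
    tl <- l + runif(1, 2, 20); tr <- tl + runif(1, 0.5, 6)
    y2 <- tr + runif(1, 0.5, 15)
    tm <- (tl + tr) / 2
    x1 <- rbinom(1, 1, 0.5)
    d <- idm_data(data.frame(entry_age = l, t_left = tl, t_right = tr,
                             t_mid = tm, last_age = y2, delta1 = 1,
                             delta2 = 1, sex = x1))
    p <- flat_params()
    u <- rnorm(3, sd = 0.2)
    sc <- function(tp, uu) aft_scale(c(1, x1), tp, uu)
    si <- sc(p$inc, u[1]); s0 <- sc(p$mort0, u[2]); s1 <- sc(p$mort1, u[3])
    manual <- log(wb_surv(tl, si, p$inc$kappa) - wb_surv(tr, si, p$inc$kappa)) +
      wb_logsurv(tr, s0, p$mort0$kappa) +
      wb_logdens(y2, s1, p$mort1$kappa) -
      wb_logsurv(l, si, p$inc$kappa) -
      wb_logsurv(l, s0, p$mort0$kappa) -
      wb_logsurv(min(tm, y2), s1, p$mort1$kappa)
    expect_close(log_contribution(d, p, u), manual, 1e-12)
  }
})

test_that("left truncation only divides by the entry survival", {
  set.seed(5)
  for (i in 1:10) {
    d <- tiny_cohort()
    p <- flat_params()
    u <- rnorm(3, sd = 0.1)
    with_l <- log_contribution(d, p, u)
    d0 <- as.data.frame(d); d0$entry_age <- 0
    # keep undiagnosed rows' t_left consistent and below t_right
    d0 <- idm_data(d0)
    without_l <- log_contribution(d0, p, u)
    X <- cbind(1, d$sex)
    for (j in 3:4) {  # cases III and IV: correction is S_i(L) S_m0(L)
      corr <- wb_logsurv(d$entry_age[j], aft_scale(X[j, ], p$inc, u[1]),
                         p$inc$kappa) +
              wb_logsurv(d$entry_age[j], aft_scale(X[j, ], p$mort0, u[2]),
                         p$mort0$kappa)
      expect_close(with_l[j], without_l[j] - corr, 1e-10)
    }
  }
})

test_that("vanishing diagnosis interval recovers the exact-onset density", {
  p <- flat_params()
  t1 <- 72; l <- 57; y2 <- 80
  lc_h <- function(h) {
    d <- idm_data(data.frame(entry_age = l, t_left = t1 - h,
                             t_right = t1 + h, t_mid = t1, last_age = y2,
                             delta1 = 1, delta2 = 1, sex = 0))
    log_contribution(d, p) - log(2 * h)
  }
  # the exact-onset log density form: f_i(t1) S_m0(t1) f_m1(y2) /
  # (S_i(l) S_m0(l) S_m1(t1)) -- interval bounds collapse onto t1
  si <- exp(p$inc$beta[1]); s0 <- exp(p$mort0$beta[1])
  s1 <- exp(p$mort1$beta[1])
  exact <- wb_logdens(t1, si, p$inc$kappa) +
    wb_logsurv(t1, s0, p$mort0$kappa) + wb_logdens(y2, s1, p$mort1$kappa) -
    wb_logsurv(l, si, p$inc$kappa) - wb_logsurv(l, s0, p$mort0$kappa) -
    wb_logsurv(t1, s1, p$mort1$kappa)
  errs <- abs(vapply(c(0.5, 0.05, 0.005), lc_h, numeric(1)) - exact)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
})

test_that("quadrature grids have the stated degenerate and exact forms", {
  g0 <- quadrature_grid(re_homvar(0), 2)
  expect_true(all(g0$nodes == 0))
  expect_equal(sum(g0$weights), 1)
  g1 <- quadrature_grid(re_homvar(1), 2)
  expect_equal(sort(g1$nodes[, 1]), c(-1, 1))
  expect_equal(g1$weights, c(0.5, 0.5))
  expect_equal(g1$nodes[, 1], g1$nodes[, 3])  # shared scalar effect

  # 3-D diagonal grid integrates a quadratic exactly
  re <- re_hetvar(0.4, 0.9, 0.25)
  g <- quadrature_grid(re, 2)
  f <- function(u) 2 + 3 * u[1] - u[2] + 0.5 * u[3] + u[1]^2 + 2 * u[2]^2 +
    u[3]^2
  val <- sum(g$weights * apply(g$nodes, 1, f))
  expect_close(val, 2 + 0.4 + 2 * 0.9 + 0.25, 1e-10)
  expect_error(quadrature_grid(re_hetvar(0.01, 0.01, 0.01, c_i_m1 = 0.5)),
               "positive semi-definite")
})

test_that("marginal likelihood reduces, adds and permutes as it must", {
  sim <- simulate_idm(idm_scenario("tiny", 400), seed = 3)
  p <- true_params_dementia(65)
  p_none <- p; p_none$re <- re_none()
  p_zero <- p; p_zero$re <- re_homvar(0)
  ll_none <- as.numeric(marginal_loglik(sim$data, p_none))
  ll_zero <- as.numeric(marginal_loglik(sim$data, p_zero, n_points = 4))
  expect_close(ll_none, ll_zero, 1e-10)

  p_h <- p; p_h$re <- re_homvar(0.01)
  ll <- as.numeric(marginal_loglik(sim$data, p_h))
  dup <- idm_data(rbind(as.data.frame(sim$data), as.data.frame(sim$data)))
  expect_close(as.numeric(marginal_loglik(dup, p_h)), 2 * ll, 1e-8)

  perm <- idm_data(as.data.frame(sim$data)[sample(nrow(sim$data)), ])
  expect_close(as.numeric(marginal_loglik(perm, p_h)), ll, 1e-8)
})

test_that("R and compiled likelihood backends agree", {
  sim <- simulate_idm(idm_scenario("tiny", 300), seed = 8)
  for (re in list(re_none(), re_homvar(0.02),
                  re_hetvar(0.01, 0.005, 0.002, 1e-4, 5e-4))) {
    p <- true_params_dementia(65); p$re <- re
    lr <- as.numeric(marginal_loglik(sim$data, p, n_points = 3,
                                     backend = "r"))
    lc <- as.numeric(marginal_loglik(sim$data, p, n_points = 3,
                                     backend = "cpp"))
    expect_close(lr, lc, 1e-8)
  }
})

test_that("quadrature refinement converges", {
  sim <- simulate_idm(idm_scenario("tiny", 200), seed = 4)
  p <- true_params_dementia(65)
  p$re <- re_hetvar(0.02, 0.01, 0.005, 1e-4, 0)
  ll <- vapply(c(2, 8, 16), function(q)
    as.numeric(marginal_loglik(sim$data, p, n_points = q)), numeric(1))
  expect_lt(abs(ll[3] - ll[2]), abs(ll[2] - ll[1]) + 1e-10)
  expect_lt(abs(ll[3] - ll[2]), 0.05)
})
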