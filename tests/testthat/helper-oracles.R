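# Shared fixtures and independent oracles used across the test files.

# A small, fully in-code dataset covering all four likelihood cases.
tiny_cohort <- function() {
  idm_data(data.frame(
    entry_age = c(57, 58, 56, 59),
    t_left    = c(70, 75, NA, NA),
    t_right   = c(74, 78, NA, NA),
    t_mid     = c(72, 76.5, NA, NA),
    last_age  = c(80, 88, 83, 90),
    delta1    = c(1, 1, 0, 0),
    delta2    = c(1, 0, 1, 0),
    sex       = c(1, 0, 1, 0)))
}

# Simple parameter bundles for likelihood tests.
flat_params <- function(re = re_none()) {
  idm_params(
    inc   = transition_params(c(log(90), 0.05), 6, "i"),
    mort0 = transition_params(c(log(85), -0.04), 9, "m0"),
    mort1 = transition_params(c(log(75), -0.08), 7, "m1"),
    re = re)
}

# Monte-Carlo oracle for the marginal log-likelihood: per subject, average
# exp(conditional log contribution) over normal draws of the random-effect
# vector. Returns the MC log-likelihood and its standard error (delta
# method on each subject's log-mean, combined across subjects).
mc_loglik <- function(data, params, n_draws = 1e5, seed = 1) {
  set.seed(seed)
  re <- params$re
  sig <- switch(re$structure,
    none = matrix(0, 3, 3),
    homvar = matrix(re$s2, 3, 3),
    hetvar = idmaft:::re_cov_matrix(re$s2_i, re$s2_m0, re$s2_m1,
                                    re$c_i_m1, re$c_m0_m1))
  es <- eigen(sig, symmetric = TRUE)
  A <- es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
  ll <- se2 <- numeric(nrow(data))
  for (j in seq_len(nrow(data))) {
    u <- matrix(rnorm(3 * n_draws), n_draws, 3) %*% t(A)
    dj <- data[rep(j, n_draws), , drop = FALSE]
    class(dj) <- c("idm_data", "data.frame")
    lc <- log_contribution(dj, params, u)
    m <- max(lc)
    vals <- exp(lc - m)
    mu <- mean(vals)
    ll[j] <- m + log(mu)
    se2[j] <- (sd(vals) / sqrt(n_draws) / mu)^2
  }
  list(loglik = sum(ll), se = sqrt(sum(se2)))
}

# Deterministic replicate seed used by run_replicate (kept in sync with the
# implementation contract: base_seed + 7919 * replicate).
expect_close <- function(x, y, tol) expect_lt(abs(x - y), tol)
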