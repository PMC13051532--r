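# Maximum likelihood estimation of the trivariate illness-death AFT model.
#
# Free parameters are optimised on an unconstrained scale: regression
# coefficients natural, Weibull shapes log, random-effect variances log,
# covariances as atanh-correlations (positive semi-definiteness by
# construction). Estimates and delta-method standard errors are reported on
# the natural scale.

theta_layout <- function(d, structure, covnames) {
  bn <- unlist(lapply(c("i", "m0", "m1"),
                      function(p) paste0("beta_", p, ".", covnames)))
  kn <- paste0("log_kappa_", c("i", "m0", "m1"))
  re <- switch(structure,
               none = character(0),
               homvar = "log_s2",
               hetvar = c("log_s2_i", "log_s2_m0", "log_s2_m1",
                          "z_i_m1", "z_m0_m1"))
  c(bn, kn, re)
}

natural_names <- function(d, structure, covnames) {
  bn <- unlist(lapply(c("i", "m0", "m1"),
                      function(p) paste0("beta_", p, ".", covnames)))
  kn <- paste0("kappa_", c("i", "m0", "m1"))
  re <- switch(structure,
               none = character(0),
               homvar = "s2",
               hetvar = c("s2_i", "s2_m0", "s2_m1", "c_i_m1", "c_m0_m1"))
  c(bn, kn, re)
}

pack_theta <- function(params, structure) {
  b <- as.numeric(beta_matrix(params))
  lk <- log(kappa_vector(params))
  re <- params$re
  tail <- switch(structure,
    none = numeric(0),
    homvar = log(max(re$s2, 1e-12)),
    hetvar = {
      v <- pmax(c(re$s2_i, re$s2_m0, re$s2_m1), 1e-12)
      r13 <- re$c_i_m1 / sqrt(v[1] * v[3])
      r23 <- re$c_m0_m1 / sqrt(v[2] * v[3])
      c(log(v), atanh(pmin(pmax(r13, -0.99), 0.99)),
        atanh(pmin(pmax(r23, -0.99), 0.99)))
    })
  c(b, lk, tail)
}

unpack_theta <- function(theta, d, structure, covnames = NULL) {
  if (is.null(covnames)) covnames <- paste0("x", seq_len(d) - 1L)
  B <- matrix(theta[seq_len(3 * d)], d, 3L)
  kap <- exp(theta[3 * d + 1:3])
  re <- switch(structure,
    none = re_none(),
    homvar = re_homvar(exp(theta[3 * d + 4])),
    hetvar = {
      v <- exp(theta[3 * d + 4:6])
      r13 <- tanh(theta[3 * d + 7])
      r23 <- tanh(theta[3 * d + 8])
      ss <- r13^2 + r23^2   # PSD of the correlation matrix needs ss <= 1
      if (ss > 0.995) {
        f <- sqrt(0.995 / ss); r13 <- r13 * f; r23 <- r23 * f
      }
      re_hetvar(v[1], v[2], v[3],
                c_i_m1 = r13 * sqrt(v[1] * v[3]),
                c_m0_m1 = r23 * sqrt(v[2] * v[3]))
    })
  idm_params(
    inc   = transition_params(setNames(B[, 1], covnames), kap[1], "i"),
    mort0 = transition_params(setNames(B[, 2], covnames), kap[2], "m0"),
    mort1 = transition_params(setNames(B[, 3], covnames), kap[3], "m1"),
    re = re)
}

natural_from_theta <- function(theta, d, structure) {
  b <- theta[seq_len(3 * d)]
  kap <- exp(theta[3 * d + 1:3])
  tail <- switch(structure,
    none = numeric(0),
    homvar = exp(theta[3 * d + 4]),
    hetvar = {
      v <- exp(theta[3 * d + 4:6])
      r13 <- tanh(theta[3 * d + 7]); r23 <- tanh(theta[3 * d + 8])
      c(v, r13 * sqrt(v[1] * v[3]), r23 * sqrt(v[2] * v[3]))
    })
  c(b, kap, tail)
}

theta_bounds <- function(d, structure) {
  lower <- c(rep(-Inf, 3 * d), rep(log(0.05), 3))
  upper <- c(rep(Inf, 3 * d), rep(log(200), 3))
  if (structure == "homvar") {
    lower <- c(lower, log(1e-12)); upper <- c(upper, log(4))
  } else if (structure == "hetvar") {
    lower <- c(lower, rep(log(1e-12), 3), rep(-6, 2))
    upper <- c(upper, rep(log(4), 3), rep(6, 2))
  }
  list(lower = lower, upper = upper)
}

# Negative marginal log-likelihood over the packed parameter vector.
# The quadrature skeleton (standard-normal node grid and weights) is built
# once; each evaluation only rescales it by the current covariance square
# root and calls the compiled kernel, keeping the optimiser's many
# evaluations cheap.
make_negloglik <- function(data, X, structure, n_points, tm_trunc) {
  d <- ncol(X)
  L <- data$entry_age
  tl <- data$t_left
  tr <- data$t_right; tr[data$delta1 == 0] <- 0
  y2 <- data$last_age
  tm <- pmin(if (tm_trunc == "midpoint") data$t_mid else data$t_right, y2)
  tm[data$delta1 == 0] <- 0   # truncation capped at the observed death age
  d1 <- as.integer(data$delta1); d2 <- as.integer(data$delta2)
  gh <- gh_probabilist(n_points)
  if (structure == "hetvar") {
    Zg <- as.matrix(expand.grid(gh$nodes, gh$nodes, gh$nodes,
                                KEEP.OUT.ATTRS = FALSE))
    dimnames(Zg) <- NULL
    wg <- as.numeric(outer(outer(gh$weights, gh$weights), gh$weights))
  }
  U0 <- matrix(0, 1L, 3L)
  ib <- seq_len(3 * d)
  function(theta) {
    B <- matrix(theta[ib], d, 3L)
    kap <- exp(theta[3 * d + 1:3])
    if (structure == "none") {
      U <- U0; w <- 1
    } else if (structure == "homvar") {
      U <- matrix(gh$nodes * sqrt(exp(theta[3 * d + 4])), n_points, 3L)
      w <- gh$weights
    } else {
      v <- exp(theta[3 * d + 4:6])
      r13 <- tanh(theta[3 * d + 7]); r23 <- tanh(theta[3 * d + 8])
      ss <- r13^2 + r23^2
      if (ss > 0.995) { f <- sqrt(0.995 / ss); r13 <- r13 * f; r23 <- r23 * f }
      sig <- re_cov_matrix(v[1], v[2], v[3],
                           r13 * sqrt(v[1] * v[3]), r23 * sqrt(v[2] * v[3]))
      es <- eigen(sig, symmetric = TRUE)
      A <- es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
      U <- Zg %*% A              # A symmetric
      w <- wg
    }
    per <- idm_loglik_cpp(L, tl, tr, tm, y2, d1, d2, X, B, kap, U, w)
    val <- -sum(per)
    if (!is.finite(val)) 1e10 else val
  }
}

#' Univariate warm-start fit for one transition
#'
#' Maximises the factor of the no-random-effects log-likelihood that
#' involves a single transition: the incidence factor is an interval- and
#' right-censored left-truncated Weibull likelihood; the
#' death-without-disease factor a right-censored left-truncated Weibull over
#' the pre-diagnosis exposure; the post-diagnosis factor a Weibull
#' left-truncated at the interval midpoint among diagnosed subjects. Used to
#' produce starting values for the trivariate fit.
#'
#' @param transition One of `"i"`, `"m0"`, `"m1"`.
#' @param data An [idm_data()] object.
#' @param X Design matrix (intercept first); defaults to intercept plus all
#'   covariate columns of `data`.
#' @param tm_trunc Truncation point for the `m1` factor.
#' @return A [transition_params()] object with the factor maximiser (or the
#'   moment-based initial values, with a warning, when the transition has no
#'   informative events).
#' @export
fit_univariate <- function(transition = c("i", "m0", "m1"), data, X = NULL,
                           tm_trunc = c("midpoint", "right")) {
  transition <- match.arg(transition)
  tm_trunc <- match.arg(tm_trunc)
  if (is.null(X)) {
    covs <- idm_covariates(data)
    X <- cbind(`(Intercept)` = 1,
               as.matrix(as.data.frame(data)[, covs, drop = FALSE]))
  }
  d <- ncol(X)
  d1 <- data$delta1 == 1; d2 <- data$delta2 == 1
  n_events <- switch(transition,
                     i = sum(d1), m0 = sum(!d1 & d2), m1 = sum(d1 & d2))
  # crude Weibull moment initialisation from the relevant observed ages:
  # sd(log T) = (pi/sqrt(6))/kappa and E[log T] = log(scale) - gamma/kappa
  tref <- switch(transition,
                 i = ifelse(d1, data$t_mid, data$last_age),
                 m0 = data$last_age,
                 m1 = data$last_age[d1])
  tref <- tref[tref > 0 & is.finite(tref)]
  k0 <- min(max(1.2825 / max(sd(log(tref)), 1e-3), 0.5), 30)
  b0 <- c(mean(log(tref)) + 0.5772 / k0, rep(0, d - 1L))
  start <- c(b0, log(k0))
  if (n_events == 0L) {
    warning(sprintf("transition '%s' has no informative events; returning moment-based initial values",
                    transition))
    return(transition_params(setNames(b0, colnames(X)), k0, transition))
  }

  L <- data$entry_age; y2 <- data$last_age
  tm <- pmin(if (tm_trunc == "midpoint") data$t_mid else data$t_right, y2)
  negll <- switch(transition,
    i = function(par) {
      lp <- as.numeric(X %*% par[seq_len(d)]); k <- exp(par[d + 1L])
      lS <- function(t) ifelse(t <= 0, 0, -exp(k * (log(t) - lp)))
      sl <- lS(data$t_left); sr <- lS(data$t_right)
      intv <- ifelse(d1, sl + log1p(-exp(pmin(sr - sl, -1e-300))), lS(y2))
      v <- -sum(intv - lS(L)); if (is.finite(v)) v else 1e10
    },
    m0 = function(par) {
      lp <- as.numeric(X %*% par[seq_len(d)]); k <- exp(par[d + 1L])
      lS <- function(t) ifelse(t <= 0, 0, -exp(k * (log(t) - lp)))
      lf <- function(t) log(k) - lp + (k - 1) * (log(t) - lp) + lS(t)
      term <- ifelse(d1, lS(data$t_right), ifelse(d2, lf(y2), lS(y2)))
      v <- -sum(term - lS(L)); if (is.finite(v)) v else 1e10
    },
    m1 = function(par) {
      lp <- as.numeric(X[d1, , drop = FALSE] %*% par[seq_len(d)])
      k <- exp(par[d + 1L])
      lS <- function(t) -exp(k * (log(t) - lp))
      lf <- function(t) log(k) - lp + (k - 1) * (log(t) - lp) + lS(t)
      term <- ifelse(d2[d1], lf(y2[d1]), lS(y2[d1]))
      v <- -sum(term - lS(tm[d1])); if (is.finite(v)) v else 1e10
    })
  opt <- nlminb(start, negll,
                lower = c(rep(-Inf, d), log(0.05)),
                upper = c(rep(Inf, d), log(200)),
                control = list(iter.max = 300))
  transition_params(setNames(opt$par[seq_len(d)], colnames(X)),
                    exp(opt$par[d + 1L]), transition)
}

#' Fit the trivariate Weibull AFT illness-death model
#'
#' Maximum likelihood estimation of the three linked AFT submodels with the
#' chosen random-effect structure, via non-adaptive Gauss-Hermite quadrature
#' and a quasi-Newton optimiser with box constraints. Warm starts come from
#' the three univariate transition fits plus a coarse grid search over
#' random-effect variance initial values (1e-6, 1e-4, 1e-2).
#'
#' @param formula One-sided formula naming the covariates, e.g. `~ sex`.
#' @param data An [idm_data()] object.
#' @param structure Random-effect structure: `"none"`, `"homvar"` (shared
#'   scalar effect) or `"hetvar"` (structured trivariate effect).
#' @param n_points Quadrature nodes per random-effect dimension (default 2).
#' @param se Compute the observed-information covariance matrix and
#'   delta-method standard errors (default `TRUE`).
#' @param start Optional [idm_params()] with starting values (overrides the
#'   warm-start procedure).
#' @param tm_trunc Truncation point of the post-diagnosis submodel.
#' @param control Passed to [stats::nlminb()]; iteration cap defaults to
#'   500.
#' @return An object of class `"idm_fit"`: natural-scale `estimate`, `se`,
#'   `vcov`, the fitted [idm_params()] in `params`, `loglik`, `aic`, `bic`,
#'   `n_subjects`, `n_free`, `converged`, and optimiser details in
#'   `optim_info`.
#' @export
#' @examples
#' sim <- simulate_idm(idm_scenario("demo", 500), seed = 1)
#' fit <- fit_idm(~ sex, sim$data, structure = "none", se = FALSE)
#' coef(fit)
fit_idm <- function(formula, data, structure = c("homvar", "none", "hetvar"),
                    n_points = 2L, se = TRUE, start = NULL,
                    tm_trunc = c("midpoint", "right"), control = list()) {
  structure <- match.arg(structure)
  tm_trunc <- match.arg(tm_trunc)
  stopifnot(inherits(data, "idm_data"))
  mf <- model.matrix(formula, as.data.frame(data))
  X <- mf
  d <- ncol(X)
  covnames <- colnames(X)
  # stop on relative function change < 1e-8 (the declared convergence
  # criterion); the iteration cap guards runaway crawls in flat directions
  ctrl <- utils::modifyList(list(iter.max = 500, eval.max = 10000,
                                 rel.tol = 1e-8), control)

  negll <- make_negloglik(data, X, structure, n_points, tm_trunc)

  parent_fit <- NULL
  if (is.null(start)) {
    # warm starts are staged through the nested structures
    # (univariate factors -> none -> homvar -> hetvar): each optimum starts
    # the next model inside its parameter space, which both speeds the
    # quasi-Newton iteration and guarantees the fitted log-likelihoods
    # respect the nesting order
    if (structure == "hetvar") {
      fh <- fit_idm(formula, data, structure = "homvar",
                    n_points = n_points, se = FALSE, tm_trunc = tm_trunc,
                    control = control)
      s0 <- max(fh$estimate[["s2"]], 1e-6)
      start_params <- fh$params
      start_params$re <- re_hetvar(s0, s0, s0)
      parent_fit <- fh
    } else if (structure == "homvar") {
      fn <- fit_idm(formula, data, structure = "none",
                    n_points = n_points, se = FALSE, tm_trunc = tm_trunc,
                    control = control)
      start_params <- fn$params
      start_params$re <- re_homvar(1e-6)
      parent_fit <- fn
    } else {
      uni <- lapply(c("i", "m0", "m1"), function(p)
        fit_univariate(p, data = data, X = X, tm_trunc = tm_trunc))
      start_params <- idm_params(uni[[1]], uni[[2]], uni[[3]], re_none())
    }
    theta0 <- pack_theta(start_params, structure)
    if (structure != "none") {
      # coarse grid search over random-effect variance initial values,
      # keeping the staged start as a candidate
      cand <- c(list(theta0), lapply(c(1e-6, 1e-4, 1e-2), function(v) {
        th <- theta0
        if (structure == "homvar") th[3 * d + 4] <- log(v)
        else th[3 * d + 4:6] <- log(v)
        th
      }))
      vals <- vapply(cand, negll, numeric(1))
      theta0 <- cand[[which.min(vals)]]
    }
  } else {
    stopifnot(inherits(start, "idm_params"))
    theta0 <- pack_theta(start, structure)
  }

  # deterministic re-initialisation if the likelihood is degenerate at start
  if (!is.finite(negll(theta0)) || negll(theta0) >= 1e10) {
    for (j in 1:5) {
      cand <- theta0 + 0.05 * j * rep_len(c(1, -1), length(theta0))
      if (negll(cand) < 1e10) { theta0 <- cand; break }
    }
  }

  bounds <- theta_bounds(d, structure)
  opt <- nlminb(theta0, negll, lower = bounds$lower, upper = bounds$upper,
                control = ctrl)
  converged <- opt$convergence == 0 && opt$iterations < ctrl$iter.max
  if (!converged) {
    # PORT can report false convergence in directions the likelihood is
    # flat in (e.g. a variance shrinking to zero); restart once and declare
    # convergence when the restart no longer improves the objective
    # (relative change < 1e-8).
    ctrl2 <- utils::modifyList(ctrl, list(iter.max = 100))
    opt2 <- nlminb(opt$par, negll, lower = bounds$lower,
                   upper = bounds$upper, control = ctrl2)
    improve <- opt$objective - opt2$objective
    if (opt2$objective <= opt$objective) opt <- opt2
    converged <- opt2$convergence == 0 ||
      (is.finite(improve) && abs(improve) < 1e-8 * max(1, abs(opt$objective)))
  }
  # nested-model coherence: if the staged parent (simpler) structure
  # attained a higher likelihood, the extra variance components belong on
  # the boundary -- adopt the parent solution with them at the lower bound
  if (!is.null(parent_fit) && parent_fit$loglik > -opt$objective) {
    pp <- parent_fit$params
    pp$re <- switch(structure, homvar = re_homvar(1e-12),
                    hetvar = re_hetvar(1e-12, 1e-12, 1e-12))
    thb <- pack_theta(pp, structure)
    if (negll(thb) < opt$objective) {
      opt$par <- thb
      opt$objective <- negll(thb)
    }
  }
  theta_hat <- opt$par
  loglik <- -opt$objective
  k_free <- length(theta_hat)
  n <- nrow(data)

  nat <- natural_from_theta(theta_hat, d, structure)
  names(nat) <- natural_names(d, structure, covnames)

  vc <- se_vec <- NULL
  se_flagged <- FALSE
  if (se) {
    H <- pracma::hessian(negll, theta_hat)
    Vtheta <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
    if (is.null(Vtheta)) {
      Vtheta <- MASS::ginv(H)
      se_flagged <- TRUE
    }
    J <- pracma::jacobian(function(th) natural_from_theta(th, d, structure),
                          theta_hat)
    vc <- J %*% Vtheta %*% t(J)
    dimnames(vc) <- list(names(nat), names(nat))
    dv <- diag(vc)
    se_vec <- ifelse(dv >= 0, sqrt(pmax(dv, 0)), NA_real_)
    names(se_vec) <- names(nat)
  }

  structure(list(
    call = match.call(), formula = formula, structure = structure,
    n_points = as.integer(n_points), tm_trunc = tm_trunc,
    params = unpack_theta(theta_hat, d, structure, covnames),
    theta = theta_hat, estimate = nat, se = se_vec, vcov = vc,
    loglik = loglik, aic = -2 * loglik + 2 * k_free,
    bic = -2 * loglik + log(n) * k_free,
    n_subjects = n, n_free = k_free, converged = converged,
    se_flagged = se_flagged, covnames = covnames,
    optim_info = list(optimizer = "nlminb (PORT)",
                      iterations = opt$iterations,
                      evaluations = opt$evaluations,
                      message = opt$message,
                      convergence = opt$convergence,
                      start = theta0)),
    class = "idm_fit")
}

#' @export
print.idm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Weibull AFT illness-death model (%s random effects)\n",
              x$structure))
  cat(sprintf("  n = %d subjects, %d free parameters, %d quadrature points/dim\n",
              x$n_subjects, x$n_free, x$n_points))
  cat(sprintf("  logLik = %.3f   AIC = %.1f   BIC = %.1f   converged: %s\n\n",
              x$loglik, x$aic, x$bic, x$converged))
  tab <- cbind(Estimate = x$estimate,
               `Std. Error` = if (is.null(x$se)) NA_real_ else x$se)
  print(round(tab, digits))
  invisible(x)
}

#' @export
coef.idm_fit <- function(object, ...) object$estimate

#' @export
vcov.idm_fit <- function(object, ...) object$vcov

#' @export
logLik.idm_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_free, nobs = object$n_subjects,
            class = "logLik")
}

#' Wald confidence interval
#'
#' @param estimate,se Point estimate(s) and standard error(s).
#' @param level Confidence level (default 0.95).
#' @return A matrix with columns `lower`, `upper`.
#' @export
#' @examples
#' wald_ci(0, 1)  # (-1.96, 1.96)
wald_ci <- function(estimate, se, level = 0.95) {
  if (any(se < 0, na.rm = TRUE)) stop("'se' must be non-negative")
  z <- qnorm(1 - (1 - level) / 2)
  cbind(lower = estimate - z * se, upper = estimate + z * se)
}
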