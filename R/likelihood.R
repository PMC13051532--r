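# Marginal likelihood of the trivariate Weibull AFT illness-death model.
#
# Conditional on the random-effect vector u = (u_i, u_m0, u_m1), each subject
# contributes one of four terms depending on (delta1, delta2); the marginal
# likelihood integrates the product over u by non-adaptive Gauss-Hermite
# quadrature. All contributions are evaluated on the log scale and the
# quadrature mixture via log-sum-exp, because survival products at ages
# 55-105 underflow in double precision.

#' Random-effect specification
#'
#' Three structures are supported: `re_none()` (no random effects),
#' `re_homvar(s2)` (one shared scalar effect with variance `s2` added to all
#' three linear predictors), and `re_hetvar()` (a trivariate normal effect
#' with transition-specific variances, a covariance between disease onset and
#' post-diagnosis death, and a covariance between the two mortalities; the
#' incidence/death-without-disease covariance is fixed at zero).
#'
#' @param s2 Shared random-effect variance (homvar).
#' @param s2_i,s2_m0,s2_m1 Transition-specific variances (hetvar).
#' @param c_i_m1 Covariance between the incidence and post-diagnosis
#'   mortality effects.
#' @param c_m0_m1 Covariance between the two mortality effects.
#' @return An object of class `"idm_re"`.
#' @export
#' @examples
#' re_homvar(0.01)
#' re_hetvar(0.008237, 0.000714, 0.000063, c_i_m1 = 0.000115)
re_none <- function() {
  structure(list(structure = "none"), class = "idm_re")
}

#' @rdname re_none
#' @export
re_homvar <- function(s2) {
  if (!is.numeric(s2) || length(s2) != 1L || s2 < 0)
    stop("'s2' must be a single non-negative number")
  structure(list(structure = "homvar", s2 = as.numeric(s2)),
            class = "idm_re")
}

#' @rdname re_none
#' @export
re_hetvar <- function(s2_i, s2_m0, s2_m1, c_i_m1 = 0, c_m0_m1 = 0) {
  v <- c(s2_i = s2_i, s2_m0 = s2_m0, s2_m1 = s2_m1)
  if (any(v < 0)) stop("variances must be non-negative")
  sig <- re_cov_matrix(s2_i, s2_m0, s2_m1, c_i_m1, c_m0_m1)
  if (min(eigen(sig, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("random-effect covariance matrix is not positive semi-definite")
  structure(list(structure = "hetvar", s2_i = s2_i, s2_m0 = s2_m0,
                 s2_m1 = s2_m1, c_i_m1 = c_i_m1, c_m0_m1 = c_m0_m1),
            class = "idm_re")
}

re_cov_matrix <- function(s2_i, s2_m0, s2_m1, c_i_m1, c_m0_m1) {
  matrix(c(s2_i,   0,      c_i_m1,
           0,      s2_m0,  c_m0_m1,
           c_i_m1, c_m0_m1, s2_m1), 3L, 3L, byrow = TRUE)
}

#' Full model parameter bundle
#'
#' Collects the three transition submodels and the random-effect
#' specification into the complete parameter vector of the illness-death
#' model.
#'
#' @param inc,mort0,mort1 [transition_params()] objects for the incidence,
#'   death-without-disease and death-after-diagnosis transitions. Their
#'   coefficient vectors must have equal length (same covariate design).
#' @param re An [re_none()]/[re_homvar()]/[re_hetvar()] object.
#' @return An object of class `"idm_params"`.
#' @export
idm_params <- function(inc, mort0, mort1, re = re_none()) {
  stopifnot(inherits(inc, "transition_params"),
            inherits(mort0, "transition_params"),
            inherits(mort1, "transition_params"),
            inherits(re, "idm_re"))
  if (length(unique(c(length(inc$beta), length(mort0$beta),
                      length(mort1$beta)))) != 1L)
    stop("the three beta vectors must have equal length")
  structure(list(inc = inc, mort0 = mort0, mort1 = mort1, re = re),
            class = "idm_params")
}

beta_matrix <- function(params) {
  cbind(i = params$inc$beta, m0 = params$mort0$beta, m1 = params$mort1$beta)
}

kappa_vector <- function(params) {
  c(i = params$inc$kappa, m0 = params$mort0$kappa, m1 = params$mort1$kappa)
}

#' Gauss-Hermite quadrature grid for the random effects
#'
#' Builds the node/weight set used to integrate the conditional likelihood
#' over the random-effect distribution. Standard (probabilists')
#' Gauss-Hermite abscissas are transformed to the target normal by a
#' symmetric eigenvalue square root of the covariance matrix, so degenerate
#' variances collapse nodes gracefully. Weights sum to one.
#'
#' @param re An `idm_re` specification.
#' @param n_points Nodes per dimension (default 2, the estimation default).
#' @return A list with `nodes` (Q x 3 matrix of random-effect values, columns
#'   i, m0, m1) and `weights` (length Q, summing to 1).
#' @export
#' @examples
#' quadrature_grid(re_homvar(1), n_points = 2)  # nodes +/- 1, weights 1/2
quadrature_grid <- function(re, n_points = 2L) {
  stopifnot(inherits(re, "idm_re"))
  n_points <- as.integer(n_points)
  if (n_points < 1L) stop("'n_points' must be >= 1")
  gh <- gh_probabilist(n_points)
  switch(re$structure,
    none = list(nodes = matrix(0, 1L, 3L,
                               dimnames = list(NULL, c("i", "m0", "m1"))),
                weights = 1),
    homvar = {
      z <- gh$nodes * sqrt(re$s2)
      list(nodes = matrix(z, n_points, 3L,
                          dimnames = list(NULL, c("i", "m0", "m1"))),
           weights = gh$weights)
    },
    hetvar = {
      sig <- re_cov_matrix(re$s2_i, re$s2_m0, re$s2_m1,
                           re$c_i_m1, re$c_m0_m1)
      es <- eigen(sig, symmetric = TRUE)
      if (min(es$values) < -1e-10)
        stop("random-effect covariance matrix is not positive semi-definite")
      A <- es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
      g <- expand.grid(z1 = gh$nodes, z2 = gh$nodes, z3 = gh$nodes)
      w <- expand.grid(w1 = gh$weights, w2 = gh$weights, w3 = gh$weights)
      nodes <- as.matrix(g) %*% t(A)
      colnames(nodes) <- c("i", "m0", "m1")
      list(nodes = nodes, weights = w$w1 * w$w2 * w$w3)
    })
}

# probabilists' Gauss-Hermite rule: integrates f against the standard normal
gh_probabilist <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = 1))
  gh <- pracma::gaussHermite(n)
  list(nodes = gh$x * sqrt(2), weights = gh$w / sqrt(pi))
}

#' Log likelihood contribution conditional on the random effects
#'
#' Reference (pure R, vectorised over subjects) evaluation of the per-subject
#' log contribution given a random-effect value. The four cases are:
#' \describe{
#'   \item{I (diagnosed, died)}{`log(S_i(Tl) - S_i(Tr)) + log S_m0(Tr) +
#'     log f_m1(Y2) - log S_i(L) - log S_m0(L) - log S_m1(Tm)`}
#'   \item{II (diagnosed, censored)}{as I with `log S_m1(Y2)` in place of
#'     the death density}
#'   \item{III (undiagnosed, died)}{`log S_i(Y2) + log f_m0(Y2) -
#'     log S_i(L) - log S_m0(L)`}
#'   \item{IV (undiagnosed, censored)}{`log S_i(Y2) + log S_m0(Y2) -
#'     log S_i(L) - log S_m0(L)`}
#' }
#' The post-diagnosis submodel is left-truncated at the interval midpoint
#' `Tm` by default (`tm_trunc = "midpoint"`), or at the right bound
#' (`tm_trunc = "right"`); in either case the truncation age is capped at
#' the last observed age `Y2` (a death-age distribution cannot be truncated
#' beyond the observed death, and without the cap the marginal likelihood
#' is unbounded in the post-diagnosis shape and variance).
#'
#' @param data An [idm_data()] object.
#' @param params An [idm_params()] object.
#' @param u Random-effect values: a length-3 vector `(u_i, u_m0, u_m1)`
#'   applied to all subjects, or an `n x 3` matrix of subject-specific
#'   values.
#' @param tm_trunc Truncation point of the post-diagnosis death age:
#'   interval midpoint (default) or right bound.
#' @return Numeric vector of per-subject log contributions. Subjects whose
#'   diagnosis interval is numerically empty under `params` get `-Inf` with
#'   a warning.
#' @export
log_contribution <- function(data, params, u = c(0, 0, 0),
                             tm_trunc = c("midpoint", "right")) {
  tm_trunc <- match.arg(tm_trunc)
  stopifnot(inherits(params, "idm_params"))
  X <- covariate_design(data, params)
  if (is.matrix(u)) {
    stopifnot(nrow(u) == nrow(data), ncol(u) == 3L)
  } else {
    stopifnot(length(u) == 3L)
    u <- matrix(u, nrow(data), 3L, byrow = TRUE)
  }
  B <- beta_matrix(params)
  kap <- kappa_vector(params)
  lp <- X %*% B + u                       # n x 3 log-scales
  klogt <- function(t, p) exp(kap[p] * (log(t) - lp[, p]))  # (t/eta)^kappa
  logS <- function(t, p) {
    out <- -klogt(t, p)
    out[t == 0] <- 0
    out
  }
  logf <- function(t, p)
    log(kap[p]) - lp[, p] + (kap[p] - 1) * (log(t) - lp[, p]) + logS(t, p)

  L <- data$entry_age; Y2 <- data$last_age
  d1 <- data$delta1 == 1; d2 <- data$delta2 == 1
  trunc1 <- if (tm_trunc == "midpoint") data$t_mid else data$t_right
  trunc1 <- pmin(trunc1, Y2)  # truncation cannot pass the observed death age

  out <- numeric(nrow(data))
  # shared truncation correction (healthy and alive at entry)
  out <- out - logS(L, 1L) - logS(L, 2L)
  # undiagnosed: survival of onset to Y2, death density or survival at Y2
  nd <- !d1
  if (any(nd)) {
    out[nd] <- out[nd] + logS(Y2, 1L)[nd] +
      ifelse(d2[nd], logf(Y2, 2L)[nd], logS(Y2, 2L)[nd])
  }
  if (any(d1)) {
    sl <- logS(data$t_left, 1L)
    sr <- logS(data$t_right, 1L)
    # log(S(Tl) - S(Tr)) = sl + log(1 - exp(sr - sl))
    dlt <- sr - sl
    int <- ifelse(dlt < 0, sl + log1p(-exp(dlt)), -Inf)
    if (any(d1 & !is.finite(int))) {
      warning("numerically empty diagnosis interval(s); contribution -Inf")
    }
    out[d1] <- out[d1] + int[d1] + logS(data$t_right, 2L)[d1] -
      logS(trunc1, 3L)[d1] +
      ifelse(d2[d1], logf(Y2, 3L)[d1], logS(Y2, 3L)[d1])
  }
  as.numeric(out)
}

# Build the n x d design matrix whose columns match the beta vectors,
# using the stored covariate order (intercept first).
covariate_design <- function(data, params) {
  d <- length(params$inc$beta)
  covs <- idm_covariates(data)
  if (d - 1L > length(covs))
    stop("model has more covariates than the data provide")
  X <- cbind(1, as.matrix(as.data.frame(data)[, covs[seq_len(d - 1L)],
                                              drop = FALSE]))
  storage.mode(X) <- "double"
  X
}

#' Marginal log-likelihood of the illness-death model
#'
#' Sum over subjects of the log of the Gauss-Hermite weighted mixture of the
#' conditional contributions, stabilised by log-sum-exp. With
#' `re_none()` (or zero variance) this reduces to the closed-form
#' no-random-effects log-likelihood.
#'
#' @inheritParams log_contribution
#' @param n_points Quadrature nodes per random-effect dimension.
#' @param backend `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation); both give identical results.
#' @return The marginal log-likelihood (scalar) with attribute
#'   `"by_subject"` holding per-subject terms. Subjects contributing
#'   `-Inf` at every node yield `-Inf`; their indices are reported in a
#'   warning.
#' @export
marginal_loglik <- function(data, params, n_points = 2L,
                            tm_trunc = c("midpoint", "right"),
                            backend = c("cpp", "r")) {
  tm_trunc <- match.arg(tm_trunc)
  backend <- match.arg(backend)
  if (nrow(data) == 0L) stop("empty dataset")
  grid <- quadrature_grid(params$re, n_points)
  per <- if (backend == "cpp") {
    X <- covariate_design(data, params)
    trunc1 <- if (tm_trunc == "midpoint") data$t_mid else data$t_right
    trunc1 <- pmin(trunc1, data$last_age)
    trunc1[data$delta1 == 0] <- 0
    tr <- data$t_right
    tr[data$delta1 == 0] <- 0
    idm_loglik_cpp(data$entry_age, data$t_left, tr, trunc1, data$last_age,
                   as.integer(data$delta1), as.integer(data$delta2),
                   X, beta_matrix(params), kappa_vector(params),
                   grid$nodes, grid$weights)
  } else {
    mat <- vapply(seq_along(grid$weights), function(q)
      log_contribution(data, params, grid$nodes[q, ], tm_trunc = tm_trunc),
      numeric(nrow(data)))
    mat <- matrix(mat, nrow = nrow(data))
    lw <- matrix(log(grid$weights), nrow(data), length(grid$weights),
                 byrow = TRUE)
    apply(mat + lw, 1L, logsumexp)
  }
  bad <- which(!is.finite(per))
  if (length(bad))
    warning("subjects with non-finite likelihood contribution: ",
            paste(utils::head(bad, 10L), collapse = ", "))
  structure(sum(per), by_subject = per)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
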