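#' @useDynLib idmaft, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median model.matrix nlminb qnorm quantile rbinom runif
#'   rnorm rweibull sd setNames terms var
#' @keywords internal
"_PACKAGE"

# Weibull convention used everywhere in this package:
#   S(t) = exp(-(t/eta)^kappa),  eta = exp(x'beta + u)  (the AFT scale),
#   kappa > 0 the shape.  Covariates act multiplicatively on the event age,
#   so exp(beta) is an acceleration factor and exp(-kappa * beta) the
#   corresponding proportional-hazards hazard ratio.

#' Transition parameters for one Weibull AFT submodel
#'
#' Bundles the regression coefficient vector and Weibull shape for one
#' transition of the illness-death model. The first element of `beta` is the
#' intercept; covariates enter on the log-age scale so that `exp(beta)` is an
#' acceleration factor.
#'
#' @param beta Numeric vector of regression coefficients, intercept first.
#' @param kappa Positive Weibull shape parameter.
#' @param label Transition label, one of `"i"` (incidence), `"m0"` (death
#'   without disease), `"m1"` (death after diagnosis).
#' @return An object of class `"transition_params"`.
#' @export
#' @examples
#' transition_params(c(4.55, 0.03), kappa = 7, label = "i")
transition_params <- function(beta, kappa, label = c("i", "m0", "m1")) {
  label <- match.arg(label)
  beta <- as.numeric(beta)
  if (length(beta) < 1L || any(!is.finite(beta)))
    stop("'beta' must be a non-empty finite numeric vector")
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) ||
      kappa <= 0)
    stop("'kappa' must be a single positive number")
  structure(list(beta = beta, kappa = as.numeric(kappa), label = label),
            class = "transition_params")
}

#' Weibull AFT scale for a covariate vector
#'
#' Computes the subject-specific Weibull scale
#' `eta = exp(x'beta + u)` (in years) for a transition, where `x` is a
#' covariate vector whose first entry is the constant 1.
#'
#' @param x Numeric covariate vector, first element 1 (the intercept column).
#' @param params A [transition_params()] object, or a plain coefficient
#'   vector.
#' @param u Random-effect value added to the linear predictor (default 0).
#' @return The positive scale `eta` in years.
#' @export
#' @examples
#' aft_scale(c(1, 0, 0), transition_params(c(4.65, 0.03, -0.05), 7), u = 0)
aft_scale <- function(x, params, u = 0) {
  beta <- if (inherits(params, "transition_params")) params$beta else params
  x <- as.numeric(x)
  if (length(x) != length(beta))
    stop("covariate vector and coefficient vector lengths differ")
  if (abs(x[1L] - 1) > .Machine$double.eps^0.5)
    stop("first element of the covariate vector must be the constant 1")
  if (any(!is.finite(x)) || any(!is.finite(u)))
    stop("non-finite inputs to aft_scale()")
  eta <- exp(sum(x * beta) + u)
  if (any(!is.finite(eta)))
    stop("Weibull scale overflowed: linear predictor too large")
  eta
}

#' Weibull survival, hazard and density
#'
#' Core Weibull functions on the age scale with the shape/scale convention
#' `S(t) = exp(-(t/scale)^kappa)`. Log-survival is evaluated in log space,
#' `-exp(kappa * (log t - log scale))`, so large ages and shapes do not
#' overflow.
#'
#' @param t Age in years (vectorised). `wb_surv` accepts `t >= 0`;
#'   `wb_haz` and `wb_dens` require `t > 0`.
#' @param scale Positive Weibull scale (years).
#' @param kappa Positive Weibull shape.
#' @return `wb_surv`: survival probabilities; `wb_logsurv`: their logs;
#'   `wb_haz`: hazard rates per year; `wb_dens`/`wb_logdens`: density values
#'   and their logs.
#' @export
#' @examples
#' wb_surv(80, scale = 90, kappa = 8)
#' wb_haz(80, scale = 90, kappa = 8)
wb_surv <- function(t, scale, kappa) exp(wb_logsurv(t, scale, kappa))

#' @rdname wb_surv
#' @export
wb_logsurv <- function(t, scale, kappa) {
  check_wb_args(scale, kappa)
  if (any(t < 0, na.rm = TRUE)) stop("'t' must be non-negative")
  out <- -exp(kappa * (log(t) - log(scale)))
  out[t == 0] <- 0
  out
}

#' @rdname wb_surv
#' @export
wb_haz <- function(t, scale, kappa) {
  check_wb_args(scale, kappa)
  if (any(t <= 0, na.rm = TRUE)) stop("'t' must be positive for the hazard")
  (kappa / scale) * exp((kappa - 1) * (log(t) - log(scale)))
}

#' @rdname wb_surv
#' @export
wb_dens <- function(t, scale, kappa) exp(wb_logdens(t, scale, kappa))

#' @rdname wb_surv
#' @export
wb_logdens <- function(t, scale, kappa) {
  check_wb_args(scale, kappa)
  if (any(t <= 0, na.rm = TRUE)) stop("'t' must be positive for the density")
  log(kappa) - log(scale) + (kappa - 1) * (log(t) - log(scale)) +
    wb_logsurv(t, scale, kappa)
}

check_wb_args <- function(scale, kappa) {
  if (any(scale <= 0, na.rm = TRUE)) stop("'scale' must be positive")
  if (any(kappa <= 0, na.rm = TRUE)) stop("'kappa' must be positive")
  invisible(NULL)
}

#' Markov conditional survival for death after diagnosis
#'
#' Under the Markov assumption the post-diagnosis death hazard depends only
#' on current age, so the survival of the death age `t2` conditional on being
#' alive at the diagnosis age `t1` is `S(t2)/S(t1)`.
#'
#' @param t2,t1 Ages in years with `0 < t1 <= t2` (vectorised).
#' @inheritParams wb_surv
#' @return Conditional survival probabilities in `(0, 1]`.
#' @export
wb_surv_cond <- function(t2, t1, scale, kappa) {
  if (any(t1 <= 0, na.rm = TRUE)) stop("'t1' must be positive")
  if (any(t2 < t1, na.rm = TRUE)) stop("'t2' must be >= 't1'")
  exp(wb_logsurv(t2, scale, kappa) - wb_logsurv(t1, scale, kappa))
}

#' Weibull mean and median event age
#'
#' Population summaries of a Weibull AFT submodel for a covariate profile
#' with linear predictor `linpred = x'beta`:
#' mean `exp(linpred) * Gamma(1 + 1/kappa)` and median
#' `exp(linpred) * log(2)^(1/kappa)`, both in years.
#'
#' @param linpred Linear predictor on the log-age scale.
#' @param kappa Positive Weibull shape.
#' @return Mean (resp. median) event age in years.
#' @export
#' @examples
#' wb_mean(log(10), kappa = 1)    # exponential: mean 10
#' wb_median(log(10), kappa = 1)  # 10 * log(2)
wb_mean <- function(linpred, kappa) {
  if (any(kappa <= 0)) stop("'kappa' must be positive")
  exp(linpred + lgamma(1 + 1 / kappa))
}

#' @rdname wb_mean
#' @export
wb_median <- function(linpred, kappa) {
  if (any(kappa <= 0)) stop("'kappa' must be positive")
  exp(linpred + log(log(2)) / kappa)
}

#' Acceleration factor and hazard ratio for an AFT coefficient
#'
#' `acceleration_factor()` returns `exp(beta)`, the multiplicative effect of
#' a covariate on the event age. `hazard_ratio()` converts the same
#' coefficient to the Weibull proportional-hazards scale, `exp(-kappa *
#' beta)`; a negative `beta` (earlier event) therefore yields a hazard ratio
#' above 1. The two satisfy `HR = AF^(-kappa)`.
#'
#' @param beta_coef AFT regression coefficient (vectorised).
#' @param kappa Positive Weibull shape.
#' @return Positive effect measure.
#' @export
#' @examples
#' acceleration_factor(-0.08)        # 0.92: males die ~8% younger
#' hazard_ratio(-0.04, kappa = 10.8) # ~1.54
acceleration_factor <- function(beta_coef) {
  if (any(!is.finite(beta_coef))) stop("'beta_coef' must be finite")
  exp(beta_coef)
}

#' @rdname acceleration_factor
#' @export
hazard_ratio <- function(beta_coef, kappa) {
  if (any(kappa <= 0)) stop("'kappa' must be positive")
  exp(-kappa * beta_coef)
}
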