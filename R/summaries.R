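# Derived effect measures and patient-profile summaries from a fitted model.

transition_index <- function(fit, p) {
  # positions of (beta_p, kappa_p) in the natural parameter vector
  d <- length(fit$covnames)
  off <- switch(p, i = 0L, m0 = d, m1 = 2L * d)
  list(beta = off + seq_len(d), kappa = 3L * d + switch(p, i = 1L,
                                                        m0 = 2L, m1 = 3L))
}

#' Acceleration-factor and hazard-ratio table
#'
#' For every covariate effect of every transition, reports the AFT
#' coefficient with its Wald interval, the acceleration factor `exp(beta)`
#' (interval obtained by exponentiating the coefficient interval), and the
#' hazard ratio `exp(-kappa * beta)` (interval by the delta method on
#' `kappa * beta`, using the joint covariance of the estimates).
#'
#' @param fit A converged [fit_idm()] result with standard errors.
#' @param level Confidence level (default 0.95).
#' @return A data frame with one row per transition x covariate effect.
#' @export
effect_table <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "idm_fit"))
  if (is.null(fit$vcov)) stop("fit was computed with se = FALSE")
  d <- length(fit$covnames)
  if (d < 2L) stop("no covariate effects: the model is intercept-only")
  z <- qnorm(1 - (1 - level) / 2)
  rows <- list()
  for (p in c("i", "m0", "m1")) {
    ix <- transition_index(fit, p)
    kap <- fit$estimate[ix$kappa]
    for (cc in 2:d) {
      bi <- ix$beta[cc]
      b <- fit$estimate[bi]; sb <- fit$se[bi]
      ci <- wald_ci(b, sb, level)
      g <- kap * b                      # delta method on kappa * beta
      vg <- b^2 * fit$vcov[ix$kappa, ix$kappa] +
            kap^2 * fit$vcov[bi, bi] +
            2 * kap * b * fit$vcov[ix$kappa, bi]
      sg <- sqrt(max(vg, 0))
      rows[[length(rows) + 1L]] <- data.frame(
        transition = p, term = fit$covnames[cc],
        beta = b, beta_lower = ci[1], beta_upper = ci[2],
        af = exp(b), af_lower = exp(ci[1]), af_upper = exp(ci[2]),
        hr = exp(-g), hr_lower = exp(-(g + z * sg)),
        hr_upper = exp(-(g - z * sg)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

profile_design <- function(fit, profiles) {
  tt <- stats::delete.response(terms(fit$formula))
  X <- model.matrix(tt, data = profiles)
  if (!identical(colnames(X), fit$covnames))
    stop("profile columns do not match the fitted covariate design")
  X
}

# mean/median of one transition for one covariate row, with delta-method CI
profile_one <- function(fit, x, p, level) {
  ix <- transition_index(fit, p)
  b <- fit$estimate[ix$beta]; kap <- fit$estimate[ix$kappa]
  lp <- sum(x * b)
  z <- qnorm(1 - (1 - level) / 2)
  V <- fit$vcov[c(ix$beta, ix$kappa), c(ix$beta, ix$kappa)]
  est <- function(what) {
    val <- if (what == "mean") wb_mean(lp, kap) else wb_median(lp, kap)
    dk <- if (what == "mean") -digamma(1 + 1 / kap) / kap^2
          else -log(log(2)) / kap^2
    grad <- c(val * x, val * dk)
    se <- sqrt(max(as.numeric(grad %*% V %*% grad), 0))
    c(val, val - z * se, val + z * se, se)
  }
  c(est("mean"), est("median"))
}

#' Patient-profile event-age summaries
#'
#' Mean and median event age per transition for each covariate profile,
#' using `E = exp(x'beta) * Gamma(1 + 1/kappa)` and
#' `Med = exp(x'beta) * log(2)^(1/kappa)`, with delta-method confidence
#' intervals propagated from the joint covariance of the coefficient and
#' shape estimates. These are population summaries of the latent Weibull
#' laws, i.e. what a cohort followed from birth would show.
#'
#' @param fit A converged [fit_idm()] result with standard errors.
#' @param profiles Data frame of covariate patterns (one row per profile);
#'   an optional `profile` column supplies labels.
#' @param level Confidence level (default 0.95).
#' @return Data frame with one row per profile x transition: `mean`,
#'   `mean_lower`, `mean_upper`, `median`, `median_lower`, `median_upper`
#'   (years).
#' @export
profile_summaries <- function(fit, profiles, level = 0.95) {
  stopifnot(inherits(fit, "idm_fit"))
  if (is.null(fit$vcov)) stop("fit was computed with se = FALSE")
  labels <- if ("profile" %in% names(profiles)) profiles$profile
            else paste0("profile_", seq_len(nrow(profiles)))
  X <- profile_design(fit, profiles)
  rows <- list()
  for (r in seq_len(nrow(X))) {
    for (p in c("i", "m0", "m1")) {
      v <- profile_one(fit, X[r, ], p, level)
      rows[[length(rows) + 1L]] <- data.frame(
        profile = labels[r], transition = p,
        mean = v[1], mean_lower = v[2], mean_upper = v[3],
        median = v[5], median_lower = v[6], median_upper = v[7])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median survival difference between the two mortality transitions
#'
#' Difference (in years) between the median age at death without disease
#' and the median age at death after diagnosis for one covariate profile —
#' a summary of how much the disease shortens life — with a delta-method
#' confidence interval.
#'
#' @param fit A converged [fit_idm()] result with standard errors.
#' @param profile One-row data frame with the covariate pattern.
#' @param level Confidence level (default 0.95).
#' @return Named vector: `difference`, `lower`, `upper` (years).
#' @export
median_survival_difference <- function(fit, profile, level = 0.95) {
  stopifnot(inherits(fit, "idm_fit"), nrow(profile) == 1L)
  if (is.null(fit$vcov)) stop("fit was computed with se = FALSE")
  x <- profile_design(fit, profile)[1L, ]
  i0 <- transition_index(fit, "m0"); i1 <- transition_index(fit, "m1")
  b0 <- fit$estimate[i0$beta]; k0 <- fit$estimate[i0$kappa]
  b1 <- fit$estimate[i1$beta]; k1 <- fit$estimate[i1$kappa]
  med0 <- unname(wb_median(sum(x * b0), unname(k0)))
  med1 <- unname(wb_median(sum(x * b1), unname(k1)))
  idx <- c(i0$beta, i0$kappa, i1$beta, i1$kappa)
  grad <- c(med0 * x, med0 * (-log(log(2)) / k0^2),
            -med1 * x, -med1 * (-log(log(2)) / k1^2))
  V <- fit$vcov[idx, idx]
  se <- sqrt(max(as.numeric(grad %*% V %*% grad), 0))
  z <- qnorm(1 - (1 - level) / 2)
  c(difference = med0 - med1, lower = med0 - med1 - z * se,
    upper = med0 - med1 + z * se)
}
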