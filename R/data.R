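# Subject-level data container for semi-competing risks cohorts.
#
# One row per subject with the observed tuple
#   (entry_age L, [t_left, t_right] diagnosis interval, t_mid, last_age Y2,
#    delta1, delta2, covariates),
# where Y2 = min(death age, censoring age), delta1 flags a diagnosis during
# follow-up and delta2 an observed death.
# Undiagnosed subjects carry t_left = last_age, t_right = Inf.

#' Construct and validate an illness-death dataset
#'
#' Wraps a data frame of per-subject records into a validated `idm_data`
#' object. Required columns: `entry_age`, `t_left`, `t_right`, `t_mid`,
#' `last_age`, `delta1`, `delta2`; any further columns are treated as
#' covariates. For rows with `delta1 == 0`, `t_left`/`t_right`/`t_mid` may be
#' `NA` and are normalised to `last_age`/`Inf`/`NA`.
#'
#' A diagnosis interval whose left bound precedes study entry (possible in
#' real cohorts when the last disease-free visit predates enrolment into the
#' analysis sample) is clamped to `t_left = entry_age` with a warning, since
#' the likelihood conditions on being disease-free at entry.
#'
#' @param df A data frame of subject records.
#' @return The validated data frame with class `c("idm_data", "data.frame")`.
#' @export
#' @examples
#' df <- data.frame(entry_age = 57, t_left = 70, t_right = 73, t_mid = 71.5,
#'                  last_age = 80, delta1 = 1, delta2 = 1, sex = 1)
#' idm_data(df)
idm_data <- function(df) {
  df <- as.data.frame(df)
  req <- c("entry_age", "t_left", "t_right", "t_mid", "last_age",
           "delta1", "delta2")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("empty dataset")

  bad_row <- function(cond, what) {
    idx <- which(cond)
    if (length(idx))
      stop(sprintf("invalid records (rows %s): %s",
                   paste(utils::head(idx, 5L), collapse = ", "), what))
  }
  bad_row(!df$delta1 %in% c(0, 1), "delta1 must be 0 or 1")
  bad_row(!df$delta2 %in% c(0, 1), "delta2 must be 0 or 1")
  bad_row(!is.finite(df$entry_age) | df$entry_age < 0,
          "entry_age must be finite and non-negative")
  bad_row(!is.finite(df$last_age) | df$last_age <= df$entry_age,
          "last_age must exceed entry_age")

  d1 <- df$delta1 == 1
  # normalise the undiagnosed rows
  df$t_left[!d1] <- df$last_age[!d1]
  df$t_right[!d1] <- Inf
  df$t_mid[!d1] <- NA_real_

  if (any(d1)) {
    clamp <- d1 & is.finite(df$t_left) & df$t_left < df$entry_age
    if (any(clamp)) {
      warning(sprintf(
        "%d diagnosis interval(s) start before study entry; left bound clamped to entry_age",
        sum(clamp)))
      df$t_left[clamp] <- df$entry_age[clamp]
      df$t_mid[clamp] <- (df$t_left[clamp] + df$t_right[clamp]) / 2
    }
    # t_right may exceed last_age: visit intervals are drawn around the
    # true onset and death can occur before the first post-onset visit
    bad_row(d1 & !is.finite(df$t_right),
            "diagnosed rows need a finite t_right")
    bad_row(d1 & (df$t_left >= df$t_right),
            "diagnosed rows need t_left < t_right")
    bad_row(d1 & (df$t_left < df$entry_age),
            "t_left must be >= entry_age")
    bad_row(d1 & abs(df$t_mid - (df$t_left + df$t_right) / 2) > 1e-8,
            "t_mid must be the interval midpoint")
  }
  class(df) <- c("idm_data", "data.frame")
  df
}

#' Likelihood case of each subject
#'
#' Classifies subjects into the four observed-data cases by their diagnosis
#' and death indicators: I = diagnosed and died, II = diagnosed and
#' censored, III = undiagnosed and died, IV = undiagnosed and censored.
#'
#' @param data An `idm_data` object (or any data frame with `delta1`,
#'   `delta2` columns).
#' @return A factor with levels `"I"`, `"II"`, `"III"`, `"IV"`.
#' @export
case_of <- function(data) {
  lab <- ifelse(data$delta1 == 1,
                ifelse(data$delta2 == 1, "I", "II"),
                ifelse(data$delta2 == 1, "III", "IV"))
  factor(lab, levels = c("I", "II", "III", "IV"))
}

#' Covariate names of an illness-death dataset
#'
#' @param data An `idm_data` object.
#' @return Character vector of non-structural column names.
#' @export
idm_covariates <- function(data) {
  setdiff(names(data), c("entry_age", "t_left", "t_right", "t_mid",
                         "last_age", "delta1", "delta2"))
}
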