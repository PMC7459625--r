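#' @include fitting.R
NULL

#' Initial decrease in log activity at the irradiation day
#'
#' The model's drop at t = 0 for dose D is \code{beta1*D + beta2*D^2}
#' (log-activity units). Confidence intervals come from the delta method:
#' the gradient (D, D^2) against the fixed-effect covariance submatrix of
#' (beta1, beta2). At D = 0 the decrease is identically 0 with a
#' zero-width interval.
#'
#' @param dose dose(s) in Gy (vectorized).
#' @param fit a converged \linkS4class{ActivityFit} with standard errors.
#' @param level confidence level (default 0.95).
#' @return data.frame with columns dose, decrease, se, ci_lower, ci_upper.
#' @export
initialDecrease <- function(dose, fit, level = 0.95) {
  stopifnot(is(fit, "ActivityFit"))
  b1 <- fit@theta[["beta1"]]
  b2 <- fit@theta[["beta2"]]
  est <- b1 * dose + b2 * dose^2
  V <- fit@vcovFixed
  bnms <- intersect(c("beta1", "beta2"), colnames(V))
  haveV <- length(V) > 0 && length(bnms) > 0 &&
    all(is.finite(V[bnms, bnms]))
  if (!haveV)
    warning("fixed-effect covariance unavailable; intervals reported missing")
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- vapply(dose, function(D) {
    if (!haveV) return(NA_real_)
    if (D == 0) return(0)
    g <- c(beta1 = D, beta2 = D^2)[bnms]
    sqrt(drop(t(g) %*% V[bnms, bnms, drop = FALSE] %*% g))
  }, numeric(1))
  data.frame(dose = dose, decrease = est, se = se,
             ci_lower = est - z * se, ci_upper = est + z * se)
}

#' Dose-specific recovery rate
#'
#' \code{r(D) = omega1 * exp(-omega2 * (D - D0))} per day. When omega2 is
#' dropped from the model the rate is common to all doses and equals
#' omega1.
#'
#' @param dose dose(s) in Gy.
#' @param fit an \linkS4class{ActivityFit}.
#' @return numeric vector of rates (per day).
#' @export
recoveryRate <- function(dose, fit) {
  stopifnot(is(fit, "ActivityFit"))
  fit@theta[["omega1"]] *
    exp(-fit@theta[["omega2"]] * (dose - fit@D0))
}

#' Fitted group trend curve
#'
#' Evaluates the fitted mean log activity on a day grid for each dose —
#' the table behind group-trend plots. The day covariate is treated as
#' real-valued, so the grid can be arbitrarily fine.
#'
#' @param fit an \linkS4class{ActivityFit}.
#' @param days numeric grid of day values.
#' @param dose dose(s) in Gy; one curve per dose.
#' @return data.frame with columns dose, day, fitted.
#' @export
fittedTrend <- function(fit, days, dose) {
  stopifnot(is(fit, "ActivityFit"))
  out <- do.call(rbind, lapply(dose, function(D)
    data.frame(dose = D, day = days,
               fitted = meanActivity(days, D, fit@theta, fit@D0))))
  rownames(out) <- NULL
  out
}

#' Time to recovery of the initial decrease
#'
#' Days until the residual decrease falls to \code{fraction} of its
#' initial magnitude; from the exponential-decay form this is
#' \code{t* = -log(fraction) / r(D)}. The 5% default is a convention: the
#' model recovers only asymptotically, so "recovered" needs a threshold.
#'
#' @param dose dose(s) in Gy (> 0; the decrease must be positive).
#' @param fit an \linkS4class{ActivityFit}.
#' @param fraction remaining fraction defining recovery (default 0.05).
#' @return numeric vector of recovery times in days.
#' @export
recoveryTime <- function(dose, fit, fraction = 0.05) {
  stopifnot(fraction > 0, fraction <= 1)
  r <- recoveryRate(dose, fit)
  if (any(r <= 0))
    stop("recovery rate must be positive for a finite recovery time")
  dec <- fit@theta[["beta1"]] * dose + fit@theta[["beta2"]] * dose^2
  if (any(dec <= 0))
    stop("initial decrease must be positive at the requested dose(s)")
  -log(fraction) / r
}

#' Dose-response summary table
#'
#' One row per dose: initial decrease with delta-method confidence
#' bounds, recovery rate and recovery time.
#'
#' @param fit an \linkS4class{ActivityFit} with standard errors.
#' @param dose doses in Gy (default the study groups 0, 2.0, 3.5, 5.0).
#' @param level confidence level.
#' @param fraction recovery threshold passed to \code{\link{recoveryTime}}.
#' @return data.frame with columns dose, decrease, se, ci_lower,
#'   ci_upper, recovery_rate, recovery_time (NA at dose 0).
#' @export
doseResponseTable <- function(fit, dose = c(0, 2.0, 3.5, 5.0),
                              level = 0.95, fraction = 0.05) {
  dec <- initialDecrease(dose, fit, level)
  dec$recovery_rate <- recoveryRate(dose, fit)
  dec$recovery_time <- NA_real_
  pos <- dose > 0 & dec$decrease > 0 & dec$recovery_rate > 0
  if (any(pos))
    dec$recovery_time[pos] <- recoveryTime(dose[pos], fit, fraction)
  dec
}

#' Observed group-mean decreases at the irradiation day
#'
#' Reconstructs the per-group observed drop at t = 0 as the deviation of
#' the group mean log activity on day 0 from the fitted baseline
#' (exported for plotting against the fitted dose-response curve; not
#' used in estimation).
#'
#' @param fit an \linkS4class{ActivityFit}.
#' @param panel the fitted panel.
#' @return data.frame with columns dose and observed_decrease.
#' @export
observedDecreases <- function(fit, panel) {
  d <- panel@data
  day0 <- d[d$day == 0, ]
  if (!nrow(day0)) stop("panel has no day-0 observations")
  baseline <- meanActivity(0, 0, fit@theta, fit@D0)  # xi0 at t = 0
  agg <- tapply(day0$log_activity, day0$dose_gy, mean)
  data.frame(dose = as.numeric(names(agg)),
             observed_decrease = baseline - as.numeric(agg))
}
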