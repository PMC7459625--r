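#' @include fitting.R
NULL

#' Posterior-mean prediction of the crossed random effects
#'
#' Conditional expectations (BLUPs) of the animal effects delta_i and day
#' effects eta_t given the data under the fitted Gaussian model:
#' \code{c_hat = G Z' Omega^{-1} (y - mu_hat)}, where G holds psi2 for
#' animal effects and phi2 for day effects and Z is the incidence of
#' effects on cells. Per-cell residuals follow from the exact identity
#' \code{y - mu_hat = delta_hat_i + eta_hat_t + eps_hat_it}.
#'
#' @param fit a converged mixed-model \linkS4class{ActivityFit}.
#' @param panel the fitted \linkS4class{ActivityPanel}.
#' @return A \linkS4class{RandomEffectPredictions}.
#' @export
predictRandomEffects <- function(fit, panel) {
  stopifnot(is(fit, "ActivityFit"), is(panel, "ActivityPanel"))
  if (!fit@spec@mixed)
    stop("ordinary regression fit has no random effects to predict")
  if (!fit@converged)
    warning("predicting random effects from a non-converged fit")
  d <- panel@data
  r <- d$log_activity - meanActivity(d$day, d$dose_gy, fit@theta, fit@D0)
  Omega <- covarianceMatrix(d, fit@delta)
  w <- solve(Omega, r)
  psi2 <- fit@delta[["psi2"]]
  phi2 <- fit@delta[["phi2"]]
  animals <- unique(d$animal_id)
  days <- sort(unique(d$day))
  deltaHat <- psi2 * vapply(animals,
    function(a) sum(w[d$animal_id == a]), numeric(1))
  etaHat <- phi2 * vapply(days,
    function(t) sum(w[d$day == t]), numeric(1))
  names(deltaHat) <- animals
  names(etaHat) <- as.character(days)
  eps <- r - deltaHat[d$animal_id] - etaHat[as.character(d$day)]
  resid <- data.frame(animal_id = d$animal_id, dose_gy = d$dose_gy,
                      day = d$day, residual = as.numeric(eps))
  new("RandomEffectPredictions", deltaHat = deltaHat, etaHat = etaHat,
      residuals = resid)
}

#' Variance decomposition into shares
#'
#' Expresses each variance component (individual differences, daily
#' fluctuation, measurement error) as a percentage of their sum.
#'
#' @param delta variance components, see \code{\link{varianceComponents}},
#'   or an \linkS4class{ActivityFit}.
#' @return list with \code{share} (unrounded percentages) and
#'   \code{display} (rounded to integer percent).
#' @examples
#' varianceShares(varianceComponents(0.0018, 0.0019, 0.0015))
#' @export
varianceShares <- function(delta) {
  if (is(delta, "ActivityFit")) delta <- delta@delta
  if (!is.numeric(delta) || length(delta) != 3 || any(delta < 0))
    stop("delta must be three non-negative variance components")
  if (is.null(names(delta))) names(delta) <- VARIANCE_NAMES
  total <- sum(delta)
  if (total <= 0) stop("all variance components are zero")
  share <- 100 * delta / total
  list(share = share, display = round(share))
}

#' Residual summary
#'
#' Standard deviation, quartiles and boxplot whisker statistics of the
#' per-cell residuals — the table behind a residual boxplot comparison of
#' competing fits.
#'
#' @param x a \linkS4class{RandomEffectPredictions}, or a numeric vector
#'   of residuals (e.g. \code{y - mu_hat} from an ordinary regression
#'   fit).
#' @return list with \code{sd}, \code{quartiles} (0/25/50/75/100
#'   percentiles), \code{boxplot} (lower whisker, hinges, median, upper
#'   whisker) and \code{n}.
#' @export
residualSummary <- function(x) {
  res <- if (is(x, "RandomEffectPredictions")) x@residuals$residual
         else as.numeric(x)
  bs <- grDevices::boxplot.stats(res)
  list(sd = stats::sd(res),
       quartiles = stats::quantile(res, c(0, 0.25, 0.5, 0.75, 1)),
       boxplot = bs$stats, n = length(res))
}

#' Fixed-effect residuals of a fit
#'
#' \code{y - mu_hat}: the residuals of an ordinary regression fit, or the
#' marginal (random effects not subtracted) residuals of a mixed fit.
#'
#' @param fit an \linkS4class{ActivityFit}.
#' @param panel the fitted panel.
#' @return numeric vector aligned with the panel rows.
#' @export
marginalResiduals <- function(fit, panel) {
  d <- panel@data
  d$log_activity - meanActivity(d$day, d$dose_gy, fit@theta, fit@D0)
}

#' Durbin-Watson statistic with a permutation p-value
#'
#' DW = sum of squared successive differences over the sum of squares of
#' the sequence; near 2 under no serial correlation, towards 0 (4) under
#' positive (negative) autocorrelation. Because the day effects are
#' posterior means rather than regression residuals, the classical DW
#' null tables do not apply; the p-value is a two-sided permutation tail
#' around 2: the fraction of random reorderings whose |DW - 2| is at
#' least the observed one.
#'
#' @param etaHat numeric sequence in time order (length >= 3), e.g. the
#'   \code{etaHat} slot of \code{\link{predictRandomEffects}}.
#' @param nPerm number of permutations (default 10000).
#' @param seed integer seed for the permutation draw; the global RNG
#'   state is restored on exit.
#' @return list with \code{statistic}, \code{p_value} and \code{nPerm}.
#' @export
durbinWatson <- function(etaHat, nPerm = 10000, seed = 20200805) {
  x <- as.numeric(etaHat)
  if (length(x) < 3) stop("need at least 3 ordered values")
  denom <- sum(x^2)
  if (denom == 0) stop("all values are zero; statistic undefined")
  dw <- function(v) sum(diff(v)^2) / sum(v^2)
  obs <- dw(x)
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  perm <- vapply(seq_len(nPerm), function(i) dw(sample(x)), numeric(1))
  p <- (1 + sum(abs(perm - 2) >= abs(obs - 2))) / (nPerm + 1)
  list(statistic = obs, p_value = p, nPerm = nPerm)
}
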