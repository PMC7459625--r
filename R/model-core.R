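#' @include AllClasses.R
NULL

#' Heaviside step of the day index
#'
#' Switches the decrease/recovery term on from the irradiation day: 0 for
#' t < 0 (pre-irradiation), 1 for t >= 0.
#'
#' @param t numeric vector of day indices.
#' @return 0/1 numeric vector.
#' @examples
#' heaviside(c(-1, 0, 20))  # 0 1 1
#' @export
heaviside <- function(t) as.numeric(t >= 0)

#' Expected log activity
#'
#' The fixed-effect mean of the activity model:
#' \deqn{f(t | D) = \xi_0 + \xi_1 t + \xi_2 t^2 -
#'   (\beta_1 D + \beta_2 D^2)\, e^{-r(D)\,t}\, h(t),}
#' with dose-specific recovery rate
#' \eqn{r(D) = \omega_1 e^{-\omega_2 (D - D_0)}} and Heaviside \eqn{h(t)}.
#' Pre-irradiation the trajectory is the baseline day polynomial; at t = 0
#' activity drops by \eqn{\beta_1 D + \beta_2 D^2} and then recovers
#' exponentially towards the baseline.
#'
#' @param t day index (real-valued; vectorized).
#' @param dose dose in Gy (vectorized, recycled against t).
#' @param theta fixed effects, see \code{\link{fixedEffects}}.
#' @param D0 centering dose in Gy (default 2.75), configuration not a
#'   parameter.
#' @return numeric vector of expected log activities.
#' @examples
#' th <- fixedEffects(xi0 = 4.319, beta1 = 0.066, beta2 = -0.006,
#'                    omega1 = 9.063)
#' meanActivity(0, 5, th)   # 4.319 - (0.066*5 - 0.006*25)
#' @export
meanActivity <- function(t, dose, theta, D0 = 2.75) {
  .checkTheta(theta)
  rate <- theta[["omega1"]] * exp(-theta[["omega2"]] * (dose - D0))
  drop <- (theta[["beta1"]] * dose + theta[["beta2"]] * dose^2) *
    exp(-rate * t) * heaviside(t)
  theta[["xi0"]] + theta[["xi1"]] * t + theta[["xi2"]] * t^2 - drop
}

#' Covariance matrix of the stacked log activities
#'
#' The crossed random-effects decomposition y = f + delta_i + eta_t + eps
#' implies, for cells (i, t) and (j, t'):
#' cov = psi2*[i == j] + phi2*[t == t'] + sigma2*[i == j and t == t'].
#' The matrix is built over exactly the observed cells, so unbalanced
#' panels are supported.
#'
#' @param design data.frame with columns \code{animal_id} and \code{day}
#'   (one row per observed cell), or an \linkS4class{ActivityPanel}.
#' @param delta variance components, see \code{\link{varianceComponents}}.
#' @return symmetric positive-definite matrix, one row per cell, in the
#'   row order of \code{design}.
#' @export
covarianceMatrix <- function(design, delta) {
  if (is(design, "ActivityPanel")) design <- design@data
  .checkDelta(delta)
  sameAnimal <- outer(design$animal_id, design$animal_id, "==")
  sameDay <- outer(design$day, design$day, "==")
  delta[["psi2"]] * sameAnimal + delta[["phi2"]] * sameDay +
    delta[["sigma2"]] * (sameAnimal & sameDay)
}

# TRUE when the panel is a complete animals-x-days grid, enabling the
# closed-form eigenstructure of the crossed covariance.
.isBalanced <- function(d) {
  nA <- length(unique(d$animal_id))
  nT <- length(unique(d$day))
  nrow(d) == nA * nT && !anyDuplicated(d[c("animal_id", "day")])
}

# Closed-form log-likelihood for a complete balanced panel. The crossed
# covariance has four eigenvalue strata (grand mean, animal-mean
# deviations, day-mean deviations, interaction); both log|Omega| and the
# quadratic form decompose over them, giving an O(n) evaluation.
.logLikBalanced <- function(R, delta) {
  A <- nrow(R); Td <- ncol(R); n <- A * Td
  s2 <- delta[["sigma2"]]
  lGrand <- s2 + delta[["psi2"]] * Td + delta[["phi2"]] * A
  lAnimal <- s2 + delta[["psi2"]] * Td
  lDay <- s2 + delta[["phi2"]] * A
  m <- mean(R)
  a <- rowMeans(R) - m
  b <- colMeans(R) - m
  E <- R - outer(a, rep(1, Td)) - outer(rep(1, A), b) - m
  logdet <- log(lGrand) + (A - 1) * log(lAnimal) + (Td - 1) * log(lDay) +
    (A - 1) * (Td - 1) * log(s2)
  quad <- n * m^2 / lGrand + Td * sum(a^2) / lAnimal +
    A * sum(b^2) / lDay + sum(E^2) / s2
  -0.5 * (n * log(2 * pi) + logdet + quad)
}

.logLikDense <- function(r, Omega) {
  ch <- tryCatch(chol(Omega), error = function(e)
    stop("covariance not positive definite: check psi2/phi2 >= 0, sigma2 > 0"))
  z <- backsolve(ch, r, transpose = TRUE)
  -0.5 * (length(r) * log(2 * pi)) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

#' Exact Gaussian log-likelihood of an activity panel
#'
#' Multivariate-normal log density of the stacked log activities at the
#' model mean and the crossed-covariance \code{covarianceMatrix}. Complete
#' balanced panels use an equivalent closed-form stratum decomposition of
#' the covariance; unbalanced panels fall back to a dense Cholesky.
#'
#' @param panel an \linkS4class{ActivityPanel}.
#' @param theta fixed effects.
#' @param delta variance components.
#' @param D0 centering dose (Gy).
#' @param method "auto" (default), "balanced" or "dense". "balanced"
#'   errors on unbalanced panels; "dense" always builds the full matrix.
#' @return scalar log-likelihood.
#' @export
panelLogLik <- function(panel, theta, delta, D0 = 2.75,
                        method = c("auto", "balanced", "dense")) {
  method <- match.arg(method)
  stopifnot(is(panel, "ActivityPanel"))
  .checkTheta(theta); .checkDelta(delta)
  d <- panel@data
  r <- d$log_activity - meanActivity(d$day, d$dose_gy, theta, D0)
  balanced <- .isBalanced(d)
  if (method == "balanced" && !balanced)
    stop("panel is unbalanced; the closed-form path needs a complete grid")
  if (method == "dense" || !balanced)
    return(.logLikDense(r, covarianceMatrix(d, delta)))
  animals <- unique(d$animal_id)
  days <- sort(unique(d$day))
  R <- matrix(0, length(animals), length(days))
  R[cbind(match(d$animal_id, animals), match(d$day, days))] <- r
  .logLikBalanced(R, delta)
}

#' Minimization objective Q = -2 log L
#'
#' The quantity minimized by direct maximum likelihood:
#' \code{Q = log|Omega| + r' Omega^{-1} r + n log(2 pi)} with
#' \code{r = y - mu(theta)}; identically \code{-2 * panelLogLik}.
#'
#' @inheritParams panelLogLik
#' @return scalar.
#' @export
qObjective <- function(panel, theta, delta, D0 = 2.75,
                       method = c("auto", "balanced", "dense")) {
  -2 * panelLogLik(panel, theta, delta, D0, method = match.arg(method))
}
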