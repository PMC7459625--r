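# Independent oracles and small fixture builders used across test files.

# Brute-force multivariate normal log density via solve()/determinant(),
# independent of the package's Cholesky / stratum-decomposition paths.
bruteLogLik <- function(panel, theta, delta, D0 = 2.75) {
  d <- panelData(panel)
  r <- d$log_activity - meanActivity(d$day, d$dose_gy, theta, D0)
  Omega <- covarianceMatrix(d, delta)
  n <- length(r)
  as.numeric(-0.5 * (n * log(2 * pi) + determinant(Omega)$modulus +
                       t(r) %*% solve(Omega) %*% r))
}

# Random small panel with arbitrary (not model-generated) responses.
randomPanel <- function(nA, nT, seed, dropCells = 0) {
  set.seed(seed)
  days <- seq_len(nT) - 2L
  d <- expand.grid(animal_id = sprintf("A%02d", seq_len(nA)), day = days,
                   stringsAsFactors = FALSE)
  dmap <- stats::runif(nA, 0, 5)
  d$dose_gy <- dmap[match(d$animal_id, sprintf("A%02d", seq_len(nA)))]
  d$log_activity <- stats::rnorm(nrow(d), 4, 0.3)
  if (dropCells > 0) d <- d[-sample(nrow(d), dropCells), ]
  suppressWarnings(activityPanel(d))
}

randomTheta <- function(seed) {
  set.seed(seed)
  fixedEffects(xi0 = stats::rnorm(1, 4, 0.5), xi1 = stats::rnorm(1, 0, 0.05),
               xi2 = stats::rnorm(1, 0, 0.01), beta1 = stats::runif(1, 0, 0.1),
               beta2 = stats::rnorm(1, 0, 0.005),
               omega1 = stats::runif(1, 0.2, 3),
               omega2 = stats::rnorm(1, 0, 0.3))
}

randomDelta <- function(seed) {
  set.seed(seed)
  varianceComponents(psi2 = stats::runif(1, 0, 0.01),
                     phi2 = stats::runif(1, 0, 0.01),
                     sigma2 = stats::runif(1, 0.0005, 0.01))
}

# Build an ActivityFit at given parameter values without optimizing
# (log-likelihood and criteria computed from the panel), for tests of
# downstream operations at controlled parameter values.
makeFitAt <- function(panel, theta, delta, spec = fullModel(), D0 = 2.75,
                      vcovFixed = NULL, se = NULL) {
  ll <- panelLogLik(panel, theta, delta, D0)
  k <- nParams(spec)
  n <- nrow(panelData(panel))
  ic <- informationCriteria(ll, k, n)
  free <- freeFixedEffects(spec)
  if (is.null(vcovFixed)) {
    vcovFixed <- matrix(NA_real_, length(free), length(free),
                        dimnames = list(free, free))
  }
  if (is.null(se)) se <- structure(rep(NA_real_, length(free)), names = free)
  new("ActivityFit", spec = spec, theta = theta, delta = delta, D0 = D0,
      se = se, vcovFixed = vcovFixed, logLik = ll, aic = ic[["aic"]],
      bic = ic[["bic"]], nObs = n, kParams = as.integer(k),
      converged = TRUE, optim = list())
}

# Joint-Gaussian conditioning oracle for the random-effect posterior
# means: stacks b = (delta_1..A, eta_1..T), builds the joint covariance
# of (b, y) from the incidence matrices, and conditions on y.
bruteBlup <- function(panel, theta, delta, D0 = 2.75) {
  d <- panelData(panel)
  animals <- unique(d$animal_id)
  days <- sort(unique(d$day))
  ZA <- outer(d$animal_id, animals, "==") * 1
  ZT <- outer(d$day, days, "==") * 1
  Z <- cbind(ZA, ZT)
  G <- diag(c(rep(delta[["psi2"]], length(animals)),
              rep(delta[["phi2"]], length(days))))
  Omega <- Z %*% G %*% t(Z) + delta[["sigma2"]] * diag(nrow(d))
  r <- d$log_activity - meanActivity(d$day, d$dose_gy, theta, D0)
  b <- drop(G %*% t(Z) %*% solve(Omega, r))
  list(deltaHat = structure(b[seq_along(animals)], names = animals),
       etaHat = structure(b[length(animals) + seq_along(days)],
                          names = as.character(days)))
}
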