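#' @import methods
NULL

FIXED_EFFECT_NAMES <- c("xi0", "xi1", "xi2", "beta1", "beta2", "omega1", "omega2")
VARIANCE_NAMES <- c("psi2", "phi2", "sigma2")

#' Fixed-effect parameter vector
#'
#' Builds the named vector of fixed-effect parameters of the activity model:
#' the baseline polynomial (\code{xi0 + xi1*t + xi2*t^2}), the initial
#' decrease (\code{beta1*D + beta2*D^2}, log-activity units at dose D Gy),
#' and the recovery rate \code{r(D) = omega1 * exp(-omega2 * (D - D0))}
#' (per day). Parameters dropped from a submodel are simply set to zero.
#'
#' @param xi0 baseline log activity at day 0 (log10 movements per night).
#' @param xi1,xi2 linear and quadratic day trend of the baseline.
#' @param beta1 initial-decrease slope per Gy.
#' @param beta2 initial-decrease curvature per Gy^2.
#' @param omega1 recovery rate per day at the centering dose; must be >= 0.
#' @param omega2 dose modulation of the recovery rate, per Gy.
#' @return Named numeric vector of length 7.
#' @examples
#' fixedEffects(xi0 = 4.319, beta1 = 0.066, beta2 = -0.006, omega1 = 9.063)
#' @export
fixedEffects <- function(xi0 = 0, xi1 = 0, xi2 = 0, beta1 = 0, beta2 = 0,
                         omega1 = 0, omega2 = 0) {
  theta <- c(xi0 = xi0, xi1 = xi1, xi2 = xi2, beta1 = beta1, beta2 = beta2,
             omega1 = omega1, omega2 = omega2)
  if (!all(is.finite(theta)))
    stop("fixed effects must be finite numbers")
  if (theta[["omega1"]] < 0)
    stop("omega1 must be non-negative (recovery, not divergence)")
  theta
}

#' Variance components of the crossed random-effects model
#'
#' @param psi2 individual-difference (animal) variance.
#' @param phi2 daily-fluctuation (day) variance.
#' @param sigma2 measurement-error variance; must be > 0.
#' @return Named numeric vector \code{c(psi2, phi2, sigma2)} on the squared
#'   log-activity scale.
#' @examples
#' varianceComponents(0.0018, 0.0019, 0.0015)
#' @export
varianceComponents <- function(psi2 = 0, phi2 = 0, sigma2 = 1) {
  delta <- c(psi2 = psi2, phi2 = phi2, sigma2 = sigma2)
  if (!all(is.finite(delta)))
    stop("variance components must be finite")
  if (psi2 < 0 || phi2 < 0)
    stop("psi2 and phi2 must be non-negative")
  if (sigma2 <= 0)
    stop("sigma2 must be strictly positive (covariance would be singular)")
  delta
}

.checkTheta <- function(theta) {
  if (!is.numeric(theta) || !identical(names(theta), FIXED_EFFECT_NAMES))
    stop("theta must be a named vector as returned by fixedEffects()")
  invisible(theta)
}

.checkDelta <- function(delta) {
  if (!is.numeric(delta) || !identical(names(delta), VARIANCE_NAMES))
    stop("delta must be a named vector as returned by varianceComponents()")
  if (delta[["psi2"]] < 0 || delta[["phi2"]] < 0 || delta[["sigma2"]] <= 0)
    stop("invalid variance components: need psi2 >= 0, phi2 >= 0, sigma2 > 0")
  invisible(delta)
}

#' Raw movement-count series for one animal
#'
#' Minute-resolution movement counts from an infrared activity sensor:
#' strictly increasing, uniformly spaced timestamps and non-negative
#' integer counts.
#'
#' @slot animalId single character identifier.
#' @slot timestamps POSIXct vector, strictly increasing, uniform spacing.
#' @slot counts integer vector of movements per interval, >= 0.
#' @export
setClass("MovementCountSeries",
  representation(animalId = "character",
                 timestamps = "POSIXct",
                 counts = "integer"))

setValidity("MovementCountSeries", function(object) {
  msgs <- character()
  if (length(object@animalId) != 1L || is.na(object@animalId))
    msgs <- c(msgs, "animalId must be a single non-missing string")
  if (length(object@timestamps) != length(object@counts))
    msgs <- c(msgs, "timestamps and counts must have equal length")
  if (length(object@timestamps) >= 2L) {
    d <- diff(as.numeric(object@timestamps))
    if (any(d <= 0))
      msgs <- c(msgs, "timestamps must be strictly increasing")
    else if (max(d) - min(d) > 1e-6)
      msgs <- c(msgs, "timestamps must be uniformly spaced")
  }
  if (any(is.na(object@counts)) || any(object@counts < 0L))
    msgs <- c(msgs, "counts must be non-negative integers")
  if (length(msgs)) msgs else TRUE
})

#' Construct a MovementCountSeries
#'
#' @param animalId single string.
#' @param timestamps POSIXct (or coercible) vector.
#' @param counts non-negative integer-valued vector.
#' @return A \linkS4class{MovementCountSeries}.
#' @export
movementCountSeries <- function(animalId, timestamps, counts) {
  if (!inherits(timestamps, "POSIXct"))
    timestamps <- as.POSIXct(timestamps, tz = "UTC")
  if (is.double(counts)) {
    if (any(abs(counts - round(counts)) > 1e-8, na.rm = TRUE))
      stop("counts must be integer-valued")
    counts <- as.integer(round(counts))
  }
  new("MovementCountSeries", animalId = animalId,
      timestamps = timestamps, counts = as.integer(counts))
}

#' Panel of nightly log activities
#'
#' Long-format container for the analysis panel: one log-transformed
#' nightly activity per animal per day, with the animal's radiation dose
#' and the day index relative to irradiation (day 0 = irradiation day).
#'
#' @slot data data.frame with columns \code{animal_id} (character),
#'   \code{dose_gy} (numeric, >= 0), \code{day} (integer) and
#'   \code{log_activity} (numeric), sorted by animal then day.
#' @export
setClass("ActivityPanel", representation(data = "data.frame"))

setValidity("ActivityPanel", function(object) {
  d <- object@data
  msgs <- character()
  need <- c("animal_id", "dose_gy", "day", "log_activity")
  if (!all(need %in% names(d)))
    return(paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  if (nrow(d) == 0L)
    msgs <- c(msgs, "panel is empty")
  if (anyDuplicated(d[c("animal_id", "day")]))
    msgs <- c(msgs, "duplicate (animal_id, day) cells")
  doseByAnimal <- tapply(d$dose_gy, d$animal_id, function(x) length(unique(x)))
  if (any(doseByAnimal != 1L))
    msgs <- c(msgs, "each animal must have exactly one dose")
  if (any(d$dose_gy < 0))
    msgs <- c(msgs, "doses must be >= 0 Gy")
  if (any(d$day != round(d$day)))
    msgs <- c(msgs, "day must be integer-valued")
  if (any(!is.finite(d$log_activity)))
    msgs <- c(msgs, "log_activity must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct an ActivityPanel
#'
#' @param data data.frame with columns \code{animal_id}, \code{dose_gy},
#'   \code{day}, \code{log_activity}.
#' @param checkDays warn when an animal's day range has gaps (the standard
#'   design is a contiguous -3..20). Gapped (unbalanced) panels are
#'   supported throughout; the warning is only a data-quality flag.
#' @return An \linkS4class{ActivityPanel}.
#' @export
activityPanel <- function(data, checkDays = TRUE) {
  data <- as.data.frame(data)
  data$animal_id <- as.character(data$animal_id)
  data$dose_gy <- as.numeric(data$dose_gy)
  data$day <- as.integer(round(data$day))
  data <- data[order(data$animal_id, data$day),
               c("animal_id", "dose_gy", "day", "log_activity")]
  rownames(data) <- NULL
  obj <- new("ActivityPanel", data = data)
  if (checkDays) {
    gaps <- tapply(data$day, data$animal_id,
                   function(d) length(d) != diff(range(d)) + 1L)
    if (any(gaps))
      warning("non-contiguous day range for animal(s): ",
              paste(names(gaps)[gaps], collapse = ", "))
  }
  obj
}

#' Model specification: which optional parameters are free
#'
#' The baseline parameters \code{xi0}, \code{beta1}, \code{omega1} and the
#' error variance \code{sigma2} are always estimated. The four optional
#' terms (\code{xi1}, \code{xi2}, \code{beta2}, \code{omega2}) can each be
#' fixed to zero, and \code{mixed = FALSE} switches off the crossed random
#' effects (\code{psi2 = phi2 = 0}), reducing the mixed model (NLMM) to an
#' ordinary non-linear regression model (NLRM).
#'
#' @slot freeXi1,freeXi2,freeBeta2,freeOmega2 logical flags.
#' @slot mixed logical; TRUE for the NLMM, FALSE for the NLRM.
#' @export
setClass("ModelSpec",
  representation(freeXi1 = "logical", freeXi2 = "logical",
                 freeBeta2 = "logical", freeOmega2 = "logical",
                 mixed = "logical"),
  prototype(freeXi1 = TRUE, freeXi2 = TRUE, freeBeta2 = TRUE,
            freeOmega2 = TRUE, mixed = TRUE))

setValidity("ModelSpec", function(object) {
  flags <- c(object@freeXi1, object@freeXi2, object@freeBeta2,
             object@freeOmega2, object@mixed)
  if (length(flags) != 5L || any(is.na(flags)))
    "all flags must be single non-missing logicals"
  else TRUE
})

#' Construct a ModelSpec
#'
#' @param freeXi1,freeXi2 free the linear / quadratic baseline day trend.
#' @param freeBeta2 free the quadratic dose term of the initial decrease.
#' @param freeOmega2 free the dose dependence of the recovery rate.
#' @param mixed TRUE for the mixed model (crossed animal and day random
#'   effects), FALSE for ordinary non-linear regression.
#' @return A \linkS4class{ModelSpec}.
#' @examples
#' fullModel()            # all seven fixed effects, mixed
#' optimalModel()         # xi0, beta1, beta2, omega1 free, mixed
#' @export
modelSpec <- function(freeXi1 = TRUE, freeXi2 = TRUE, freeBeta2 = TRUE,
                      freeOmega2 = TRUE, mixed = TRUE) {
  new("ModelSpec", freeXi1 = freeXi1, freeXi2 = freeXi2,
      freeBeta2 = freeBeta2, freeOmega2 = freeOmega2, mixed = mixed)
}

#' @rdname modelSpec
#' @export
fullModel <- function(mixed = TRUE) modelSpec(TRUE, TRUE, TRUE, TRUE, mixed)

#' @rdname modelSpec
#' @export
optimalModel <- function(mixed = TRUE)
  modelSpec(freeXi1 = FALSE, freeXi2 = FALSE, freeBeta2 = TRUE,
            freeOmega2 = FALSE, mixed = mixed)

#' Fitted activity model
#'
#' Result of maximum-likelihood estimation: parameter estimates on the
#' natural scale (dropped parameters stored as exact zeros), standard
#' errors, the fixed-effect covariance matrix, log-likelihood and
#' information criteria.
#'
#' @slot spec the \linkS4class{ModelSpec} that was fitted.
#' @slot theta named length-7 fixed-effect vector.
#' @slot delta named length-3 variance-component vector.
#' @slot D0 centering dose in Gy.
#' @slot se named standard errors for the free parameters (variance
#'   component entries are large-sample approximations).
#' @slot vcovFixed covariance matrix of the free fixed effects.
#' @slot logLik,aic,bic scalars.
#' @slot nObs,kParams counts.
#' @slot converged logical optimizer status.
#' @slot optim list with the optimizer trace summary.
#' @export
setClass("ActivityFit",
  representation(spec = "ModelSpec", theta = "numeric", delta = "numeric",
                 D0 = "numeric", se = "numeric", vcovFixed = "matrix",
                 logLik = "numeric", aic = "numeric", bic = "numeric",
                 nObs = "integer", kParams = "integer",
                 converged = "logical", optim = "list"))

setValidity("ActivityFit", function(object) {
  msgs <- character()
  if (!identical(names(object@theta), FIXED_EFFECT_NAMES))
    msgs <- c(msgs, "theta must carry the seven fixed-effect names")
  if (!identical(names(object@delta), VARIANCE_NAMES))
    msgs <- c(msgs, "delta must carry (psi2, phi2, sigma2)")
  if (length(object@logLik) == 1L && is.finite(object@logLik)) {
    if (abs(object@aic - (-2 * object@logLik + 2 * object@kParams)) > 1e-6)
      msgs <- c(msgs, "AIC identity violated")
    if (abs(object@bic - (-2 * object@logLik +
                          object@kParams * log(object@nObs))) > 1e-6)
      msgs <- c(msgs, "BIC identity violated")
  }
  if (length(msgs)) msgs else TRUE
})

#' Posterior-mean random-effect predictions
#'
#' @slot deltaHat named per-animal posterior means (log-activity units).
#' @slot etaHat named per-day posterior means (log-activity units).
#' @slot residuals data.frame (animal_id, dose_gy, day, residual) of the
#'   per-cell measurement-error estimates.
#' @export
setClass("RandomEffectPredictions",
  representation(deltaHat = "numeric", etaHat = "numeric",
                 residuals = "data.frame"))

#' Simulation design for the synthetic-data generator
#'
#' Defaults reproduce the study layout: 4 dose groups (0, 2.0, 3.5,
#' 5.0 Gy) of 4 animals each, observed on days -3..20 around irradiation,
#' generated from the activity model at its published-scale parameter
#' values.
#'
#' @slot nPerGroup animals per dose group.
#' @slot doses dose levels in Gy.
#' @slot days integer day range.
#' @slot theta,delta generating parameters.
#' @slot D0 centering dose (Gy).
#' @slot seed integer root seed.
#' @export
setClass("SimulationDesign",
  representation(nPerGroup = "integer", doses = "numeric", days = "integer",
                 theta = "numeric", delta = "numeric", D0 = "numeric",
                 seed = "integer"))

setValidity("SimulationDesign", function(object) {
  msgs <- character()
  if (object@nPerGroup < 1L) msgs <- c(msgs, "nPerGroup must be >= 1")
  if (length(object@doses) < 1L) msgs <- c(msgs, "need at least one dose")
  if (length(object@days) < 2L) msgs <- c(msgs, "need at least two days")
  if (!identical(names(object@theta), FIXED_EFFECT_NAMES))
    msgs <- c(msgs, "theta must be a fixedEffects() vector")
  if (!identical(names(object@delta), VARIANCE_NAMES))
    msgs <- c(msgs, "delta must be a varianceComponents() vector")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SimulationDesign
#'
#' @param nPerGroup animals per dose group (default 4).
#' @param doses dose levels in Gy (default 0, 2.0, 3.5, 5.0).
#' @param days integer day range (default -3..20).
#' @param theta generating fixed effects; defaults to the published-scale
#'   estimates of the optimal mixed model (xi0 = 4.319, beta1 = 0.066,
#'   beta2 = -0.006, omega1 = 9.063).
#' @param delta generating variance components; default
#'   (0.0018, 0.0019, 0.0015).
#' @param D0 centering dose, default 2.75 Gy.
#' @param seed integer root seed; per-component streams (animal effects,
#'   day effects, errors, raw counts) are derived from it.
#' @return A \linkS4class{SimulationDesign}.
#' @export
simulationDesign <- function(nPerGroup = 4L,
                             doses = c(0, 2.0, 3.5, 5.0),
                             days = -3L:20L,
                             theta = fixedEffects(xi0 = 4.319, beta1 = 0.066,
                                                  beta2 = -0.006,
                                                  omega1 = 9.063),
                             delta = varianceComponents(0.0018, 0.0019, 0.0015),
                             D0 = 2.75, seed = 1L) {
  new("SimulationDesign", nPerGroup = as.integer(nPerGroup),
      doses = as.numeric(doses), days = as.integer(days),
      theta = .checkTheta(theta), delta = .checkDelta(delta),
      D0 = D0, seed = as.integer(seed))
}

#' Simulated panel with its generating truth
#'
#' @slot panel the simulated \linkS4class{ActivityPanel}.
#' @slot deltaTrue,etaTrue named true random-effect draws.
#' @slot epsTrue per-cell error draws, aligned with the panel rows.
#' @slot design the generating \linkS4class{SimulationDesign}.
#' @export
setClass("SimulatedTruth",
  representation(panel = "ActivityPanel", deltaTrue = "numeric",
                 etaTrue = "numeric", epsTrue = "numeric",
                 design = "SimulationDesign"))

setValidity("SimulatedTruth", function(object) {
  d <- object@panel@data
  mu <- meanActivity(d$day, d$dose_gy, object@design@theta, object@design@D0)
  recon <- mu + object@deltaTrue[d$animal_id] +
    object@etaTrue[as.character(d$day)] + object@epsTrue
  if (max(abs(recon - d$log_activity)) > 1e-10)
    "cell identity y = f + delta_i + eta_t + eps_it violated"
  else TRUE
})
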