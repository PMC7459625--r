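#' @include AllClasses.R
NULL

#' Animal identifiers in a panel or series collection
#' @param x object.
#' @return character vector of animal ids.
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))

#' Observed day indices
#' @param x object.
#' @return sorted integer vector of observed days.
#' @export
setGeneric("panelDays", function(x) standardGeneric("panelDays"))

#' Dose per animal
#' @param x object.
#' @return named numeric vector of doses (Gy), one per animal.
#' @export
setGeneric("doses", function(x) standardGeneric("doses"))

#' Long-format panel data
#' @param x object.
#' @return data.frame with columns animal_id, dose_gy, day, log_activity.
#' @export
setGeneric("panelData", function(x) standardGeneric("panelData"))

#' Animal-by-day matrix of log activities
#' @param x an ActivityPanel.
#' @return numeric matrix (animals in rows, days in columns) with NA for
#'   unobserved cells.
#' @export
setGeneric("activityMatrix", function(x) standardGeneric("activityMatrix"))

#' Estimated fixed effects of a fit
#' @param object an ActivityFit.
#' @return named length-7 numeric vector (dropped terms are exact zeros).
#' @export
setGeneric("fixedEstimates", function(object) standardGeneric("fixedEstimates"))

#' Estimated variance components of a fit
#' @param object an ActivityFit.
#' @return named vector (psi2, phi2, sigma2).
#' @export
setGeneric("varianceEstimates",
           function(object) standardGeneric("varianceEstimates"))

#' Model specification of a fit
#' @param object an ActivityFit.
#' @return the ModelSpec.
#' @export
setGeneric("fitSpec", function(object) standardGeneric("fitSpec"))

#' Optimizer convergence status
#' @param object an ActivityFit.
#' @return logical.
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))

#' Number of free parameters implied by a model specification
#' @param object a ModelSpec or ActivityFit.
#' @return integer count: free fixed effects plus 3 variance components for
#'   the mixed model, or 1 error variance for ordinary regression.
#' @export
setGeneric("nParams", function(object) standardGeneric("nParams"))

#' Names of the free fixed-effect parameters
#' @param object a ModelSpec.
#' @return character vector in canonical order.
#' @export
setGeneric("freeFixedEffects",
           function(object) standardGeneric("freeFixedEffects"))

# -- methods ----------------------------------------------------------------

#' @describeIn ActivityPanel animal identifiers.
#' @param x an ActivityPanel.
#' @export
setMethod("animalIds", "ActivityPanel",
          function(x) unique(x@data$animal_id))

#' @describeIn ActivityPanel sorted observed days.
#' @export
setMethod("panelDays", "ActivityPanel",
          function(x) sort(unique(x@data$day)))

#' @describeIn ActivityPanel dose (Gy) per animal, named by animal id.
#' @export
setMethod("doses", "ActivityPanel", function(x) {
  d <- x@data[!duplicated(x@data$animal_id), ]
  structure(d$dose_gy, names = d$animal_id)
})

#' @describeIn ActivityPanel the long-format data.frame.
#' @export
setMethod("panelData", "ActivityPanel", function(x) x@data)

#' @describeIn ActivityPanel animal-by-day matrix (NA = unobserved cell).
#' @export
setMethod("activityMatrix", "ActivityPanel", function(x) {
  d <- x@data
  animals <- unique(d$animal_id)
  days <- sort(unique(d$day))
  m <- matrix(NA_real_, length(animals), length(days),
              dimnames = list(animals, as.character(days)))
  m[cbind(match(d$animal_id, animals), match(d$day, days))] <- d$log_activity
  m
})

#' @export
setMethod("show", "ActivityPanel", function(object) {
  d <- object@data
  cat("ActivityPanel:", length(unique(d$animal_id)), "animals x",
      length(unique(d$day)), "days (", nrow(d), "cells )\n")
  cat("  doses (Gy):", paste(sort(unique(d$dose_gy)), collapse = ", "), "\n")
  cat("  days:", min(d$day), "..", max(d$day), "\n")
  cat("  log activity range:",
      sprintf("%.3f .. %.3f", min(d$log_activity), max(d$log_activity)), "\n")
})

#' @describeIn nParams count for a specification.
#' @export
setMethod("nParams", "ModelSpec", function(object) {
  3L + sum(object@freeXi1, object@freeXi2, object@freeBeta2,
           object@freeOmega2) + if (object@mixed) 3L else 1L
})

#' @describeIn freeFixedEffects canonical order xi0, xi1, xi2, beta1,
#'   beta2, omega1, omega2 restricted to the free terms.
#' @export
setMethod("freeFixedEffects", "ModelSpec", function(object) {
  keep <- c(TRUE, object@freeXi1, object@freeXi2, TRUE, object@freeBeta2,
            TRUE, object@freeOmega2)
  FIXED_EFFECT_NAMES[keep]
})

#' @export
setMethod("show", "ModelSpec", function(object) {
  cat(if (object@mixed) "Mixed" else "Ordinary-regression",
      "activity model spec\n")
  cat("  free fixed effects:", paste(freeFixedEffects(object), collapse = ", "),
      "\n")
  cat("  parameters:", nParams(object), "\n")
})

#' @describeIn ActivityFit estimated fixed effects (length 7).
#' @param object an ActivityFit.
#' @export
setMethod("fixedEstimates", "ActivityFit", function(object) object@theta)

#' @describeIn ActivityFit estimated variance components.
#' @export
setMethod("varianceEstimates", "ActivityFit", function(object) object@delta)

#' @describeIn ActivityFit the fitted specification.
#' @export
setMethod("fitSpec", "ActivityFit", function(object) object@spec)

#' @describeIn ActivityFit optimizer convergence flag.
#' @export
setMethod("converged", "ActivityFit", function(object) object@converged)

#' @describeIn nParams count for a fit.
#' @export
setMethod("nParams", "ActivityFit", function(object) object@kParams)

#' @describeIn ActivityFit log-likelihood with df and nobs attributes.
#' @export
setMethod("logLik", "ActivityFit", function(object, ...) {
  structure(object@logLik, df = object@kParams, nobs = object@nObs,
            class = "logLik")
})

#' Extract AIC / BIC from a fit
#' @param object an ActivityFit.
#' @param ... ignored.
#' @param k ignored (fixed at 2, the standard AIC penalty).
#' @return scalar.
#' @export
setMethod("AIC", "ActivityFit", function(object, ..., k = 2) object@aic)

#' @rdname AIC-ActivityFit-method
#' @export
setMethod("BIC", "ActivityFit", function(object, ...) object@bic)

#' @export
setMethod("nobs", "ActivityFit", function(object, ...) object@nObs)

#' @describeIn ActivityFit covariance matrix of the free fixed effects.
#' @export
setMethod("vcov", "ActivityFit", function(object, ...) object@vcovFixed)

#' @export
setMethod("show", "ActivityFit", function(object) {
  cat(if (object@spec@mixed) "Non-linear mixed effects fit (NLMM)"
      else "Non-linear regression fit (NLRM)", "\n")
  free <- freeFixedEffects(object@spec)
  est <- object@theta[free]
  se <- object@se[free]
  tab <- data.frame(estimate = round(est, 4), se = round(se, 4))
  print(tab)
  if (object@spec@mixed)
    cat(sprintf("  variance components: psi2 = %.4g, phi2 = %.4g, sigma2 = %.4g\n",
                object@delta[["psi2"]], object@delta[["phi2"]],
                object@delta[["sigma2"]]))
  else
    cat(sprintf("  residual variance: sigma2 = %.4g\n",
                object@delta[["sigma2"]]))
  cat(sprintf("  logLik %.3f | AIC %.2f | BIC %.2f | n = %d, k = %d%s\n",
              object@logLik, object@aic, object@bic, object@nObs,
              object@kParams,
              if (object@converged) "" else " | NOT CONVERGED"))
})

#' @export
setMethod("show", "RandomEffectPredictions", function(object) {
  cat("Random-effect predictions (posterior means)\n")
  cat("  animals:", length(object@deltaHat),
      sprintf("| sd(delta_hat) = %.4f\n", stats::sd(object@deltaHat)))
  cat("  days:", length(object@etaHat),
      sprintf("| sd(eta_hat) = %.4f\n", stats::sd(object@etaHat)))
  cat(sprintf("  residual sd = %.4f\n", stats::sd(object@residuals$residual)))
})

#' @export
setMethod("show", "SimulationDesign", function(object) {
  cat("SimulationDesign:", object@nPerGroup, "animals x",
      length(object@doses), "dose groups, days",
      min(object@days), "..", max(object@days), "\n")
  cat("  doses (Gy):", paste(object@doses, collapse = ", "),
      "| seed:", object@seed, "\n")
})
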