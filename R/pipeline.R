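#' @include simulate.R
NULL

#' Run configuration with documented defaults
#'
#' Merges a YAML configuration file (and/or an override list) over the
#' package defaults, which reproduce the standard analysis end to end:
#' centering dose 2.75 Gy, log base 10, night window 18:00-06:00, the
#' full mixed model, and the study simulation design. Precedence:
#' overrides > file > defaults.
#'
#' @param path optional YAML file path.
#' @param overrides optional named list applied last.
#' @return nested configuration list.
#' @export
runConfig <- function(path = NULL, overrides = list()) {
  defaults <- list(
    D0 = 2.75,
    logBase = 10,
    nightStart = "18:00",
    nightEnd = "06:00",
    seed = 1L,
    model = list(freeXi1 = TRUE, freeXi2 = TRUE, freeBeta2 = TRUE,
                 freeOmega2 = TRUE, mixed = TRUE),
    optimizer = list(maxit = 2000, factr = 1e4, restarts = 5),
    simulation = list(nPerGroup = 4L, doses = c(0, 2.0, 3.5, 5.0),
                      dayMin = -3L, dayMax = 20L),
    doses = c(0, 2.0, 3.5, 5.0))
  cfg <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  }
  utils::modifyList(cfg, overrides)
}

.configSpec <- function(cfg) {
  m <- cfg$model
  modelSpec(freeXi1 = isTRUE(m$freeXi1), freeXi2 = isTRUE(m$freeXi2),
            freeBeta2 = isTRUE(m$freeBeta2),
            freeOmega2 = isTRUE(m$freeOmega2), mixed = isTRUE(m$mixed))
}

.configDesign <- function(cfg) {
  s <- cfg$simulation
  simulationDesign(nPerGroup = s$nPerGroup, doses = s$doses,
                   days = seq(s$dayMin, s$dayMax), D0 = cfg$D0,
                   seed = cfg$seed)
}

.log <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(..., collapse = " ")))
}

#' Pipeline stage: simulate a panel
#'
#' Writes the simulated panel CSV (ingest dialect) and a truth JSON with
#' the generating parameters and the per-animal/per-day draws.
#'
#' @param config list from \code{\link{runConfig}}.
#' @param panelPath,truthPath output paths.
#' @return the \linkS4class{SimulatedTruth}, invisibly.
#' @export
cmdSimulate <- function(config = runConfig(), panelPath, truthPath = NULL) {
  design <- .configDesign(config)
  .log("simulate", "seed =", config$seed)
  truth <- simulatePanel(design)
  writeActivityPanel(truth@panel, panelPath)
  if (!is.null(truthPath)) {
    jsonlite::write_json(list(
      theta = as.list(design@theta), delta = as.list(design@delta),
      D0 = design@D0, seed = design@seed,
      delta_true = as.list(truth@deltaTrue),
      eta_true = as.list(truth@etaTrue)),
      truthPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(truth)
}

#' Pipeline stage: fit a model to a panel CSV
#'
#' Writes the parameter table CSV (estimate, SE, Wald bounds, one-sided
#' p) and a footer JSON (log-likelihood, AIC, BIC, variance components).
#'
#' @param config list from \code{\link{runConfig}}.
#' @param panelPath input panel CSV.
#' @param tablePath,footerPath output paths (optional).
#' @param spec optional \linkS4class{ModelSpec}; default from config.
#' @return the \linkS4class{ActivityFit}, invisibly.
#' @export
cmdFit <- function(config = runConfig(), panelPath, tablePath = NULL,
                   footerPath = NULL, spec = NULL) {
  panel <- readActivityPanel(panelPath)
  if (is.null(spec)) spec <- .configSpec(config)
  .log("fit", .specLabel(spec))
  fit <- fitActivityModel(panel, spec, D0 = config$D0,
                          control = config$optimizer)
  if (!is.null(tablePath))
    utils::write.csv(parameterTable(fit), tablePath, row.names = FALSE)
  if (!is.null(footerPath)) {
    footer <- list(loglik = fit@logLik, aic = fit@aic, bic = fit@bic,
                   n_obs = fit@nObs, k_params = fit@kParams,
                   converged = fit@converged,
                   sigma2 = fit@delta[["sigma2"]])
    if (spec@mixed) {
      footer$psi2 <- fit@delta[["psi2"]]
      footer$phi2 <- fit@delta[["phi2"]]
    }
    jsonlite::write_json(footer, footerPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(fit)
}

#' Pipeline stage: AIC model selection
#'
#' Fits all candidate specifications, writes the comparison table, and
#' the selected model's parameter table.
#'
#' @param config list from \code{\link{runConfig}}.
#' @param panelPath input panel CSV.
#' @param comparisonPath,bestTablePath output CSV paths (optional).
#' @return the \code{\link{selectModel}} result, invisibly.
#' @export
cmdSelect <- function(config = runConfig(), panelPath,
                      comparisonPath = NULL, bestTablePath = NULL) {
  panel <- readActivityPanel(panelPath)
  .log("select", "16 candidate specs, mixed =", config$model$mixed)
  sel <- selectModel(panel, candidateSpecs(mixed = isTRUE(config$model$mixed)),
                     D0 = config$D0, control = config$optimizer)
  if (!is.null(comparisonPath))
    utils::write.csv(sel$table, comparisonPath, row.names = FALSE)
  if (!is.null(bestTablePath))
    utils::write.csv(parameterTable(sel$best), bestTablePath,
                     row.names = FALSE)
  invisible(sel)
}

#' Pipeline stage: diagnostics and dose-response outputs
#'
#' For a mixed fit: random-effect CSVs (per animal and per day), the
#' long-format residual CSV, a residual summary, the Durbin-Watson check
#' on the day effects, and the dose-response table. For an ordinary
#' regression fit the random-effect outputs are skipped with a notice.
#'
#' @param config list from \code{\link{runConfig}}.
#' @param fit an \linkS4class{ActivityFit}.
#' @param panel the fitted \linkS4class{ActivityPanel}.
#' @param outDir output directory (created if missing); NULL to skip
#'   file output.
#' @return list with the computed diagnostics, invisibly.
#' @export
cmdDiagnose <- function(config = runConfig(), fit, panel, outDir = NULL) {
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  out <- list()
  if (fit@spec@mixed) {
    pred <- predictRandomEffects(fit, panel)
    out$predictions <- pred
    out$residualSummary <- residualSummary(pred)
    out$durbinWatson <- durbinWatson(pred@etaHat,
                                     seed = .deriveSeed(config$seed, 99L))
    out$varianceShares <- varianceShares(fit)
    if (!is.null(outDir)) {
      doseMap <- doses(panel)
      utils::write.csv(data.frame(animal_id = names(pred@deltaHat),
                                  dose_gy = doseMap[names(pred@deltaHat)],
                                  delta_hat = pred@deltaHat),
                       file.path(outDir, "animal_effects.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(day = as.integer(names(pred@etaHat)),
                                  eta_hat = pred@etaHat),
                       file.path(outDir, "day_effects.csv"),
                       row.names = FALSE)
      utils::write.csv(pred@residuals,
                       file.path(outDir, "residuals.csv"), row.names = FALSE)
    }
  } else {
    .log("diagnose", "ordinary regression fit: no random effects to predict")
    out$residualSummary <- residualSummary(marginalResiduals(fit, panel))
  }
  out$doseResponse <- doseResponseTable(fit, dose = config$doses)
  out$trends <- fittedTrend(fit, seq(min(panel@data$day),
                                     max(panel@data$day), by = 0.1),
                            config$doses)
  if (!is.null(outDir)) {
    utils::write.csv(out$doseResponse,
                     file.path(outDir, "dose_response.csv"),
                     row.names = FALSE)
    utils::write.csv(out$trends, file.path(outDir, "trends.csv"),
                     row.names = FALSE)
  }
  invisible(out)
}
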