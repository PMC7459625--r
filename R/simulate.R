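#' @include AllClasses.R
NULL

# Derived per-component seeds from a root seed, kept inside 32-bit range.
.deriveSeed <- function(root, stream) {
  as.integer((as.numeric(root) * 48271 + stream * 1000003) %% 2147483629)
}

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

#' Simulate an activity panel from the model
#'
#' Draws the crossed random effects and measurement errors from their
#' zero-mean normals (delta_i ~ N(0, psi2), eta_t ~ N(0, phi2),
#' eps_it ~ N(0, sigma2)) and assembles log activities by the exact cell
#' identity y = f(t | D) + delta_i + eta_t + eps_it. Animal effects, day
#' effects and errors come from separate streams derived from the root
#' seed, so the same design and seed always reproduce the same panel.
#'
#' @param design a \linkS4class{SimulationDesign}.
#' @return A \linkS4class{SimulatedTruth} holding the panel and the true
#'   draws.
#' @examples
#' truth <- simulatePanel(simulationDesign(seed = 1))
#' truth@panel
#' @export
simulatePanel <- function(design) {
  stopifnot(is(design, "SimulationDesign"))
  nA <- design@nPerGroup * length(design@doses)
  wid <- max(2L, nchar(as.character(nA)))
  animals <- sprintf(paste0("R%0", wid, "d"), seq_len(nA))
  doseByAnimal <- rep(design@doses, each = design@nPerGroup)
  days <- sort(design@days)
  nT <- length(days)
  deltaTrue <- .withSeed(.deriveSeed(design@seed, 1L),
    stats::rnorm(nA, 0, sqrt(design@delta[["psi2"]])))
  etaTrue <- .withSeed(.deriveSeed(design@seed, 2L),
    stats::rnorm(nT, 0, sqrt(design@delta[["phi2"]])))
  epsTrue <- .withSeed(.deriveSeed(design@seed, 3L),
    stats::rnorm(nA * nT, 0, sqrt(design@delta[["sigma2"]])))
  names(deltaTrue) <- animals
  names(etaTrue) <- as.character(days)
  grid <- data.frame(animal_id = rep(animals, each = nT),
                     dose_gy = rep(doseByAnimal, each = nT),
                     day = rep(days, times = nA))
  mu <- meanActivity(grid$day, grid$dose_gy, design@theta, design@D0)
  y <- mu + deltaTrue[grid$animal_id] + etaTrue[as.character(grid$day)] +
    epsTrue
  grid$log_activity <- as.numeric(y)
  new("SimulatedTruth", panel = activityPanel(grid),
      deltaTrue = deltaTrue, etaTrue = etaTrue,
      epsTrue = as.numeric(epsTrue), design = design)
}

#' Simulate raw circadian movement counts
#'
#' Generates minute-resolution counts for each animal from an
#' inhomogeneous Poisson process with a higher nocturnal rate: within
#' each night (18:00-06:00) the rate is set so the expected nightly
#' total equals \code{10^log_activity} from the panel, and the daytime
#' rate is a fixed fraction of the preceding night's rate. Feeding the
#' result through \code{\link{nightlyActivity}} and
#' \code{\link{toLogActivity}} recovers the panel up to Poisson count
#' noise.
#'
#' @param truth a \linkS4class{SimulatedTruth} (or any
#'   \linkS4class{ActivityPanel} via \code{panel =}).
#' @param panel optional panel overriding \code{truth@panel}.
#' @param dayNightRatio daytime rate as a fraction of the night rate
#'   (default 0.25; must be > 0 — the sensors always register some
#'   daytime movement).
#' @param irradiationDate calendar date of day 0 (default 2014-06-01).
#' @param seed integer; default derived from the design seed.
#' @return named list of \linkS4class{MovementCountSeries}.
#' @export
simulateRawCounts <- function(truth = NULL, panel = NULL,
                              dayNightRatio = 0.25,
                              irradiationDate = as.Date("2014-06-01"),
                              seed = NULL) {
  if (is.null(panel)) {
    stopifnot(is(truth, "SimulatedTruth"))
    panel <- truth@panel
    if (is.null(seed)) seed <- .deriveSeed(truth@design@seed, 4L)
  }
  if (is.null(seed)) seed <- 20140601L
  if (dayNightRatio <= 0)
    stop("dayNightRatio must be > 0")
  d <- panel@data
  if (any(10^d$log_activity < 1))
    stop("target log activity implies fewer than one expected count per night")
  irradiationDate <- as.Date(irradiationDate)
  .withSeed(seed, {
    out <- lapply(split(d, d$animal_id), function(dd) {
      dd <- dd[order(dd$day), ]
      # minutes from 18:00 of the first night to 06:00 after the last,
      # night (720 min) and following day (720 min) per panel day
      pieces <- lapply(seq_len(nrow(dd)), function(i) {
        nightRate <- 10^dd$log_activity[i] / 720
        nStart <- as.POSIXct(paste(irradiationDate + dd$day[i], "18:00:00"),
                             tz = "UTC")
        nightTs <- nStart + 60 * (0:719)
        dayTs <- nStart + 60 * (720:1439)
        last <- i == nrow(dd)
        list(ts = c(nightTs, if (!last) dayTs),
             rate = c(rep(nightRate, 720),
                      if (!last) rep(nightRate * dayNightRatio, 720)))
      })
      ts <- do.call(c, lapply(pieces, `[[`, "ts"))
      rate <- unlist(lapply(pieces, `[[`, "rate"))
      movementCountSeries(dd$animal_id[1], ts, stats::rpois(length(ts), rate))
    })
    out[order(names(out))]
  })
}

#' Parameter-recovery experiment
#'
#' Simulates replicate panels from a design, refits each with a given
#' specification, and aggregates per-parameter mean estimate, bias, SD,
#' RMSE, Monte-Carlo standard error of the mean, and 95% Wald-interval
#' coverage (fixed effects with available SEs). Non-converged replicates
#' are excluded and counted.
#'
#' @param design the generating \linkS4class{SimulationDesign}.
#' @param nReplicates number of replicates (>= 2).
#' @param spec specification to refit (default \code{optimalModel()}).
#' @param seed root seed; replicate r uses a seed derived from
#'   \code{seed} and r, so earlier replicates never reshuffle.
#' @param level coverage level (default 0.95).
#' @return list with \code{summary} (data.frame: parameter, truth, mean,
#'   bias, sd, rmse, mcse, coverage), \code{estimates} (replicate x
#'   parameter matrix), \code{nConverged}, \code{nExcluded}.
#' @export
recoveryExperiment <- function(design, nReplicates, spec = optimalModel(),
                               seed = design@seed, level = 0.95) {
  stopifnot(nReplicates >= 2)
  freeF <- freeFixedEffects(spec)
  vc <- if (spec@mixed) VARIANCE_NAMES else "sigma2"
  pars <- c(freeF, vc)
  est <- matrix(NA_real_, nReplicates, length(pars),
                dimnames = list(NULL, pars))
  cover <- matrix(NA, nReplicates, length(freeF),
                  dimnames = list(NULL, freeF))
  ok <- logical(nReplicates)
  z <- stats::qnorm(1 - (1 - level) / 2)
  for (r in seq_len(nReplicates)) {
    des <- design
    des@seed <- .deriveSeed(seed, 10L + r)
    sim <- simulatePanel(des)
    fit <- tryCatch(
      suppressWarnings(fitActivityModel(sim@panel, spec, D0 = design@D0)),
      error = function(e) NULL)
    if (is.null(fit) || !fit@converged) next
    ok[r] <- TRUE
    est[r, freeF] <- fit@theta[freeF]
    est[r, vc] <- fit@delta[vc]
    for (nm in freeF) {
      se <- if (length(fit@se)) fit@se[[nm]] else NA_real_
      if (is.finite(se) && se > 0) {
        truthVal <- design@theta[[nm]]
        cover[r, nm] <- abs(fit@theta[[nm]] - truthVal) <= z * se
      }
    }
  }
  est <- est[ok, , drop = FALSE]
  cover <- cover[ok, , drop = FALSE]
  truthAll <- c(design@theta[freeF], design@delta[vc])
  summary <- data.frame(
    parameter = pars,
    truth = as.numeric(truthAll),
    mean = colMeans(est),
    bias = colMeans(est) - as.numeric(truthAll),
    sd = apply(est, 2, stats::sd),
    rmse = sqrt(colMeans(sweep(est, 2, as.numeric(truthAll))^2)),
    mcse = apply(est, 2, stats::sd) / sqrt(nrow(est)),
    coverage = c(colMeans(cover, na.rm = TRUE),
                 rep(NA_real_, length(vc))))
  rownames(summary) <- NULL
  list(summary = summary, estimates = est,
       nConverged = sum(ok), nExcluded = sum(!ok))
}
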