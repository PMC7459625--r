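# A well-identified generating configuration for fitter unit tests:
# moderate recovery rate so the decrease is visible over several days.
testTheta <- fixedEffects(xi0 = 4.3, beta1 = 0.07, beta2 = -0.004,
                          omega1 = 0.8)

test_that("near-noiseless data recover the generating parameters", {
  des <- simulationDesign(theta = testTheta,
                          delta = varianceComponents(0, 0, 1e-10),
                          seed = 101)
  panel <- simulatePanel(des)@panel
  fit <- suppressWarnings(
    fitActivityModel(panel, optimalModel(), control = list(se = FALSE)))
  expect_true(converged(fit))
  est <- fixedEstimates(fit)
  expect_equal(est[["xi0"]], 4.3, tolerance = 1e-4)
  expect_equal(est[["beta1"]], 0.07, tolerance = 1e-3)
  expect_equal(est[["beta2"]], -0.004, tolerance = 1e-3)
  expect_equal(est[["omega1"]], 0.8, tolerance = 1e-2)
  expect_equal(est[["xi1"]], 0)  # dropped terms are exact zeros
})

test_that("mixed-model likelihood dominates the regression limit", {
  des <- simulationDesign(theta = testTheta, seed = 102)
  panel <- simulatePanel(des)@panel
  fitM <- fitActivityModel(panel, optimalModel(mixed = TRUE),
                           control = list(se = FALSE))
  fitR <- fitActivityModel(panel, optimalModel(mixed = FALSE),
                           control = list(se = FALSE))
  expect_true(converged(fitM) && converged(fitR))
  expect_gte(logLik(fitM), logLik(fitR))
  expect_equal(varianceEstimates(fitR)[["psi2"]], 0)
  # information-criterion identities (also enforced by class validity)
  expect_equal(AIC(fitM), -2 * as.numeric(logLik(fitM)) + 2 * nParams(fitM))
  expect_equal(BIC(fitM),
               -2 * as.numeric(logLik(fitM)) + nParams(fitM) * log(nobs(fitM)))
})

test_that("refitting from the solution is stable and order-invariant", {
  des <- simulationDesign(theta = testTheta, seed = 103)
  panel <- simulatePanel(des)@panel
  fit <- fitActivityModel(panel, optimalModel(), control = list(se = FALSE))
  refit <- fitActivityModel(panel, optimalModel(), control = list(se = FALSE),
                            init = list(theta = fixedEstimates(fit),
                                        delta = varianceEstimates(fit)))
  expect_lt(abs(-2 * (refit@logLik - fit@logLik)), 1e-6)
  d <- panelData(panel)
  shuffled <- activityPanel(d[rev(seq_len(nrow(d))), ])
  fit2 <- fitActivityModel(shuffled, optimalModel(),
                           control = list(se = FALSE))
  expect_equal(fixedEstimates(fit2), fixedEstimates(fit), tolerance = 1e-8)
  # fixing variance components at their estimates reproduces theta
  prof <- fitActivityModel(panel, optimalModel(), control = list(se = FALSE),
                           init = list(theta = fixedEstimates(fit),
                                       delta = varianceEstimates(fit)))
  expect_equal(fixedEstimates(prof)[c("xi0", "beta1", "beta2")],
               fixedEstimates(fit)[c("xi0", "beta1", "beta2")],
               tolerance = 1e-5)
})

test_that("single-dose designs are rejected", {
  d <- expand.grid(animal_id = c("a", "b"), day = -1:3,
                   stringsAsFactors = FALSE)
  d$dose_gy <- 2
  d$log_activity <- rnorm(nrow(d), 4, 0.1)
  expect_error(fitActivityModel(activityPanel(d), optimalModel()),
               "dose groups")
})

test_that("standard errors are available and coherent for identified directions", {
  des <- simulationDesign(theta = testTheta, seed = 104)
  panel <- simulatePanel(des)@panel
  fit <- fitActivityModel(panel, optimalModel())
  se <- fit@se
  expect_true(all(is.finite(se[c("xi0", "beta1", "beta2", "omega1")])))
  expect_true(all(se[c("xi0", "beta1")] > 0))
  V <- vcov(fit)
  expect_equal(V, t(V))
  expect_equal(sqrt(diag(V)), se[colnames(V)], tolerance = 1e-6)
  # standalone recomputation matches the slots
  se2 <- standardErrors(fit, panel)
  expect_equal(as.numeric(se2), as.numeric(se), tolerance = 1e-6)
})

test_that("Wald intervals and one-sided p-values reproduce printed-style arithmetic", {
  ci <- waldInterval(9.063, 2.949)
  expect_equal(round(ci[["lower"]], 3), 3.283)
  expect_equal(round(ci[["upper"]], 3), 14.843)
  expect_equal(waldInterval(0, 1), c(lower = -1.959964, upper = 1.959964),
               tolerance = 1e-6)
  ci2 <- waldInterval(0.066, 0.016)
  expect_equal(round(ci2, 3), c(lower = 0.035, upper = 0.097))
  expect_equal(oneSidedP(0.082, 0.166), 0.310, tolerance = 0.002 / 0.310)
  expect_equal(oneSidedP(0, 1), 0.5)
  expect_equal(oneSidedP(-0.008, 0.022), 0.358, tolerance = 1e-3)
  expect_equal(oneSidedP(-0.008, 0.022), oneSidedP(0.008, 0.022))
  expect_error(waldInterval(1, 0), "se")
})

test_that("parameter table carries estimates, intervals and p-values", {
  des <- simulationDesign(theta = testTheta, seed = 105)
  panel <- simulatePanel(des)@panel
  fit <- fitActivityModel(panel, optimalModel())
  tab <- parameterTable(fit)
  expect_equal(tab$parameter, c("xi0", "beta1", "beta2", "omega1"))
  ok <- is.finite(tab$se)
  expect_true(all(tab$ci_lower[ok] <= tab$estimate[ok]))
  expect_true(all(tab$ci_upper[ok] >= tab$estimate[ok]))
  expect_true(all(tab$p_value[ok] <= 0.5))
})

test_that("AIC selection returns the smallest-AIC converged candidate", {
  des <- simulationDesign(theta = testTheta, seed = 106)
  panel <- simulatePanel(des)@panel
  sel <- selectModel(panel)
  expect_equal(nrow(sel$table), 16)
  expect_equal(sel$table$aic, sort(sel$table$aic))
  expect_equal(sel$table$aic, -2 * sel$table$loglik + 2 * sel$table$k)
  expect_equal(AIC(sel$best), min(sel$table$aic))
  # nesting: the full model dominates every submodel's likelihood
  full <- sel$fits[["NLMM:xi1+xi2+beta2+omega2"]]
  expect_true(all(full@logLik >= sel$table$loglik - 1e-6))
  # the selected fit carries standard errors
  expect_true(any(is.finite(sel$best@se)))
})

test_that("information criteria helper implements the standard formulas", {
  ic <- informationCriteria(100, k = 5, n = 50)
  expect_equal(ic[["aic"]], -190)
  expect_equal(ic[["bic"]], -200 + 5 * log(50))
})
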