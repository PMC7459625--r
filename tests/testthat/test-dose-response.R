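# Fit with hand-set estimates and covariance for closed-form checks.
publishedFit <- function() {
  p <- simulatePanel(simulationDesign(seed = 501))@panel
  th <- fixedEffects(xi0 = 4.319, beta1 = 0.066, beta2 = -0.006,
                     omega1 = 9.063)
  V <- matrix(c(2.56e-4, -4.0e-5, NA, NA,
                -4.0e-5, 9.0e-6, NA, NA,
                NA, NA, NA, NA, NA, NA, NA, NA), 4, 4,
              dimnames = list(c("beta1", "beta2", "xi0", "omega1"),
                              c("beta1", "beta2", "xi0", "omega1")))
  makeFitAt(p, th, varianceComponents(0.0018, 0.0019, 0.0015),
            spec = optimalModel(), vcovFixed = V[c("xi0", "beta1", "beta2",
                                                   "omega1"),
                                                 c("xi0", "beta1", "beta2",
                                                   "omega1")])
}

test_that("initial decrease follows the quadratic dose form with delta-method CIs", {
  fit <- publishedFit()
  dr <- initialDecrease(c(0, 2, 3.5, 5), fit)
  expect_equal(dr$decrease, 0.066 * c(0, 2, 3.5, 5) -
                 0.006 * c(0, 2, 3.5, 5)^2)
  expect_equal(dr$decrease[4], 0.18)
  # dose 0: exactly zero with zero-width interval
  expect_equal(dr$decrease[1], 0)
  expect_equal(dr$ci_lower[1], 0)
  expect_equal(dr$ci_upper[1], 0)
  expect_true(all(dr$ci_lower <= dr$decrease & dr$decrease <= dr$ci_upper))
  # delta-method SE at D: sqrt(D^2 v11 + 2 D^3 v12 + D^4 v22)
  D <- 3.5
  V <- vcov(fit)[c("beta1", "beta2"), c("beta1", "beta2")]
  seExp <- sqrt(D^2 * V[1, 1] + 2 * D^3 * V[1, 2] + D^4 * V[2, 2])
  expect_equal(dr$se[3], seExp)
})

test_that("decrease-dose curvature has the sign of beta2", {
  fit <- publishedFit()
  dgrid <- c(1, 2, 3)
  dec <- initialDecrease(dgrid, fit)$decrease
  secondDiff <- dec[3] - 2 * dec[2] + dec[1]
  expect_equal(sign(secondDiff), sign(2 * fixedEstimates(fit)[["beta2"]]))
})

test_that("recovery rate centers at D0 and responds to omega2", {
  fit <- publishedFit()
  expect_equal(recoveryRate(2.75, fit), 9.063)           # D = D0
  expect_equal(recoveryRate(0, fit), recoveryRate(5, fit))  # omega2 = 0
  th2 <- fixedEffects(xi0 = 4.3, beta1 = 0.07, omega1 = 2, omega2 = 0.5)
  fit2 <- makeFitAt(simulatePanel(simulationDesign(seed = 502))@panel,
                    th2, varianceComponents(0.001, 0.001, 0.001))
  rates <- recoveryRate(c(0, 2, 4), fit2)
  expect_true(all(diff(rates) < 0))                      # decreasing in dose
  expect_equal(rates[2], 2 * exp(-0.5 * (2 - 2.75)))
})

test_that("fitted trends jump by the initial decrease and decay to baseline", {
  fit <- publishedFit()
  tr0 <- fittedTrend(fit, seq(-3, 20, 0.5), 0)
  # control curve: a single polynomial, symmetric around irradiation here
  expect_equal(tr0$fitted, rep(4.319, nrow(tr0)))
  tr5 <- fittedTrend(fit, c(-1e-9, 0, 15), 5)
  expect_equal(tr5$fitted[1] - tr5$fitted[2], 0.18, tolerance = 1e-6)
  expect_equal(tr5$fitted[3], 4.319, tolerance = 1e-6)   # recovered
  # one curve per dose
  tr <- fittedTrend(fit, 0:2, c(0, 5))
  expect_equal(nrow(tr), 6)
})

test_that("recovery time follows the closed exponential form", {
  fit <- publishedFit()
  expect_equal(recoveryTime(5, fit, fraction = 1), 0)
  expect_equal(recoveryTime(5, fit), -log(0.05) / 9.063)
  th <- fixedEffects(xi0 = 4.3, beta1 = 0.07, omega1 = 9.063 / 7)
  fitSlow <- makeFitAt(simulatePanel(simulationDesign(seed = 503))@panel,
                       th, varianceComponents(0.001, 0.001, 0.001))
  expect_equal(recoveryTime(5, fitSlow), 2.314, tolerance = 1e-3)
  # halving the rate doubles the time
  thHalf <- th; thHalf[["omega1"]] <- th[["omega1"]] / 2
  fitHalf <- makeFitAt(simulatePanel(simulationDesign(seed = 503))@panel,
                       thHalf, varianceComponents(0.001, 0.001, 0.001))
  expect_equal(recoveryTime(5, fitHalf), 2 * recoveryTime(5, fitSlow))
  # degenerate requests are errors
  thNeg <- fixedEffects(xi0 = 4, beta1 = -0.01, omega1 = 1)
  fitNeg <- makeFitAt(simulatePanel(simulationDesign(seed = 504))@panel,
                      thNeg, varianceComponents(0.001, 0.001, 0.001))
  expect_error(recoveryTime(5, fitNeg), "positive")
})

test_that("delta-method intervals agree with a parametric bootstrap", {
  des <- simulationDesign(
    theta = fixedEffects(xi0 = 4.3, beta1 = 0.07, beta2 = -0.004,
                         omega1 = 0.8),
    seed = 505)
  panel <- simulatePanel(des)@panel
  fit <- fitActivityModel(panel, optimalModel())
  dr <- initialDecrease(3.5, fit)
  boot <- vapply(1:120, function(b) {
    desB <- simulationDesign(
      theta = fixedEstimates(fit),
      delta = do.call(varianceComponents,
                      as.list(varianceEstimates(fit))),
      seed = 9000 + b)
    fb <- suppressWarnings(
      fitActivityModel(simulatePanel(desB)@panel, optimalModel(),
                       control = list(se = FALSE)))
    est <- fixedEstimates(fb)
    est[["beta1"]] * 3.5 + est[["beta2"]] * 3.5^2
  }, numeric(1))
  seBoot <- sd(boot)
  expect_equal(dr$se, seBoot, tolerance = 0.2)
  ciBoot <- quantile(boot, c(0.025, 0.975)) - mean(boot) + dr$decrease
  expect_equal(unname(ciBoot[1]), dr$ci_lower, tolerance = 0.15)
  expect_equal(unname(ciBoot[2]), dr$ci_upper, tolerance = 0.15)
})

test_that("observed group decreases are reconstructed from day-0 means", {
  des <- simulationDesign(seed = 506)
  panel <- simulatePanel(des)@panel
  fit <- fitActivityModel(panel, optimalModel(), control = list(se = FALSE))
  od <- observedDecreases(fit, panel)
  expect_equal(od$dose, c(0, 2, 3.5, 5))
  # higher doses show larger observed drops on average at these settings
  expect_gt(od$observed_decrease[4], od$observed_decrease[1])
})
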