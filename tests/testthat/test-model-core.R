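test_that("heaviside switches exactly at the irradiation day", {
  expect_identical(heaviside(c(-3, -1, -1e-9)), c(0, 0, 0))
  expect_identical(heaviside(c(0, 1e-9, 20)), c(1, 1, 1))
})

test_that("mean function reduces to the baseline polynomial where expected", {
  th <- fixedEffects(xi0 = 4.2, xi1 = 0.02, xi2 = -0.003, beta1 = 0.07,
                     beta2 = -0.004, omega1 = 1.5, omega2 = 0.2)
  # pre-irradiation: decrease term off regardless of dose
  expect_equal(meanActivity(-2, 5, th), 4.2 - 2 * 0.02 + 4 * (-0.003))
  # controls: no decrease at any time
  expect_equal(meanActivity(5, 0, th), 4.2 + 5 * 0.02 + 25 * (-0.003))
  # jump at t = 0 equals the initial decrease
  D <- 3.5
  jump <- meanActivity(-1e-12, D, th) - meanActivity(0, D, th)
  expect_equal(jump, 0.07 * D - 0.004 * D^2, tolerance = 1e-9)
  # dose-independent recovery when omega2 = 0
  th0 <- fixedEffects(xi0 = 4, beta1 = 0.05, omega1 = 2, omega2 = 0)
  d1 <- 4 - meanActivity(3, 2, th0)
  d2 <- 4 - meanActivity(3, 2, th0, D0 = 5)  # centering irrelevant
  expect_equal(d1, d2)
})

test_that("mean function matches hand evaluation at published-scale values", {
  th <- fixedEffects(xi0 = 4.319, beta1 = 0.066, beta2 = -0.006,
                     omega1 = 9.063)
  expect_equal(meanActivity(0, 5, th), 4.319 - (0.066 * 5 - 0.006 * 25))
  expect_equal(meanActivity(0, 5, th), 4.139)
})

test_that("covariance entries follow the crossed random-effects rule", {
  dl <- varianceComponents(1, 2, 4)
  d1 <- data.frame(animal_id = "a", day = 0L)
  expect_equal(covarianceMatrix(d1, dl), matrix(7), ignore_attr = TRUE)
  d2 <- expand.grid(animal_id = c("a", "b"), day = 0:1,
                    stringsAsFactors = FALSE)
  Om <- covarianceMatrix(d2, dl)
  same_animal <- outer(d2$animal_id, d2$animal_id, "==")
  same_day <- outer(d2$day, d2$day, "==")
  expect_equal(Om[same_animal & same_day], rep(7, 4))       # diagonal
  expect_equal(Om[same_animal & !same_day], rep(1, 4))      # psi2 only
  expect_equal(Om[!same_animal & same_day], rep(2, 4))      # phi2 only
  expect_equal(Om[!same_animal & !same_day], rep(0, 4))
})

test_that("entrywise covariance equals the Kronecker construction on the full design", {
  dl <- varianceComponents(0.0018, 0.0019, 0.0015)
  d <- expand.grid(day = -3:20, animal_id = sprintf("R%02d", 1:16),
                   stringsAsFactors = FALSE)[, c("animal_id", "day")]
  Om <- covarianceMatrix(d, dl)
  J <- function(m) matrix(1, m, m)
  OmKron <- kronecker(diag(16), dl[["psi2"]] * J(24) +
                        dl[["sigma2"]] * diag(24)) +
    dl[["phi2"]] * kronecker(J(16), diag(24))
  expect_equal(max(abs(Om - OmKron)), 0)
})

test_that("covariance is symmetric positive definite over the parameter space", {
  for (s in 1:20) {
    dl <- randomDelta(300 + s)
    p <- randomPanel(3, 4, 400 + s)
    Om <- covarianceMatrix(panelData(p), dl)
    expect_equal(Om, t(Om))
    expect_no_error(chol(Om))
  }
})

test_that("log-likelihood agrees with the dense brute-force oracle", {
  for (s in 1:12) {
    p <- randomPanel(3, 4, s)
    th <- randomTheta(100 + s)
    dl <- randomDelta(200 + s)
    ll <- panelLogLik(p, th, dl)
    expect_equal(ll, bruteLogLik(p, th, dl), tolerance = 1e-10)
    # and the two internal paths agree on balanced panels
    expect_equal(panelLogLik(p, th, dl, method = "balanced"),
                 panelLogLik(p, th, dl, method = "dense"),
                 tolerance = 1e-10)
  }
  # unbalanced panels use the dense path and still match the oracle
  pu <- randomPanel(4, 5, 77, dropCells = 4)
  th <- randomTheta(7); dl <- randomDelta(8)
  expect_equal(panelLogLik(pu, th, dl), bruteLogLik(pu, th, dl),
               tolerance = 1e-10)
  expect_error(panelLogLik(pu, th, dl, method = "balanced"), "unbalanced")
})

test_that("NLRM limit equals the sum of univariate normal densities", {
  p <- randomPanel(3, 5, 11)
  th <- randomTheta(12)
  dl <- varianceComponents(0, 0, 0.004)
  d <- panelData(p)
  r <- d$log_activity - meanActivity(d$day, d$dose_gy, th)
  expect_equal(panelLogLik(p, th, dl),
               sum(stats::dnorm(r, 0, sqrt(0.004), log = TRUE)),
               tolerance = 1e-12)
})

test_that("zero residuals leave only the normalization and determinant", {
  th <- randomTheta(21)
  dl <- randomDelta(22)
  d <- expand.grid(animal_id = c("a", "b", "c"), day = -1:2,
                   stringsAsFactors = FALSE)
  d$dose_gy <- c(0, 2, 5)[match(d$animal_id, c("a", "b", "c"))]
  d$log_activity <- meanActivity(d$day, d$dose_gy, th)
  p <- activityPanel(d)
  Om <- covarianceMatrix(panelData(p), dl)
  n <- nrow(panelData(p))
  expect_equal(panelLogLik(p, th, dl),
               -0.5 * as.numeric(determinant(Om)$modulus) -
                 (n / 2) * log(2 * pi),
               tolerance = 1e-12)
})

test_that("Q objective is -2 logLik with the diagonal closed form", {
  p <- randomPanel(2, 4, 31)
  th <- randomTheta(32)
  dl <- randomDelta(33)
  expect_equal(qObjective(p, th, dl) + 2 * panelLogLik(p, th, dl), 0)
  # diagonal case: Q = n log(2 pi) + n log(sigma2) + RSS / sigma2
  dln <- varianceComponents(0, 0, 0.002)
  d <- panelData(p)
  rss <- sum((d$log_activity - meanActivity(d$day, d$dose_gy, th))^2)
  n <- nrow(d)
  expect_equal(qObjective(p, th, dln),
               n * log(2 * pi) + n * log(0.002) + rss / 0.002,
               tolerance = 1e-10)
  # perturbing y away from the mean increases Q
  d2 <- d
  d2$log_activity <- meanActivity(d2$day, d2$dose_gy, th)
  base <- qObjective(activityPanel(d2), th, dl)
  d2$log_activity[3] <- d2$log_activity[3] + 0.5
  expect_gt(qObjective(activityPanel(d2), th, dl), base)
})

test_that("degenerate variance components are rejected by name", {
  expect_error(varianceComponents(-0.1, 0, 0.001), "psi2")
  expect_error(varianceComponents(0, 0, 0), "sigma2")
})
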