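test_that("peak finding interpolates and enforces minimum separation", {
  t <- seq(0, 96, by = 0.25)
  x <- cos(2 * pi * (t - 3.1) / 24)
  pk <- findPeaks(t, x)
  expect_equal(nrow(pk), 4)
  expect_equal(pk$time, c(3.1, 27.1, 51.1, 75.1), tolerance = 1e-3)
  # two nearby bumps: only the larger survives the 12-h separation rule
  y <- exp(-(t - 30)^2 / 4) + 0.5 * exp(-(t - 36)^2 / 4)
  pk2 <- findPeaks(t, y)
  expect_equal(nrow(pk2), 1)
  expect_equal(pk2$time, 30, tolerance = 0.05)
})

test_that("classification identifies sustained, damped and flat series", {
  t <- seq(0, 240, by = 0.25)
  sus <- classifyRhythm(t, 5 + 2 * cos(2 * pi * t / 23.5))
  expect_equal(sus$classification, "sustained")
  expect_equal(sus$period, 23.5, tolerance = 0.01)
  dam <- classifyRhythm(t, 5 + 2 * exp(-0.01 * t) * cos(2 * pi * t / 23.5))
  expect_equal(dam$classification, "damped")
  expect_equal(dam$damping_rate, 0.01, tolerance = 0.002)
  expect_equal(classifyRhythm(t, rep(3, length(t)))$classification,
               "arrhythmic")
  # monotone relaxation has no repeated peaks
  expect_equal(classifyRhythm(t, 5 * exp(-0.05 * t))$classification,
               "arrhythmic")
})

test_that("wild-type reduced model sustains a ~23.8 h rhythm", {
  v <- cachedWtVerdict()
  expect_equal(v$classification, "sustained")
  expect_equal(v$period, 23.8, tolerance = 0.1 / 23.8)
  expect_gt(v$relative_amplitude, 0.1)
})

test_that("period estimates are robust to tolerance tightening", {
  m <- cachedWtModel()
  v1 <- findCycle(m, settleDays = 20, observeDays = 10, rtol = 1e-8,
                  atol = 1e-10)
  v2 <- findCycle(m, settleDays = 20, observeDays = 10, rtol = 1e-9,
                  atol = 1e-11)
  expect_lt(abs(v1$period - v2$period), 0.01)
})

test_that("removing all repression channels abolishes rhythmicity", {
  m <- buildReducedModel(list(chrono_enabled = FALSE))
  m <- applyPerturbation(m, "Cry1:ko,Cry2:ko")
  v <- findCycle(m, settleDays = 20, observeDays = 10)
  expect_equal(v$classification, "arrhythmic")
})

test_that("uniform rate scaling rescales the period exactly", {
  m <- cachedWtModel()
  p0 <- cachedWtVerdict()$period
  m2 <- scaleModelRates(m, 2)
  v2 <- findCycle(m2, settleDays = 20, observeDays = 10)
  expect_equal(v2$period, p0 / 2, tolerance = 0.02 / p0)
})

test_that("calibration hits the target period and is idempotent", {
  m <- cachedWtModel()
  cal <- calibratePeriod(m, targetPeriod = 22, settleDays = 20)
  v <- findCycle(cal, settleDays = 20, observeDays = 10)
  expect_equal(v$period, 22, tolerance = 0.02 / 22)
  # scaling factor 1: measured period already equals the target
  same <- calibratePeriod(m, targetPeriod = cachedWtVerdict()$period,
                          settleDays = 20)
  expect_equal(parameterValues(same), parameterValues(m),
               tolerance = 1e-3)
  expect_error(calibratePeriod(applyPerturbation(
    buildReducedModel(list(chrono_enabled = FALSE)), "Cry1:ko,Cry2:ko"),
    settleDays = 20), "not sustained")
})

test_that("an empty perturbation list reproduces the wild-type verdict", {
  m <- cachedWtModel()
  res <- runGenotype(m, list(), days = 40, wtState = cachedWtState())
  expect_equal(res$verdict$classification, "sustained")
  expect_equal(res$verdict$period, cachedWtVerdict()$period,
               tolerance = 0.02 / 23.8)
})
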