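test_that("periodogram peaks at the true period of a square wave", {
  # deterministic square wave, period 24 h, 6-min bins, 12 days
  bw <- 0.1
  t <- seq(0, 12 * 24 - bw, by = bw)
  x <- as.numeric((t %% 24) >= 12)
  pg <- chiSquaredPeriodogram(x, binWidth = bw)
  expect_equal(pg$best_period, 24)
  i24 <- which(pg$test_periods == 24)
  # the matched fold of a deterministic rhythm attains the maximum
  # K*N*(between-variance/total-variance) = K*N
  K <- 240; N <- length(x) %/% K
  expect_equal(pg$Qp[i24], K * N)
  expect_equal(pg$Qp[i24], max(pg$Qp))
  expect_gt(pg$Qp[i24], pg$significance_line[i24])
})

test_that("a constant series gives Qp = 0 everywhere and no best period", {
  pg <- chiSquaredPeriodogram(rep(5, 24 * 10 * 10), binWidth = 0.1)
  expect_true(all(pg$Qp == 0))
  expect_true(is.na(pg$best_period))
})

test_that("bin width must divide the period grid step", {
  expect_error(chiSquaredPeriodogram(rnorm(7000), binWidth = 0.1,
                                     periodStep = 0.25),
               "divide")
})

test_that("synthetic actogram period is recovered within one grid step", {
  act <- genActogram(period = 23.8, daysLD = 0, daysDD = 14,
                     meanRate = 2, nocturnality = 5, seed = 11)
  counts6 <- rebinCounts(act, 6)
  pg <- chiSquaredPeriodogram(counts6, binWidth = 0.1)
  expect_lte(abs(pg$best_period - 23.8), 0.1 + 1e-9)
})

test_that("free-running period estimation uses the first week of DD", {
  act <- genActogram(period = 23.96, daysLD = 7, daysDD = 10,
                     meanRate = 2, nocturnality = 5, seed = 5)
  rs <- estimateFreeRunningPeriod(act, windowDays = 7)
  expect_true(rs$rhythmic)
  expect_lte(abs(rs$period - 23.96), 0.1 + 1e-9)
  # stability: 6-day window agrees within one grid step
  rs6 <- estimateFreeRunningPeriod(act, windowDays = 6)
  expect_lte(abs(rs6$period - rs$period), 0.1 + 1e-9)
})

test_that("an LD-entrained segment is masked to 24 h", {
  act <- genActogram(period = 23.0, daysLD = 10, daysDD = 0,
                     meanRate = 2, nocturnality = 5, seed = 3)
  counts6 <- rebinCounts(act, 6)
  pg <- chiSquaredPeriodogram(counts6, binWidth = 0.1)
  expect_lte(abs(pg$best_period - 24), 0.1 + 1e-9)
  expect_error(estimateFreeRunningPeriod(act), "no DD segment")
})

test_that("null calibration: type-I rate at a pre-registered period is ~ alpha", {
  # homogeneous Poisson noise has no rhythm; test only P = 24 h
  nrep <- 400
  hits <- 0
  for (r in seq_len(nrep)) {
    counts <- chronoclock:::withSeed(2000 + r, rpois(7 * 240, 5))
    pg <- chiSquaredPeriodogram(counts, binWidth = 0.1,
                                periodRange = c(24, 24))
    hits <- hits + !is.na(pg$best_period)
  }
  rate <- hits / nrep
  # binomial 3*SE band around 0.05 for n = 400
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / nrep))
})
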