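test_that("generators are pure functions of their seed", {
  a1 <- genActogram(23.8, daysLD = 3, daysDD = 4, seed = 7)
  a2 <- genActogram(23.8, daysLD = 3, daysDD = 4, seed = 7)
  a3 <- genActogram(23.8, daysLD = 3, daysDD = 4, seed = 8)
  expect_identical(a1$counts, a2$counts)
  expect_false(identical(a1$counts, a3$counts))
  b1 <- genBioluminescence(noiseSd = 1, seed = 9)
  b2 <- genBioluminescence(noiseSd = 1, seed = 9)
  expect_identical(b1, b2)
})

test_that("the RNG state of the caller is not disturbed", {
  set.seed(123); before <- .Random.seed
  invisible(genActogram(24, 2, 2, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("LD dark-phase count share matches the rate-model expectation", {
  act <- genActogram(period = 24, daysLD = 14, daysDD = 0, meanRate = 3,
                     nocturnality = 5, seed = 13)
  dark <- act$lights == 0
  share <- sum(act$counts[dark]) / sum(act$counts)
  expected <- sum(act$rate[dark]) / sum(act$rate)
  # nocturnality 5 puts ~5/6 of events in the dark phase
  expect_equal(expected, 5 / 6, tolerance = 0.03)
  se <- sqrt(expected * (1 - expected) / sum(act$counts))
  expect_lt(abs(share - expected), 4 * se + 1e-4)
})

test_that("expected total actogram counts match the rate integral", {
  # average over replicates within 3 SD of the Poisson expectation
  tot <- vapply(1:100, function(s)
    sum(genActogram(23.5, daysLD = 0, daysDD = 2, meanRate = 2,
                    nocturnality = 4, seed = s)$counts), numeric(1))
  exp_total <- genActogram(23.5, daysLD = 0, daysDD = 2, meanRate = 2,
                           nocturnality = 4, seed = 1)$expected_total
  se <- sqrt(exp_total / 100)
  expect_lt(abs(mean(tot) - exp_total), 3 * se)
})

test_that("DD actogram round-trips through the periodogram", {
  act <- genActogram(period = 23.96, daysLD = 0, daysDD = 14, seed = 17)
  pg <- chiSquaredPeriodogram(rebinCounts(act, 6), binWidth = 0.1)
  expect_lte(abs(pg$best_period - 23.96), 0.1 + 1e-9)
})

test_that("bioluminescence round-trips: drift, detrend, damped fit", {
  # long-period trace: the period survives detrending with a 24-h window
  tr <- genBioluminescence(period = 27.29, amplitude = 8,
                           dampingRate = 0.004, driftSlope = 0.15,
                           noiseSd = 0.3, days = 7, seed = 31)
  d <- detrendSeries(tr$time_h, tr$value_kcpm, window = 24)
  fit <- fitDampedCosine(d$time, d$value)
  expect_lt(abs(fit$period - 27.29) / 27.29, 0.01)

  # window-matched rhythm under drift: amplitude restored within 5%
  tr24 <- genBioluminescence(period = 24, amplitude = 8,
                             dampingRate = 0.004, driftSlope = 0.15,
                             noiseSd = 0.3, days = 7, seed = 32)
  d24 <- detrendSeries(tr24$time_h, tr24$value_kcpm, window = 24)
  fit24 <- fitDampedCosine(d24$time, d24$value)
  a_true <- 8 * exp(-0.004 * d24$time[1])
  expect_lt(abs(fit24$amplitude - a_true) / a_true, 0.05)
})

test_that("qPCR max100 normalization yields an exact 100 at the peak mean", {
  tr <- integrateModel(cachedWtModel(), tEnd = 35 * 24, stepOut = 0.1)
  sel <- tr@times >= 25 * 24
  sub <- new("Trajectory", times = tr@times[sel],
             states = tr@states[sel, , drop = FALSE],
             metadata = tr@metadata)
  tab0 <- genQpcrTimecourse(sub, "Chrono_mRNA",
                            design = samplingDesign(), noiseCv = 0,
                            seed = 2)
  means <- tapply(tab0$value, tab0$CT, mean)
  expect_equal(max(means), 100)
  # with noise, replicate tables are reproducible under a fixed seed
  tabA <- genQpcrTimecourse(sub, "Chrono_mRNA", noiseCv = 0.1, seed = 5)
  tabB <- genQpcrTimecourse(sub, "Chrono_mRNA", noiseCv = 0.1, seed = 5)
  expect_identical(tabA, tabB)
  expect_error(genQpcrTimecourse(sub, "NoSuchGene_mRNA"), "not in trajectory")
})
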