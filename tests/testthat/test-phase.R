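settledWtTrajectory <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- integrateModel(cachedWtModel(), tEnd = 40 * 24, stepOut = 0.1)
      sel <- tr@times >= 30 * 24
      cache <<- new("Trajectory", times = tr@times[sel],
                    states = tr@states[sel, , drop = FALSE],
                    metadata = tr@metadata)
    }
    cache
  }
})

test_that("a variable compared with itself has phase difference zero", {
  res <- phaseAmplitudeSummary(settledWtTrajectory(), "Per2_mRNA",
                               "Per2_mRNA")
  expect_identical(res$phase_difference, 0)
})

test_that("Chrono mRNA is antiphasic to Bmal1 mRNA", {
  res <- phaseAmplitudeSummary(settledWtTrajectory(), "Chrono_mRNA",
                               "Bmal1_mRNA")
  expect_true(res$summary$rhythmic && res$reference$rhythmic)
  expect_gte(abs(res$phase_difference), 8)
  expect_lte(abs(res$phase_difference), 16)
})

test_that("Chrono mRNA has larger amplitude and earlier peak than Cry2 mRNA", {
  res <- phaseAmplitudeSummary(settledWtTrajectory(), "Chrono_mRNA",
                               "Cry2_mRNA")
  expect_gt(res$summary$relative_amplitude,
            res$reference$relative_amplitude)
  # advanced phase: Chrono peaks before Cry2 within the cycle
  expect_lt(res$phase_difference, 0)
})

test_that("arrhythmic variables get a flagged absent phase", {
  # flatten one variable artificially
  tr <- settledWtTrajectory()
  st <- tr@states
  st[, "Cry2_mRNA"] <- mean(st[, "Cry2_mRNA"])
  flat <- new("Trajectory", times = tr@times, states = st,
              metadata = tr@metadata)
  res <- phaseAmplitudeSummary(flat, "Cry2_mRNA", "Bmal1_mRNA")
  expect_false(res$summary$rhythmic)
  expect_true(is.na(res$summary$peak_phase))
  expect_true(is.na(res$phase_difference))
})

test_that("simulated qPCR sampling finds the Chrono peak near CT 12", {
  tab <- genQpcrTimecourse(settledWtTrajectory(), "Chrono_mRNA",
                           design = samplingDesign(), noiseCv = 0.05,
                           seed = 42)
  means <- tapply(tab$value, tab$CT, mean)
  peak_ct <- as.numeric(names(means)[which.max(means)])
  expect_gte(peak_ct, 10)
  expect_lte(peak_ct, 14)
})
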