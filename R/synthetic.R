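#' @include phase.R
NULL

# run code under a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derived per-replicate stream seeds, deterministic and < 2^31
deriveSeed <- function(seed, k) (as.integer(seed) + 1000003L * k) %% 2147483647L

# smooth two-level day/night activity profile as a function of circadian
# phase in [0, 1); 1-h sigmoidal transitions at the half-cycle boundaries.
# night occupies [0.5, 1); the profile is periodic via the circular
# distance of the phase from the night centre (0.75)
activityLevel <- function(phase, period, nocturnality, transition_h = 1) {
  s <- transition_h / period / 4  # logistic scale in phase units
  d <- abs((phase - 0.75 + 0.5) %% 1 - 0.5)  # circular distance to 0.75
  night <- 1 / (1 + exp(-(0.25 - d) / s))    # ~1 inside the night half
  1 + (nocturnality - 1) * night
}

#' Generate a synthetic locomotor actogram
#'
#' Emulates infrared beam-break recordings in 1-min bins: counts are
#' drawn from an inhomogeneous Poisson process whose rate follows a
#' smoothed two-level day/night profile (1-h sigmoidal transitions),
#' entrained to lights-off during the LD segment (24-h cycle, lights on
#' for the first 12 h of each day) and free-running at \code{period}
#' during DD, phase-continuous with the last LD cycle.
#'
#' @param period free-running period, hours (in [20, 28]).
#' @param daysLD,daysDD days under 12:12 LD and under constant darkness.
#' @param meanRate overall mean event rate, counts/min.
#' @param nocturnality night/day rate ratio (>= 1).
#' @param seed integer seed; identical seeds give identical output.
#' @param binWidth bin width, minutes (default 1).
#' @return an \code{Actogram}: list with \code{bin_width} (min),
#'   \code{counts}, \code{schedule} (per-day \code{"LD"}/\code{"DD"}),
#'   \code{days}, \code{lights} (0/1 per bin), and the generating
#'   \code{period}.
#' @export
genActogram <- function(period, daysLD, daysDD, meanRate = 2,
                        nocturnality = 5, seed = 1, binWidth = 1) {
  stopifnot(period >= 20, period <= 28, nocturnality >= 1)
  days <- daysLD + daysDD
  bins_per_day <- 24 * 60 / binWidth
  t_h <- (seq_len(days * bins_per_day) - 0.5) * binWidth / 60  # bin centers, h
  t_dd0 <- daysLD * 24

  # circadian phase: 0 at lights-on; night (activity) is phase in [0.5, 1)
  phase <- ifelse(t_h < t_dd0,
                  (t_h %% 24) / 24,
                  ((t_dd0 %% 24) / 24 + (t_h - t_dd0) / period) %% 1)
  lvl <- activityLevel(phase, ifelse(t_h < t_dd0, 24, period), nocturnality)
  rate <- meanRate * lvl / mean(c(1, nocturnality))  # counts/min, mean ~ meanRate
  lam <- rate * binWidth
  counts <- withSeed(seed, rpois(length(lam), lam))
  lights <- as.integer(t_h < t_dd0 & (t_h %% 24) < 12)
  structure(list(bin_width = binWidth, counts = counts,
                 schedule = c(rep("LD", daysLD), rep("DD", daysDD)),
                 days = days, lights = lights, period = period,
                 rate = rate, expected_total = sum(lam)),
            class = "Actogram")
}

#' @export
print.Actogram <- function(x, ...) {
  cat(sprintf("Actogram: %d days (%s), %g-min bins, %d events\n",
              x$days, paste(rle(x$schedule)$values, collapse = " then "),
              x$bin_width, sum(x$counts)))
  invisible(x)
}

#' Generate a synthetic bioluminescence trace
#'
#' A damped cosine on a drifting baseline with Gaussian noise, in kcpm
#' (1,000 photon counts per minute):
#' \deqn{b + A e^{-\lambda t} \cos(2\pi t/P + \phi) + s t + \epsilon.}
#'
#' @param period P, hours.
#' @param amplitude A, kcpm.
#' @param dampingRate lambda, 1/h.
#' @param driftSlope baseline drift s, kcpm/h.
#' @param noiseSd Gaussian noise SD, kcpm.
#' @param days recording length (>= 3).
#' @param samplingMin sampling interval, minutes (default 10).
#' @param seed integer seed.
#' @param baseline b, kcpm.
#' @param phase phi, radians.
#' @return \code{data.frame} with \code{time_h} and \code{value_kcpm}.
#' @export
genBioluminescence <- function(period = 24, amplitude = 10,
                               dampingRate = 0, driftSlope = 0,
                               noiseSd = 0, days = 6, samplingMin = 10,
                               seed = 1, baseline = 20, phase = 0) {
  stopifnot(days >= 3)
  t <- seq(0, days * 24, by = samplingMin / 60)
  det <- baseline + amplitude * exp(-dampingRate * t) *
    cos(2 * pi * t / period + phase) + driftSlope * t
  noise <- if (noiseSd > 0) withSeed(seed, rnorm(length(t), 0, noiseSd))
           else 0
  data.frame(time_h = t, value_kcpm = det + noise)
}

#' A qPCR sampling design
#'
#' @param start first sampling circadian time, CT hours.
#' @param interval sampling interval, hours (must divide 24).
#' @param replicates replicates per time point.
#' @param normalization \code{"max100"} (replicate-mean maximum set to
#'   100) or \code{"none"}.
#' @return a \code{SamplingDesign} list.
#' @export
samplingDesign <- function(start = 0, interval = 4, replicates = 3,
                           normalization = c("max100", "none")) {
  if (24 %% interval != 0) stop("interval must divide 24")
  structure(list(start = start, interval = interval,
                 replicates = replicates,
                 normalization = match.arg(normalization)),
            class = "SamplingDesign")
}

#' Generate a synthetic qPCR time course from a model trajectory
#'
#' Samples one mRNA from a settled trajectory at the design circadian
#' times (CT 0 anchored at the Bmal1 mRNA peak, cycle normalized to
#' 24 CT hours), applies multiplicative lognormal noise with the given
#' coefficient of variation, and normalizes (max100: the maximum
#' replicate mean is set to 100).
#'
#' @param trajectory a settled \code{\link{Trajectory}} spanning at
#'   least 24 h past its transient.
#' @param variable mRNA species to sample.
#' @param design a \code{\link{samplingDesign}}.
#' @param noiseCv lognormal coefficient of variation (0 for noiseless).
#' @param seed integer seed; replicate streams are split
#'   deterministically.
#' @param ct0Variable species whose peak anchors CT 0.
#' @return \code{data.frame} with columns \code{CT}, \code{replicate},
#'   \code{value}.
#' @export
genQpcrTimecourse <- function(trajectory, variable, design = samplingDesign(),
                              noiseCv = 0.1, seed = 1,
                              ct0Variable = "Bmal1_mRNA") {
  tt <- trajectory@times
  if (max(tt) - min(tt) < 24)
    stop("trajectory must span at least 24 h")
  x <- trajSeries(trajectory, variable)  # errors if variable absent
  anchor <- variableCycleStats(tt, trajSeries(trajectory, ct0Variable))
  if (is.null(anchor))
    stop("cannot anchor CT 0: ", ct0Variable, " is not rhythmic")
  period <- anchor$period
  # sample one full cycle starting from the last CT0 anchor that leaves
  # room for a cycle; walk backwards from the final anchor peak
  ct0_time <- anchor$peak_time
  while (ct0_time + period > max(tt)) ct0_time <- ct0_time - period
  if (ct0_time < min(tt))
    stop("trajectory too short to place a full sampling cycle")
  cts <- seq(design$start, 24 - design$interval + design$start,
             by = design$interval)
  t_samp <- ct0_time + cts / 24 * period
  vals <- approx(tt, x, xout = t_samp)$y
  reps <- lapply(seq_len(design$replicates), function(r) {
    noise <- if (noiseCv > 0) {
      sdlog <- sqrt(log(1 + noiseCv^2))
      withSeed(deriveSeed(seed, r),
               rlnorm(length(vals), -sdlog^2 / 2, sdlog))
    } else 1
    data.frame(CT = cts, replicate = r, value = vals * noise)
  })
  out <- do.call(rbind, reps)
  if (design$normalization == "max100") {
    means <- tapply(out$value, out$CT, mean)
    out$value <- out$value * 100 / max(means)
  }
  rownames(out) <- NULL
  out
}
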