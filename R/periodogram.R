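#' @include cycle.R
NULL

#' Chi-squared periodogram (Sokolove-Bushell)
#'
#' For each trial period P with K bins per cycle and N complete cycles,
#' the evenly binned series is folded modulo P; with column means M_h and
#' grand mean M over the used points,
#' \deqn{Q_P = \frac{N \sum_h (M_h - M)^2}{\sum_i (x_i - M)^2 / (KN)}
#'  = K N^2 \frac{\sum_h (M_h - M)^2}{\sum_i (x_i - M)^2},}
#' which has null mean K - 1 and is compared against the upper-alpha
#' quantile of a chi-squared distribution with K - 1 degrees of freedom.
#' A fold-matched deterministic rhythm attains the maximum
#' \eqn{Q_P = K N} (between-cycle variance equal to total variance).  The best period is the
#' significant trial period maximizing Qp - threshold.  A zero-variance
#' series yields Qp = 0 everywhere and no significant period.
#'
#' @param counts evenly binned counts (or any evenly sampled series).
#' @param binWidth bin width, hours (default 0.1 = 6 min).
#' @param periodRange trial-period range, hours (default c(20, 28)).
#' @param alpha significance level (default 0.05).
#' @param bonferroni apply a Bonferroni correction over the period grid
#'   (default FALSE, matching common actogram practice).
#' @param periodStep grid step, hours; defaults to the bin width, which
#'   keeps every trial period an integer number of bins.
#' @return a \code{PeriodogramResult}: list with \code{test_periods},
#'   \code{Qp}, \code{significance_line}, \code{df}, \code{best_period}
#'   (NA when nothing is significant), \code{alpha}.
#' @export
chiSquaredPeriodogram <- function(counts, binWidth = 0.1,
                                  periodRange = c(20, 28), alpha = 0.05,
                                  bonferroni = FALSE,
                                  periodStep = binWidth) {
  stopifnot(length(periodRange) == 2, periodRange[1] <= periodRange[2])
  if (abs(periodStep / binWidth - round(periodStep / binWidth)) > 1e-8)
    stop("bin width must divide the period grid step")
  n <- length(counts)
  Ks <- seq(round(periodRange[1] / binWidth),
            round(periodRange[2] / binWidth))
  Ks <- Ks[Ks %% round(periodStep / binWidth) == 0 | periodStep == binWidth]
  periods <- Ks * binWidth
  if (n < 2 * max(Ks))
    stop("series too short: need at least two full cycles of the longest ",
         "trial period")
  m <- length(periods)
  a_eff <- if (bonferroni) alpha / m else alpha
  Qp <- numeric(m); thr <- numeric(m)
  for (i in seq_len(m)) {
    K <- Ks[i]
    N <- n %/% K
    x <- counts[seq_len(N * K)]
    M <- mean(x)
    tot <- sum((x - M)^2)
    thr[i] <- qchisq(1 - a_eff, df = K - 1)
    if (tot < 1e-300) { Qp[i] <- 0; next }
    col_means <- rowMeans(matrix(x, nrow = K))
    Qp[i] <- K * N^2 * sum((col_means - M)^2) / tot
  }
  sig <- Qp > thr
  best <- if (any(sig)) periods[which.max(ifelse(sig, Qp - thr, -Inf))]
          else NA_real_
  structure(list(test_periods = periods, Qp = Qp,
                 significance_line = thr, df = Ks - 1,
                 best_period = best, alpha = alpha,
                 bonferroni = bonferroni, bin_width = binWidth),
            class = "PeriodogramResult")
}

#' @export
print.PeriodogramResult <- function(x, ...) {
  cat(sprintf("Chi-squared periodogram: %d trial periods in [%.2f, %.2f] h\n",
              length(x$test_periods), min(x$test_periods),
              max(x$test_periods)))
  if (is.na(x$best_period)) cat("  no significant period\n")
  else cat(sprintf("  best period: %.2f h (Qp = %.1f, threshold %.1f)\n",
                   x$best_period, max(x$Qp),
                   x$significance_line[which(x$test_periods ==
                                             x$best_period)]))
  invisible(x)
}

#' Rebin an actogram's counts to a coarser bin width
#'
#' @param actogram an \code{Actogram} (see \code{\link{genActogram}}).
#' @param binWidthMin target bin width, minutes (must be a multiple of
#'   the actogram's bin width).
#' @return numeric vector of rebinned counts.
#' @export
rebinCounts <- function(actogram, binWidthMin = 6) {
  f <- binWidthMin / actogram$bin_width
  if (abs(f - round(f)) > 1e-9 || f < 1)
    stop("target bin width must be a multiple of the actogram bin width")
  f <- as.integer(round(f))
  n <- (length(actogram$counts) %/% f) * f
  colSums(matrix(actogram$counts[seq_len(n)], nrow = f))
}

#' Estimate the free-running period from an actogram
#'
#' Restricts to the first \code{windowDays} days of the DD (constant
#' darkness) segment, rebins the 1-min event counts to 6-min columns, and
#' runs the chi-squared periodogram over 20-28 h.
#'
#' @param actogram an \code{Actogram}.
#' @param windowDays analysis window, days (default 7).
#' @param periodRange trial periods, hours.
#' @param alpha significance level.
#' @return a \code{RhythmSummary} (period from the periodogram best
#'   period; \code{rhythmic} reflects significance).  The full
#'   \code{PeriodogramResult} is attached as attribute
#'   \code{"periodogram"}.
#' @export
estimateFreeRunningPeriod <- function(actogram, windowDays = 7,
                                      periodRange = c(20, 28),
                                      alpha = 0.05) {
  dd_days <- which(actogram$schedule == "DD")
  if (!length(dd_days)) stop("actogram has no DD segment")
  if (length(dd_days) < windowDays)
    stop("actogram has fewer than ", windowDays, " days of DD data")
  bins_per_day <- 24 * 60 / actogram$bin_width
  use_days <- dd_days[seq_len(windowDays)]
  sel <- unlist(lapply(use_days, function(d)
    ((d - 1) * bins_per_day + 1):(d * bins_per_day)))
  sub <- list(bin_width = actogram$bin_width,
              counts = actogram$counts[sel],
              schedule = rep("DD", windowDays), days = windowDays)
  class(sub) <- "Actogram"
  counts6 <- rebinCounts(sub, 6)
  pg <- chiSquaredPeriodogram(counts6, binWidth = 0.1,
                              periodRange = periodRange, alpha = alpha)
  period <- pg$best_period
  relamp <- NA_real_; phase <- NA_real_
  if (!is.na(period)) {
    K <- round(period / 0.1)
    N <- length(counts6) %/% K
    prof <- rowMeans(matrix(counts6[seq_len(K * N)], nrow = K))
    if (mean(prof) > 0) relamp <- (max(prof) - min(prof)) / mean(prof)
    phase <- (which.max(prof) - 1) * 0.1 * 24 / period  # CT hours
  }
  structure(
    structure(list(period = period, relative_amplitude = relamp,
                   peak_phase = phase, damping_rate = NA_real_,
                   rhythmic = !is.na(period)),
              class = "RhythmSummary"),
    periodogram = pg)
}
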