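#' @include periodogram.R
NULL

#' Detrend a series by subtracting a centered running mean
#'
#' Removes slow baseline drift (e.g. in bioluminescence recordings) by
#' subtracting a centered running mean of width \code{window}.  The
#' output loses half a window at each edge, where the running mean is
#' undefined.
#'
#' @param time sampling times, hours (evenly spaced).
#' @param value series values.
#' @param window running-mean width, hours (default 24).
#' @return \code{data.frame} with \code{time} and \code{value}
#'   (detrended); approximately zero-mean.
#' @export
detrendSeries <- function(time, value, window = 24) {
  stopifnot(length(time) == length(value))
  dt <- diff(time)
  if (any(abs(dt - dt[1]) > 1e-6 * dt[1]))
    stop("detrendSeries requires evenly spaced samples")
  dur <- time[length(time)] - time[1]
  if (dur < 2 * window)
    stop("series too short: duration must be at least twice the window")
  # symmetric kernel whose effective width is exactly `window`:
  # full-weight interior taps plus fractional end taps
  W <- window / dt[1]
  m <- floor(W / 2)
  kern <- rep(1, 2 * m + 1)
  kern[c(1, 2 * m + 1)] <- (W - (2 * m - 1)) / 2
  kern <- kern / W
  run <- as.numeric(filter(value, kern, sides = 2))
  keep <- !is.na(run)
  data.frame(time = time[keep], value = value[keep] - run[keep])
}
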