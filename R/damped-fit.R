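#' @include detrend.R
NULL

#' Fit a damped cosine to a series
#'
#' Least-squares fit of
#' \deqn{b + A e^{-\lambda t} \cos(2\pi t / P + \phi).}
#' Initialization is a deterministic multi-start grid over period and
#' damping rate; for each grid node the amplitude/phase/baseline enter
#' linearly and are solved exactly, then the best node is refined by
#' Levenberg-Marquardt (\code{minpack.lm::nlsLM}) with \eqn{\lambda \ge 0}.
#'
#' @param time sampling times, hours.
#' @param value series values.
#' @param periodGrid multi-start periods, hours.
#' @param lambdaGrid multi-start damping rates, 1/h.
#' @return list with \code{period} (h), \code{damping_rate} (1/h),
#'   \code{amplitude}, \code{phase} (radians), \code{baseline},
#'   \code{rms} (residual RMS) and \code{identifiable} (FALSE for
#'   degenerate flat input, in which case the damping rate is NA rather
#'   than an error being raised).
#' @export
fitDampedCosine <- function(time, value,
                            periodGrid = seq(18, 32, by = 1),
                            lambdaGrid = c(0, 0.002, 0.005, 0.01, 0.02,
                                           0.05, 0.1)) {
  stopifnot(length(time) == length(value), length(time) >= 8)
  t0 <- time - time[1]
  if (sd(value) < 1e-12 * max(abs(mean(value)), 1))
    return(list(period = NA_real_, damping_rate = NA_real_,
                amplitude = 0, phase = NA_real_,
                baseline = mean(value), rms = 0, identifiable = FALSE))

  best <- NULL
  for (P in periodGrid) for (lam in lambdaGrid) {
    e <- exp(-lam * t0)
    X <- cbind(1, e * cos(2 * pi * t0 / P), e * sin(2 * pi * t0 / P))
    fit <- tryCatch(lm.fit(X, value), error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss) {
      cc <- fit$coefficients
      best <- list(rss = rss, P = P, lam = lam, b = cc[1],
                   A = sqrt(cc[2]^2 + cc[3]^2),
                   phi = atan2(-cc[3], cc[2]))
    }
  }
  start <- list(b = unname(best$b), A = unname(best$A), lam = best$lam,
                P = best$P, phi = unname(best$phi))
  df <- data.frame(t = t0, y = value)
  nls_fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b + A * exp(-lam * t) * cos(2 * pi * t / P + phi),
      data = df, start = start,
      lower = c(b = -Inf, A = 0, lam = 0, P = min(periodGrid) / 2,
                phi = -2 * pi),
      upper = c(b = Inf, A = Inf, lam = 1, P = max(periodGrid) * 2,
                phi = 2 * pi),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(nls_fit)) {
    cf <- coef(nls_fit)
    res <- df$y - predict(nls_fit)
    out <- list(period = unname(cf["P"]),
                damping_rate = unname(cf["lam"]),
                amplitude = unname(cf["A"]),
                phase = unname(cf["phi"]) %% (2 * pi),
                baseline = unname(cf["b"]),
                rms = sqrt(mean(res^2)), identifiable = TRUE)
  } else {
    out <- list(period = best$P, damping_rate = best$lam,
                amplitude = unname(best$A),
                phase = unname(best$phi) %% (2 * pi),
                baseline = unname(best$b),
                rms = sqrt(best$rss / length(value)), identifiable = TRUE)
  }
  if (out$amplitude < 1e-10 * max(abs(out$baseline), 1))
    out$identifiable <- FALSE
  out
}
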