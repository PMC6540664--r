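#' Calibration model for twilight errors
#'
#' In-habitat calibration of the threshold method: the zenith angle of the
#' sun at the moment the light series crosses the threshold, and a
#' log-normal model of the twilight delay caused by shading. Shading can
#' only make the logger see sunrise later and sunset earlier than the
#' geometric crossing, so delays are one-sided: `delay >= 0`, oriented as
#' `observed - predicted` for sunrises and `predicted - observed` for
#' sunsets, in minutes.
#'
#' @param zenith_deg solar zenith angle (degrees from vertical) at threshold
#'   crossing; must lie in \[85, 100\].
#' @param err_meanlog,err_sdlog parameters of the log-normal delay
#'   distribution (delay in minutes).
#' @param threshold the light threshold the model was calibrated for.
#' @return An object of class `CalibrationModel`.
#' @export
calibrationModel <- function(zenith_deg, err_meanlog, err_sdlog,
                             threshold = 0.5) {
  if (zenith_deg < 85 || zenith_deg > 100)
    stop("zenith_deg outside plausible range [85, 100]")
  if (err_sdlog < 0) stop("err_sdlog must be >= 0")
  if (threshold <= 0) stop("threshold must be positive")
  structure(list(zenith_deg = zenith_deg, err_meanlog = err_meanlog,
                 err_sdlog = err_sdlog, threshold = threshold),
            class = "CalibrationModel")
}

#' @export
print.CalibrationModel <- function(x, ...) {
  cat(sprintf(paste0("CalibrationModel: zenith %.2f deg, delay ~ LogNormal",
                     "(meanlog %.3f, sdlog %.3f) min, threshold %.2f\n"),
              x$zenith_deg, x$err_meanlog, x$err_sdlog, x$threshold))
  invisible(x)
}

#' Calibrate the threshold method at a known location
#'
#' Uses light recorded while the bird was at a known site (typically the
#' capture location before departure) to jointly estimate, by maximum
#' likelihood over a zenith grid, the zenith angle and the log-normal
#' distribution of the per-twilight delays between observed crossings and
#' the crossings predicted at that zenith. The zenith of the naive
#' estimator -- the median solar zenith at the observed crossings -- is
#' biased towards the horizon by the median shading delay itself, so it is
#' used only to seed the grid; the profile likelihood treats a non-positive
#' delay as impossible (shading is one-sided), which anchors the zenith.
#'
#' Delays are floored at `delay_floor` minutes before taking logs (a
#' marginally non-positive delay at the fitted zenith is
#' sampling/interpolation noise). When the observed delays are essentially
#' noise-free the fitted `sdlog` is clamped to `sdlog_min` with a warning.
#'
#' @param series a [lightSeries()] covering the calibration window.
#' @param lat,lon known coordinates, decimal degrees.
#' @param window optional length-2 Date vector restricting the series.
#' @param threshold light threshold (default 0.5).
#' @param min_dark_minutes passed to [findTwilights()].
#' @param delay_floor minimum delay in minutes (default 0.01).
#' @param sdlog_min lower bound for `err_sdlog` (default 0.01).
#' @return A [calibrationModel()] with attribute `n_twilights`.
#' @export
calibrate <- function(series, lat, lon, window = NULL, threshold = 0.5,
                      min_dark_minutes = 120, delay_floor = 0.01,
                      sdlog_min = 0.01) {
  if (!is.null(window)) {
    window <- as.Date(window)
    keep <- as.Date(series$time, tz = "UTC") >= window[1] &
      as.Date(series$time, tz = "UTC") <= window[2]
    series <- lightSeries(series$time[keep], series$light[keep],
                          attr(series, "logger_id"))
  }
  twl <- findTwilights(series, threshold, min_dark_minutes)
  pairs <- twilightPairs(twl)
  if (nrow(pairs) < 10)
    stop("calibration window must contain at least 10 twilight pairs")
  events <- c(pairs$sunrise, pairs$sunset)
  sgn <- rep(c(1, -1), each = nrow(pairs))   # sunrise late, sunset early
  delaysAt <- function(z) {
    pred <- predictTwilights(pairs$date, lat, lon, z)
    sgn * as.numeric(difftime(events, c(pred$sunrise, pred$sunset),
                              units = "mins"))
  }
  profileLL <- function(z) {
    d <- delaysAt(z)
    if (any(!is.finite(d)) || any(d <= 0)) return(-Inf)
    ld <- log(d)
    m <- mean(ld)
    s <- max(sqrt(mean((ld - m)^2)), sdlog_min)
    sum(stats::dlnorm(d, m, s, log = TRUE))
  }
  z0 <- stats::median(solarZenith(events, lat, lon))   # lower anchor
  zgrid <- seq(max(85, z0 - 1), 100, by = 0.02)
  ll <- vapply(zgrid, profileLL, numeric(1))
  if (all(!is.finite(ll)))
    stop("no zenith in [85, 100] yields one-sided twilight delays")
  zenith <- zgrid[which.max(ll)]
  delays <- pmax(delaysAt(zenith), delay_floor)
  if (stats::median(delays) <= 0.5) {
    # a median delay under half a minute is within crossing-detection
    # quantisation, not shading; the log-spread of such residuals is
    # meaningless
    warning("observed twilight delays are nearly noise-free; ",
            "err_sdlog clamped to the configured minimum")
    meanlog <- log(max(stats::median(delays), delay_floor))
    sdlog <- sdlog_min
  } else {
    ld <- log(delays)
    meanlog <- mean(ld)
    sdlog <- sqrt(mean((ld - meanlog)^2))    # ML estimate
    if (sdlog < sdlog_min) {
      warning("observed twilight delays are nearly noise-free; ",
              "err_sdlog clamped to the configured minimum")
      sdlog <- sdlog_min
    }
  }
  out <- calibrationModel(zenith, meanlog, sdlog, threshold)
  attr(out, "n_twilights") <- length(delays)
  out
}
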