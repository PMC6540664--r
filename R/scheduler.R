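#' Segment a location posterior into stationary periods
#'
#' Change-point segmentation of the daily posterior track by natural breaks
#' in the running posterior mean, honouring the location uncertainty of
#' light-level geolocation. A greedy forward pass maintains the running
#' mean of the open segment's daily medians and its pooled uncertainty (the
#' mean daily 95% CrI half-width); a new segment opens when the incoming
#' day's median departs from the running mean by more than
#' `z_break` x pooled half-width on either axis. Within
#' `equinox_window_days` of an equinox and with `equinox_lon_only = TRUE`,
#' only longitude is tested (latitude is unidentifiable there). Segments of
#' at least `min_days` days become stationary periods; shorter ones are
#' movement days.
#'
#' @param post a `LocationPosterior` (or its `summary` data.frame).
#' @param min_days minimum stationary-period length in days (default 2).
#' @param z_break break threshold in pooled CrI half-widths (default 2).
#' @param equinox_lon_only test only longitude near the equinoxes.
#' @param equinox_window_days half-width of the equinox windows, days
#'   (default 15, around Mar 20 and Sep 22).
#' @return A `Schedule`: data.frame of segments with columns `period_id`,
#'   `start`, `end`, `duration_days`, `lat_med`, `lon_med`, `lat_lo`,
#'   `lat_hi`, `lon_lo`, `lon_hi`, `kind` ("stationary" or "movement"),
#'   with attribute `equinox_lon_only`.
#' @export
segmentStationary <- function(post, min_days = 2, z_break = 2,
                              equinox_lon_only = FALSE,
                              equinox_window_days = 15) {
  s <- if (inherits(post, "LocationPosterior")) post$summary else post
  if (is.null(s) || nrow(s) == 0) stop("empty posterior")
  if (nrow(s) < min_days) stop("posterior shorter than min_days")
  s <- s[order(s$date), ]
  lat_hw <- (s$lat_hi - s$lat_lo) / 2
  lon_hw <- (s$lon_hi - s$lon_lo) / 2
  nearEq <- nearEquinox(s$date, equinox_window_days)

  n <- nrow(s)
  seg <- integer(n)
  seg[1] <- 1L
  cur <- 1L
  start <- 1L
  for (i in 2:n) {
    span <- start:(i - 1L)
    mlat <- mean(s$lat_med[span]); mlon <- mean(s$lon_med[span])
    hlat <- max(mean(lat_hw[span]), 1e-9)
    hlon <- max(mean(lon_hw[span]), 1e-9)
    dev_lat <- abs(s$lat_med[i] - mlat) / hlat
    dev_lon <- abs(circDiff(s$lon_med[i], mlon)) / hlon
    brk <- if (equinox_lon_only && nearEq[i]) dev_lon > z_break
           else dev_lat > z_break || dev_lon > z_break
    if (brk) { cur <- cur + 1L; start <- i }
    seg[i] <- cur
  }

  samples <- if (inherits(post, "LocationPosterior"))
    list(lat = post$lat_samples, lon = post$lon_samples) else NULL
  rows <- lapply(split(seq_len(n), seg), function(ii) {
    dur <- as.integer(s$date[ii[length(ii)]] - s$date[ii[1]]) + 1L
    if (!is.null(samples)) {
      la <- as.vector(samples$lat[ii, , drop = FALSE])
      lo <- as.vector(samples$lon[ii, , drop = FALSE])
      qla <- stats::quantile(la, c(0.025, 0.5, 0.975), names = FALSE)
      qlo <- stats::quantile(lo, c(0.025, 0.5, 0.975), names = FALSE)
    } else {
      qla <- c(min(s$lat_lo[ii]), stats::median(s$lat_med[ii]), max(s$lat_hi[ii]))
      qlo <- c(min(s$lon_lo[ii]), stats::median(s$lon_med[ii]), max(s$lon_hi[ii]))
    }
    data.frame(start = s$date[ii[1]], end = s$date[ii[length(ii)]],
               duration_days = dur,
               lat_med = qla[2], lat_lo = qla[1], lat_hi = qla[3],
               lon_med = qlo[2], lon_lo = qlo[1], lon_hi = qlo[3])
  })
  out <- do.call(rbind, rows)
  out$kind <- ifelse(out$duration_days >= min_days, "stationary", "movement")
  out <- out[order(out$start), ]
  out$period_id <- seq_len(nrow(out))
  out <- out[, c("period_id", "start", "end", "duration_days",
                 "lat_med", "lon_med", "lat_lo", "lat_hi",
                 "lon_lo", "lon_hi", "kind")]
  rownames(out) <- NULL
  attr(out, "equinox_lon_only") <- equinox_lon_only
  class(out) <- c("Schedule", "data.frame")
  out
}

#' @export
print.Schedule <- function(x, ...) {
  cat(sprintf("Schedule: %d stationary period(s), %d movement segment(s), %s to %s\n",
              sum(x$kind == "stationary"), sum(x$kind == "movement"),
              format(min(x$start)), format(max(x$end))))
  print.data.frame(x)
  invisible(x)
}

#' Count stationary periods in a date window
#'
#' Number of stationary periods whose midpoint falls inside `window`
#' (inclusive on both ends).
#'
#' @param schedule a `Schedule`.
#' @param window length-2 Date vector.
#' @return integer count.
#' @export
periodCounts <- function(schedule, window) {
  window <- as.Date(window)
  st <- schedule[schedule$kind == "stationary", ]
  if (!nrow(st)) return(0L)
  mid <- st$start + floor(as.numeric(st$end - st$start) / 2)
  sum(mid >= window[1] & mid <= window[2])
}

#' Read/write schedule CSV
#'
#' @param schedule a `Schedule`.
#' @param path file path.
#' @return `writeSchedule()` returns `path` invisibly; `readSchedule()`
#'   returns the `Schedule`.
#' @export
writeSchedule <- function(schedule, path) {
  d <- as.data.frame(schedule)
  d$start <- format(d$start); d$end <- format(d$end)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSchedule
#' @export
readSchedule <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$start <- as.Date(d$start); d$end <- as.Date(d$end)
  class(d) <- c("Schedule", "data.frame")
  d
}

# -- internals ----------------------------------------------------------------

nearEquinox <- function(date, window_days) {
  doy <- as.POSIXlt(date)$yday + 1L
  mar <- as.POSIXlt(as.Date(paste0(format(date, "%Y"), "-03-20")))$yday + 1L
  sep <- as.POSIXlt(as.Date(paste0(format(date, "%Y"), "-09-22")))$yday + 1L
  abs(doy - mar) <= window_days | abs(doy - sep) <= window_days
}

circDiff <- function(a, b) {
  d <- (a - b + 180) %% 360 - 180
  ifelse(d == -180, 180, d)
}
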