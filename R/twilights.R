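#' Detect twilight events in a light series
#'
#' Finds the threshold crossings of a light series: one sunrise (upward
#' crossing) and one sunset (downward crossing) per light period. Crossing
#' times are linearly interpolated between the two adjacent samples. Dark
#' spells shorter than `min_dark_minutes` are treated as daytime shading and
#' merged into the surrounding light period; symmetric short light spells
#' (e.g. moonlight or sensor glitches at night) are merged into darkness.
#'
#' @param series a [lightSeries()].
#' @param threshold light level defining twilight (default 0.5, the
#'   conventional threshold for BAS-style loggers).
#' @param min_dark_minutes dark (or light) runs shorter than this are merged
#'   (default 120 min).
#' @return data.frame with columns `time` (POSIXct UTC), `kind`
#'   (`"sunrise"`/`"sunset"`) and `excluded` (all `FALSE`), sorted by time.
#'   Empty (with a warning) when the threshold is never crossed.
#' @export
findTwilights <- function(series, threshold = 0.5, min_dark_minutes = 120) {
  stopifnot(inherits(series, "LightSeries"))
  light <- series$light
  time <- series$time
  day <- light > threshold
  if (all(day) || all(!day)) {
    warning("light threshold never crossed; no twilights found")
    return(data.frame(time = as.POSIXct(character(), tz = "UTC"),
                      kind = character(), excluded = logical(),
                      stringsAsFactors = FALSE))
  }
  interval <- attr(series, "interval_min")
  min_run <- max(1L, ceiling(min_dark_minutes / interval))
  day <- mergeShortRuns(day, FALSE, min_run)   # short dark spells -> day
  day <- mergeShortRuns(day, TRUE, min_run)    # short light spells -> night
  idx <- which(diff(day) != 0L)                # boundary between idx, idx+1
  if (!length(idx)) {
    warning("no twilights after shading rejection")
    return(data.frame(time = as.POSIXct(character(), tz = "UTC"),
                      kind = character(), excluded = logical(),
                      stringsAsFactors = FALSE))
  }
  l0 <- light[idx]; l1 <- light[idx + 1L]
  frac <- ifelse(l1 == l0, 0.5, (threshold - l0) / (l1 - l0))
  frac <- pmin(1, pmax(0, frac))
  tcross <- time[idx] +
    frac * as.numeric(difftime(time[idx + 1L], time[idx], units = "secs"))
  kind <- ifelse(day[idx + 1L], "sunrise", "sunset")
  out <- data.frame(time = tcross, kind = kind, excluded = FALSE,
                    stringsAsFactors = FALSE)
  out <- out[order(out$time), ]
  if (any(out$kind[-1] == out$kind[-nrow(out)]))
    warning("non-alternating twilight kinds detected; inspect for shading")
  rownames(out) <- NULL
  out
}

# set runs of value `state` shorter than min_run samples to !state
mergeShortRuns <- function(day, state, min_run) {
  r <- rle(day)
  short <- r$values == state & r$lengths < min_run
  # never flip the leading/trailing partial run: it may be truncated data
  short[c(1L, length(short))] <- FALSE
  r$values[short] <- !state
  inverse.rle(r)
}

#' Pair twilights into light-period days
#'
#' Pairs each non-excluded sunrise with the next sunset and keys the pair to
#' a civil date: the date of the pair midpoint shifted by the longitude the
#' pair itself implies (via the twilight midpoint), so that a day boundary
#' never splits a light period.
#'
#' @param twl twilight data.frame from [findTwilights()].
#' @return data.frame with columns `date` (Date), `sunrise`, `sunset`
#'   (POSIXct UTC).
#' @export
twilightPairs <- function(twl) {
  twl <- twl[!twl$excluded, ]
  twl <- twl[order(twl$time), ]
  sr <- which(twl$kind == "sunrise")
  keep <- sr[sr < nrow(twl) & twl$kind[pmin(sr + 1L, nrow(twl))] == "sunset"]
  if (!length(keep))
    return(data.frame(date = as.Date(character()),
                      sunrise = as.POSIXct(character(), tz = "UTC"),
                      sunset = as.POSIXct(character(), tz = "UTC")))
  sunrise <- twl$time[keep]
  sunset <- twl$time[keep + 1L]
  mid <- sunrise + as.numeric(difftime(sunset, sunrise, units = "secs")) / 2
  sp <- solarPosition(mid)
  lt <- as.POSIXlt(mid, tz = "UTC")
  mid_min <- lt$hour * 60 + lt$min + lt$sec / 60
  lon <- wrapLon((720 - sp$eot - mid_min) / 4)
  date <- as.Date(mid + lon / 15 * 3600, tz = "UTC")
  data.frame(date = date, sunrise = sunrise, sunset = sunset)
}
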