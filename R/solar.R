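#' Low-precision solar position
#'
#' Solar declination and the equation of time from the NOAA low-accuracy
#' closed-form algorithm (a Fourier series in the fractional year). Accuracy
#' is about 0.3 degrees in declination and 0.5 minutes in the equation of
#' time -- far below the 0.5--2 degree error floor of light-level
#' geolocation itself.
#'
#' @param t POSIXct timestamp(s), UTC.
#' @return A list with numeric vectors `declination` (degrees, positive
#'   north) and `eot` (equation of time, minutes; positive when the true sun
#'   leads mean solar time).
#' @examples
#' solarPosition(as.POSIXct("2014-06-21 12:00:00", tz = "UTC"))
#' @export
solarPosition <- function(t) {
  t <- asUTC(t)
  lt <- as.POSIXlt(t, tz = "UTC")
  if (any(lt$year + 1900L < 1950L | lt$year + 1900L > 2100L))
    stop("timestamps must fall within 1950-2100")
  frac_hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  gamma <- 2 * pi / 365 * (lt$yday + (frac_hour - 12) / 24)
  eot <- 229.18 * (0.000075 +
    0.001868 * cos(gamma) - 0.032077 * sin(gamma) -
    0.014615 * cos(2 * gamma) - 0.040849 * sin(2 * gamma))
  decl <- 0.006918 -
    0.399912 * cos(gamma) + 0.070257 * sin(gamma) -
    0.006758 * cos(2 * gamma) + 0.000907 * sin(2 * gamma) -
    0.002697 * cos(3 * gamma) + 0.00148 * sin(3 * gamma)
  list(declination = decl * 180 / pi, eot = eot)
}

#' Solar zenith angle
#'
#' Apparent solar zenith angle (degrees from vertical, no refraction beyond
#' the calibrated zenith offset) at given times and positions. Vectorised
#' over all arguments.
#'
#' @param t POSIXct timestamp(s), UTC.
#' @param lat,lon decimal degrees (south / west negative).
#' @return numeric vector of zenith angles in degrees.
#' @export
solarZenith <- function(t, lat, lon) {
  t <- asUTC(t)
  sp <- solarPosition(t)
  lt <- as.POSIXlt(t, tz = "UTC")
  mins <- lt$hour * 60 + lt$min + lt$sec / 60
  tst <- mins + 4 * lon + sp$eot           # true solar time, minutes
  ha <- tst / 4 - 180                      # hour angle, degrees
  phi <- lat * pi / 180
  dec <- sp$declination * pi / 180
  cosz <- sin(phi) * sin(dec) + cos(phi) * cos(dec) * cos(ha * pi / 180)
  acos(pmin(1, pmax(-1, cosz))) * 180 / pi
}

#' Predict twilight times for a date and location
#'
#' Forward model of the threshold method: the two times on a civil date at
#' which the solar zenith crosses `zenith_deg` at the given position.
#' Returns `NA` for both when the sun never reaches that zenith (polar day
#' or night at that zenith). Vectorised over `date`, `lat`, `lon`.
#'
#' Solar declination and the equation of time are evaluated at local
#' apparent noon, so a twilight pair and its midpoint share one solar
#' geometry; [thresholdLocation()] inverts exactly that geometry.
#'
#' @param date Date (or coercible) -- the local civil date of the light
#'   period.
#' @param lat,lon decimal degrees.
#' @param zenith_deg zenith angle defining twilight (typically 90--98 for
#'   light-logger thresholds).
#' @return data.frame with POSIXct columns `sunrise` and `sunset` (UTC).
#' @export
predictTwilights <- function(date, lat, lon, zenith_deg) {
  date <- as.Date(date)
  n <- max(length(date), length(lat), length(lon))
  date <- rep_len(date, n); lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  # approximate solar noon: 12:00 UTC shifted by longitude, then refined
  t0 <- as.POSIXct(paste(format(date), "12:00:00"), tz = "UTC") - lon / 15 * 3600
  sp <- solarPosition(t0)
  noon_min <- 720 - 4 * lon - sp$eot       # solar noon, minutes UTC
  t_noon <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC") + noon_min * 60
  sp <- solarPosition(t_noon)
  phi <- lat * pi / 180
  dec <- sp$declination * pi / 180
  cosH <- (cos(zenith_deg * pi / 180) - sin(phi) * sin(dec)) /
    (cos(phi) * cos(dec))
  H <- acos(pmin(1, pmax(-1, cosH))) * 180 / pi   # degrees
  none <- abs(cosH) > 1
  half <- H * 4                                    # minutes, 4 min per degree
  sunrise <- t_noon - half * 60
  sunset <- t_noon + half * 60
  sunrise[none] <- NA
  sunset[none] <- NA
  data.frame(sunrise = sunrise, sunset = sunset)
}

#' Threshold-method location from one twilight pair
#'
#' Inverts solar geometry for a sunrise/sunset pair observed at a calibrated
#' zenith angle: longitude from the twilight midpoint against apparent solar
#' noon (equation of time applied), latitude from day length and solar
#' declination. Near the equinoxes day length is ~12 h at every latitude,
#' so latitude is unidentifiable; such fixes keep their longitude but carry
#' `flag = "latitude_unreliable"` (day length within `equinox_min` minutes
#' of 12 h, or no latitude solves the day-length equation).
#'
#' @param sunrise,sunset POSIXct UTC twilight times of one light period.
#' @param zenith_deg calibrated zenith angle, degrees.
#' @param equinox_min half-width (minutes) of the day-length window around
#'   12 h inside which latitude is flagged unreliable. Default 8.
#' @return data.frame with `lat`, `lon`, `flag` ("ok" or
#'   "latitude_unreliable").
#' @export
thresholdLocation <- function(sunrise, sunset, zenith_deg, equinox_min = 8) {
  sunrise <- asUTC(sunrise); sunset <- asUTC(sunset)
  if (any(sunset <= sunrise)) stop("sunset must follow sunrise")
  daylen <- as.numeric(difftime(sunset, sunrise, units = "mins"))
  if (any(daylen >= 24 * 60)) stop("day length must be below 24 h")
  tmid <- sunrise + as.numeric(difftime(sunset, sunrise, units = "secs")) / 2
  sp <- solarPosition(tmid)
  lt <- as.POSIXlt(tmid, tz = "UTC")
  mid_min <- lt$hour * 60 + lt$min + lt$sec / 60
  lon <- (720 - sp$eot - mid_min) / 4
  lon <- wrapLon(lon)
  # latitude: solve sin(phi) sin(dec) + cos(phi) cos(dec) cos(H) = cos(z)
  dec <- sp$declination * pi / 180
  H <- (daylen / 2) / 4 * pi / 180         # half day length as hour angle
  A <- sin(dec)
  B <- cos(dec) * cos(H)
  R <- sqrt(A^2 + B^2)
  psi <- atan2(B, A)
  s <- pmin(1, pmax(-1, cos(zenith_deg * pi / 180) / R))
  cand1 <- asin(s) - psi
  cand2 <- pi - asin(s) - psi
  pick <- function(c1, c2) {
    c1 <- (c1 + pi) %% (2 * pi) - pi
    c2 <- (c2 + pi) %% (2 * pi) - pi
    ifelse(abs(c1) <= pi / 2, c1, ifelse(abs(c2) <= pi / 2, c2, NA_real_))
  }
  phi <- pick(cand1, cand2)
  lat <- phi * 180 / pi
  degenerate <- abs(cos(zenith_deg * pi / 180) / R) > 1 | is.na(phi)
  flag <- ifelse(degenerate | abs(daylen - 720) < equinox_min,
                 "latitude_unreliable", "ok")
  lat[degenerate] <- NA_real_
  data.frame(lat = lat, lon = lon, flag = flag, stringsAsFactors = FALSE)
}

# -- small internal helpers ---------------------------------------------------

asUTC <- function(t) {
  if (inherits(t, "POSIXct")) {
    attr(t, "tzone") <- "UTC"
    return(t)
  }
  as.POSIXct(t, tz = "UTC")
}

wrapLon <- function(lon) {
  lon <- (lon + 180) %% 360 - 180
  ifelse(lon == -180, 180, lon)
}

clampLat <- function(lat) pmin(90, pmax(-90, lat))
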