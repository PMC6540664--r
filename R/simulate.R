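#' Noise model for simulated light series
#'
#' Forward model of the twilight error process: log-normal twilight delays
#' (shading makes sunrise late and sunset early by `rlnorm(delay_meanlog,
#' delay_sdlog)` minutes), transient daytime shading events that darken the
#' sensor, and clipping at the sensor maximum. `delay_meanlog = -Inf` turns
#' delays off (noise-free twilights).
#'
#' @param delay_meanlog,delay_sdlog log-normal delay parameters (minutes).
#' @param shading_rate expected shading events per day (Poisson).
#' @param shading_minutes duration of one shading event.
#' @param shading_depth fraction of light removed during an event (1 =
#'   fully dark).
#' @param sensor_max clipping ceiling, light units.
#' @param interval_min sampling interval; one of 1, 2, 5, 10 minutes.
#' @return object of class `NoiseConfig`.
#' @export
noiseConfig <- function(delay_meanlog = log(5), delay_sdlog = 0.6,
                        shading_rate = 0, shading_minutes = 30,
                        shading_depth = 1, sensor_max = 64,
                        interval_min = 5) {
  stopifnot(shading_rate >= 0, shading_minutes > 0,
            shading_depth >= 0, shading_depth <= 1,
            interval_min %in% c(1, 2, 5, 10))
  if (is.finite(delay_meanlog) && delay_sdlog < 0)
    stop("delay_sdlog must be >= 0")
  structure(list(delay_meanlog = delay_meanlog, delay_sdlog = delay_sdlog,
                 shading_rate = shading_rate,
                 shading_minutes = shading_minutes,
                 shading_depth = shading_depth, sensor_max = sensor_max,
                 interval_min = interval_min), class = "NoiseConfig")
}

#' Annual-track scenario
#'
#' Parameterises one simulated deployment: breeding at one of the built-in
#' sites, fall migration to the northern South American wintering grounds
#' (around 2--3 deg N), a winter split over one or more stationary sites,
#' and a spring migration back with a configurable number of stopovers.
#' Defaults emulate the observed movement structure: winter centred near
#' (2.5 N, 65 W), spring distances of roughly 2,600--5,100 km covered in
#' 16--57 days with 0--5 stopovers.
#'
#' @param site breeding-site code (one of [siteConfigs()]).
#' @param deploy_start,track_end tracking span (Dates).
#' @param fall_departure date the bird leaves the breeding site.
#' @param winter_arrival start of the first winter stationary period.
#' @param spring_initiation end of the last winter stationary period.
#' @param spring_arrival first day back at the breeding site.
#' @param n_winter_sites number of winter stationary sites.
#' @param n_stopovers number of spring stopovers.
#' @param stopover_days vector (recycled) of stopover durations, days.
#' @param winter_lat,winter_lon centre of the wintering area.
#' @param winter_jitter_deg SD of the random displacement of each winter
#'   site about the centre.
#' @return object of class `TrackScenario`.
#' @export
trackScenario <- function(site = "EEI",
                          deploy_start = NULL, track_end = NULL,
                          fall_departure = NULL, winter_arrival = NULL,
                          spring_initiation = NULL, spring_arrival = NULL,
                          n_winter_sites = NULL, n_stopovers = 3,
                          stopover_days = c(5, 4, 6),
                          winter_lat = 2.5, winter_lon = -65,
                          winter_jitter_deg = 1.5) {
  cfg <- siteConfigs(site)
  austral <- cfg$group == "austral"
  defaults <- if (austral) list(
    deploy_start = "2013-11-01", track_end = "2014-11-15",
    fall_departure = "2014-02-10", winter_arrival = "2014-04-05",
    spring_initiation = "2014-09-05", spring_arrival = "2014-10-08",
    n_winter_sites = 2L
  ) else list(
    deploy_start = "2013-10-15", track_end = "2014-10-20",
    fall_departure = "2014-02-20", winter_arrival = "2014-03-15",
    spring_initiation = "2014-08-05", spring_arrival = "2014-08-28",
    n_winter_sites = 1L
  )
  pick <- function(x, d) as.Date(if (is.null(x)) d else x)
  out <- list(
    site = cfg,
    deploy_start = pick(deploy_start, defaults$deploy_start),
    track_end = pick(track_end, defaults$track_end),
    fall_departure = pick(fall_departure, defaults$fall_departure),
    winter_arrival = pick(winter_arrival, defaults$winter_arrival),
    spring_initiation = pick(spring_initiation, defaults$spring_initiation),
    spring_arrival = pick(spring_arrival, defaults$spring_arrival),
    n_winter_sites = if (is.null(n_winter_sites)) defaults$n_winter_sites
                     else as.integer(n_winter_sites),
    n_stopovers = as.integer(n_stopovers),
    stopover_days = stopover_days,
    winter_lat = winter_lat, winter_lon = winter_lon,
    winter_jitter_deg = winter_jitter_deg)
  with(out, {
    if (!(deploy_start < fall_departure && fall_departure < winter_arrival &&
          winter_arrival < spring_initiation &&
          spring_initiation < spring_arrival && spring_arrival < track_end))
      stop("scenario dates are not in chronological order")
  })
  class(out) <- "TrackScenario"
  out
}

#' Simulate an annual track with ground truth
#'
#' Builds the itinerary of stationary legs (breeding, winter sites, spring
#' stopovers) implied by a [trackScenario()], interpolates daily transit
#' positions along great-circle segments, and retains the full phenology
#' truth table. Deterministic given `seed`.
#'
#' @param scenario a [trackScenario()].
#' @param seed integer RNG seed.
#' @return A `SimTrack`: list with `positions` (data.frame `date`, `lat`,
#'   `lon`), `legs` (stationary legs with kind), `truth` (true phenology:
#'   winter start, initiation, arrival, counts, distance, stopover days)
#'   and `scenario`.
#' @export
simulateAnnualTrack <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "TrackScenario"))
  set.seed(seed)
  sc <- scenario
  site <- sc$site

  # winter stationary sites around the wintering centre
  wlat <- sc$winter_lat + stats::rnorm(sc$n_winter_sites, 0, sc$winter_jitter_deg)
  wlon <- sc$winter_lon + stats::rnorm(sc$n_winter_sites, 0,
                                       2 * sc$winter_jitter_deg)
  wlat <- pmin(pmax(wlat, -5), 8)          # stay in the wintering belt
  winter_days <- as.integer(sc$spring_initiation - sc$winter_arrival) + 1L
  # split the winter span into n legs (>= 31 d each so every leg counts as
  # a winter site), separated by 2-day moves
  nw <- sc$n_winter_sites
  move <- 2L
  avail <- winter_days - move * (nw - 1L)
  if (avail < 31L * nw)
    stop("winter span too short for the requested number of winter sites")
  cuts <- if (nw > 1) sort(sample(seq(31L, avail - 31L * (nw - 1L)), nw - 1L))
          else integer(0)
  lens <- diff(c(0L, cuts, avail))
  while (any(lens < 31L)) {          # rebalance rare tight draws
    i <- which.min(lens); j <- which.max(lens)
    lens[i] <- lens[i] + 1L; lens[j] <- lens[j] - 1L
  }
  legs <- list()
  addLeg <- function(lat, lon, start, end, kind)
    legs[[length(legs) + 1L]] <<- data.frame(
      lat = lat, lon = lon, start = start, end = end, kind = kind,
      stringsAsFactors = FALSE)
  addLeg(site$lat, site$lon, sc$deploy_start, sc$fall_departure, "breeding")
  s <- sc$winter_arrival
  for (i in seq_len(nw)) {
    e <- s + lens[i] - 1L
    addLeg(wlat[i], wlon[i], s, e, "winter")
    s <- e + move + 1L
  }
  legs[[length(legs)]]$end <- sc$spring_initiation   # last winter leg ends
                                                     # at initiation
  # spring stopovers along the route from the last winter site to breeding
  last <- legs[[length(legs)]]
  spring_span <- as.integer(sc$spring_arrival - sc$spring_initiation)
  ns <- sc$n_stopovers
  sdays <- if (ns > 0) rep_len(sc$stopover_days, ns) else integer(0)
  transit_days <- spring_span - sum(sdays)
  if (transit_days < ns + 1)
    stop("spring span too short for the requested stopovers")
  if (ns > 0) {
    frac <- sort(stats::runif(ns, 0.15, 0.85))
    t_before <- round(diff(c(0, frac, 1)) * transit_days)
    t_before[length(t_before)] <- transit_days - sum(t_before[-length(t_before)])
    # every transit hop needs at least one movement day
    while (any(t_before < 1)) {
      i <- which.min(t_before); j <- which.max(t_before)
      t_before[i] <- t_before[i] + 1L; t_before[j] <- t_before[j] - 1L
    }
    s <- sc$spring_initiation
    for (i in seq_len(ns)) {
      s <- s + t_before[i]
      e <- s + sdays[i] - 1L
      lat <- last$lat + frac[i] * (site$lat - last$lat) +
        stats::rnorm(1, 0, 0.5)
      lon <- last$lon + frac[i] * (site$lon - last$lon) +
        stats::rnorm(1, 0, 0.5)
      addLeg(lat, lon, s, e, "stopover")
      s <- e + 1L
    }
  }
  addLeg(site$lat, site$lon, sc$spring_arrival, sc$track_end, "breeding")
  legs <- do.call(rbind, legs)

  # daily positions: leg position inside legs, great-circle-ish linear
  # interpolation across transits
  dates <- seq(sc$deploy_start, sc$track_end, by = "day")
  lat <- lon <- rep(NA_real_, length(dates))
  for (i in seq_len(nrow(legs))) {
    ii <- dates >= legs$start[i] & dates <= legs$end[i]
    lat[ii] <- legs$lat[i]; lon[ii] <- legs$lon[i]
  }
  miss <- is.na(lat)
  lat[miss] <- stats::approx(as.numeric(dates)[!miss], lat[!miss],
                             as.numeric(dates)[miss])$y
  lon[miss] <- stats::approx(as.numeric(dates)[!miss], lon[!miss],
                             as.numeric(dates)[miss])$y

  winter_legs <- legs[legs$kind == "winter", ]
  lastw <- winter_legs[nrow(winter_legs), ]
  truth <- list(
    winter_start = winter_legs$start[1],
    spring_initiation = sc$spring_initiation,
    spring_arrival = sc$spring_arrival,
    n_winter_sites = nrow(winter_legs),
    n_spring_stopovers = sum(legs$kind == "stopover"),
    spring_stopover_days = sum(sdays),
    spring_duration_days = as.integer(sc$spring_arrival -
                                        sc$spring_initiation) + 1L,
    winter_duration_days = as.integer(sc$spring_initiation -
                                        winter_legs$start[1]) + 1L,
    spring_distance_km = greatCircleKm(lastw$lat, lastw$lon,
                                       site$lat, site$lon),
    last_winter_lat = lastw$lat, last_winter_lon = lastw$lon)
  truth$spring_rate_km_per_day <-
    truth$spring_distance_km / truth$spring_duration_days

  # transit speed sanity: daily steps within the behavioural ceiling
  step <- greatCircleKm(lat[-1], lon[-1], lat[-length(lat)], lon[-length(lon)])
  stopifnot(max(step) <= 24 * 80)

  structure(list(positions = data.frame(date = dates, lat = lat, lon = lon),
                 legs = legs, truth = truth, scenario = sc, seed = seed),
            class = "SimTrack")
}

#' @export
print.SimTrack <- function(x, ...) {
  cat(sprintf(paste0("SimTrack (%s, seed %d): %d days, %d winter site(s), ",
                     "%d stopover(s), spring %d km in %d d\n"),
              x$scenario$site$code, x$seed, nrow(x$positions),
              x$truth$n_winter_sites, x$truth$n_spring_stopovers,
              round(x$truth$spring_distance_km),
              x$truth$spring_duration_days))
  invisible(x)
}

#' Simulate a geolocator light series from a track
#'
#' Generates ambient light on a regular sampling grid along the track: a
#' logistic response to solar altitude, scaled so that the light crosses
#' `threshold` exactly when the sun reaches `zenith_deg`, clipped at the
#' sensor maximum. Twilight delays shift the morning limb later and the
#' evening limb earlier by independent log-normal draws; shading events
#' darken the sensor for their duration. Deterministic given `seed`.
#'
#' @param track a `SimTrack`.
#' @param zenith_deg true zenith angle of the threshold crossing.
#' @param noise a [noiseConfig()].
#' @param threshold light level at the zenith crossing (default 0.5).
#' @param steepness logistic slope in light-units per degree of solar
#'   altitude (default 1.2).
#' @param seed RNG seed.
#' @return a [lightSeries()].
#' @export
simulateLight <- function(track, zenith_deg = 96, noise = noiseConfig(),
                          threshold = 0.5, steepness = 1.2, seed = 1L) {
  stopifnot(inherits(track, "SimTrack"), inherits(noise, "NoiseConfig"))
  set.seed(seed)
  pos <- track$positions
  n_days <- nrow(pos)
  t0 <- as.POSIXct(paste(format(pos$date[1]), "00:00:00"), tz = "UTC")
  tend <- as.POSIXct(paste(format(pos$date[n_days]), "23:59:59"), tz = "UTC")
  times <- seq(t0, tend, by = noise$interval_min * 60)
  day_idx <- pmin(pmax(as.integer(as.Date(times, tz = "UTC") - pos$date[1]) + 1L,
                       1L), n_days)
  lat <- pos$lat[day_idx]; lon <- pos$lon[day_idx]

  # per-day twilight shifts (minutes): sunrise late, sunset early
  if (is.finite(noise$delay_meanlog)) {
    d_sr <- stats::rlnorm(n_days, noise$delay_meanlog, noise$delay_sdlog)
    d_ss <- stats::rlnorm(n_days, noise$delay_meanlog, noise$delay_sdlog)
  } else d_sr <- d_ss <- numeric(n_days)

  # morning samples see the solar altitude of (t - d_sr); evening samples
  # that of (t + d_ss); split at local solar noon
  local_hour <- (as.numeric(times, units = "secs") / 3600 + lon / 15) %% 24
  morning <- local_hour < 12
  shift <- ifelse(morning, -d_sr[day_idx], d_ss[day_idx]) * 60
  zen <- solarZenith(times + shift, lat, lon)
  alt <- 90 - zen
  alt0 <- 90 - zenith_deg
  a0 <- alt0 + log((noise$sensor_max - threshold) / threshold) / steepness
  light <- noise$sensor_max / (1 + exp(-steepness * (alt - a0)))

  if (noise$shading_rate > 0) {
    n_ev <- stats::rpois(n_days, noise$shading_rate)
    for (d in which(n_ev > 0)) {
      starts <- as.POSIXct(paste(format(pos$date[d]), "00:00:00"),
                           tz = "UTC") + stats::runif(n_ev[d], 0, 86400)
      for (s in as.numeric(starts)) {
        hit <- as.numeric(times) >= s &
          as.numeric(times) < s + noise$shading_minutes * 60
        light[hit] <- light[hit] * (1 - noise$shading_depth)
      }
    }
  }
  light <- pmin(pmax(light, 0), noise$sensor_max)
  lightSeries(times, light, sprintf("sim-%s-%d", track$scenario$site$code,
                                    track$seed))
}

#' Write a track's truth table
#'
#' @param track a `SimTrack`.
#' @param path CSV path for the stationary legs; the scalar truth values
#'   are appended as a JSON sidecar at `paste0(path, ".json")`.
#' @export
writeTrackTruth <- function(track, path) {
  legs <- track$legs
  legs$start <- format(legs$start); legs$end <- format(legs$end)
  utils::write.csv(legs, path, row.names = FALSE, quote = FALSE)
  tr <- track$truth
  tr$winter_start <- format(tr$winter_start)
  tr$spring_initiation <- format(tr$spring_initiation)
  tr$spring_arrival <- format(tr$spring_arrival)
  jsonlite::write_json(tr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
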