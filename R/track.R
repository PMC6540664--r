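#' Flight-speed prior
#'
#' Beta-distributed behavioural model of plausible flight speeds between
#' consecutive daily locations: `speed / max_speed_kmh` (clamped into the
#' open unit interval) follows Beta(`shape1`, `shape2`).
#'
#' The default `Beta(0.7, 8)` is monotone decreasing: most days are
#' stationary, with enough tail mass for migratory hops (mean speed
#' ~6.4 km/h ~ 154 km/day at the default ceiling, consistent with observed
#' passerine migration rates).
#'
#' @param shape1,shape2 beta shape parameters (both > 0).
#' @param max_speed_kmh speed mapped to 1 on the beta support.
#' @return object of class `SpeedPrior`.
#' @export
speedPrior <- function(shape1 = 0.7, shape2 = 8, max_speed_kmh = 80) {
  stopifnot(shape1 > 0, shape2 > 0, max_speed_kmh > 0)
  structure(list(shape1 = shape1, shape2 = shape2,
                 max_speed_kmh = max_speed_kmh), class = "SpeedPrior")
}

#' Sampler configuration
#'
#' Protocol of the Metropolis sampler: `n_runs` successive runs of
#' `n_chains` chains with `n_iter` iterations each. All runs but the last
#' are burn-in; each run is initialised at the previous run's median daily
#' locations; only the final run is retained, thinned by `thin`.
#'
#' @param n_iter iterations per run (default 5000).
#' @param n_chains chains per run (default 3).
#' @param n_runs number of runs (default 3; the first `n_runs - 1` are
#'   burn-in).
#' @param thin keep every `thin`-th iteration of the final run (default 2).
#' @param proposal_sd_deg SD of the Gaussian random-walk proposal, degrees.
#' @param seed RNG seed; the sampler is deterministic given it.
#' @return object of class `MCMCConfig`.
#' @export
mcmcConfig <- function(n_iter = 5000, n_chains = 3, n_runs = 3, thin = 2,
                       proposal_sd_deg = 0.5, seed = 1L) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (n_chains < 1) stop("n_chains must be >= 1")
  if (n_runs < 1) stop("n_runs must be >= 1")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(n_iter = as.integer(n_iter), n_chains = as.integer(n_chains),
                 n_runs = as.integer(n_runs), thin = as.integer(thin),
                 proposal_sd_deg = proposal_sd_deg, seed = as.integer(seed)),
            class = "MCMCConfig")
}

#' Land mask
#'
#' A set of closed polygons (lon/lat vertex matrices) on which positions
#' are permitted. Point-in-polygon lookup uses even-odd ray casting, so a
#' ring contained in another acts as a hole.
#'
#' @param polygons list of two-column matrices (`lon`, `lat`), each a closed
#'   or implicitly closed ring.
#' @return object of class `LandMask` (a function-backed list).
#' @export
landMask <- function(polygons) {
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2) stop("each polygon must have two columns (lon, lat)")
    p
  })
  structure(list(polygons = polygons), class = "LandMask")
}

#' @rdname landMask
#' @param path GeoJSON file containing Polygon/MultiPolygon features (outer
#'   rings and holes both become rings).
#' @export
readLandMaskGeoJSON <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  rings <- list()
  addGeom <- function(geom) {
    if (is.null(geom$type)) return()
    if (geom$type == "Polygon") {
      for (ring in geom$coordinates)
        rings[[length(rings) + 1L]] <<-
          do.call(rbind, lapply(ring, function(xy) c(xy[[1]], xy[[2]])))
    } else if (geom$type == "MultiPolygon") {
      for (poly in geom$coordinates) for (ring in poly)
        rings[[length(rings) + 1L]] <<-
          do.call(rbind, lapply(ring, function(xy) c(xy[[1]], xy[[2]])))
    }
  }
  if (identical(g$type, "FeatureCollection")) {
    for (f in g$features) addGeom(f$geometry)
  } else if (identical(g$type, "Feature")) {
    addGeom(g$geometry)
  } else addGeom(g)
  if (!length(rings)) stop("no polygon geometry found in GeoJSON")
  landMask(rings)
}

#' @rdname landMask
#' @param mask a `LandMask`.
#' @param lat,lon query coordinates (vectorised).
#' @return `onMask()` returns a logical vector.
#' @export
onMask <- function(mask, lat, lon) {
  stopifnot(inherits(mask, "LandMask"))
  inside <- rep(FALSE, length(lat))
  for (p in mask$polygons) {
    px <- p[, 1]; py <- p[, 2]
    n <- length(px)
    j <- c(n, seq_len(n - 1L))
    hit <- rep(FALSE, length(lat))
    for (k in seq_len(n)) {           # even-odd rule, edge (j[k] -> k)
      x1 <- px[j[k]]; y1 <- py[j[k]]; x2 <- px[k]; y2 <- py[k]
      crosses <- ((y1 > lat) != (y2 > lat)) &
        (lon < (x2 - x1) * (lat - y1) / (y2 - y1) + x1)
      hit <- xor(hit, crosses & !is.na(crosses))
    }
    inside <- xor(inside, hit)
  }
  inside
}

#' Twilight log-likelihood of a location
#'
#' Log-likelihood of one day's observed twilight pair at a candidate
#' location under a calibration model: the sum over the day's twilights of
#' the log-normal log-density of the delay (observed minus predicted for
#' sunrise; predicted minus observed for sunset, both in minutes). A
#' non-positive delay, or a location where the calibrated zenith is never
#' reached (polar day/night), contributes `-Inf`.
#'
#' @param date civil date of the light period (Date, vectorised).
#' @param sunrise,sunset observed twilight times (POSIXct UTC, vectorised).
#' @param lat,lon candidate coordinates (vectorised with `date`).
#' @param calib a [calibrationModel()].
#' @param delay_floor minimum positive delay in minutes (default 0.01).
#' @return numeric vector of per-day log-likelihoods.
#' @export
twilightLogLik <- function(date, sunrise, sunset, lat, lon, calib,
                           delay_floor = 0.01) {
  geom <- dayGeometry(as.Date(date), asUTC(sunrise), asUTC(sunset))
  twilightLLNum(geom, lat, lon, calib, delay_floor)
}

# Precompute per-day solar geometry so the sampler's inner loop is pure
# arithmetic: declination/eot are evaluated once per day at the observed
# twilight midpoint (the same reference thresholdLocation inverts).
dayGeometry <- function(date, sunrise, sunset) {
  mid <- sunrise + as.numeric(difftime(sunset, sunrise, units = "secs")) / 2
  sp <- solarPosition(mid)
  midnight <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC")
  list(
    date = date,
    sr_min = as.numeric(difftime(sunrise, midnight, units = "mins")),
    ss_min = as.numeric(difftime(sunset, midnight, units = "mins")),
    mid_min = as.numeric(difftime(mid, midnight, units = "mins")),
    sindec = sin(sp$declination * pi / 180),
    cosdec = cos(sp$declination * pi / 180),
    eot = sp$eot
  )
}

# per-day log-likelihood from precomputed geometry; lat/lon vectors of the
# same length as the geometry
twilightLLNum <- function(geom, lat, lon, calib, delay_floor = 0.01) {
  phi <- lat * pi / 180
  cosz <- cos(calib$zenith_deg * pi / 180)
  cosH <- (cosz - sin(phi) * geom$sindec) / (cos(phi) * geom$cosdec)
  noon <- 720 - 4 * lon - geom$eot
  noon <- noon + 1440 * round((geom$mid_min - noon) / 1440)
  H <- acos(pmin(1, pmax(-1, cosH))) * 180 / pi
  half <- 4 * H                                 # minutes
  d_sr <- geom$sr_min - (noon - half)           # sunrise observed late
  d_ss <- (noon + half) - geom$ss_min           # sunset observed early
  ll <- stats::dlnorm(pmax(d_sr, delay_floor), calib$err_meanlog,
                      calib$err_sdlog, log = TRUE) +
    stats::dlnorm(pmax(d_ss, delay_floor), calib$err_meanlog,
                  calib$err_sdlog, log = TRUE)
  bad <- abs(cosH) > 1 | d_sr <= 0 | d_ss <= 0
  ll[bad] <- -Inf
  ll
}

#' Sample daily location posteriors from twilight times
#'
#' Metropolis MCMC over one location per twilight day. The target combines
#' the log-normal twilight likelihood, a beta flight-speed prior on the
#' great-circle speed between consecutive days, and (optionally) a land
#' mask under which off-mask locations have zero posterior mass. Proposals
#' are Gaussian random walks on (lat, lon); latitude reflects at the poles
#' and longitude wraps. Days are updated in two alternating blocks (odd and
#' even indices) so that each block's conditionals factorise and the sweep
#' vectorises over days.
#'
#' Following the run protocol, the first `cfg$n_runs - 1` runs are burn-in:
#' after each, the per-day posterior medians re-initialise the next run.
#' Only the final run's draws are kept, thinned by `cfg$thin`, pooled over
#' chains.
#'
#' @param pairs data.frame from [twilightPairs()] (`date`, `sunrise`,
#'   `sunset`), one row per day; at least 2 rows (4 twilights).
#' @param calib a [calibrationModel()].
#' @param prior a [speedPrior()].
#' @param mask optional [landMask()]; applied to every day.
#' @param cfg an [mcmcConfig()].
#' @param delay_floor minimum positive delay, minutes.
#' @param lat_range latitude support (degrees). With a calibrated zenith
#'   beyond 90 the twilight-to-twilight day length is non-monotonic in
#'   latitude and a spurious mode exists near the poles where the sun
#'   grazes the calibrated zenith all day; the default `c(-80, 80)`
#'   excludes those degenerate caps (a land mask removes them too).
#' @return A `LocationPosterior`: list with `date`, matrices `lat_samples`
#'   and `lon_samples` (days x retained draws), `summary` (per-day median
#'   and central 95% credible interval), and `acceptance` (overall
#'   acceptance rate).
#' @export
sampleTrackPosterior <- function(pairs, calib, prior = speedPrior(),
                                 mask = NULL, cfg = mcmcConfig(),
                                 delay_floor = 0.01,
                                 lat_range = c(-80, 80)) {
  stopifnot(inherits(cfg, "MCMCConfig"), inherits(prior, "SpeedPrior"))
  if (nrow(pairs) < 2) stop("need at least 4 twilights (2 twilight days)")
  set.seed(cfg$seed)
  geom <- dayGeometry(as.Date(pairs$date), asUTC(pairs$sunrise),
                      asUTC(pairs$sunset))
  n <- nrow(pairs)
  dt_h <- as.numeric(diff(as.Date(pairs$date))) * 24   # hours between days
  eps <- 1e-6

  dayLL <- function(lat, lon, idx) {
    ll <- twilightLLNum(subGeom(geom, idx), lat, lon, calib, delay_floor)
    ll[lat < lat_range[1] | lat > lat_range[2]] <- -Inf
    if (!is.null(mask)) ll[!onMask(mask, lat, lon)] <- -Inf
    ll
  }
  edgeLL <- function(lat1, lon1, lat2, lon2, hours) {
    sp <- greatCircleKm(lat1, lon1, lat2, lon2) / hours / prior$max_speed_kmh
    stats::dbeta(pmin(pmax(sp, eps), 1 - eps), prior$shape1, prior$shape2,
                 log = TRUE)
  }

  # initial state: threshold locations with the median calibrated delay
  # removed (raw threshold fixes sit at delay 0, outside the error support)
  m <- exp(calib$err_meanlog) * 60
  init <- thresholdLocation(asUTC(pairs$sunrise) - m,
                            asUTC(pairs$sunset) + m, calib$zenith_deg)
  lat0 <- init$lat
  lat0[init$flag != "ok"] <- NA
  lat0 <- fillSeries(lat0)
  lon0 <- fillSeries(init$lon)
  lat0 <- pmin(pmax(lat0, lat_range[1]), lat_range[2])
  if (!is.null(mask)) {
    off <- !onMask(mask, lat0, lon0)
    if (any(off)) lat0[off] <- snapToMask(mask, lat0[off], lon0[off])$lat
    if (any(off)) lon0[off] <- snapToMask(mask, lat0[off], lon0[off])$lon
  }
  state <- cbind(lat0, lon0)

  odd <- seq(1L, n, by = 2L)
  even <- if (n > 1) seq(2L, n, by = 2L) else integer(0)
  n_accept <- 0; n_prop <- 0
  keep_every <- cfg$thin
  n_keep <- cfg$n_iter %/% keep_every

  sweepBlock <- function(state, idx) {
    prop_lat <- state[idx, 1] + stats::rnorm(length(idx), 0, cfg$proposal_sd_deg)
    prop_lon <- state[idx, 2] + stats::rnorm(length(idx), 0, cfg$proposal_sd_deg)
    prop_lat <- reflectLat(prop_lat)
    prop_lon <- wrapLon(prop_lon)
    d_cur <- dayLL(state[idx, 1], state[idx, 2], idx)
    d_new <- dayLL(prop_lat, prop_lon, idx)
    e_cur <- e_new <- 0
    left <- idx[idx > 1L]
    if (length(left)) {
      li <- match(left, idx)
      e_cur_l <- edgeLL(state[left - 1L, 1], state[left - 1L, 2],
                        state[left, 1], state[left, 2], dt_h[left - 1L])
      e_new_l <- edgeLL(state[left - 1L, 1], state[left - 1L, 2],
                        prop_lat[li], prop_lon[li], dt_h[left - 1L])
      e_cur <- numeric(length(idx)); e_new <- numeric(length(idx))
      e_cur[li] <- e_cur_l; e_new[li] <- e_new_l
    }
    right <- idx[idx < n]
    if (length(right)) {
      ri <- match(right, idx)
      e_cur_r <- edgeLL(state[right, 1], state[right, 2],
                        state[right + 1L, 1], state[right + 1L, 2], dt_h[right])
      e_new_r <- edgeLL(prop_lat[ri], prop_lon[ri],
                        state[right + 1L, 1], state[right + 1L, 2], dt_h[right])
      if (length(e_cur) == 1 && identical(e_cur, 0)) {
        e_cur <- numeric(length(idx)); e_new <- numeric(length(idx))
      }
      e_cur[ri] <- e_cur[ri] + e_cur_r; e_new[ri] <- e_new[ri] + e_new_r
    }
    logr <- (d_new + e_new) - (d_cur + e_cur)
    acc <- log(stats::runif(length(idx))) < logr
    acc[is.na(acc)] <- FALSE
    state[idx[acc], 1] <- prop_lat[acc]
    state[idx[acc], 2] <- prop_lon[acc]
    n_accept <<- n_accept + sum(acc)
    n_prop <<- n_prop + length(idx)
    state
  }

  lat_samples <- lon_samples <- NULL
  for (run in seq_len(cfg$n_runs)) {
    final <- run == cfg$n_runs
    if (final) {
      lat_samples <- matrix(NA_real_, n, n_keep * cfg$n_chains)
      lon_samples <- matrix(NA_real_, n, n_keep * cfg$n_chains)
    }
    run_lat <- matrix(NA_real_, n, cfg$n_iter * cfg$n_chains)
    run_lon <- matrix(NA_real_, n, cfg$n_iter * cfg$n_chains)
    for (chain in seq_len(cfg$n_chains)) {
      st <- state
      st[, 1] <- reflectLat(st[, 1] + stats::rnorm(n, 0, 0.1))
      st[, 2] <- wrapLon(st[, 2] + stats::rnorm(n, 0, 0.1))
      # fall back to the shared initial state if the jitter broke support
      bad <- !is.finite(dayLL(st[, 1], st[, 2], seq_len(n)))
      st[bad, ] <- state[bad, ]
      kept <- 0L
      for (it in seq_len(cfg$n_iter)) {
        st <- sweepBlock(st, odd)
        if (length(even)) st <- sweepBlock(st, even)
        col <- (chain - 1L) * cfg$n_iter + it
        run_lat[, col] <- st[, 1]; run_lon[, col] <- st[, 2]
        if (final && it %% keep_every == 0L) {
          kept <- kept + 1L
          kcol <- (chain - 1L) * n_keep + kept
          lat_samples[, kcol] <- st[, 1]
          lon_samples[, kcol] <- st[, 2]
        }
      }
    }
    # median daily location of this run initialises the next
    state <- cbind(apply(run_lat, 1, stats::median),
                   apply(run_lon, 1, stats::median))
  }

  acc_rate <- n_accept / n_prop
  if (acc_rate < 0.05 || acc_rate > 0.80)
    warning(sprintf(paste0("Metropolis acceptance rate %.1f%% outside 5-80%%;",
                           " consider adjusting proposal_sd_deg"),
                    100 * acc_rate))
  out <- list(date = as.Date(pairs$date),
              lat_samples = lat_samples, lon_samples = lon_samples,
              summary = NULL, acceptance = acc_rate)
  class(out) <- "LocationPosterior"
  out$summary <- summarizePosterior(out)
  out
}

#' @export
print.LocationPosterior <- function(x, ...) {
  cat(sprintf(paste0("LocationPosterior: %d days (%s to %s), %d retained",
                     " draws/day, acceptance %.1f%%\n"),
              length(x$date), format(min(x$date)), format(max(x$date)),
              ncol(x$lat_samples), 100 * x$acceptance))
  invisible(x)
}

#' Summarise a location posterior
#'
#' Componentwise per-day median and central 95% credible interval
#' (2.5--97.5% linear-interpolation quantiles) of retained samples.
#'
#' @param post a `LocationPosterior`, or a list with matrices
#'   `lat_samples`/`lon_samples` (days x draws) and `date`.
#' @param level credible level (default 0.95).
#' @return data.frame with `date`, `lat_med`, `lat_lo`, `lat_hi`,
#'   `lon_med`, `lon_lo`, `lon_hi`.
#' @export
summarizePosterior <- function(post, level = 0.95) {
  if (ncol(post$lat_samples) < 10)
    stop("need at least 10 retained samples per day")
  q <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
  qa <- function(m) t(apply(m, 1, stats::quantile, probs = q, names = FALSE))
  la <- qa(post$lat_samples); lo <- qa(post$lon_samples)
  data.frame(date = as.Date(post$date),
             lat_med = la[, 2], lat_lo = la[, 1], lat_hi = la[, 3],
             lon_med = lo[, 2], lon_lo = lo[, 1], lon_hi = lo[, 3])
}

#' Export a posterior
#'
#' `writePosteriorSamples()` writes the long per-draw CSV (`date`,
#' `sample_id`, `lat`, `lon`); `writePosteriorSummary()` writes the per-day
#' summary CSV.
#'
#' @param post a `LocationPosterior`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePosteriorSamples <- function(post, path) {
  S <- ncol(post$lat_samples)
  utils::write.csv(
    data.frame(date = rep(format(post$date), each = S),
               sample_id = rep(seq_len(S), length(post$date)),
               lat = as.vector(t(post$lat_samples)),
               lon = as.vector(t(post$lon_samples))),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePosteriorSamples
#' @export
writePosteriorSummary <- function(post, path) {
  s <- post$summary
  s$date <- format(s$date)
  utils::write.csv(s, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePosteriorSamples
#' @export
readPosteriorSummary <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$date <- as.Date(d$date)
  d
}

# -- internals ----------------------------------------------------------------

subGeom <- function(geom, idx) {
  lapply(geom, function(v) v[idx])
}

reflectLat <- function(lat) {
  lat <- ((lat + 90) %% 360) - 90
  ifelse(lat > 90, 180 - lat, lat)
}

# linear interpolation over index for interior NAs, nearest value at ends
fillSeries <- function(x) {
  if (all(is.na(x))) stop("no usable initial locations")
  idx <- seq_along(x)
  stats::approx(idx[!is.na(x)], x[!is.na(x)], xout = idx, rule = 2)$y
}

# move off-mask points to the nearest polygon vertex (coarse but only used
# for initialisation)
snapToMask <- function(mask, lat, lon) {
  verts <- do.call(rbind, mask$polygons)
  out_lat <- lat; out_lon <- lon
  for (i in seq_along(lat)) {
    d <- greatCircleKm(lat[i], lon[i], verts[, 2], verts[, 1])
    j <- which.min(d)
    out_lat[i] <- verts[j, 2]; out_lon[i] <- verts[j, 1]
  }
  list(lat = out_lat, lon = out_lon)
}
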