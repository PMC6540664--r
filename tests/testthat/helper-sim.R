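# shared fixtures built in code: twilight pairs with known truth, small
# posteriors with prescribed medians/CrIs

# observed twilight pairs for a bird sitting at (lat, lon): geometric
# twilights at `zenith` plus one-sided log-normal delays (sunrise late,
# sunset early); delays in minutes
makeStationaryPairs <- function(lat, lon, dates, zenith = 96,
                                meanlog = log(5), sdlog = 0.6, seed = 1) {
  set.seed(seed)
  tw <- predictTwilights(dates, lat, lon, zenith)
  n <- length(dates)
  d_sr <- if (is.finite(meanlog)) rlnorm(n, meanlog, sdlog) else numeric(n)
  d_ss <- if (is.finite(meanlog)) rlnorm(n, meanlog, sdlog) else numeric(n)
  data.frame(date = dates,
             sunrise = tw$sunrise + d_sr * 60,
             sunset = tw$sunset - d_ss * 60)
}

# pairs along an arbitrary daily track (data.frame date, lat, lon)
makeTrackPairs <- function(positions, zenith = 96, meanlog = log(5),
                           sdlog = 0.6, seed = 1) {
  set.seed(seed)
  tw <- predictTwilights(positions$date, positions$lat, positions$lon, zenith)
  n <- nrow(positions)
  d_sr <- if (is.finite(meanlog)) rlnorm(n, meanlog, sdlog) else numeric(n)
  d_ss <- if (is.finite(meanlog)) rlnorm(n, meanlog, sdlog) else numeric(n)
  data.frame(date = positions$date,
             sunrise = tw$sunrise + d_sr * 60,
             sunset = tw$sunset - d_ss * 60)
}

# a fake LocationPosterior with prescribed per-day medians and CrI
# half-widths (Gaussian scatter), for scheduler tests
makePosterior <- function(date, lat, lon, half_lat = 0.5, half_lon = 0.5,
                          n_samples = 60, seed = 1) {
  set.seed(seed)
  n <- length(date)
  sd_lat <- rep_len(half_lat, n) / 1.96
  sd_lon <- rep_len(half_lon, n) / 1.96
  lat_s <- t(vapply(seq_len(n), function(i) lat[i] + rnorm(n_samples, 0, sd_lat[i]),
                    numeric(n_samples)))
  lon_s <- t(vapply(seq_len(n), function(i) lon[i] + rnorm(n_samples, 0, sd_lon[i]),
                    numeric(n_samples)))
  post <- list(date = as.Date(date), lat_samples = lat_s, lon_samples = lon_s,
               acceptance = 0.5)
  class(post) <- "LocationPosterior"
  post$summary <- summarizePosterior(post)
  post
}

defaultCalib <- function(zenith = 96, meanlog = log(5), sdlog = 0.6)
  calibrationModel(zenith, meanlog, sdlog)

# a schedule assembled directly from period specs:
# list(c(duration_days, lat, lon), ...) laid end to end with 1-day gaps
makeSchedule <- function(specs, start = as.Date("2014-03-01"), gap = 3) {
  rows <- list()
  s <- start
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    e <- s + sp[1] - 1
    rows[[i]] <- data.frame(period_id = i, start = s, end = e,
                            duration_days = as.integer(sp[1]),
                            lat_med = sp[2], lon_med = sp[3],
                            lat_lo = sp[2] - 1, lat_hi = sp[2] + 1,
                            lon_lo = sp[3] - 1, lon_hi = sp[3] + 1,
                            kind = "stationary", stringsAsFactors = FALSE)
    s <- e + gap + 1
  }
  out <- do.call(rbind, rows)
  class(out) <- c("Schedule", "data.frame")
  out
}
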