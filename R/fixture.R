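#' Packaged Fork-tailed Flycatcher migration histories
#'
#' The reference table of 28 individual migration histories of Fork-tailed
#' Flycatchers tracked with light-level geolocators from four South
#' American breeding sites: 17 austral migrants (RED, RPL; Argentina) and
#' 11 intratropical migrants (DF, EEI; Brazil). Durations are in days,
#' distances in km, rates in km/day; one individual (id 3) has no
#' detectable spring arrival, so its duration and rate are missing.
#'
#' @return data.frame with columns `id`, `site`, `group`, `sex`,
#'   `n_winter_sites`, `winter_duration_days`, `n_spring_stopovers`,
#'   `spring_duration_days`, `spring_distance_km`,
#'   `spring_rate_km_per_day`, `spring_stopover_days`, `spring_initiation`
#'   (Date), `spring_arrival` (Date).
#' @export
flycatcherHistories <- function() {
  path <- system.file("extdata", "flycatcher_histories.csv",
                      package = "flytrack", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("NA", ""))
  d$spring_initiation <- as.Date(d$spring_initiation)
  d$spring_arrival <- as.Date(d$spring_arrival)
  d
}
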