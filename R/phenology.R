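#' Breeding-site configuration
#'
#' A breeding site with coordinates, migratory group, and (for the austral
#' sites) the first-arrival dates from transect censuses used to floor
#' geolocator-derived arrival estimates.
#'
#' @param code short site code.
#' @param lat,lon breeding coordinates, decimal degrees.
#' @param group `"austral"` or `"intratropical"`.
#' @param census named character/Date vector of first-observation dates,
#'   names = year. Must fall in September--December.
#' @return object of class `SiteConfig`.
#' @export
siteConfig <- function(code, lat, lon, group = c("austral", "intratropical"),
                       census = NULL) {
  group <- match.arg(group)
  if (!is.null(census)) {
    census <- as.Date(census)
    mo <- as.integer(format(census, "%m"))
    if (any(mo < 9 | mo > 12)) stop("census dates must fall in Sep-Dec")
    names(census) <- format(census, "%Y")
  }
  structure(list(code = code, lat = lat, lon = lon, group = group,
                 census = census), class = "SiteConfig")
}

#' Built-in breeding sites
#'
#' The four Fork-tailed Flycatcher breeding sites: DF (Brasilia, Brazil)
#' and EEI (Estacao Ecologica de Itirapina, Brazil), both intratropical,
#' and RED (Reserva Natural El Destino, Argentina) and RPL (Reserva
#' Provincial Parque Luro, Argentina), both austral. The austral sites
#' carry the El Destino census first-arrival dates (2010-10-10, 2011-09-29,
#' 2014-10-05, 2015-10-12) used to constrain spring arrival.
#'
#' @param code optional site code; when given, that single `SiteConfig` is
#'   returned.
#' @return A named list of `SiteConfig` objects, or one `SiteConfig`.
#' @export
siteConfigs <- function(code = NULL) {
  census <- c("2010" = "2010-10-10", "2011" = "2011-09-29",
              "2014" = "2014-10-05", "2015" = "2015-10-12")
  sites <- list(
    DF  = siteConfig("DF", -15.8, -47.8, "intratropical"),
    EEI = siteConfig("EEI", -22.3, -47.9, "intratropical"),
    RED = siteConfig("RED", -35.1, -57.4, "austral", census),
    RPL = siteConfig("RPL", -36.8, -64.3, "austral", census)
  )
  if (is.null(code)) sites else sites[[code]]
}

#' Delimit the winter period and spring initiation
#'
#' Applies the duration rules for the nonbreeding season: the winter period
#' begins with the first stationary period of at least `min_winter_days`
#' days; spring migration initiates at the end of the first such period
#' that is not followed by another period of `min_winter_days` or more
#' (i.e. the last long stationary period). Winter sites are the long
#' stationary periods between those bounds.
#'
#' The search is hemisphere-free ("fall" has no fixed months for birds
#' wintering March--September): it starts only after the deployment
#' residency -- by default the first stationary period of the schedule,
#' which is the breeding-season stint at the capture site -- has ended.
#'
#' @param schedule a `Schedule` spanning fall through spring.
#' @param min_winter_days duration defining a winter-grade stationary
#'   period (default 30).
#' @param search_from Date; only stationary periods starting after this
#'   date are considered. Default: the end of the schedule's first
#'   stationary period (the deployment residency).
#' @return list with `winter_start`, `winter_end` (= `initiation`),
#'   `initiation` (Date), `n_winter_sites`, `winter_duration_days`
#'   (inclusive), `last_winter_lat`, `last_winter_lon`, and `defined`
#'   (FALSE, with everything else NA, when no period qualifies).
#' @export
delimitWinter <- function(schedule, min_winter_days = 30,
                          search_from = NULL) {
  st <- schedule[schedule$kind == "stationary", ]
  st <- st[order(st$start), ]
  if (is.null(search_from) && nrow(st)) search_from <- st$end[1]
  if (!is.null(search_from)) st <- st[st$start > as.Date(search_from), ]
  big <- st[st$duration_days >= min_winter_days, ]
  if (!nrow(big)) {
    return(list(defined = FALSE, winter_start = as.Date(NA),
                winter_end = as.Date(NA), initiation = as.Date(NA),
                n_winter_sites = NA_integer_,
                winter_duration_days = NA_integer_,
                last_winter_lat = NA_real_, last_winter_lon = NA_real_))
  }
  winter_start <- big$start[1]
  last <- big[nrow(big), ]                  # first long period with no
  initiation <- last$end                    # later long period
  list(defined = TRUE,
       winter_start = winter_start,
       winter_end = initiation,
       initiation = initiation,
       n_winter_sites = nrow(big),
       winter_duration_days = as.integer(initiation - winter_start) + 1L,
       last_winter_lat = last$lat_med,
       last_winter_lon = last$lon_med)
}

#' Detect spring arrival at the breeding site
#'
#' Termination of spring migration: the first post-initiation date whose
#' daily longitude 95% credible interval contains the breeding-site
#' longitude. For austral sites with census data the estimate is floored at
#' the first-observation census date of that year (the tag-based estimate
#' can run early where the migration route passes over the site's
#' longitude). Returns `NA` when no day qualifies.
#'
#' @param post a `LocationPosterior` (or its `summary` data.frame).
#' @param site a [siteConfig()].
#' @param initiation spring initiation date ([delimitWinter()]).
#' @return Date, or `NA`.
#' @export
detectArrival <- function(post, site, initiation) {
  s <- if (inherits(post, "LocationPosterior")) post$summary else post
  s <- s[order(s$date), ]
  cand <- s$date > as.Date(initiation) &
    s$lon_lo <= site$lon & s$lon_hi >= site$lon
  if (!any(cand)) return(as.Date(NA))
  arrival <- min(s$date[cand])
  if (site$group == "austral" && !is.null(site$census)) {
    yr <- format(arrival, "%Y")
    if (yr %in% names(site$census))
      arrival <- max(arrival, site$census[[yr]])
  }
  arrival
}

#' Assemble one individual's spring phenology record
#'
#' Combines a schedule's winter delimitation and an arrival date into the
#' per-individual migration history: spring distance (great-circle from the
#' last winter stationary period's median to the breeding site), durations
#' (inclusive day counts: both endpoints counted), rate, and stopover use
#' (stationary periods strictly between initiation and arrival). A missing
#' arrival propagates to duration and rate; distance is still reported.
#'
#' @param schedule a `Schedule`.
#' @param winter result of [delimitWinter()].
#' @param arrival Date or `NA`, from [detectArrival()].
#' @param site a [siteConfig()].
#' @param id,sex identifiers carried into the record.
#' @return one-row data.frame (a phenology record): `id`, `site`, `sex`,
#'   `n_winter_sites`, `winter_duration_days`, `n_spring_stopovers`,
#'   `spring_duration_days`, `spring_distance_km`, `spring_rate_km_per_day`,
#'   `spring_stopover_days`, `spring_initiation`, `spring_arrival`,
#'   `excluded`, `exclude_reason`.
#' @export
springMetrics <- function(schedule, winter, arrival, site,
                          id = NA_character_, sex = NA_character_) {
  if (!isTRUE(winter$defined))
    return(data.frame(id = id, site = site$code, sex = sex,
                      n_winter_sites = NA_integer_,
                      winter_duration_days = NA_integer_,
                      n_spring_stopovers = NA_integer_,
                      spring_duration_days = NA_integer_,
                      spring_distance_km = NA_real_,
                      spring_rate_km_per_day = NA_real_,
                      spring_stopover_days = NA_integer_,
                      spring_initiation = as.Date(NA),
                      spring_arrival = as.Date(NA),
                      excluded = TRUE, exclude_reason = "winter_undefined",
                      stringsAsFactors = FALSE))
  init <- winter$initiation
  arrival <- as.Date(arrival)
  if (!is.na(arrival) && arrival < init)
    stop("arrival precedes spring initiation")
  distance <- greatCircleKm(winter$last_winter_lat, winter$last_winter_lon,
                            site$lat, site$lon)
  duration <- if (is.na(arrival)) NA_integer_
              else as.integer(arrival - init) + 1L
  rate <- if (is.na(duration)) NA_real_ else distance / duration
  st <- schedule[schedule$kind == "stationary", ]
  between <- st$start > init &
    (if (is.na(arrival)) TRUE else st$end < arrival)
  stopovers <- st[between, ]
  data.frame(id = id, site = site$code, sex = sex,
             n_winter_sites = winter$n_winter_sites,
             winter_duration_days = winter$winter_duration_days,
             n_spring_stopovers = nrow(stopovers),
             spring_duration_days = duration,
             spring_distance_km = distance,
             spring_rate_km_per_day = rate,
             spring_stopover_days = as.integer(sum(stopovers$duration_days)),
             spring_initiation = init,
             spring_arrival = arrival,
             excluded = FALSE, exclude_reason = NA_character_,
             stringsAsFactors = FALSE)
}

#' Flag implausible migration rates
#'
#' Within each site, flags any record whose spring rate exceeds `factor`
#' times the next-fastest rate at that site (default double) -- such rates
#' are artefacts of arrival-date uncertainty, not flight performance.
#' Records at sites with a single rated individual are never flagged.
#'
#' @param records phenology record data.frame (rows as from
#'   [springMetrics()]).
#' @param factor multiple of the next-fastest site rate above which a
#'   record is excluded (default 2).
#' @return `records` with `excluded`/`exclude_reason` updated.
#' @export
qcRateOutlier <- function(records, factor = 2) {
  for (site in unique(records$site)) {
    ii <- which(records$site == site & !is.na(records$spring_rate_km_per_day))
    if (length(ii) < 2) next
    r <- records$spring_rate_km_per_day[ii]
    ord <- order(r, decreasing = TRUE)
    flag <- r > factor * r[ord[2]]   # only the fastest can exceed 2x the
    ji <- ii[flag]                   # next fastest
    records$excluded[ji] <- TRUE
    records$exclude_reason[ji] <- "rate_outlier"
  }
  records
}

#' Write/read phenology records
#'
#' CSV mirroring the per-individual migration-history table layout.
#'
#' @param records phenology record data.frame.
#' @param path file path.
#' @export
writePhenology <- function(records, path) {
  d <- records
  d$spring_initiation <- format(d$spring_initiation)
  d$spring_arrival <- format(d$spring_arrival)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePhenology
#' @export
readPhenology <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  d$spring_initiation <- as.Date(d$spring_initiation)
  d$spring_arrival <- as.Date(d$spring_arrival)
  d
}
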