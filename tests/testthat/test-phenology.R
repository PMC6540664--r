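# winter delimitation, arrival detection and the spring metrics

test_that("winter rules pick the last long stationary period", {
  # deployment residency, then 40 d, 35 d, 10 d, 5 d
  sched <- makeSchedule(list(c(60, -22.3, -47.9), c(40, 2.5, -65),
                             c(35, 1.5, -63), c(10, -5, -58),
                             c(5, -12, -52)))
  w <- delimitWinter(sched)
  expect_true(w$defined)
  expect_equal(w$winter_start, sched$start[2])
  expect_equal(w$initiation, sched$end[3])     # end of the 35-day period
  expect_equal(w$n_winter_sites, 2L)
  expect_equal(w$winter_duration_days,
               as.integer(sched$end[3] - sched$start[2]) + 1L)
})

test_that("a single long winter period is its own initiation", {
  sched <- makeSchedule(list(c(50, -22.3, -47.9), c(133, 2.5, -65),
                             c(6, -8, -58), c(4, -15, -52)))
  w <- delimitWinter(sched)
  expect_equal(w$n_winter_sites, 1L)
  expect_equal(w$initiation, sched$end[2])
  expect_equal(w$winter_duration_days, 133L)
})

test_that("no long stationary period leaves winter undefined", {
  sched <- makeSchedule(list(c(40, -22.3, -47.9), c(20, 2.5, -65),
                             c(15, -8, -58)))
  w <- delimitWinter(sched)
  expect_false(w$defined)
  rec <- springMetrics(sched, w, as.Date(NA), siteConfigs("EEI"))
  expect_true(rec$excluded)
  expect_identical(rec$exclude_reason, "winter_undefined")
})

test_that("arrival is the first day the site longitude enters the CrI", {
  d <- seq(as.Date("2014-08-01"), by = "day", length.out = 30)
  lon <- seq(-65, -46, length.out = 30)          # drifts over site lon -47.9
  summ <- data.frame(date = d, lat_med = -10, lat_lo = -12, lat_hi = -8,
                     lon_med = lon, lon_lo = lon - 1, lon_hi = lon + 1)
  site <- siteConfigs("EEI")                     # intratropical: no census
  arr <- detectArrival(summ, site, initiation = d[1])
  expect_equal(arr, min(d[lon + 1 >= site$lon & d > d[1]]))

  # austral site: floored at the census first-observation date
  red <- siteConfigs("RED")
  d14 <- seq(as.Date("2014-09-20"), by = "day", length.out = 30)
  summ14 <- data.frame(date = d14, lat_med = -20, lat_lo = -25, lat_hi = -15,
                       lon_med = -57.4, lon_lo = -58.4, lon_hi = -56.4)
  arr14 <- detectArrival(summ14, red, initiation = d14[1])
  expect_equal(arr14, as.Date("2014-10-05"))

  # never entering the interval -> missing
  far <- data.frame(date = d, lat_med = -10, lat_lo = -12, lat_hi = -8,
                    lon_med = -65, lon_lo = -66, lon_hi = -64)
  expect_true(is.na(detectArrival(far, site, initiation = d[1])))
})

test_that("great-circle distances agree with an independent haversine oracle", {
  expect_equal(greatCircleKm(2.5, -65, 2.5, -65), 0)
  expect_equal(greatCircleKm(0, 0, 0, 90), pi / 2 * 6371, tolerance = 0.1 / 10007)
  expect_equal(greatCircleKm(0, 0, 0, 90), greatCircleKm(0, 90, 0, 0))
  skip_if_not_installed("geosphere")
  d <- greatCircleKm(-15.8, -47.8, -35.1, -57.4)
  oracle <- geosphere::distHaversine(c(-47.8, -15.8), c(-57.4, -35.1),
                                     r = 6371000) / 1000
  expect_lt(abs(d - oracle), 0.1)
  set.seed(8)
  for (i in 1:20) {
    a <- c(runif(1, -90, 90), runif(1, -180, 180))
    b <- c(runif(1, -90, 90), runif(1, -180, 180))
    expect_lt(abs(greatCircleKm(a[1], a[2], b[1], b[2]) -
                  geosphere::distHaversine(rev(a), rev(b), r = 6371000) / 1000),
              0.1)
  }
})

test_that("spring metrics use inclusive day arithmetic", {
  # a 2,922 km migration from 23 Sep to 10 Oct is 18 days at 162.3 km/day
  sched <- makeSchedule(list(c(60, -35.1, -57.4), c(133, 2.7, -66.1)),
                        start = as.Date("2010-03-01"), gap = 2)
  sched$end[2] <- as.Date("2010-09-23")
  sched$duration_days[2] <- as.integer(sched$end[2] - sched$start[2]) + 1L
  w <- delimitWinter(sched)
  site <- siteConfigs("RED")
  rec <- springMetrics(sched, w, as.Date("2010-10-10"), site, id = "2")
  expect_equal(rec$spring_duration_days, 18L)
  d <- greatCircleKm(2.7, -66.1, site$lat, site$lon)
  expect_equal(rec$spring_distance_km, d)
  expect_equal(rec$spring_rate_km_per_day, d / 18)
  expect_equal(round(2922 / 18, 1), 162.3)   # the inclusive-count convention
  expect_equal(round(2604 / 16, 1), 162.8)
  expect_equal(rec$n_spring_stopovers, 0L)
})

test_that("a missing arrival propagates to duration and rate only", {
  sched <- makeSchedule(list(c(50, -35.1, -57.4), c(90, 2.5, -65),
                             c(40, 1.0, -60)))
  w <- delimitWinter(sched)
  rec <- springMetrics(sched, w, as.Date(NA), siteConfigs("RED"), id = "3")
  expect_true(is.na(rec$spring_duration_days))
  expect_true(is.na(rec$spring_rate_km_per_day))
  expect_false(is.na(rec$spring_distance_km))
  expect_error(springMetrics(sched, w, w$initiation - 5, siteConfigs("RED")),
               "precedes")
})

test_that("stopovers are the stationary periods strictly inside spring", {
  sched <- makeSchedule(list(c(45, -22.3, -47.9), c(80, 2.5, -65),
                             c(35, 1.5, -62), c(8, -5, -58), c(6, -12, -54)),
                        gap = 2)
  w <- delimitWinter(sched)
  arrival <- sched$end[5] + 4
  rec <- springMetrics(sched, w, arrival, siteConfigs("EEI"))
  expect_equal(rec$n_spring_stopovers, 2L)
  expect_equal(rec$spring_stopover_days, 14L)
  expect_equal(rec$spring_duration_days,
               as.integer(arrival - w$initiation) + 1L)
})

test_that("rate outliers are flagged per site against the next fastest", {
  rec <- data.frame(id = as.character(1:5), site = c("RED", "RED", "RED", "RPL", "RPL"),
                    spring_rate_km_per_day = c(535, 223, 168, 170, 168),
                    excluded = FALSE, exclude_reason = NA_character_,
                    stringsAsFactors = FALSE)
  out <- qcRateOutlier(rec)
  expect_identical(out$excluded, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(out$exclude_reason[1], "rate_outlier")
  solo <- data.frame(id = "9", site = "DF", spring_rate_km_per_day = 999,
                     excluded = FALSE, exclude_reason = NA_character_,
                     stringsAsFactors = FALSE)
  expect_false(qcRateOutlier(solo)$excluded)
})

test_that("site configurations match the published coordinates", {
  s <- siteConfigs()
  expect_equal(s$DF$lat, -15.8);  expect_equal(s$DF$lon, -47.8)
  expect_equal(s$EEI$lat, -22.3); expect_equal(s$EEI$lon, -47.9)
  expect_equal(s$RED$lat, -35.1); expect_equal(s$RED$lon, -57.4)
  expect_equal(s$RPL$lat, -36.8); expect_equal(s$RPL$lon, -64.3)
  expect_identical(s$RED$group, "austral")
  expect_identical(s$DF$group, "intratropical")
  expect_equal(unname(s$RED$census["2011"]), as.Date("2011-09-29"))
  expect_error(siteConfig("X", 0, 0, "austral", census = "2014-02-01"),
               "Sep-Dec")
})
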