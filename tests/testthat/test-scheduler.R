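# segmentation of the daily posterior into stationary periods

test_that("a clean two-site posterior splits into two periods at the jump", {
  d1 <- seq(as.Date("2014-04-01"), by = "day", length.out = 40)
  d2 <- seq(max(d1) + 1, by = "day", length.out = 35)
  post <- makePosterior(c(d1, d2),
                        lat = c(rep(2.5, 40), rep(-15.8, 35)),
                        lon = c(rep(-65, 40), rep(-47.8, 35)),
                        half_lat = 0.8, half_lon = 0.6, seed = 1)
  sched <- segmentStationary(post)
  st <- sched[sched$kind == "stationary", ]
  expect_equal(nrow(st), 2)
  expect_lte(abs(as.integer(st$end[1] - max(d1))), 1)
  expect_lte(abs(as.integer(st$start[2] - min(d2))), 1)
  expect_lt(abs(st$lat_med[1] - 2.5), 0.5)
  expect_lt(abs(st$lon_med[2] + 47.8), 0.5)
})

test_that("a constant-location posterior is one stationary period", {
  d <- seq(as.Date("2014-04-01"), by = "day", length.out = 25)
  post <- makePosterior(d, rep(2.5, 25), rep(-65, 25), seed = 2)
  sched <- segmentStationary(post)
  expect_equal(sum(sched$kind == "stationary"), 1)
  expect_equal(sched$start[1], d[1])
  expect_equal(sched$end[1], d[25])
})

test_that("simulated stopovers of 8, 6 and 10 days are recovered within 2 days", {
  # winter site -> three stopovers -> breeding site, 2 movement days between
  legs <- list(c(lat = 2.5, lon = -65, days = 35),
               c(lat = -3, lon = -60, days = 8),
               c(lat = -8, lon = -56, days = 6),
               c(lat = -13, lon = -52, days = 10),
               c(lat = -22.3, lon = -47.9, days = 20))
  d <- as.Date("2014-05-01"); rows <- list(); truth <- list()
  for (i in seq_along(legs)) {
    lg <- legs[[i]]
    dd <- seq(d, by = "day", length.out = lg["days"])
    rows[[i]] <- data.frame(date = dd, lat = unname(lg["lat"]),
                            lon = unname(lg["lon"]))
    truth[[i]] <- data.frame(start = min(dd), end = max(dd))
    d <- max(dd) + 3            # two interpolated movement days
    if (i < length(legs)) {
      nxt <- legs[[i + 1]]
      mv <- data.frame(date = max(dd) + 1:2,
                       lat = lg["lat"] + (1:2) / 3 * (nxt["lat"] - lg["lat"]),
                       lon = lg["lon"] + (1:2) / 3 * (nxt["lon"] - lg["lon"]))
      rows[[length(legs) + i]] <- mv
    }
  }
  pos <- do.call(rbind, rows)
  pos <- pos[order(pos$date), ]
  post <- makePosterior(pos$date, pos$lat, pos$lon,
                        half_lat = 1.2, half_lon = 0.9, seed = 3)
  sched <- segmentStationary(post, min_days = 2)
  st <- sched[sched$kind == "stationary" & sched$duration_days >= 4, ]
  expect_gte(nrow(st), 5)
  for (i in seq_along(legs)) {
    tr <- truth[[i]]
    hit <- which.min(abs(as.numeric(st$start - tr$start)))
    expect_lte(abs(as.numeric(st$start[hit] - tr$start)), 2)
    expect_lte(abs(as.numeric(st$end[hit] - tr$end)), 2)
  }
})

test_that("raising the break threshold never yields more periods", {
  d <- seq(as.Date("2014-04-01"), by = "day", length.out = 60)
  set.seed(4)
  lat <- 2.5 + cumsum(rnorm(60, 0, 0.4))
  lon <- -65 + cumsum(rnorm(60, 0, 0.4))
  post <- makePosterior(d, lat, lon, seed = 4)
  n_periods <- vapply(c(0.5, 1, 2, 4, 8), function(z)
    nrow(segmentStationary(post, z_break = z)), numeric(1))
  expect_true(all(diff(n_periods) <= 0))
})

test_that("segmentation partitions days and is idempotent on its own output", {
  d1 <- seq(as.Date("2014-04-01"), by = "day", length.out = 30)
  d2 <- seq(max(d1) + 1, by = "day", length.out = 20)
  post <- makePosterior(c(d1, d2), c(rep(2.5, 30), rep(-10, 20)),
                        c(rep(-65, 30), rep(-55, 20)), seed = 5)
  sched <- segmentStationary(post)
  # partition: segments tile the tracked span without overlap
  expect_true(all(sched$start[-1] > sched$end[-nrow(sched)]))
  days_covered <- sum(as.integer(sched$end - sched$start) + 1L)
  expect_equal(days_covered, 50)
  # idempotence: re-segmenting the reconstructed daily medians keeps the
  # same boundaries
  daily <- do.call(rbind, lapply(seq_len(nrow(sched)), function(i) {
    dd <- seq(sched$start[i], sched$end[i], by = "day")
    data.frame(date = dd, lat_med = sched$lat_med[i], lon_med = sched$lon_med[i],
               lat_lo = sched$lat_med[i] - 0.5, lat_hi = sched$lat_med[i] + 0.5,
               lon_lo = sched$lon_med[i] - 0.5, lon_hi = sched$lon_med[i] + 0.5)
  }))
  again <- segmentStationary(daily)
  expect_equal(again$start, sched$start)
  expect_equal(again$end, sched$end)
})

test_that("period counting respects the window and empty cases", {
  sched <- makeSchedule(list(c(40, 2.5, -65), c(35, 1, -60), c(10, -5, -55),
                             c(8, -10, -50), c(12, -20, -48)))
  whole <- c(min(sched$start), max(sched$end))
  expect_equal(periodCounts(sched, whole), 5)
  expect_equal(periodCounts(sched, as.Date(c("2000-01-01", "2000-01-02"))), 0)
  expect_equal(periodCounts(sched, c(min(sched$start), sched$end[2])), 2)
})

test_that("schedules survive a CSV round trip", {
  sched <- makeSchedule(list(c(40, 2.5, -65), c(10, -5, -55)))
  f <- tempfile(fileext = ".csv")
  writeSchedule(sched, f)
  back <- readSchedule(f)
  expect_equal(back$start, sched$start)
  expect_equal(back$duration_days, sched$duration_days)
  expect_equal(back$lat_med, sched$lat_med)
})
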