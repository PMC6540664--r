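# twilight likelihood and the Metropolis track sampler

test_that("twilight log-likelihood matches the log-normal density oracle", {
  cal <- defaultCalib()
  date <- as.Date("2014-07-10")
  tw <- predictTwilights(date, 2.5, -65, cal$zenith_deg)
  m <- exp(cal$err_meanlog)    # put both delays at the distribution median
  ll <- twilightLogLik(date, tw$sunrise + m * 60, tw$sunset - m * 60,
                       2.5, -65, cal)
  oracle <- 2 * dlnorm(m, cal$err_meanlog, cal$err_sdlog, log = TRUE)
  expect_equal(ll, oracle, tolerance = 1e-6)
})

test_that("non-positive delays and polar geometry are impossible", {
  cal <- defaultCalib()
  date <- as.Date("2014-07-10")
  tw <- predictTwilights(date, 2.5, -65, cal$zenith_deg)
  # observed sunrise before the geometric one: delay <= 0
  expect_identical(twilightLogLik(date, tw$sunrise - 300, tw$sunset - 300,
                                  2.5, -65, cal), -Inf)
  # no twilight at the calibrated zenith in polar winter
  twp <- makeStationaryPairs(2.5, -65, date, seed = 1)
  expect_identical(twilightLogLik(as.Date("2014-12-21"), twp$sunrise,
                                  twp$sunset, 85, -65, cal), -Inf)
})

test_that("the likelihood is additive over days", {
  cal <- defaultCalib()
  pairs <- makeStationaryPairs(2.5, -65,
                               seq(as.Date("2014-07-01"), by = "day",
                                   length.out = 2), seed = 3)
  both <- twilightLogLik(pairs$date, pairs$sunrise, pairs$sunset,
                         c(2.5, 2.5), c(-65, -65), cal)
  one <- twilightLogLik(pairs$date[1], pairs$sunrise[1], pairs$sunset[1],
                        2.5, -65, cal)
  two <- twilightLogLik(pairs$date[2], pairs$sunrise[2], pairs$sunset[2],
                        2.5, -65, cal)
  expect_equal(sum(both), one + two, tolerance = 1e-10)
})

test_that("posterior summaries follow the quantile oracle", {
  post <- list(date = as.Date("2014-01-01"),
               lat_samples = matrix(1:100, 1), lon_samples = matrix(1:100, 1))
  s <- summarizePosterior(post)
  expect_equal(c(s$lat_lo, s$lat_hi), c(3.475, 97.525))  # type-7 quantiles
  expect_equal(s$lat_med, 50.5)
  # permutation invariance
  perm <- list(date = post$date,
               lat_samples = matrix(sample(1:100), 1),
               lon_samples = matrix(sample(1:100), 1))
  expect_equal(summarizePosterior(perm)$lat_med, s$lat_med)
  # degenerate spread
  flat <- list(date = post$date, lat_samples = matrix(5, 1, 50),
               lon_samples = matrix(-60, 1, 50))
  sf <- summarizePosterior(flat)
  expect_equal(sf$lat_lo, sf$lat_hi)
  expect_error(summarizePosterior(list(date = post$date,
                                       lat_samples = matrix(1, 1, 5),
                                       lon_samples = matrix(1, 1, 5))),
               "at least 10")
})

test_that("a stationary bird's posterior concentrates on the truth", {
  dates <- seq(as.Date("2014-07-01"), by = "day", length.out = 30)
  pairs <- makeStationaryPairs(2.5, -65, dates, seed = 1)
  post <- sampleTrackPosterior(pairs, defaultCalib(),
                               cfg = mcmcConfig(n_iter = 1000, n_chains = 3,
                                                n_runs = 3, thin = 2,
                                                seed = 1))
  expect_equal(ncol(post$lat_samples), 1000 * 3 / 2)
  s <- post$summary
  expect_lt(abs(median(s$lat_med) - 2.5), 1.0)
  expect_lt(abs(median(s$lon_med) + 65), 0.5)
  expect_gt(post$acceptance, 0.05)
  expect_lt(post$acceptance, 0.80)
})

test_that("the 95 percent credible intervals cover the truth on most days", {
  dates <- seq(as.Date("2014-07-01"), by = "day", length.out = 20)
  pairs <- makeStationaryPairs(2.5, -65, dates, seed = 1)
  post <- sampleTrackPosterior(pairs, defaultCalib(),
                               cfg = mcmcConfig(n_iter = 1000, n_chains = 2,
                                                n_runs = 2, thin = 2,
                                                seed = 1))
  s <- post$summary
  covered <- s$lat_lo <= 2.5 & s$lat_hi >= 2.5 &
    s$lon_lo <= -65 & s$lon_hi >= -65
  expect_gte(mean(covered), 0.8)
})

test_that("a two-stage track is recovered day by day off-equinox", {
  datesA <- seq(as.Date("2014-05-01"), by = "day", length.out = 30)
  transit <- seq(max(datesA) + 1, by = "day", length.out = 10)
  datesB <- seq(max(transit) + 1, by = "day", length.out = 30)
  posA <- data.frame(date = datesA, lat = 2.5, lon = -65)
  frac <- seq_along(transit) / (length(transit) + 1)
  posT <- data.frame(date = transit, lat = 2.5 + frac * (-15.8 - 2.5),
                     lon = -65 + frac * (-47.8 + 65))
  posB <- data.frame(date = datesB, lat = -15.8, lon = -47.8)
  pos <- rbind(posA, posT, posB)
  pairs <- makeTrackPairs(pos, seed = 2)
  post <- sampleTrackPosterior(pairs, defaultCalib(),
                               cfg = mcmcConfig(n_iter = 1000, n_chains = 2,
                                                n_runs = 2, thin = 2,
                                                seed = 2))
  s <- merge(post$summary, pos, by = "date")
  # single-day twilight delays of ~5 min leave residual daily errors of a
  # couple of degrees (mostly latitude); the bulk of days sit on the truth
  err <- pmax(abs(s$lat_med - s$lat), abs(s$lon_med - s$lon))
  expect_gte(mean(err < 2), 0.85)
  expect_true(all(err < 5))
})

test_that("the sampler is deterministic given its seed", {
  dates <- seq(as.Date("2014-07-01"), by = "day", length.out = 8)
  pairs <- makeStationaryPairs(2.5, -65, dates, seed = 5)
  cfg <- mcmcConfig(n_iter = 200, n_chains = 2, n_runs = 2, thin = 2,
                    seed = 9)
  p1 <- sampleTrackPosterior(pairs, defaultCalib(), cfg = cfg)
  p2 <- sampleTrackPosterior(pairs, defaultCalib(), cfg = cfg)
  expect_identical(p1$lat_samples, p2$lat_samples)
  expect_identical(p1$lon_samples, p2$lon_samples)
})

test_that("a land mask confines every retained sample", {
  dates <- seq(as.Date("2014-07-01"), by = "day", length.out = 10)
  pairs <- makeStationaryPairs(2.5, -65, dates, seed = 6)
  box <- landMask(list(cbind(c(-70, -60, -60, -70), c(-3, -3, 8, 8))))
  expect_true(onMask(box, 2.5, -65))
  expect_false(onMask(box, 2.5, -50))
  post <- sampleTrackPosterior(pairs, defaultCalib(), mask = box,
                               cfg = mcmcConfig(n_iter = 300, n_chains = 2,
                                                n_runs = 2, thin = 2,
                                                seed = 7))
  expect_true(all(onMask(box, as.vector(post$lat_samples),
                         as.vector(post$lon_samples))))
})

test_that("GeoJSON masks load as polygon rings (holes via even-odd rule)", {
  f <- tempfile(fileext = ".geojson")
  writeLines(jsonlite::toJSON(list(
    type = "Feature",
    geometry = list(type = "Polygon", coordinates = list(
      list(list(-70, -10), list(-40, -10), list(-40, 10), list(-70, 10)),
      list(list(-60, -2), list(-50, -2), list(-50, 2), list(-60, 2)))),
    properties = NULL), auto_unbox = TRUE), f)
  m <- readLandMaskGeoJSON(f)
  expect_true(onMask(m, 8, -65))       # inside outer ring
  expect_false(onMask(m, 0, -55))      # inside the hole
  expect_false(onMask(m, 0, -20))      # outside everything
})

test_that("configuration preconditions are enforced", {
  expect_error(mcmcConfig(n_iter = 0), "n_iter")
  expect_error(mcmcConfig(thin = 0), "thin")
  expect_error(speedPrior(0, 1, 10), "shape1")
  pairs <- makeStationaryPairs(2.5, -65, as.Date("2014-07-01"), seed = 1)
  expect_error(sampleTrackPosterior(pairs, defaultCalib()),
               "at least 4 twilights")
})
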