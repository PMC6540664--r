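#' Default run configuration
#'
#' Assembles the nested configuration consumed by [runPipeline()]:
#' simulation scenario, light threshold, calibration window, sampler
#' settings, scheduler parameters and statistics options. Any part can be
#' overridden by the matching element of `...` or by a YAML file via
#' [readRunConfig()].
#'
#' @param outdir artifact directory.
#' @param seed integer seed used by every stochastic stage.
#' @param ... named overrides merged over the defaults (one level deep).
#' @return a named list (class `RunConfig`).
#' @export
runConfig <- function(outdir = "flytrack-run", seed = 1L, ...) {
  cfg <- list(
    outdir = outdir,
    seed = as.integer(seed),
    scenario = list(site = "EEI", n_stopovers = 3L),
    light = list(threshold = 0.5, min_dark_minutes = 120),
    calibration = list(days = 40),   # days at the breeding site post-deploy
    zenith_true = 96,                # simulator truth
    noise = list(delay_meanlog = log(5), delay_sdlog = 0.6,
                 shading_rate = 0, interval_min = 5),
    mcmc = list(n_iter = 1000L, n_chains = 2L, n_runs = 2L, thin = 2L,
                proposal_sd_deg = 0.5),
    scheduler = list(min_days = 2L, z_break = 2,
                     equinox_lon_only = FALSE, equinox_window_days = 15L),
    phenology = list(min_winter_days = 30L, rate_outlier_factor = 2),
    stats = list(alpha = 0.05, group_by = "group"),
    log_level = "info")
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(ov[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], ov[[nm]])
    else cfg[[nm]] <- ov[[nm]]
  }
  validateRunConfig(cfg)
  class(cfg) <- c("RunConfig", "list")
  cfg
}

#' @rdname runConfig
#' @param path YAML file with the same nesting as [runConfig()].
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  do.call(runConfig, c(list(outdir = y$outdir %||% "flytrack-run",
                            seed = y$seed %||% 1L),
                       y[setdiff(names(y), c("outdir", "seed"))]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validateRunConfig <- function(cfg) {
  need <- c("outdir", "seed", "scenario", "light", "calibration", "mcmc",
            "scheduler", "phenology", "stats")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("config missing field(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(cfg$seed)) stop("config field 'seed' must be numeric")
  if (cfg$light$threshold <= 0) stop("config field 'light$threshold' must be > 0")
  invisible(TRUE)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order --
#' `simulate -> calibrate -> twilights -> locate -> schedule -> phenology
#' -> stats` -- each reading its predecessor's CSV artifact from
#' `cfg$outdir` and writing its own, so any stage can be re-run or
#' replaced by externally supplied files. A `manifest.json` records the
#' package version, seed and a parameter hash. The `stats` stage runs on
#' the pipeline's own phenology records, or on the packaged Fork-tailed
#' Flycatcher histories when `cfg$stats$records == "packaged"`.
#'
#' @param cfg a [runConfig()] (or path to a YAML config).
#' @param stages character vector of stage names (default: all).
#' @return the artifact directory path, invisibly.
#' @export
runPipeline <- function(cfg = runConfig(),
                        stages = c("simulate", "calibrate", "twilights",
                                   "locate", "schedule", "phenology",
                                   "stats")) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(cfg$outdir, f)
  needArtifact <- function(f, stage) {
    if (!file.exists(art(f)))
      stop(sprintf("stage '%s' needs missing upstream artifact '%s'",
                   stage, f))
    art(f)
  }
  stageLog <- function(name, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    if (!identical(cfg$log_level, "quiet"))
      message(sprintf("[%s] done in %.1fs", name,
                      as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  if ("simulate" %in% stages) stageLog("simulate", {
    sc <- do.call(trackScenario, cfg$scenario)
    track <- simulateAnnualTrack(sc, seed = cfg$seed)
    noise <- do.call(noiseConfig, cfg$noise)
    series <- simulateLight(track, zenith_deg = cfg$zenith_true,
                            noise = noise,
                            threshold = cfg$light$threshold,
                            seed = cfg$seed + 1L)
    writeLightCSV(series, art("light.csv"))
    writeTrackTruth(track, art("truth.csv"))
    jsonlite::write_json(list(site = track$scenario$site$code),
                         art("site.json"), auto_unbox = TRUE)
  })

  siteFromArtifacts <- function(stage) {
    s <- jsonlite::read_json(needArtifact("site.json", stage))
    siteConfigs(s$site)
  }

  if ("calibrate" %in% stages) stageLog("calibrate", {
    series <- readLightCSV(needArtifact("light.csv", "calibrate"))
    site <- siteFromArtifacts("calibrate")
    w0 <- as.Date(series$time[1], tz = "UTC")
    calib <- calibrate(series, site$lat, site$lon,
                       window = c(w0, w0 + cfg$calibration$days),
                       threshold = cfg$light$threshold,
                       min_dark_minutes = cfg$light$min_dark_minutes)
    jsonlite::write_json(unclass(calib), art("calibration.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  if ("twilights" %in% stages) stageLog("twilights", {
    series <- readLightCSV(needArtifact("light.csv", "twilights"))
    twl <- findTwilights(series, cfg$light$threshold,
                         cfg$light$min_dark_minutes)
    writeTwilights(twl, art("twilights.csv"))
  })

  if ("locate" %in% stages) stageLog("locate", {
    twl <- readTwilights(needArtifact("twilights.csv", "locate"))
    cj <- jsonlite::read_json(needArtifact("calibration.json", "locate"))
    calib <- calibrationModel(cj$zenith_deg, cj$err_meanlog, cj$err_sdlog,
                              cj$threshold)
    pairs <- twilightPairs(twl)
    mcfg <- do.call(mcmcConfig, c(cfg$mcmc, list(seed = cfg$seed + 2L)))
    post <- sampleTrackPosterior(pairs, calib, cfg = mcfg)
    writePosteriorSummary(post, art("posterior_summary.csv"))
  })

  if ("schedule" %in% stages) stageLog("schedule", {
    summ <- readPosteriorSummary(needArtifact("posterior_summary.csv",
                                              "schedule"))
    sched <- segmentStationary(summ,
                               min_days = cfg$scheduler$min_days,
                               z_break = cfg$scheduler$z_break,
                               equinox_lon_only = cfg$scheduler$equinox_lon_only,
                               equinox_window_days = cfg$scheduler$equinox_window_days)
    writeSchedule(sched, art("schedule.csv"))
  })

  if ("phenology" %in% stages) stageLog("phenology", {
    sched <- readSchedule(needArtifact("schedule.csv", "phenology"))
    summ <- readPosteriorSummary(needArtifact("posterior_summary.csv",
                                              "phenology"))
    site <- siteFromArtifacts("phenology")
    winter <- delimitWinter(sched, cfg$phenology$min_winter_days)
    arrival <- if (winter$defined) detectArrival(summ, site, winter$initiation)
               else as.Date(NA)
    rec <- springMetrics(sched, winter, arrival, site,
                         id = paste0("sim-", cfg$seed))
    rec$group <- site$group
    writePhenology(rec, art("phenology.csv"))
  })

  if ("stats" %in% stages) stageLog("stats", {
    records <- if (identical(cfg$stats$records, "packaged"))
      flycatcherHistories()
    else readPhenology(needArtifact("phenology.csv", "stats"))
    vars <- intersect(c("n_winter_sites", "winter_duration_days",
                        "n_spring_stopovers", "spring_duration_days",
                        "spring_distance_km", "spring_rate_km_per_day",
                        "spring_stopover_days", "spring_initiation",
                        "spring_arrival"), names(records))
    gs <- groupSummary(records, cfg$stats$group_by, vars)
    utils::write.csv(gs, art("group_summary.csv"), row.names = FALSE)
    if (length(unique(records$site)) > 1 && nrow(records) > 8) {
      records$initiation_doy <- dayOfYear(records$spring_initiation)
      fits <- list(
        spring_distance_km = fitLM(spring_distance_km ~ site, records),
        spring_initiation = fitLM(initiation_doy ~ site, records))
      utils::write.csv(modelSummaryTable(fits), art("models.csv"),
                       row.names = FALSE)
    }
  })

  jsonlite::write_json(
    list(package = "flytrack",
         version = as.character(utils::packageVersion("flytrack")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         seed = cfg$seed,
         stages = stages,
         parameter_hash = configHash(cfg),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    art("manifest.json"), auto_unbox = TRUE)
  invisible(cfg$outdir)
}

# order-stable hash of the configuration (timestamp-free)
configHash <- function(cfg) {
  cfg$outdir <- NULL
  canon <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                            digits = NA)
  tmp <- tempfile()
  writeLines(as.character(canon), tmp)
  on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}

#' Export stationary periods as GeoJSON
#'
#' Writes a FeatureCollection of point features (period medians) with the
#' period metadata as properties, for quick inspection in any GIS viewer.
#'
#' @param schedule a `Schedule`.
#' @param path output path.
#' @export
writeScheduleGeoJSON <- function(schedule, path) {
  feats <- lapply(seq_len(nrow(schedule)), function(i) {
    r <- schedule[i, ]
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(r$lon_med, r$lat_med)),
         properties = list(period_id = r$period_id,
                           start = format(r$start), end = format(r$end),
                           kind = r$kind,
                           duration_days = r$duration_days))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
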