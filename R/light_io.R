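#' Construct a light series
#'
#' A `LightSeries` is a data.frame of timestamped ambient-light readings
#' from one logger deployment, with columns `time` (POSIXct, UTC) and
#' `light` (arbitrary non-negative units). Times must be strictly
#' increasing on a constant nominal sampling interval; gaps are allowed and
#' flagged via the `gaps` attribute.
#'
#' @param time POSIXct (or coercible) timestamps, UTC.
#' @param light numeric light readings, finite and non-negative.
#' @param logger_id identifier of the deployment.
#' @return A `LightSeries` data.frame with attributes `logger_id`,
#'   `interval_min` (nominal sampling interval, minutes) and `gaps`
#'   (indices after which a gap longer than the nominal interval occurs).
#' @export
lightSeries <- function(time, light, logger_id = "logger") {
  time <- asUTC(time)
  light <- as.numeric(light)
  if (length(time) != length(light)) stop("time and light lengths differ")
  if (length(time) < 2) stop("a light series needs at least two samples")
  if (any(!is.finite(light))) stop("light values must be finite")
  dt <- as.numeric(diff(time), units = "mins")
  if (any(dt <= 0)) stop("times must be strictly increasing")
  interval <- stats::median(dt)
  gaps <- which(dt > 1.5 * interval)
  if (length(gaps))
    warning(sprintf("%d sampling gap(s) detected (nominal interval %.1f min)",
                    length(gaps), interval))
  out <- data.frame(time = time, light = light)
  attr(out, "logger_id") <- logger_id
  attr(out, "interval_min") <- interval
  attr(out, "gaps") <- gaps
  class(out) <- c("LightSeries", "data.frame")
  out
}

#' @export
print.LightSeries <- function(x, ...) {
  cat(sprintf("LightSeries '%s': %d samples @ %.1f min, %s to %s\n",
              attr(x, "logger_id"), nrow(x), attr(x, "interval_min"),
              format(min(x$time)), format(max(x$time))))
  invisible(x)
}

#' Read geolocator light files
#'
#' `readLig()` reads the BAS `.lig` dialect (comma-separated
#' `status, dd/mm/yy hh:mm:ss, seconds, light`); `readLux()` reads the
#' Migrate Technology `.lux` dialect (free-text header lines followed by
#' tab-separated `dd/mm/yyyy hh:mm:ss<TAB>light`); `readLightCSV()` reads
#' the canonical two-column CSV (`time` ISO-8601 UTC, `light`).
#'
#' @param path file path.
#' @param logger_id deployment id; defaults to the file name.
#' @return A [lightSeries()].
#' @export
readLig <- function(path, logger_id = basename(path)) {
  d <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 4) stop("not a .lig file: expected 4 comma-separated fields")
  t <- as.POSIXct(d[[2]], format = "%d/%m/%y %H:%M:%S", tz = "UTC")
  if (anyNA(t)) stop("unparseable date-time in .lig file")
  lightSeries(t, d[[4]], logger_id)
}

#' @rdname readLig
#' @export
readLux <- function(path, logger_id = basename(path)) {
  lines <- readLines(path)
  is_data <- grepl("^\\d{2}/\\d{2}/\\d{4}", lines)
  if (!any(is_data)) stop("no data lines found in .lux file")
  d <- utils::read.delim(text = lines[is_data], header = FALSE,
                         stringsAsFactors = FALSE)
  t <- as.POSIXct(d[[1]], format = "%d/%m/%Y %H:%M:%S", tz = "UTC")
  if (anyNA(t)) stop("unparseable date-time in .lux file")
  lightSeries(t, d[[ncol(d)]], logger_id)
}

#' @rdname readLig
#' @export
readLightCSV <- function(path, logger_id = basename(path)) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time", "light") %in% names(d)))
    stop("canonical light CSV needs 'time' and 'light' columns")
  lightSeries(as.POSIXct(d$time, tz = "UTC",
                         tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S")),
              d$light, logger_id)
}

#' Write light series
#'
#' `writeLightCSV()` emits the canonical CSV (`time` ISO-8601, `light`);
#' `writeLig()` emits the BAS `.lig` dialect.
#'
#' @param x a [lightSeries()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeLightCSV <- function(x, path) {
  utils::write.csv(
    data.frame(time = format(x$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               light = x$light),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeLightCSV
#' @export
writeLig <- function(x, path) {
  lines <- sprintf("ok,%s,%d,%.3f",
                   format(x$time, "%d/%m/%y %H:%M:%S", tz = "UTC"),
                   as.integer(x$time), x$light)
  writeLines(lines, path)
  invisible(path)
}

#' Read/write a twilight table
#'
#' Twilight events as CSV with columns `time` (ISO-8601 UTC), `kind`
#' (`sunrise`/`sunset`) and `excluded` (logical; manual edit flag, never set
#' automatically). The pair round-trips exactly at second resolution.
#'
#' @param x data.frame of twilight events as produced by [findTwilights()].
#' @param path file path.
#' @return `readTwilights()` returns the twilight data.frame;
#'   `writeTwilights()` returns `path` invisibly.
#' @export
writeTwilights <- function(x, path) {
  if (is.null(x$excluded)) x$excluded <- FALSE
  utils::write.csv(
    data.frame(time = format(x$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               kind = x$kind, excluded = x$excluded),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTwilights
#' @export
readTwilights <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(time = as.POSIXct(d$time, tz = "UTC",
                               tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                              "%Y-%m-%d %H:%M:%S")),
             kind = d$kind,
             excluded = as.logical(d$excluded),
             stringsAsFactors = FALSE)
}
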