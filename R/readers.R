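#' Readers and writers for logger and environmental files
#'
#' Plain-CSV dialects (timestamp ISO-8601 UTC) plus the BAS-style `.lig`
#' (light) and `.act` (activity) comma dialects used by archival geolocators:
#' `status,dd/mm/yy HH:MM:SS,seconds,value`.
#'
#' @name readers
NULL

#' @rdname readers
#' @param path file path.
#' @return `read_light_csv`: data.frame `timestamp` (POSIXct UTC), `light`.
#' @export
read_light_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("timestamp", "light") %in% names(d)))
  d$timestamp <- as.POSIXct(d$timestamp, tz = "UTC",
                            tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                           "%Y-%m-%d %H:%M:%S"))
  d[, c("timestamp", "light")]
}

#' @rdname readers
#' @param trace data.frame to write.
#' @export
write_light_csv <- function(trace, path) {
  out <- data.frame(
    timestamp = strftime(trace$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    light = trace$light)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# shared BAS-dialect parser: status,dd/mm/yy HH:MM:SS,seconds,value
.read_bas <- function(path, value_name) {
  d <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 4) stop("expected 4-column BAS dialect in ", path)
  ts <- as.POSIXct(d[[2]], format = "%d/%m/%y %H:%M:%S", tz = "UTC")
  out <- data.frame(timestamp = ts, value = as.numeric(d[[4]]))
  names(out)[2] <- value_name
  out
}

#' @rdname readers
#' @export
read_light_lig <- function(path) .read_bas(path, "light")

#' @rdname readers
#' @return `read_immersion_csv`: data.frame `bin_start` (POSIXct UTC),
#'   `score` (integer 0--200); 10-min spacing is checked and gaps flagged in
#'   attribute `gaps`.
#' @export
read_immersion_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("bin_start", "score") %in% names(d)))
  d$bin_start <- as.POSIXct(d$bin_start, tz = "UTC",
                            tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                           "%Y-%m-%d %H:%M:%S"))
  d$score <- as.integer(d$score)
  d <- d[, c("bin_start", "score")]
  dt <- diff(as.numeric(d$bin_start))
  if (any(dt != 600)) {
    if (any(dt %% 600 != 0)) {
      stop("immersion bins are not at 10-min spacing: device excluded")
    }
    attr(d, "gaps") <- which(dt != 600)
  }
  d
}

#' @rdname readers
#' @export
write_immersion_csv <- function(trace, path) {
  out <- data.frame(
    bin_start = strftime(trace$bin_start, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    score = as.integer(trace$score))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname readers
#' @export
read_immersion_act <- function(path) {
  d <- .read_bas(path, "score")
  names(d)[1] <- "bin_start"
  d$score <- as.integer(d$score)
  d
}

#' @rdname readers
#' @return `read_index_csv`: data.frame `year`, `month`, `value`. Accepts
#'   either the long layout (those three columns) or the NOAA monthly-table
#'   layout (a `year` column followed by one column per month).
#' @export
read_index_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- tolower(names(d))
  if (all(c("year", "month", "value") %in% nm)) {
    names(d) <- nm
    return(d[, c("year", "month", "value")])
  }
  if (nm[1] == "year" && ncol(d) >= 13) {
    long <- data.frame(
      year = rep(d$year, each = 12),
      month = rep(1:12, nrow(d)),
      value = as.numeric(t(as.matrix(d[, 2:13]))))
    return(long[!is.na(long$value), ])
  }
  stop("unrecognised index layout in ", path)
}

#' @rdname readers
#' @param series data.frame `year`, `month`, `value`.
#' @export
write_index_csv <- function(series, path) {
  utils::write.csv(series[, c("year", "month", "value")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname readers
#' @return `read_chl_csv`: a [chl_field()] from a long-format CSV with
#'   columns `lat`, `lon`, `value` (optionally `year`, `month`).
#' @export
read_chl_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("lat", "lon", "value") %in% names(d)))
  lat <- sort(unique(d$lat))
  lon <- sort(unique(d$lon))
  m <- matrix(NA_real_, length(lat), length(lon))
  m[cbind(match(d$lat, lat), match(d$lon, lon))] <- d$value
  chl_field(lat, lon, m,
            year = if ("year" %in% names(d)) d$year[1] else NA_integer_,
            month = if ("month" %in% names(d)) d$month[1] else 1L)
}

#' @rdname readers
#' @param field a [chl_field()].
#' @export
write_chl_csv <- function(field, path) {
  long <- data.frame(
    lat = rep(field$lat, times = length(field$lon)),
    lon = rep(field$lon, each = length(field$lat)),
    value = as.vector(field$values),
    year = field$year, month = field$month)
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
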