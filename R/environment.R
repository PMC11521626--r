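#' Climate-index covariates and chlorophyll-peak latitude
#'
#' Seasonal means of monthly climate indices (SOI over October--December for
#' non-breeding conditions; NAO over December--March and June--August for
#' breeding conditions) and extraction of the latitude of maximum January
#' chlorophyll in the Patagonian-shelf box (35--45 S, 59--63 W).
#'
#' @name environment
NULL

#' Seasonal mean of a monthly climate index
#'
#' Arithmetic mean over the stated months. For the winter season
#' (December--March) December is assigned to the following year's winter,
#' so winter 2014 averages Dec 2013 with Jan--Mar 2014. A year with any
#' requested month missing gets NA.
#'
#' @param series data.frame `year`, `month`, `value` (one row per
#'   year-month).
#' @param season one of "soi_ond" (Oct--Dec), "nao_winter" (Dec--Mar,
#'   December rolled forward), "nao_summer" (Jun--Aug), or "custom".
#' @param months integer months, used when `season = "custom"`.
#' @return data.frame `year`, `value`.
#' @export
seasonal_index_mean <- function(series,
                                season = c("soi_ond", "nao_winter",
                                           "nao_summer", "custom"),
                                months = NULL) {
  season <- match.arg(season)
  stopifnot(all(series$month %in% 1:12))
  if (anyDuplicated(series[, c("year", "month")])) {
    stop("duplicate year-month rows in index series")
  }
  s <- series
  if (season == "soi_ond") {
    months <- 10:12
  } else if (season == "nao_summer") {
    months <- 6:8
  } else if (season == "nao_winter") {
    months <- c(12, 1:3)
    # December belongs to the following year's winter
    s$year <- ifelse(s$month == 12, s$year + 1, s$year)
  } else if (is.null(months)) {
    stop("custom season requires `months`")
  }
  s <- s[s$month %in% months, , drop = FALSE]
  years <- sort(unique(s$year))
  value <- vapply(years, function(y) {
    v <- s$value[s$year == y]
    if (length(v) < length(months)) NA_real_ else mean(v)
  }, numeric(1))
  data.frame(year = years, value = value)
}

#' Gridded chlorophyll field
#'
#' @param lat,lon strictly monotone grid vectors (degrees).
#' @param values matrix `length(lat) x length(lon)`, values >= 0 or NA.
#' @param year,month time stamp.
#' @return object of class `chl_field`.
#' @export
chl_field <- function(lat, lon, values, year = NA_integer_, month = 1L) {
  stopifnot(is.matrix(values), nrow(values) == length(lat),
            ncol(values) == length(lon))
  if (is.unsorted(lat, strictly = TRUE) && is.unsorted(rev(lat), strictly = TRUE)) {
    stop("latitude grid must be strictly monotone")
  }
  if (is.unsorted(lon, strictly = TRUE) && is.unsorted(rev(lon), strictly = TRUE)) {
    stop("longitude grid must be strictly monotone")
  }
  if (any(values < 0, na.rm = TRUE)) stop("chlorophyll values must be >= 0")
  structure(list(lat = lat, lon = lon, values = values,
                 year = year, month = month),
            class = "chl_field")
}

#' @export
print.chl_field <- function(x, ...) {
  cat("chl_field", x$year, sprintf("month %d:", x$month),
      length(x$lat), "x", length(x$lon), "grid, lat",
      sprintf("[%.1f, %.1f]", min(x$lat), max(x$lat)), "lon",
      sprintf("[%.1f, %.1f]", min(x$lon), max(x$lon)), "\n")
  invisible(x)
}

#' Latitude of peak chlorophyll in a box
#'
#' Within the box, either the missing-aware longitudinal (zonal) mean per
#' latitude row followed by an argmax (default; robust to single-pixel
#' blooms), or the latitude of the single maximum cell. Ties break toward
#' the latitude closest to the box centre.
#'
#' @param field a [chl_field()].
#' @param lat_range,lon_range box bounds (degrees), defaults the
#'   Patagonian-shelf box 35--45 S, 59--63 W.
#' @param method "zonal-mean" or "max-cell".
#' @param min_coverage minimum fraction of non-missing cells in the box.
#' @return latitude (degrees) of the peak, or NA with attribute `reason`
#'   when coverage is insufficient.
#' @export
chlorophyll_peak_latitude <- function(field,
                                      lat_range = c(-45, -35),
                                      lon_range = c(-63, -59),
                                      method = c("zonal-mean", "max-cell"),
                                      min_coverage = 0.5) {
  method <- match.arg(method)
  li <- which(field$lat >= lat_range[1] & field$lat <= lat_range[2])
  lj <- which(field$lon >= lon_range[1] & field$lon <= lon_range[2])
  if (!length(li) || !length(lj)) stop("box does not overlap the grid")
  sub <- field$values[li, lj, drop = FALSE]
  if (mean(!is.na(sub)) < min_coverage) {
    return(structure(NA_real_, reason = "insufficient coverage"))
  }
  lats <- field$lat[li]
  centre <- mean(lat_range)
  if (method == "zonal-mean") {
    zonal <- rowMeans(sub, na.rm = TRUE)
    best <- which(zonal == max(zonal, na.rm = TRUE))
  } else {
    mx <- max(sub, na.rm = TRUE)
    best <- unique(which(sub == mx, arr.ind = TRUE)[, 1])
  }
  lats[best][which.min(abs(lats[best] - centre))]
}
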