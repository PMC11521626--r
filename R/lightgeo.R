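#' Threshold light-level geolocation
#'
#' Twilight events are the times the light trace crosses a fixed intensity
#' threshold (default 10 logger units, the conventional "10 lux" threshold).
#' Day length between sunrise and sunset gives latitude through the sunrise
#' equation at a calibrated sun elevation angle; the midpoint of the two
#' twilights gives longitude through the equation of time. The calibration
#' angle is selected per track so that summer latitudes match the known
#' colony latitude.
#'
#' @name lightgeo
NULL

#' Detect twilight events in a light trace
#'
#' One event per monotone crossing of the threshold, with the crossing time
#' linearly interpolated between the adjacent samples. Same-direction
#' crossings within a refractory window (shading artefacts) are merged to
#' the first.
#'
#' @param trace data.frame with `timestamp` (POSIXct UTC, strictly
#'   increasing) and `light` (>= 0).
#' @param threshold light threshold (default 10).
#' @param refractory_hours merge window for repeated same-kind crossings.
#' @return data.frame `time`, `kind` ("sunrise"/"sunset"), `flagged`
#'   (TRUE when the event was the survivor of a merge). An all-dark or
#'   all-light trace returns zero rows with attribute `warning` set.
#' @export
detect_twilights <- function(trace, threshold = 10, refractory_hours = 4) {
  stopifnot(nrow(trace) > 0, threshold > 0)
  if (is.unsorted(as.numeric(trace$timestamp), strictly = TRUE)) {
    stop("timestamps must be strictly increasing")
  }
  above <- trace$light > threshold
  if (all(above) || all(!above)) {
    out <- data.frame(time = as.POSIXct(character(), tz = "UTC"),
                      kind = character(), flagged = logical())
    attr(out, "warning") <- if (all(above)) "all-light trace" else "all-dark trace"
    return(out)
  }
  i <- which(above[-1] != above[-length(above)])
  l0 <- trace$light[i]; l1 <- trace$light[i + 1]
  frac <- (threshold - l0) / (l1 - l0)
  t0 <- as.numeric(trace$timestamp[i])
  tc <- t0 + frac * (as.numeric(trace$timestamp[i + 1]) - t0)
  kind <- ifelse(l1 > l0, "sunrise", "sunset")
  ev <- data.frame(time = as.POSIXct(tc, origin = "1970-01-01", tz = "UTC"),
                   kind = kind, flagged = FALSE)

  # crossings alternate; an interval between consecutive crossings shorter
  # than the refractory window is a shading dip (or spike), not a day or a
  # night -- drop the artefact pair and flag the surviving neighbours
  repeat {
    if (nrow(ev) < 2) break
    gaps <- diff(as.numeric(ev$time))
    if (min(gaps) >= refractory_hours * 3600) break
    j <- which.min(gaps)   # tightest interval first: the dip itself
    nb <- intersect(c(j - 1, j + 2), seq_len(nrow(ev)))
    ev$flagged[nb] <- TRUE
    ev <- ev[-c(j, j + 1), , drop = FALSE]
  }
  row.names(ev) <- NULL
  ev
}

#' Pair twilights into sunrise/sunset days
#'
#' Pairs each sunrise with the next sunset (one pair per light day).
#'
#' @param twilights output of [detect_twilights()].
#' @return data.frame `date` (of the sunrise), `sunrise`, `sunset`.
#' @export
pair_twilights <- function(twilights) {
  out <- NULL
  j <- 1
  n <- nrow(twilights)
  while (j <= n) {
    if (twilights$kind[j] == "sunrise" && j < n &&
        twilights$kind[j + 1] == "sunset") {
      out <- rbind(out, data.frame(
        date = as.Date(twilights$time[j], tz = "UTC"),
        sunrise = twilights$time[j], sunset = twilights$time[j + 1]))
      j <- j + 2
    } else {
      j <- j + 1
    }
  }
  if (is.null(out)) {
    out <- data.frame(date = as.Date(character()),
                      sunrise = as.POSIXct(character(), tz = "UTC"),
                      sunset = as.POSIXct(character(), tz = "UTC"))
  }
  out
}

# latitude from observed day length: solve
#   sin(a) = sin(phi) sin(delta) + cos(H0) cos(phi) cos(delta)
# for phi, where H0 = day_length/2 in degrees of hour angle. Scanned on a
# coarse grid for sign changes, refined by uniroot to 0.01 degrees.
.latitude_from_daylength <- function(day_length_h, decl, angle) {
  h0 <- .deg2rad(day_length_h * 15 / 2)
  d <- .deg2rad(decl)
  a <- .deg2rad(angle)
  f <- function(phi_deg) {
    phi <- .deg2rad(phi_deg)
    sin(phi) * sin(d) + cos(h0) * cos(phi) * cos(d) - sin(a)
  }
  # near the equinoxes day length is latitude-independent: degenerate
  if (abs(sin(d)) < 0.01) {
    return(list(lat = NA_real_, valid = FALSE, reason = "equinox-degenerate"))
  }
  grid <- seq(-89.5, 89.5, by = 1)
  fg <- vapply(grid, f, numeric(1))
  sgn <- which(fg[-1] * fg[-length(fg)] <= 0 & fg[-length(fg)] != 0)
  if (!length(sgn)) {
    return(list(lat = NA_real_, valid = FALSE, reason = "no-root"))
  }
  roots <- vapply(sgn, function(i)
    stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-4)$root, numeric(1))
  roots <- roots[!duplicated(round(roots, 1))]
  # with a non-zero twilight angle and small |declination| two latitudes can
  # share one day length; the observation cannot tell them apart
  if (length(roots) > 1) {
    return(list(lat = NA_real_, valid = FALSE, reason = "ambiguous-latitude"))
  }
  list(lat = roots[1], valid = TRUE, reason = NA_character_)
}

#' Estimate a position from one twilight pair
#'
#' Longitude from the offset of observed midday (midpoint of sunrise and
#' sunset) from Greenwich apparent noon, at 15 degrees per hour, corrected
#' by the equation of time; latitude by numerically inverting the sunrise
#' equation at the calibration angle to 0.01-degree tolerance. Near an
#' equinox day length carries no latitude information and the estimate is
#' returned invalid with a reason rather than a number.
#'
#' @param sunrise,sunset POSIXct UTC, sunrise < sunset.
#' @param date the Date the pair belongs to (defaults to the sunrise date).
#' @param angle sun elevation angle assumed at threshold crossing (degrees,
#'   negative below the horizon).
#' @return one-row data.frame: `date`, `lat`, `lon`, `day_length`, `valid`,
#'   `reason`.
#' @export
estimate_position <- function(sunrise, sunset, date = NULL, angle = -4) {
  if (is.null(date)) date <- as.Date(sunrise, tz = "UTC")
  if (sunset <= sunrise) stop("sunset must be after sunrise")
  day_length <- as.numeric(difftime(sunset, sunrise, units = "hours"))
  doy <- as.integer(strftime(date, "%j", tz = "UTC"))
  eqt <- equation_of_time(doy)
  midday_min <- (.hour_utc(sunrise) + .hour_utc(sunset)) / 2 * 60
  # sunrise just before, sunset just after a UTC midnight: recentre
  if (.hour_utc(sunset) < .hour_utc(sunrise)) {
    midday_min <- midday_min + 720
  }
  lon <- (720 - eqt - midday_min) / 4
  lon <- ((lon + 180) %% 360) - 180
  if (lon == -180) lon <- 180
  decl <- solar_declination(doy)
  sol <- .latitude_from_daylength(day_length, decl, angle)
  data.frame(date = date, lat = sol$lat, lon = ifelse(sol$valid, lon, lon),
             day_length = day_length, valid = sol$valid,
             reason = sol$reason, stringsAsFactors = FALSE)
}

#' Estimate daily positions for a whole trace
#'
#' @param pairs output of [pair_twilights()] (or of [detect_twilights()],
#'   which is paired first).
#' @param angle calibration sun elevation angle.
#' @return data.frame of [estimate_position()] rows, one per twilight pair.
#' @export
estimate_positions <- function(pairs, angle = -4) {
  if (!all(c("sunrise", "sunset") %in% names(pairs))) {
    pairs <- pair_twilights(pairs)
  }
  if (!nrow(pairs)) {
    return(data.frame(date = as.Date(character()), lat = numeric(),
                      lon = numeric(), day_length = numeric(),
                      valid = logical(), reason = character()))
  }
  do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
    estimate_position(pairs$sunrise[i], pairs$sunset[i],
                      pairs$date[i], angle)))
}

#' Calibrate the sun elevation angle against the colony
#'
#' Estimates summer latitudes under each candidate angle and returns the
#' candidate minimising the median absolute deviation from the known colony
#' latitude ("known breeding latitude during the summer months"). Ties break
#' toward the smaller absolute angle.
#'
#' @param pairs twilight pairs ([pair_twilights()]).
#' @param colony_lat colony latitude (degrees).
#' @param summer_window Date vector of length 2 (inclusive window); pairs
#'   outside it are ignored.
#' @param candidates candidate angles (degrees), default -3 to -5 by 0.5.
#' @param min_valid minimum valid summer estimates required per candidate.
#' @return the selected angle (numeric scalar) with attribute `errors`
#'   (named median absolute errors per candidate).
#' @export
calibrate_sun_elevation <- function(pairs, colony_lat, summer_window,
                                    candidates = c(-3, -3.5, -4, -4.5, -5),
                                    min_valid = 10) {
  stopifnot(length(candidates) >= 1)
  pairs <- pairs[pairs$date >= summer_window[1] &
                   pairs$date <= summer_window[2], , drop = FALSE]
  errs <- vapply(candidates, function(a) {
    est <- estimate_positions(pairs, angle = a)
    est <- est[est$valid, , drop = FALSE]
    if (nrow(est) < min_valid) return(NA_real_)
    stats::median(abs(est$lat - colony_lat))
  }, numeric(1))
  names(errs) <- as.character(candidates)
  if (all(is.na(errs))) {
    stop("no candidate angle yields at least ", min_valid,
         " valid summer estimates")
  }
  best <- which(errs <= min(errs, na.rm = TRUE) + 1e-12)
  ang <- candidates[best[order(abs(candidates[best]))][1]]
  attr(ang, "errors") <- errs
  ang
}

#' Circular mean of longitudes
#'
#' Vector (resultant) mean on the circle; safe across the date line and the
#' prime meridian.
#'
#' @param lon longitudes in degrees.
#' @param na.rm drop NAs.
#' @return mean longitude in (-180, 180].
#' @export
circular_mean_lon <- function(lon, na.rm = TRUE) {
  if (na.rm) lon <- lon[!is.na(lon)]
  if (!length(lon)) return(NA_real_)
  r <- .deg2rad(lon)
  m <- .rad2deg(atan2(mean(sin(r)), mean(cos(r))))
  if (m <= -180) m <- m + 360
  m
}

#' Rolling 3-day mean of positions
#'
#' Centred rolling mean over valid estimates only (minimum one valid member
#' per window); latitude averaged arithmetically, longitude on the circle.
#' Dates are unchanged; windows with no valid member stay invalid.
#'
#' @param positions data.frame from [estimate_positions()] (date-ordered).
#' @param window window width in days (odd; default 3).
#' @return positions with smoothed `lat`/`lon`.
#' @export
smooth_positions <- function(positions, window = 3) {
  stopifnot(window %% 2 == 1)
  half <- (window - 1) / 2
  n <- nrow(positions)
  out <- positions
  for (i in seq_len(n)) {
    lo <- positions$date[i] - half
    hi <- positions$date[i] + half
    w <- which(positions$date >= lo & positions$date <= hi & positions$valid)
    if (!length(w)) next
    out$lat[i] <- mean(positions$lat[w])
    out$lon[i] <- circular_mean_lon(positions$lon[w])
  }
  out
}

#' Interquartile-range outlier filter
#'
#' Tukey fences at Q1 - 1.5 IQR and Q3 + 1.5 IQR; values exactly on a fence
#' are retained (the lower and upper bounds of the data are kept).
#'
#' @param x numeric values (one bird-month of latitudes or longitudes).
#' @param k fence multiplier (default 1.5).
#' @return the retained values; fewer than 4 inputs are returned unfiltered
#'   with a warning.
#' @export
remove_outliers_iqr <- function(x, k = 1.5) {
  xx <- x[!is.na(x)]
  if (length(xx) < 4) {
    warning("fewer than 4 values; returned unfiltered")
    return(xx)
  }
  q <- stats::quantile(xx, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  xx[xx >= q[1] - k * iqr & xx <= q[2] + k * iqr]
}

#' Mean monthly position
#'
#' IQR-filters the month's valid latitudes and longitudes, then returns the
#' arithmetic mean latitude and circular mean longitude. Mean January
#' position is the non-breeding foraging-ground location.
#'
#' @param positions data.frame from [estimate_positions()] /
#'   [smooth_positions()].
#' @param month month number (1 = January).
#' @param year optional calendar year to restrict to.
#' @param min_n minimum valid estimates required (default 5).
#' @return list `lat`, `lon`, `n`, `valid`, `reason`.
#' @export
mean_monthly_position <- function(positions, month, year = NULL, min_n = 5) {
  sel <- as.integer(format(positions$date, "%m")) == month & positions$valid
  if (!is.null(year)) {
    sel <- sel & as.integer(format(positions$date, "%Y")) == year
  }
  p <- positions[sel & !is.na(positions$lat), , drop = FALSE]
  if (nrow(p) < min_n) {
    return(list(lat = NA_real_, lon = NA_real_, n = nrow(p), valid = FALSE,
                reason = "too few valid estimates"))
  }
  lat <- if (nrow(p) >= 4) suppressWarnings(remove_outliers_iqr(p$lat)) else p$lat
  lon <- if (nrow(p) >= 4) suppressWarnings(remove_outliers_iqr(p$lon)) else p$lon
  list(lat = mean(lat), lon = circular_mean_lon(lon),
       n = nrow(p), valid = TRUE, reason = NA_character_)
}

#' Mask estimates near the equinoxes
#'
#' Marks estimates within `days` of either equinox invalid (reason
#' "equinox-masked") and records the fraction masked; nothing is imputed.
#'
#' @param positions data.frame from [estimate_positions()].
#' @param days half-width of the mask (default 15).
#' @return positions, with attribute `masked_fraction`.
#' @export
mask_equinox <- function(positions, days = 15) {
  doy <- as.integer(strftime(positions$date, "%j", tz = "UTC"))
  near <- pmin(abs(doy - 79), abs(doy - 265), abs(doy - 79 - 365),
               abs(doy - 265 + 365)) <= days
  hit <- near & positions$valid
  positions$valid[hit] <- FALSE
  positions$reason[hit] <- "equinox-masked"
  attr(positions, "masked_fraction") <- mean(near)
  positions
}
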