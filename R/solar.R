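#' Low-precision solar model
#'
#' Closed-form NOAA-style solar ephemeris: fractional-year expansion of the
#' solar declination and the equation of time, good to roughly 0.01 degrees
#' in declination -- ample for threshold geolocation, where shading noise and
#' the twilight-angle calibration dominate the error budget. A single
#' implementation is shared by the geolocation inversion, the light-trace
#' forward simulator and the night/day definitions used by the immersion
#' module, so the three can never disagree about where the sun is.
#'
#' All angles are in degrees, times in UTC. Longitude is positive east.
#'
#' @name solar
NULL

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

# fractional year (radians) from day-of-year and decimal hour UTC
.solar_gamma <- function(doy, hour = 12) {
  2 * pi / 365 * (doy - 1 + (hour - 12) / 24)
}

#' Solar declination
#'
#' @param doy day of year (1--366), vectorised.
#' @param hour decimal hour UTC used in the fractional-year term.
#' @return declination in degrees (positive north).
#' @export
solar_declination <- function(doy, hour = 12) {
  g <- .solar_gamma(doy, hour)
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  .rad2deg(decl)
}

#' Equation of time
#'
#' @inheritParams solar_declination
#' @return apparent minus mean solar time, in minutes.
#' @export
equation_of_time <- function(doy, hour = 12) {
  g <- .solar_gamma(doy, hour)
  229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
    0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
}

.doy <- function(time) as.integer(strftime(time, "%j", tz = "UTC"))

.hour_utc <- function(time) {
  lt <- as.POSIXlt(time, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}

#' Solar elevation angle
#'
#' @param time POSIXct (UTC), vectorised.
#' @param lat,lon position in degrees.
#' @return elevation above the horizon in degrees (negative below).
#' @export
solar_elevation <- function(time, lat, lon) {
  doy <- .doy(time)
  hour <- .hour_utc(time)
  g <- .solar_gamma(doy, hour)
  decl <- .deg2rad(solar_declination(doy, hour))
  eqt <- equation_of_time(doy, hour)
  tst <- hour * 60 + eqt + 4 * lon          # true solar time, minutes
  ha <- .deg2rad(tst / 4 - 180)             # hour angle
  phi <- .deg2rad(lat)
  cosz <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(ha)
  90 - .rad2deg(acos(pmin(1, pmax(-1, cosz))))
}

# Half day-length hour angle H0 (degrees) at a given sun elevation `angle`;
# NA when the sun never reaches the angle (polar day/night handled by caller).
.hour_angle_h0 <- function(lat, decl, angle) {
  phi <- .deg2rad(lat)
  d <- .deg2rad(decl)
  a <- .deg2rad(angle)
  cosh0 <- (sin(a) - sin(phi) * sin(d)) / (cos(phi) * cos(d))
  ifelse(cosh0 > 1, NA_real_,             # sun never up to `angle`: 0-length day
    ifelse(cosh0 < -1, NA_real_,          # sun never down to `angle`
      .rad2deg(acos(cosh0))))
}

#' Day length at a given sun elevation angle
#'
#' Length of the interval during which the sun is above `angle`, from the
#' sunrise equation. Polar night returns 0, polar day 24.
#'
#' @param lat latitude in degrees.
#' @param doy day of year.
#' @param angle sun elevation angle defining "day" (default 0, the geometric
#'   horizon).
#' @return hours, in [0, 24].
#' @export
day_length_hours <- function(lat, doy, angle = 0) {
  decl <- solar_declination(doy)
  phi <- .deg2rad(lat)
  d <- .deg2rad(decl)
  a <- .deg2rad(angle)
  cosh0 <- (sin(a) - sin(phi) * sin(d)) / (cos(phi) * cos(d))
  ifelse(cosh0 > 1, 0, ifelse(cosh0 < -1, 24, 2 * .rad2deg(acos(cosh0)) / 15))
}

#' Sunrise and sunset times
#'
#' Threshold-crossing times of the sun through elevation `angle` on `date`
#' at a fixed position, from the closed-form sunrise equation.
#'
#' @param date Date (UTC day), vectorised.
#' @param lat,lon position in degrees.
#' @param angle sun elevation angle of the crossing (default 0).
#' @return data.frame with columns `date`, `sunrise`, `sunset` (POSIXct UTC;
#'   NA during polar day or night) and `day_length` (hours).
#' @export
sunrise_sunset <- function(date, lat, lon, angle = 0) {
  date <- as.Date(date)
  doy <- as.integer(strftime(date, "%j", tz = "UTC"))
  decl <- solar_declination(doy)
  eqt <- equation_of_time(doy)
  h0 <- .hour_angle_h0(lat, decl, angle)
  noon <- 720 - 4 * lon - eqt                       # minutes UTC
  rise_min <- noon - 4 * h0
  set_min <- noon + 4 * h0
  day0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  data.frame(
    date = date,
    sunrise = day0 + rise_min * 60,
    sunset = day0 + set_min * 60,
    day_length = 2 * h0 / 15
  )
}
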