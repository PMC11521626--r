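#' Migration phenology from longitude series
#'
#' Migration timing is read from longitude rather than full positions because
#' longitude is immune to equinox error. The visual criteria of the original
#' field workflow are replaced here by an explicit run-length rule: a
#' migration leg starts on the first day of a sustained (>= K days)
#' displacement of more than D degrees of longitude.
#'
#' @name phenology
NULL

# wrapped signed difference a - b in (-180, 180]
.lon_diff <- function(a, b) {
  d <- (a - b + 180) %% 360 - 180
  ifelse(d == -180, 180, d)
}

# first index starting a run of >= k consecutive TRUEs
.first_run_start <- function(flag, k) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values & r$lengths >= k)
  if (!length(hit)) NA_integer_ else starts[hit[1]]
}

#' Detect migration dates from a longitude series
#'
#' Southbound start: first date of a run of at least `k_days` consecutive
#' days displaced more than `d_lon` degrees from the colony longitude.
#' Northbound start: first date after the mid-winter stationary period on
#' which displacement from the winter longitude centroid exceeds `d_lon`,
#' toward the colony, sustained `k_days`. Northbound end (colony return):
#' first subsequent date beginning `k_days` within `d_lon` of the colony
#' longitude.
#'
#' @param dates Date vector (consecutive days).
#' @param lon longitudes (degrees), smoothed.
#' @param colony_lon colony longitude (degrees).
#' @param k_days run length K (default 5 days).
#' @param d_lon displacement threshold D (default 10 degrees).
#' @param eps_lon once a qualifying run is found, the reported date is
#'   refined to the edge of the movement: the scan walks back (or, for the
#'   return, forward) along the monotone displacement ramp until longitude
#'   is within `eps_lon` degrees of the stationary side (default 1).
#' @return object of class `phenology_dates`: list with `southbound_start`,
#'   `northbound_start`, `northbound_end` (Dates or NA), `method`,
#'   `confidence`, `reason`.
#' @export
detect_migration_dates <- function(dates, lon, colony_lon,
                                   k_days = 5, d_lon = 10, eps_lon = 1) {
  stopifnot(length(dates) == length(lon))
  o <- order(dates)
  dates <- dates[o]; lon <- lon[o]
  ok <- !is.na(lon)
  res <- structure(list(southbound_start = as.Date(NA),
                        northbound_start = as.Date(NA),
                        northbound_end = as.Date(NA),
                        method = "runlength", confidence = "none",
                        reason = NA_character_),
                   class = "phenology_dates")
  miss <- function(reason) {
    res$reason <- reason
    if (!is.na(res$southbound_start)) res$confidence <- "partial"
    res
  }
  disp <- .lon_diff(lon, colony_lon)
  away <- abs(disp) > d_lon & ok

  # walk back from a qualifying run start along the monotone displacement
  # ramp to the first clearly-displaced day
  backtrack <- function(i, displacement) {
    while (i > 1 && !is.na(displacement[i - 1]) &&
           abs(displacement[i - 1]) > eps_lon &&
           abs(displacement[i - 1]) < abs(displacement[i])) {
      i <- i - 1
    }
    i
  }

  i_south <- .first_run_start(away, k_days)
  if (is.na(i_south)) return(miss("no sustained departure from colony"))
  res$southbound_start <- dates[backtrack(i_south, disp)]

  # winter centroid: the middle half of the away period after departure
  away_idx <- which(away & seq_along(dates) >= i_south)
  if (length(away_idx) < 4 * k_days) return(miss("incomplete track"))
  mid <- away_idx[away_idx >= stats::quantile(away_idx, 0.25) &
                    away_idx <= stats::quantile(away_idx, 0.75)]
  centroid <- circular_mean_lon(lon[mid])
  toward_colony_sign <- sign(.lon_diff(colony_lon, centroid))

  from_centroid <- .lon_diff(lon, centroid)
  after_mid <- seq_along(dates) > stats::median(away_idx)
  leaving <- abs(from_centroid) > d_lon &
    sign(from_centroid) == toward_colony_sign & after_mid & ok
  i_north <- .first_run_start(leaving, k_days)
  if (is.na(i_north)) return(miss("no northbound departure detected"))
  i_north <- backtrack(i_north, from_centroid)
  res$northbound_start <- dates[i_north]

  home <- abs(disp) <= d_lon & seq_along(dates) > i_north & ok
  i_end <- .first_run_start(home, k_days)
  if (is.na(i_end)) return(miss("no colony return detected"))
  # walk forward down the arrival ramp to the first on-colony day
  n <- length(dates)
  while (i_end < n && !is.na(disp[i_end]) && abs(disp[i_end]) > eps_lon &&
         !is.na(disp[i_end + 1]) && abs(disp[i_end + 1]) < abs(disp[i_end])) {
    i_end <- i_end + 1
  }
  res$northbound_end <- dates[i_end]
  res$confidence <- "algorithmic"
  res
}

#' @export
print.phenology_dates <- function(x, ...) {
  cat("phenology_dates:",
      "\n  southbound start :", format(x$southbound_start),
      "\n  northbound start :", format(x$northbound_start),
      "\n  northbound end   :", format(x$northbound_end),
      "\n  method:", x$method, " confidence:", x$confidence, "\n")
  if (!is.na(x$reason)) cat("  reason:", x$reason, "\n")
  invisible(x)
}
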