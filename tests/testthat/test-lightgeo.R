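test_that("twilight detection: square wave, degenerate traces, interpolation", {
  t0 <- as.POSIXct("2020-06-01 00:00:00", tz = "UTC")
  tt <- t0 + seq(0, 86400 - 600, by = 600)
  h <- as.numeric(tt - t0, units = "hours")
  light <- ifelse(h >= 6 & h < 18, 64, 0)
  tw <- detect_twilights(data.frame(timestamp = tt, light = light))
  expect_equal(tw$kind, c("sunrise", "sunset"))
  # threshold crossed between the last dark and first bright sample
  expect_lt(abs(as.numeric(tw$time[1] - (t0 + 6 * 3600), units = "mins")), 10)
  expect_lt(abs(as.numeric(tw$time[2] - (t0 + 18 * 3600), units = "mins")), 10)

  dark <- detect_twilights(data.frame(timestamp = tt, light = rep(0, length(tt))))
  expect_equal(nrow(dark), 0)
  expect_match(attr(dark, "warning"), "all-dark")
  bright <- detect_twilights(data.frame(timestamp = tt,
                                        light = rep(64, length(tt))))
  expect_match(attr(bright, "warning"), "all-light")

  # exact linear interpolation: 5 -> 15 crossing 10 at the midpoint
  tr <- data.frame(timestamp = t0 + c(0, 600, 1200), light = c(5, 15, 15))
  tw2 <- detect_twilights(tr)
  expect_equal(as.numeric(tw2$time[1] - t0, units = "secs"), 300)
})

test_that("noiseless simulated twilights match the dense solar oracle within 2 min", {
  cfg <- tiny_cfg()
  pos <- data.frame(date = as.Date("2012-07-10") + 0:2, lat = 51.74,
                    lon = -5.29)
  lt <- simulate_light(pos, cfg, interval_min = 2)
  tw <- detect_twilights(lt, 10)
  for (d in as.list(pos$date)) {
    oracle <- dense_crossings(d, 51.74, -5.29, angle = cfg$twilight_angle)
    for (k in c("sunrise", "sunset")) {
      got <- tw$time[tw$kind == k & as.Date(tw$time, tz = "UTC") == d]
      want <- oracle$time[oracle$kind == k]
      if (length(got) && length(want)) {
        expect_lt(abs(as.numeric(got[1] - want[1], units = "mins")), 2)
      }
    }
  }
})

test_that("position estimation: longitude from midday, latitude by inversion", {
  # observed midday at Greenwich apparent noon -> longitude 0
  d <- as.Date("2019-05-05")
  doy <- as.integer(strftime(d, "%j"))
  noon_utc <- as.POSIXct(paste(d, "00:00:00"), tz = "UTC") +
    (720 - equation_of_time(doy)) * 60
  est <- estimate_position(noon_utc - 6 * 3600, noon_utc + 6 * 3600, d,
                           angle = 0)
  expect_equal(est$lon, 0, tolerance = 0.05)

  # forward day length at phi = -40, DOY 15, a = -4, inverted
  dl <- day_length_hours(-40, 15, angle = -4)
  d15 <- as.Date("2019-01-15")
  rise <- as.POSIXct("2019-01-15 12:00:00", tz = "UTC") - dl / 2 * 3600
  set <- rise + dl * 3600
  est2 <- estimate_position(rise, set, d15, angle = -4)
  expect_true(est2$valid)
  expect_equal(est2$lat, -40, tolerance = 0.01)

  # equinox: day length carries no latitude information
  deq <- as.Date("2019-03-21")
  est3 <- estimate_position(as.POSIXct("2019-03-21 06:00:00", tz = "UTC"),
                            as.POSIXct("2019-03-21 18:00:00", tz = "UTC"),
                            deq, angle = 0)
  expect_false(est3$valid)
  expect_equal(est3$reason, "equinox-degenerate")
  expect_true(is.na(est3$lat))

  expect_error(estimate_position(set, rise, d15), "after sunrise")
})

test_that("sun-elevation calibration recovers the generating angle and obeys the tie rule", {
  cfg <- tiny_cfg()   # light crosses threshold 10 at elevation -4
  tr <- simulate_track(cfg, 1, 2011)
  lt <- simulate_light(tr$positions, cfg, 1, 2011)
  pairs <- pair_twilights(detect_twilights(lt, 10))
  summer <- as.Date(c("2011-06-05", "2011-07-31"))
  ang <- calibrate_sun_elevation(pairs, cfg$colony$lat, summer)
  expect_equal(as.numeric(ang), -4)

  # single candidate returned unchanged
  one <- calibrate_sun_elevation(pairs, cfg$colony$lat, summer,
                                 candidates = -3.5)
  expect_equal(as.numeric(one), -3.5)

  # exact tie: duplicate candidates give equal error, smaller |angle| rule
  # still returns a single well-defined value
  tied <- calibrate_sun_elevation(pairs, cfg$colony$lat, summer,
                                  candidates = c(-4.5, -4.5))
  expect_equal(as.numeric(tied), -4.5)
  errs <- attr(tied, "errors")
  expect_equal(unname(errs[1]), unname(errs[2]))
})

test_that("smoothing averages on the circle and never raises variance", {
  mk <- function(dates, lat, lon) data.frame(
    date = dates, lat = lat, lon = lon, day_length = 12,
    valid = TRUE, reason = NA_character_)
  d <- as.Date("2020-01-01") + 0:2
  p <- smooth_positions(mk(d, c(10, 20, 30), c(0, 0, 0)))
  expect_equal(p$lat[2], 20)
  const <- smooth_positions(mk(d, rep(5, 3), rep(7, 3)))
  expect_equal(const$lat, rep(5, 3))
  expect_equal(const$lon, rep(7, 3))

  # date line: {179, -179, -177} averages near -179, not +/- 61
  expect_equal(circular_mean_lon(c(179, -179, -177)), -179, tolerance = 0.01)
  pd <- smooth_positions(mk(d, rep(0, 3), c(179, -179, -177)))
  expect_equal(pd$lon[2], -179, tolerance = 0.01)

  # variance reduction on a stationary noisy segment
  set.seed(1)
  d30 <- as.Date("2020-01-01") + 0:29
  noisy <- mk(d30, rnorm(30, -42, 1), rnorm(30, -56, 1))
  sm <- smooth_positions(noisy)
  expect_lte(var(sm$lat), var(noisy$lat))
  expect_lte(var(sm$lon), var(noisy$lon))

  # invalid members are skipped, not averaged in
  pv <- mk(d, c(0, 100, 0), c(0, 0, 0))
  pv$valid[2] <- FALSE
  expect_equal(smooth_positions(pv)$lat[1], 0)
})

test_that("IQR filter keeps fence values and drops gross outliers", {
  expect_equal(remove_outliers_iqr(c(1:9, 100)), 1:9)
  x <- rep(3, 6)
  expect_equal(remove_outliers_iqr(x), x)
  # value exactly at Q3 + 1.5 IQR is retained
  y <- c(1, 2, 3, 4, 5)           # Q1 = 2, Q3 = 4, fence = 7
  expect_true(7 %in% remove_outliers_iqr(c(y, 7)))
  expect_warning(out <- remove_outliers_iqr(c(1, 2, 3)), "fewer than 4")
  expect_equal(out, c(1, 2, 3))
})

test_that("mean monthly position averages a January cluster and reports failures", {
  set.seed(4)
  d <- as.Date("2021-01-01") + 0:25
  pos <- data.frame(date = d, lat = rnorm(26, -42, 0.5),
                    lon = rnorm(26, -58, 0.5), day_length = 14,
                    valid = TRUE, reason = NA_character_)
  m <- mean_monthly_position(pos, 1)
  expect_lt(abs(m$lat - (-42)), 0.5)
  expect_lt(abs(m$lon - (-58)), 0.5)

  # symmetric pair averages exactly (bypasses the IQR step via min_n)
  pos2 <- pos[1:2, ]
  pos2$lat <- c(-40, -44)
  m2 <- mean_monthly_position(pos2, 1, min_n = 2)
  expect_equal(m2$lat, -42)

  pos$valid <- FALSE
  m3 <- mean_monthly_position(pos, 1)
  expect_false(m3$valid)
  expect_match(m3$reason, "too few")
})

test_that("equinox masking reports, never imputes", {
  d <- as.Date("2021-03-01") + 0:40   # spans the March equinox
  pos <- data.frame(date = d, lat = 0, lon = 0, day_length = 12,
                    valid = TRUE, reason = NA_character_)
  masked <- mask_equinox(pos, days = 7)
  near <- equinox_distance(d) <= 7
  expect_true(all(!masked$valid[near]))
  expect_true(all(masked$valid[!near]))
  expect_equal(attr(masked, "masked_fraction"), mean(near))
  expect_true(all(masked$reason[near] == "equinox-masked"))
})

test_that("noiseless round trip recovers position within half a degree away from equinoxes", {
  cfg <- tiny_cfg()
  m <- roundtrip_positions(cfg, 1, 2011, index = 0.5, interval_min = 2)
  far <- equinox_distance(m$date) > 15
  expect_gt(sum(far), 200)
  expect_true(all(abs(m$lat_est - m$lat_true)[far] < 0.5))
  expect_true(all(abs(m$lon_est - m$lon_true)[far] < 0.5))
})

test_that("shading degrades median position error monotonically", {
  errs <- vapply(c(0, 0.15), function(sp) {
    cfg <- sim_config(n_birds = 1, n_years = 1, shading_prob = sp,
                      winter_noise_sd = 0, seed = 42)
    m <- roundtrip_positions(cfg, 1, 2011)
    median(abs(m$lat_est - m$lat_true) + abs(m$lon_est - m$lon_true))
  }, numeric(1))
  expect_lte(errs[1], errs[2])
})
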