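test_that("score boundaries map to the three at-sea states", {
  expect_equal(classify_states(0), "dry")
  expect_equal(classify_states(200), "wet")
  expect_equal(classify_states(57), "intermediate")
  expect_equal(classify_states(c(0, 1, 199, 200)),
               c("dry", "intermediate", "intermediate", "wet"))
  expect_error(classify_states(c(0, 300)), "bin 2")
  expect_error(classify_states(-1), "bin 1")
})

test_that("daytime burrow rule: 6 h boundary and day-only restriction", {
  d <- as.Date("2020-08-05")
  sun <- data.frame(date = c(d, d + 1),
                    sunrise = as.POSIXct(paste(c(d, d + 1), "05:00:00"),
                                         tz = "UTC"),
                    sunset = as.POSIXct(paste(c(d, d + 1), "20:00:00"),
                                        tz = "UTC"))
  day0 <- as.POSIXct(paste(d, "00:00:00"), tz = "UTC")
  base <- rep(100L, 288)   # two days of wet bins
  mk <- function(idx) { s <- base; s[idx] <- 0L; make_imm_trace(s, day0) }

  # 36 zero bins (6 h) fully in daylight -> burrow
  b36 <- detect_daytime_burrow(mk(37:72), sun)
  expect_equal(nrow(b36), 1)
  expect_equal(b36$n_bins, 36)
  # 35 bins (5 h 50 m) -> not burrow
  expect_equal(nrow(detect_daytime_burrow(mk(37:71), sun)), 0)
  # 6 h dry run straddling sunset (ends 23:00) -> not a daytime interval
  expect_equal(nrow(detect_daytime_burrow(mk(103:138), sun)), 0)
})

test_that("nightly wet events count bins with any immersion", {
  tr <- make_imm_trace(c(0, 3, 0, 200, 17, 0))
  n0 <- tr$bin_start[1]; n1 <- tr$bin_start[6] + 600
  expect_equal(count_night_wet_events(tr, n0, n1), 3)
  expect_equal(count_night_wet_events(make_imm_trace(rep(0, 10)),
                                      n0, n0 + 6000), 0)
  expect_equal(count_night_wet_events(make_imm_trace(rep(50, 48)),
                                      n0, n0 + 48 * 600), 48)
  # empty night interval (polar day): missing
  expect_true(is.na(count_night_wet_events(tr, n1, n0)))
})

test_that("EM mixture recovers well-separated components and is monotone", {
  nc <- simulate_night_counts(400, seed = 3)
  fit <- fit_night_mixture(nc$count)
  expect_true(fit$converged)
  expect_lt(abs(fit$means[1] - 2), 1)
  expect_lt(abs(fit$means[2] - 30), 1)
  expect_lt(fit$means[1], fit$means[2])
  expect_equal(sum(fit$weights), 1)
  expect_true(all(diff(fit$loglik) >= -1e-9))

  expect_error(fit_night_mixture(rep(5, 30)), "identical")
  expect_error(fit_night_mixture(1:10), "at least 20")
})

test_that("EM log-likelihood beats the grid-search oracle", {
  nc <- simulate_night_counts(200, seed = 12)
  fit <- fit_night_mixture(nc$count)
  ll_grid <- grid_mixture_loglik(nc$count)
  expect_gte(tail(fit$loglik, 1), ll_grid - 1e-6)
})

test_that("posterior symmetry and visit classification threshold", {
  fit <- structure(list(means = c(0, 10), sds = c(2, 2), weights = c(0.5, 0.5),
                        loglik = 0, iterations = 1, converged = TRUE, n = 40),
                   class = "mixture_fit")
  # equidistant in standardised units with equal weights -> 0.5
  expect_equal(posterior_dry(fit, 5), 0.5)

  s <- data.frame(night_date = as.Date("2020-08-01") + 0:3,
                  wet_event_count = c(0, 2, 9, 40))
  cls <- classify_night_visits(s, fit)
  expect_true(cls$is_visit[1])
  expect_false(cls$is_visit[4])
  # monotone non-increasing in the count
  expect_true(all(diff(cls$posterior_dry_component) <= 1e-12))
  expect_true(all(diff(as.integer(cls$is_visit)) <= 0))

  bad <- fit; bad$converged <- FALSE
  expect_error(classify_night_visits(s, bad), "converge")
})

test_that("night visits on simulated counts are nearly perfectly classified", {
  # component means >= 4 sd apart
  nc <- simulate_night_counts(300, mean_dry = 2, sd_dry = 1, mean_sea = 40,
                              sd_sea = 6, seed = 5)
  fit <- fit_night_mixture(nc$count)
  cls <- classify_night_visits(
    data.frame(night_date = as.Date("2020-01-01") + seq_len(300),
               wet_event_count = nc$count), fit)
  expect_gte(mean(cls$is_visit == nc$is_visit), 0.95)
})

test_that("incubation stints respect the 3-day boundary exactly", {
  expect_true(detect_incubation(make_imm_trace(rep(0, 432)))$evidence)
  expect_false(detect_incubation(make_imm_trace(rep(0, 431)))$evidence)
  # a single wet bin splitting two 2-day dry runs: no evidence
  split <- c(rep(0, 288), 7, rep(0, 288))
  expect_false(detect_incubation(make_imm_trace(split))$evidence)
  inc <- detect_incubation(make_imm_trace(c(rep(0, 500), 100, rep(0, 10))))
  expect_equal(inc$intervals$n_bins, 500)
})

test_that("foraging effort standardises by day length and flags overflow", {
  d <- as.Date("2021-01-10")
  sun <- data.frame(date = d,
                    sunrise = as.POSIXct(paste(d, "05:00:00"), tz = "UTC"),
                    sunset = as.POSIXct(paste(d, "19:00:00"), tz = "UTC"),
                    day_length = 14)
  day0 <- as.POSIXct(paste(d, "00:00:00"), tz = "UTC")
  scores <- rep(0L, 144)
  daylight_idx <- 31:114   # bins starting 05:00 to 18:50

  # every daylight bin intermediate -> proportion 1.0
  s1 <- scores; s1[daylight_idx] <- 50L
  e1 <- foraging_effort(make_imm_trace(s1, day0), sun)
  expect_equal(e1$proportion, 1.0)

  # half of daylight bins intermediate -> 0.5
  s2 <- scores; s2[daylight_idx[1:42]] <- 50L
  e2 <- foraging_effort(make_imm_trace(s2, day0), sun)
  expect_equal(e2$proportion, 0.5)

  # 21 intermediate bins = 3.5 h over a 14 h day -> 0.25
  s3 <- scores; s3[daylight_idx[1:21]] <- 50L
  e3 <- foraging_effort(make_imm_trace(s3, day0), sun)
  expect_equal(e3$proportion, 0.25)
  expect_false(e3$flagged)

  # shortened reference day length -> proportion > 1, flagged not clipped
  sun_short <- sun; sun_short$day_length <- 10
  e4 <- foraging_effort(make_imm_trace(s1, day0), sun_short)
  expect_gt(e4$proportion, 1)
  expect_true(e4$flagged)

  # colony bins are excluded from at-sea foraging
  mask <- rep(FALSE, 144); mask[daylight_idx] <- TRUE
  e5 <- foraging_effort(make_imm_trace(s1, day0), sun, mask)
  expect_equal(e5$proportion, 0)
})

test_that("August colony visits combine nights and non-adjoining burrow days", {
  nights <- data.frame(
    night_date = as.Date("2020-08-01") + 0:9,
    wet_event_count = c(0, 0, 30, 30, 0, 30, 30, 30, 30, 30),
    posterior_dry_component = c(1, 1, 0, 0, 1, 0, 0, 0, 0, 0),
    is_visit = c(TRUE, TRUE, FALSE, FALSE, TRUE, rep(FALSE, 5)))
  expect_equal(count_colony_visits(nights, NULL), 3L)

  # a burrow day adjoining a visit night is the same stay; a lone one is not
  burrow <- data.frame(date = as.Date(c("2020-08-02", "2020-08-07")))
  expect_equal(count_colony_visits(nights, burrow), 4L)
  expect_equal(count_colony_visits(nights, burrow, include_daytime = FALSE), 3L)

  none <- nights; none$is_visit <- FALSE
  expect_equal(count_colony_visits(none, NULL), 0L)
  expect_true(is.na(count_colony_visits(nights, NULL, month = 12)))
})

test_that("geolocation and immersion share one solar implementation", {
  # the night definition used for wet-event counting must equal the
  # twilight times the geolocation module would infer at the same angle
  cfg <- tiny_cfg()
  pos <- data.frame(date = as.Date("2011-08-10") + 0:1, lat = cfg$colony$lat,
                    lon = cfg$colony$lon)
  lt <- simulate_light(pos, cfg, interval_min = 2)
  tw <- detect_twilights(lt, 10)
  ss <- sunrise_sunset(pos$date, cfg$colony$lat, cfg$colony$lon,
                       angle = cfg$twilight_angle)
  i <- which(tw$kind == "sunrise")[1]
  expect_lt(abs(as.numeric(tw$time[i] - ss$sunrise[1], units = "mins")), 2)
  j <- which(tw$kind == "sunset")[1]
  expect_lt(abs(as.numeric(tw$time[j] - ss$sunset[1], units = "mins")), 2)
})
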