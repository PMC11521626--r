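#' Synthetic bird-year generator
#'
#' Forward-simulates everything the pipeline consumes -- annual
#' trans-equatorial tracks, light traces, saltwater-immersion traces, a
#' monthly climate index and January chlorophyll fields -- with the ground
#' truth retained, so every downstream stage can be tested for parameter
#' recovery without field data.
#'
#' The simulated annual cycle mirrors a small North Atlantic procellariiform:
#' summer at a northern colony, a September southbound migration to a
#' Patagonian-shelf wintering box (35--50 degrees S), and a March northbound
#' return. Winter latitude responds to an ENSO-like index with a known
#' within-individual slope plus a per-bird offset, which is exactly the
#' structure the subject-centring analysis is meant to recover.
#'
#' @name synthio
NULL

# One RNG stream per (seed, bird, year): reproducible under any evaluation
# order. Kept below 2^31 - 1.
.stream_seed <- function(seed, bird = 0, year = 0) {
  as.integer((as.double(seed) * 48271 + as.double(bird) * 100003 +
    as.double(year) * 7919) %% 2147483647)
}

.with_stream <- function(seed, bird, year, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.stream_seed(seed, bird, year))
  force(expr)
}

.SIM_STATES <- c("flight", "forage", "rest", "colony")

#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic generator. The
#' defaults are the study conditions: a Welsh-island colony, a winter
#' latitude base of -42 responding to the index with a within-individual
#' slope of -0.30 degrees latitude per index unit, and a three-state
#' (flight/forage/rest) first-order Markov behaviour process with separate
#' day and night transition matrices.
#'
#' @param n_birds,n_years number of birds and of bird-years per bird.
#' @param colony list with `name`, `lat`, `lon` (degrees).
#' @param start_year first calendar year of the first bird-year (a bird-year
#'   runs 1 June to 31 May).
#' @param winter_latitude_base mean wintering latitude at index 0 (degrees).
#' @param within_slope degrees latitude per index unit, applied within bird.
#' @param between_sd SD of the per-bird latitude offset (degrees).
#' @param winter_noise_sd residual SD of winter latitude per bird-year.
#' @param winter_longitude mean wintering longitude (degrees).
#' @param index_params list: `ar1` coefficient and `innovation_sd` of the
#'   monthly AR(1) climate index.
#' @param phenology_means,phenology_sds day-of-year means and SDs for
#'   (southbound start, northbound start, northbound end); must be in
#'   calendar order northbound start < northbound end < southbound start.
#' @param migration_days southbound travel time, days.
#' @param day_tm,night_tm 3x3 row-stochastic transition matrices over
#'   (flight, forage, rest) per 10-min bin.
#' @param night_visit_prob probability a breeding-season night is spent at
#'   the colony.
#' @param raft_lambda Poisson mean of the number of on-water (rafting) bins
#'   at the start of a colony-visit night, before landfall; gives visit
#'   nights a small non-zero wet-event count, as in real traces.
#' @param incubation_stint_days,incubation_stints length (days) and number
#'   of continuous-dry incubation stints simulated in June.
#' @param shading_prob probability a daytime light sample is occluded.
#' @param shading_factor multiplicative attenuation of an occluded sample.
#' @param twilight_angle sun elevation (degrees) at which the simulated
#'   light curve crosses the 10-unit threshold; the truth the calibration
#'   step must recover.
#' @param light_max saturation value of the logger light scale.
#' @param ridge_base,ridge_slope,ridge_sd January chlorophyll ridge: peak
#'   latitude = base + slope * OND index + N(0, sd).
#' @param seed master seed; per-bird-year streams are derived from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_birds = 10, n_years = 5,
                       colony = list(name = "colonyA", lat = 51.74, lon = -5.29),
                       start_year = 2010,
                       winter_latitude_base = -42,
                       within_slope = -0.30,
                       between_sd = 0.8,
                       winter_noise_sd = 0.2,
                       winter_longitude = -56,
                       index_params = list(ar1 = 0.5, innovation_sd = 1),
                       phenology_means = c(southbound = 260, northbound_start = 60,
                                           northbound_end = 85),
                       phenology_sds = c(4, 4, 3),
                       migration_days = 20,
                       day_tm = matrix(c(0.50, 0.40, 0.10,
                                         0.15, 0.65, 0.20,
                                         0.20, 0.30, 0.50), 3, byrow = TRUE),
                       night_tm = matrix(c(0.30, 0.10, 0.60,
                                           0.10, 0.30, 0.60,
                                           0.05, 0.10, 0.85), 3, byrow = TRUE),
                       night_visit_prob = 0.35,
                       raft_lambda = 1.5,
                       incubation_stint_days = 5,
                       incubation_stints = 2,
                       shading_prob = 0.05,
                       shading_factor = 0.02,
                       twilight_angle = -4,
                       light_max = 64,
                       ridge_base = -40,
                       ridge_slope = 2.4,
                       ridge_sd = 0.3,
                       seed = 1L) {
  cfg <- list(
    n_birds = n_birds, n_years = n_years, colony = colony,
    start_year = start_year,
    winter_latitude_base = winter_latitude_base, within_slope = within_slope,
    between_sd = between_sd, winter_noise_sd = winter_noise_sd,
    winter_longitude = winter_longitude, index_params = index_params,
    phenology_means = phenology_means, phenology_sds = phenology_sds,
    migration_days = migration_days, day_tm = day_tm, night_tm = night_tm,
    night_visit_prob = night_visit_prob, raft_lambda = raft_lambda,
    incubation_stint_days = incubation_stint_days,
    incubation_stints = incubation_stints,
    shading_prob = shading_prob, shading_factor = shading_factor,
    twilight_angle = twilight_angle, light_max = light_max,
    ridge_base = ridge_base, ridge_slope = ridge_slope, ridge_sd = ridge_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param cfg a `sim_config`.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  probs <- c(cfg$night_visit_prob, cfg$shading_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  for (tm in list(cfg$day_tm, cfg$night_tm)) {
    if (!all(dim(tm) == c(3, 3)) || any(tm < 0) ||
        any(abs(rowSums(tm) - 1) > 1e-8)) {
      stop("transition matrices must be 3x3 row-stochastic")
    }
  }
  lats <- c(cfg$colony$lat, cfg$winter_latitude_base)
  if (any(lats < -90 | lats > 90)) stop("latitudes must lie in [-90, 90]")
  pm <- cfg$phenology_means
  if (!(pm[2] < pm[3] && pm[3] < pm[1])) {
    stop("phenology means out of calendar order: require northbound start < ",
         "northbound end < southbound start (day of year)")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_birds, "birds x", x$n_years, "bird-years from",
      x$start_year, "\n  colony", x$colony$name,
      sprintf("(%.2f, %.2f)", x$colony$lat, x$colony$lon),
      "\n  winter latitude base", x$winter_latitude_base,
      "within slope", x$within_slope, "between sd", x$between_sd,
      "\n  seed", x$seed, "\n")
  invisible(x)
}

# per-bird latitude offset, constant across that bird's years
.bird_offset <- function(cfg, bird) {
  if (cfg$between_sd == 0) return(0)
  .with_stream(cfg$seed, bird, 0, rnorm(1, 0, cfg$between_sd))
}

#' Simulate one bird-year track
#'
#' Daily positions for a bird-year (1 June to 31 May): at the colony outside
#' the migration window, linear interpolation along each migration leg, and a
#' stationary wintering position whose latitude is
#' `winter_latitude_base + within_slope * index + bird offset + noise`.
#'
#' @param cfg a [sim_config()].
#' @param bird,year bird id (integer) and first calendar year of the
#'   bird-year.
#' @param index the climate-index value driving this winter's latitude.
#' @return list with `positions` (data.frame date/lat/lon), `phenology`
#'   (southbound_start, northbound_start, northbound_end as Dates),
#'   `winter_lat`, `winter_lon`.
#' @export
simulate_track <- function(cfg, bird, year, index = 0) {
  validate_sim_config(cfg)
  offset <- .bird_offset(cfg, bird)
  .with_stream(cfg$seed, bird, year, {
    pm <- cfg$phenology_means
    ps <- cfg$phenology_sds
    sb <- as.Date(sprintf("%d-01-01", year)) +
      round(rnorm(1, pm[1], ps[1])) - 1
    nb_start <- as.Date(sprintf("%d-01-01", year + 1)) +
      round(rnorm(1, pm[2], ps[2])) - 1
    nb_end <- as.Date(sprintf("%d-01-01", year + 1)) +
      round(rnorm(1, pm[3], ps[3])) - 1
    if (nb_end <= nb_start) nb_end <- nb_start + 1
    wlat <- cfg$winter_latitude_base + cfg$within_slope * index + offset +
      rnorm(1, 0, cfg$winter_noise_sd)
    wlon <- cfg$winter_longitude + rnorm(1, 0, 1)

    dates <- seq(as.Date(sprintf("%d-06-01", year)),
                 as.Date(sprintf("%d-05-31", year + 1)), by = "day")
    arrive <- sb + cfg$migration_days
    lat <- rep(cfg$colony$lat, length(dates))
    lon <- rep(cfg$colony$lon, length(dates))
    south <- dates > sb & dates < arrive
    f <- as.numeric(dates[south] - sb) / cfg$migration_days
    lat[south] <- cfg$colony$lat + f * (wlat - cfg$colony$lat)
    lon[south] <- cfg$colony$lon + f * (wlon - cfg$colony$lon)
    winter <- dates >= arrive & dates <= nb_start
    lat[winter] <- wlat
    lon[winter] <- wlon
    north <- dates > nb_start & dates < nb_end
    f <- as.numeric(dates[north] - nb_start) / as.numeric(nb_end - nb_start)
    lat[north] <- wlat + f * (cfg$colony$lat - wlat)
    lon[north] <- wlon + f * (cfg$colony$lon - wlon)

    list(
      positions = data.frame(date = dates, lat = lat, lon = lon),
      phenology = list(southbound_start = sb, northbound_start = nb_start,
                       northbound_end = nb_end),
      winter_lat = wlat, winter_lon = wlon
    )
  })
}

#' Simulate a light trace from daily positions
#'
#' Forward model of a threshold light logger: light is a saturating
#' log-scaled function of solar elevation at the true position, calibrated so
#' the trace crosses 10 units exactly when the sun crosses
#' `cfg$twilight_angle`, clipped at `cfg$light_max` (like a real logger) and
#' at zero. Shading events, drawn independently per daytime sample, only
#' ever reduce light.
#'
#' @param positions data.frame with date, lat, lon (daily).
#' @param cfg a [sim_config()].
#' @param bird,year identify the RNG stream for shading draws.
#' @param interval_min sampling interval in minutes (<= 10).
#' @return data.frame `timestamp` (POSIXct UTC), `light` (>= 0), with
#'   attribute `polar_dark_dates`: dates whose light never exceeded the
#'   10-unit threshold.
#' @export
simulate_light <- function(positions, cfg, bird = 0, year = 0,
                           interval_min = 10) {
  stopifnot(interval_min <= 10)
  t0 <- as.POSIXct(paste(min(positions$date), "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(max(positions$date) + 1, "00:00:00"), tz = "UTC")
  times <- seq(t0, t1 - 1, by = interval_min * 60)
  idx <- match(as.Date(times, tz = "UTC"), positions$date)
  elev <- solar_elevation(times, positions$lat[idx], positions$lon[idx])

  # log-linear in elevation: light(twilight_angle) = 10, light(0) = light_max
  b <- (log(cfg$light_max) - log(10)) / (0 - cfg$twilight_angle)
  light <- exp(log(10) + b * (elev - cfg$twilight_angle))
  light <- pmin(light, cfg$light_max)
  light[light < 0.05] <- 0

  if (cfg$shading_prob > 0) {
    light <- .with_stream(cfg$seed, bird, year + 5000, {
      day <- light > 10
      shaded <- day & (runif(length(light)) < cfg$shading_prob)
      light[shaded] <- light[shaded] * cfg$shading_factor
      light
    })
  }
  out <- data.frame(timestamp = times, light = light)
  daymax <- tapply(light, as.Date(times, tz = "UTC"), max)
  attr(out, "polar_dark_dates") <- as.Date(names(daymax)[daymax <= 10])
  out
}

#' Simulate the behaviour process
#'
#' First-order Markov chain over (flight, forage, rest) per 10-minute bin,
#' with separate day and night transition matrices (day = sun above the
#' horizon at the true position). During the breeding season (before
#' southbound departure and after northbound return) nights are colony
#' visits with probability `night_visit_prob`, and June holds
#' `incubation_stints` continuous multi-day colony stints; both are recorded
#' as truth.
#'
#' @inheritParams simulate_light
#' @param phenology the phenology list from [simulate_track()].
#' @return list: `states` (data.frame bin_start, state), `visit_nights`
#'   (Dates, night labelled by its sunset date), `incubation` (data.frame
#'   start, end).
#' @export
simulate_behaviour <- function(positions, phenology, cfg, bird = 0, year = 0) {
  t0 <- as.POSIXct(paste(min(positions$date), "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(max(positions$date) + 1, "00:00:00"), tz = "UTC")
  bins <- seq(t0, t1 - 1, by = 600)
  bin_date <- as.Date(bins, tz = "UTC")
  idx <- match(bin_date, positions$date)
  elev <- solar_elevation(bins, positions$lat[idx], positions$lon[idx])
  is_day <- elev > 0
  # label each night bin by its sunset date (post-midnight bins -> previous day)
  night_date <- bin_date
  post_mid <- !is_day & .hour_utc(bins) < 12
  night_date[post_mid] <- night_date[post_mid] - 1

  breeding <- bin_date < phenology$southbound_start |
    bin_date >= phenology$northbound_end

  .with_stream(cfg$seed, bird, year + 10000, {
    n <- length(bins)
    st <- integer(n)
    st[1] <- 3L # rest
    u <- runif(n)
    for (i in 2:n) {
      tm <- if (is_day[i]) cfg$day_tm else cfg$night_tm
      p <- tm[st[i - 1], ]
      st[i] <- findInterval(u[i], cumsum(p)) + 1L
      if (st[i] > 3L) st[i] <- 3L
    }
    state <- .SIM_STATES[st]

    # breeding-season night colony visits
    cand_nights <- sort(unique(night_date[!is_day & breeding]))
    visit <- cand_nights[runif(length(cand_nights)) < cfg$night_visit_prob]
    on_visit <- !is_day & breeding & (night_date %in% visit)
    state[on_visit] <- "colony"
    # dusk rafting: a few on-water bins before landfall on visit nights
    for (vd in as.list(visit)) {
      idx <- which(!is_day & night_date == vd)
      k <- min(stats::rpois(1, cfg$raft_lambda), 3L, length(idx))
      if (k > 0) state[idx[seq_len(k)]] <- "rest"
    }

    # June incubation stints (continuous dry, day and night)
    inc <- data.frame(start = as.Date(character()), end = as.Date(character()))
    if (cfg$incubation_stints > 0) {
      s <- as.Date(sprintf("%d-06-10", year))
      for (k in seq_len(cfg$incubation_stints)) {
        e <- s + cfg$incubation_stint_days - 1
        inc <- rbind(inc, data.frame(start = s, end = e))
        state[bin_date >= s & bin_date <= e] <- "colony"
        s <- e + cfg$incubation_stint_days + 1
      }
      # drop visit nights swallowed by incubation from the visit truth
      visit <- visit[!vapply(visit, function(d)
        any(d >= inc$start - 1 & d <= inc$end), logical(1))]
    }

    list(states = data.frame(bin_start = bins, state = state),
         visit_nights = as.Date(visit, origin = "1970-01-01"),
         incubation = inc)
  })
}

#' Simulate an immersion trace from behaviour states
#'
#' Deterministic mapping of the forward model: flight and colony bins are
#' completely dry (score 0), rest bins completely wet (200), foraging bins
#' an intermediate integer in 1--199.
#'
#' @param states data.frame bin_start/state from [simulate_behaviour()].
#' @inheritParams simulate_light
#' @return data.frame `bin_start`, `score` (integer 0--200).
#' @export
simulate_immersion <- function(states, cfg, bird = 0, year = 0) {
  bad <- setdiff(unique(states$state), .SIM_STATES)
  if (length(bad)) stop("unknown state label: ", paste(bad, collapse = ", "))
  .with_stream(cfg$seed, bird, year + 20000, {
    score <- integer(nrow(states))
    score[states$state %in% c("flight", "colony")] <- 0L
    score[states$state == "rest"] <- 200L
    nf <- sum(states$state == "forage")
    score[states$state == "forage"] <- sample(1:199, nf, replace = TRUE)
    data.frame(bin_start = states$bin_start, score = score)
  })
}

#' Simulate the climate index and January chlorophyll fields
#'
#' The index is a monthly AR(1) series. Each January chlorophyll field is a
#' single zonal ridge on a regular 0.5-degree grid whose peak latitude is
#' `ridge_base + ridge_slope * (previous OND index mean) + N(0, ridge_sd)`.
#'
#' @param cfg a [sim_config()].
#' @return list: `index` (data.frame year, month, value; class
#'   attributes suit [seasonal_index_mean()]), `chl` (named list of
#'   `chl_field` objects, one per January), `truth` (data.frame jan_year,
#'   index_ond, peak_lat).
#' @export
simulate_environment <- function(cfg) {
  validate_sim_config(cfg)
  years <- cfg$start_year:(cfg$start_year + cfg$n_years)
  .with_stream(cfg$seed, 0, 90000, {
    ym <- expand.grid(month = 1:12, year = years)[, c("year", "month")]
    n <- nrow(ym)
    x <- numeric(n)
    innov <- rnorm(n, 0, cfg$index_params$innovation_sd)
    x[1] <- innov[1]
    for (i in 2:n) x[i] <- cfg$index_params$ar1 * x[i - 1] + innov[i]
    index <- data.frame(year = ym$year, month = ym$month, value = x)

    lat <- seq(-55, -25, by = 0.5)
    lon <- seq(-70, -50, by = 0.5)
    chl <- list()
    truth <- NULL
    for (jy in (cfg$start_year + 1):(cfg$start_year + cfg$n_years)) {
      ond <- mean(index$value[index$year == jy - 1 & index$month %in% 10:12])
      peak <- cfg$ridge_base + cfg$ridge_slope * ond + rnorm(1, 0, cfg$ridge_sd)
      vals <- outer(lat, lon, function(la, lo)
        5 * exp(-(la - peak)^2 / (2 * 2^2)))
      vals <- vals + matrix(abs(rnorm(length(vals), 0, 0.02)),
                            nrow(vals), ncol(vals))
      chl[[as.character(jy)]] <- chl_field(lat, lon, vals, year = jy, month = 1)
      truth <- rbind(truth,
                     data.frame(jan_year = jy, index_ond = ond, peak_lat = peak))
    }
    list(index = index, chl = chl, truth = truth)
  })
}

#' Simulate a full study
#'
#' Generates the environment once, then every bird-year's track and
#' (optionally) light, behaviour and immersion traces, wired together
#' coherently: the OND mean of the simulated index in calendar year y drives
#' both the winter latitude of bird-year y and the January y+1 chlorophyll
#' ridge.
#'
#' @param cfg a [sim_config()].
#' @param include character subset of c("light", "behaviour", "immersion");
#'   tracks and environment are always generated.
#' @return list with `env`, `bird_years` (list of per-bird-year lists) and
#'   `truth` (one row per bird-year: bird, year, index, winter_lat,
#'   phenology dates).
#' @export
simulate_study <- function(cfg, include = c("light", "behaviour", "immersion")) {
  validate_sim_config(cfg)
  env <- simulate_environment(cfg)
  ond <- function(y) mean(env$index$value[env$index$year == y &
                                            env$index$month %in% 10:12])
  bird_years <- list()
  truth <- NULL
  for (b in seq_len(cfg$n_birds)) {
    for (y in cfg$start_year:(cfg$start_year + cfg$n_years - 1)) {
      idx <- ond(y)
      tr <- simulate_track(cfg, b, y, index = idx)
      by <- list(bird = b, year = y, index = idx, track = tr)
      if ("light" %in% include) {
        by$light <- simulate_light(tr$positions, cfg, b, y)
      }
      if (any(c("behaviour", "immersion") %in% include)) {
        by$behaviour <- simulate_behaviour(tr$positions, tr$phenology, cfg, b, y)
        if ("immersion" %in% include) {
          by$immersion <- simulate_immersion(by$behaviour$states, cfg, b, y)
        }
      }
      bird_years[[sprintf("b%03d_y%d", b, y)]] <- by
      truth <- rbind(truth, data.frame(
        bird = b, year = y, index = idx,
        winter_lat = tr$winter_lat, winter_lon = tr$winter_lon,
        southbound_start = tr$phenology$southbound_start,
        northbound_start = tr$phenology$northbound_start,
        northbound_end = tr$phenology$northbound_end))
    }
  }
  list(env = env, bird_years = bird_years, truth = truth)
}

# ---- small known-truth generators for the inference layer -------------------

#' Simulate nightly wet-event counts from a two-component truth
#'
#' @param n nights; `p_visit` mixing weight of the dry (colony) component.
#' @param mean_dry,sd_dry,mean_sea,sd_sea component parameters on the count
#'   scale.
#' @param seed integer.
#' @return data.frame `count` (non-negative integer), `is_visit` (truth).
#' @export
simulate_night_counts <- function(n, p_visit = 0.5, mean_dry = 2, sd_dry = 1,
                                  mean_sea = 30, sd_sea = 5, seed = 1) {
  .with_stream(seed, 0, 0, {
    visit <- runif(n) < p_visit
    x <- ifelse(visit, rnorm(n, mean_dry, sd_dry), rnorm(n, mean_sea, sd_sea))
    data.frame(count = pmax(0L, as.integer(round(x))), is_visit = visit)
  })
}

#' Simulate subject-centred regression data
#'
#' `y = between * xbar_j + within * (x - xbar_j) + u_j + e`, the generative
#' model under which the subject-centring decomposition is exactly
#' identified.
#'
#' @param n_birds,n_per design size.
#' @param within,between true slopes.
#' @param xbar_sd,xdev_sd SDs of the per-bird covariate mean and of the
#'   within-bird deviations.
#' @param id_sd,resid_sd random-intercept and residual SDs.
#' @param seed integer.
#' @return data.frame bird, x, y.
#' @export
simulate_centring_data <- function(n_birds = 30, n_per = 5,
                                   within = -0.30, between = -0.77,
                                   xbar_sd = 1, xdev_sd = 1,
                                   id_sd = 0.5, resid_sd = 0.5, seed = 1) {
  .with_stream(seed, 0, 0, {
    xbar <- rnorm(n_birds, 0, xbar_sd)
    u <- rnorm(n_birds, 0, id_sd)
    bird <- rep(seq_len(n_birds), each = n_per)
    dev <- rnorm(n_birds * n_per, 0, xdev_sd)
    x <- xbar[bird] + dev
    # slopes act on the observed decomposition (per-bird sample mean and
    # deviations from it), the estimand of the centring model
    xbar_obs <- ave(x, bird)
    y <- between * xbar_obs + within * (x - xbar_obs) + u[bird] +
      rnorm(n_birds * n_per, 0, resid_sd)
    data.frame(bird = factor(bird), x = x, y = y)
  })
}

#' Simulate data from a recursive path model
#'
#' Exogenous variables are standard normal; each endogenous variable is the
#' linear combination of its parents plus Gaussian residual, generated in
#' topological order.
#'
#' @param spec a [path_model_spec()].
#' @param beta named numeric of true coefficients, names "from->to"; edges
#'   absent from `beta` get 0.
#' @param n rows.
#' @param resid_sd residual SD of every endogenous variable.
#' @param seed integer.
#' @return data.frame with one column per variable in `spec`.
#' @export
simulate_path_data <- function(spec, beta = NULL, n = 200, resid_sd = 1,
                               seed = 1) {
  ord <- .topological_order(spec)
  .with_stream(seed, 0, 0, {
    dat <- as.data.frame(matrix(NA_real_, n, length(ord),
                                dimnames = list(NULL, ord)))
    for (v in ord) {
      parents <- spec$edges$from[spec$edges$to == v]
      if (!length(parents)) {
        dat[[v]] <- rnorm(n)
      } else {
        mu <- 0
        for (p in parents) {
          key <- paste0(p, "->", v)
          b <- if (!is.null(beta) && key %in% names(beta)) beta[[key]] else 0
          mu <- mu + b * dat[[p]]
        }
        dat[[v]] <- mu + rnorm(n, 0, resid_sd)
      }
    }
    dat
  })
}

#' Simulate chick peak-mass records
#'
#' `mass = intercept + beta_visits * visits + beta_date * peak_date +
#' burrow effect + noise`.
#'
#' @param n_burrows,years_per design size.
#' @param beta_visits,beta_date true fixed effects (g per visit, g per day).
#' @param intercept baseline mass (g).
#' @param burrow_sd,resid_sd random-intercept and residual SDs (g).
#' @param seed integer.
#' @return data.frame burrow, year, visits, peak_date (day of year), mass.
#' @export
simulate_peak_mass <- function(n_burrows = 20, years_per = 3,
                               beta_visits = 2.13, beta_date = 0,
                               intercept = 380, burrow_sd = 10,
                               resid_sd = 15, seed = 1) {
  .with_stream(seed, 0, 0, {
    burrow <- rep(seq_len(n_burrows), each = years_per)
    u <- rnorm(n_burrows, 0, burrow_sd)
    n <- length(burrow)
    visits <- rpois(n, 8)
    peak_date <- as.integer(round(rnorm(n, 235, 5)))
    mass <- intercept + beta_visits * visits + beta_date * peak_date +
      u[burrow] + rnorm(n, 0, resid_sd)
    data.frame(burrow = factor(burrow),
               year = rep(seq_len(years_per), n_burrows),
               visits = visits, peak_date = peak_date, mass = mass)
  })
}
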