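# Shared fixtures and independent oracles, built in code at test time.

# a small, fast simulation configuration
tiny_cfg <- function(...) {
  sim_config(n_birds = 2, n_years = 2, shading_prob = 0,
             winter_noise_sd = 0, seed = 42, ...)
}

# immersion trace from a score vector, 10-min bins from `start`
make_imm_trace <- function(scores, start = as.POSIXct("2020-08-01 00:00:00",
                                                      tz = "UTC")) {
  data.frame(bin_start = start + (seq_along(scores) - 1) * 600,
             score = as.integer(scores))
}

# brute-force solar oracle: threshold-crossing times of solar elevation
# through `angle` on one UTC day at a fixed position, scanned at 10 s
dense_crossings <- function(date, lat, lon, angle, step_s = 10) {
  t0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  tt <- seq(t0, t0 + 86400 - step_s, by = step_s)
  e <- solar_elevation(tt, lat, lon)
  up <- e > angle
  i <- which(up[-1] != up[-length(up)])
  if (!length(i)) return(NULL)
  frac <- (angle - e[i]) / (e[i + 1] - e[i])
  data.frame(time = tt[i] + frac * step_s,
             kind = ifelse(e[i + 1] > e[i], "sunrise", "sunset"))
}

# grid-search oracle for the two-component normal mixture: common sigma,
# exhaustive over (mu1, mu2, sigma, w); returns the best grid log-likelihood
grid_mixture_loglik <- function(x, n_mu = 25, n_sigma = 8, n_w = 9) {
  mu_grid <- seq(min(x), max(x), length.out = n_mu)
  s_grid <- seq(max(stats::sd(x) / 10, 0.5), stats::sd(x), length.out = n_sigma)
  w_grid <- seq(0.1, 0.9, length.out = n_w)
  best <- -Inf
  for (m1 in mu_grid) for (m2 in mu_grid) {
    if (m2 <= m1) next
    for (s in s_grid) for (w in w_grid) {
      ll <- sum(log(w * stats::dnorm(x, m1, s) +
                      (1 - w) * stats::dnorm(x, m2, s)))
      if (ll > best) best <- ll
    }
  }
  best
}

# day-of-year distance to the nearest equinox (DOY 79 / 265)
equinox_distance <- function(dates) {
  doy <- as.integer(strftime(dates, "%j", tz = "UTC"))
  pmin(abs(doy - 79), abs(doy - 265), abs(doy - 79 - 365),
       abs(doy - 265 + 365))
}

# run one noiseless bird-year through the geolocation chain at a fixed angle
roundtrip_positions <- function(cfg, bird, year, index = 0, angle = -4,
                                interval_min = 10, mask_days = 15) {
  tr <- simulate_track(cfg, bird, year, index = index)
  lt <- simulate_light(tr$positions, cfg, bird, year,
                       interval_min = interval_min)
  pos <- estimate_positions(pair_twilights(detect_twilights(lt, 10)),
                            angle = angle)
  pos <- mask_equinox(pos, days = mask_days)
  merge(pos[pos$valid & !is.na(pos$lat), ], tr$positions, by = "date",
        suffixes = c("_est", "_true"))
}
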