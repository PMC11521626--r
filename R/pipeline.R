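#' Pipeline orchestration
#'
#' Runs simulate -> geolocate -> phenology -> behaviour -> environment ->
#' summary -> infer with plain-CSV intermediate artifacts, a per-stage
#' manifest (config and input hashes) that lets unchanged stages be skipped
#' on re-runs, and a filter-accounting log that asserts
#' rows_in - rows_excluded = rows_out at every stage.
#'
#' @name pipeline
NULL

#' Pipeline run configuration
#'
#' @param out_dir artifact directory.
#' @param seed master seed (also seeds the simulator unless `sim$seed` is
#'   given).
#' @param sim list of [sim_config()] arguments.
#' @param light_threshold twilight light threshold (logger units).
#' @param angles candidate sun elevation angles for calibration.
#' @param equinox_mask_days half-width of the equinox latitude mask.
#' @param phenology_k,phenology_d run length (days) and longitude
#'   displacement (degrees) for migration-date detection.
#' @param min_dry_hours daytime burrow rule.
#' @param mixture_scope "bird" (per bird-season, default), "pooled".
#' @param peak_method chlorophyll peak extraction method.
#' @param count_daytime_burrow include daytime-only burrow stays in August
#'   colony-visit counts.
#' @param nboot bootstrap draws for the inference stage.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, sim = list(),
                       light_threshold = 10,
                       angles = c(-3, -3.5, -4, -4.5, -5),
                       equinox_mask_days = 15,
                       phenology_k = 5, phenology_d = 10,
                       min_dry_hours = 6,
                       mixture_scope = "bird",
                       peak_method = "zonal-mean",
                       count_daytime_burrow = TRUE,
                       nboot = 200) {
  stopifnot(light_threshold > 0, equinox_mask_days >= 0,
            phenology_k >= 1, phenology_d > 0, min_dry_hours > 0,
            mixture_scope %in% c("bird", "pooled"),
            peak_method %in% c("zonal-mean", "max-cell"))
  if (is.null(sim$seed)) sim$seed <- seed
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 light_threshold = light_threshold, angles = angles,
                 equinox_mask_days = equinox_mask_days,
                 phenology_k = phenology_k, phenology_d = phenology_d,
                 min_dry_hours = min_dry_hours,
                 mixture_scope = mixture_scope, peak_method = peak_method,
                 count_daytime_burrow = count_daytime_burrow,
                 nboot = nboot),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$sim <- as.list(x$sim)
  do.call(run_config, x)
}

# hash an R object via its canonical JSON serialisation
.hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

.stage_dir <- function(config, stage) {
  d <- file.path(config$out_dir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

# run `fn(dir)` unless the stage manifest matches `key` and all declared
# outputs exist; the manifest records the key, input hashes and timestamps
.run_stage <- function(config, stage, key, inputs, fn, log_level = "info") {
  d <- .stage_dir(config, stage)
  manifest_path <- file.path(d, "manifest.json")
  input_hashes <- if (length(inputs)) unname(tools::md5sum(inputs)) else character(0)
  full_key <- .hash_obj(list(stage = stage, key = key, inputs = input_hashes))
  if (file.exists(manifest_path)) {
    m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    if (identical(m$key, as.character(full_key)) &&
        all(file.exists(file.path(d, m$outputs)))) {
      if (log_level != "quiet") message("[", stage, "] up to date, skipped")
      return(invisible(FALSE))
    }
  }
  if (log_level != "quiet") message("[", stage, "] running")
  fn(d)
  outputs <- setdiff(list.files(d, recursive = TRUE), "manifest.json")
  jsonlite::write_json(
    list(stage = stage, key = full_key, outputs = outputs,
         output_md5 = unname(tools::md5sum(file.path(d, outputs))),
         written = format(Sys.time(), tz = "UTC")),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(TRUE)
}

.by_id <- function(bird, year) sprintf("b%03d_y%d", bird, year)

#' Run the full pipeline
#'
#' @param config a [run_config()].
#' @param log_level "info" or "quiet".
#' @return list: `summary` (the bird-year summary table), `centring`,
#'   `path` (a `path_model_result`), `accounting` (filter log), `out_dir`.
#' @export
run_pipeline <- function(config, log_level = "info") {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(config$out_dir, "config.json"))
  scfg <- do.call(sim_config, config$sim)
  colony <- scfg$colony
  accounting <- NULL
  note <- function(stage, rows_in, rows_excluded) {
    rows_out <- rows_in - rows_excluded
    stopifnot(rows_out >= 0)
    accounting <<- rbind(accounting, data.frame(
      stage = stage, rows_in = rows_in, rows_excluded = rows_excluded,
      rows_out = rows_out))
  }

  # ---- stage 1: simulate ----------------------------------------------------
  .run_stage(config, "simulate", key = config$sim, inputs = character(0),
             log_level = log_level, fn = function(d) {
    study <- simulate_study(scfg)
    dir.create(file.path(d, "light"), showWarnings = FALSE)
    dir.create(file.path(d, "immersion"), showWarnings = FALSE)
    for (by in study$bird_years) {
      id <- .by_id(by$bird, by$year)
      write_light_csv(by$light, file.path(d, "light", paste0(id, ".csv")))
      write_immersion_csv(by$immersion,
                          file.path(d, "immersion", paste0(id, ".csv")))
    }
    tr <- study$truth
    tr$southbound_start <- format(tr$southbound_start)
    tr$northbound_start <- format(tr$northbound_start)
    tr$northbound_end <- format(tr$northbound_end)
    utils::write.csv(tr, file.path(d, "truth.csv"), row.names = FALSE)
    write_index_csv(study$env$index, file.path(d, "index.csv"))
    for (nm in names(study$env$chl)) {
      write_chl_csv(study$env$chl[[nm]],
                    file.path(d, paste0("chl_", nm, ".csv")))
    }
  })
  sim_d <- file.path(config$out_dir, "simulate")
  truth <- utils::read.csv(file.path(sim_d, "truth.csv"))
  ids <- .by_id(truth$bird, truth$year)

  # ---- stage 2: geolocate ---------------------------------------------------
  geo_key <- config[c("light_threshold", "angles", "equinox_mask_days")]
  .run_stage(config, "geolocate", key = geo_key,
             inputs = file.path(sim_d, "light", paste0(ids, ".csv")),
             log_level = log_level, fn = function(d) {
    dir.create(file.path(d, "positions"), showWarnings = FALSE)
    january <- NULL
    calib <- NULL
    excluded <- 0
    for (i in seq_along(ids)) {
      id <- ids[i]; y <- truth$year[i]
      trace <- read_light_csv(file.path(sim_d, "light", paste0(id, ".csv")))
      tw <- detect_twilights(trace, threshold = config$light_threshold)
      pairs <- pair_twilights(tw)
      angle <- tryCatch(
        calibrate_sun_elevation(
          pairs, colony$lat,
          summer_window = as.Date(sprintf("%d-0%d-01", y, 6:7)) + c(4, 30),
          candidates = config$angles),
        error = function(e) NA_real_)
      if (is.na(angle)) { excluded <- excluded + 1; next }
      pos <- estimate_positions(pairs, angle = angle)
      pos <- smooth_positions(pos)
      pos <- mask_equinox(pos, days = config$equinox_mask_days)
      utils::write.csv(
        transform(pos, date = format(date)),
        file.path(d, "positions", paste0(id, ".csv")), row.names = FALSE)
      jan <- mean_monthly_position(pos, month = 1, year = y + 1)
      january <- rbind(january, data.frame(
        bird = truth$bird[i], year = y,
        january_latitude = jan$lat, january_longitude = jan$lon,
        n_january = jan$n))
      calib <- rbind(calib, data.frame(bird = truth$bird[i], year = y,
                                       angle = as.numeric(angle)))
    }
    utils::write.csv(january, file.path(d, "january.csv"), row.names = FALSE)
    utils::write.csv(calib, file.path(d, "calibration.csv"), row.names = FALSE)
    writeLines(as.character(excluded), file.path(d, "excluded.txt"))
  })
  geo_d <- file.path(config$out_dir, "geolocate")
  january <- utils::read.csv(file.path(geo_d, "january.csv"))
  note("geolocate", length(ids),
       as.integer(readLines(file.path(geo_d, "excluded.txt"))))

  # ---- stage 3: phenology ---------------------------------------------------
  pos_files <- list.files(file.path(geo_d, "positions"), full.names = TRUE)
  .run_stage(config, "phenology",
             key = config[c("phenology_k", "phenology_d")],
             inputs = pos_files, log_level = log_level, fn = function(d) {
    phen <- NULL
    for (i in seq_along(ids)) {
      f <- file.path(geo_d, "positions", paste0(ids[i], ".csv"))
      if (!file.exists(f)) next
      pos <- utils::read.csv(f)
      pos$date <- as.Date(pos$date)
      # longitude is usable even where latitude was equinox-masked
      lon <- ifelse(is.na(pos$lon), NA, pos$lon)
      ph <- detect_migration_dates(pos$date, lon, colony$lon,
                                   k_days = config$phenology_k,
                                   d_lon = config$phenology_d)
      phen <- rbind(phen, data.frame(
        bird = truth$bird[i], year = truth$year[i],
        southbound_start = format(ph$southbound_start),
        northbound_start = format(ph$northbound_start),
        northbound_end = format(ph$northbound_end),
        reason = ph$reason))
    }
    utils::write.csv(phen, file.path(d, "phenology.csv"), row.names = FALSE)
  })
  phen <- utils::read.csv(file.path(config$out_dir, "phenology",
                                    "phenology.csv"))
  note("phenology", nrow(phen), sum(is.na(phen$southbound_start)))

  # ---- stage 4: behaviour ---------------------------------------------------
  .run_stage(config, "behaviour",
             key = config[c("min_dry_hours", "mixture_scope",
                            "count_daytime_burrow")],
             inputs = c(file.path(sim_d, "immersion", paste0(ids, ".csv")),
                        file.path(geo_d, "january.csv")),
             log_level = log_level, fn = function(d) {
    beh <- NULL
    excluded <- 0
    for (i in seq_along(ids)) {
      id <- ids[i]; y <- truth$year[i]; b <- truth$bird[i]
      imm <- read_immersion_csv(file.path(sim_d, "immersion",
                                          paste0(id, ".csv")))
      row <- tryCatch(
        .behaviour_bird_year(imm, b, y, colony, january, config),
        error = function(e) NULL)
      if (is.null(row)) { excluded <- excluded + 1; next }
      beh <- rbind(beh, row)
    }
    utils::write.csv(beh, file.path(d, "behaviour.csv"), row.names = FALSE)
    writeLines(as.character(excluded), file.path(d, "excluded.txt"))
  })
  beh_d <- file.path(config$out_dir, "behaviour")
  behaviour <- utils::read.csv(file.path(beh_d, "behaviour.csv"))
  note("behaviour", length(ids),
       as.integer(readLines(file.path(beh_d, "excluded.txt"))))

  # ---- stage 5: environment -------------------------------------------------
  chl_files <- list.files(sim_d, pattern = "^chl_.*\\.csv$", full.names = TRUE)
  .run_stage(config, "environment", key = config["peak_method"],
             inputs = c(file.path(sim_d, "index.csv"), chl_files),
             log_level = log_level, fn = function(d) {
    index <- read_index_csv(file.path(sim_d, "index.csv"))
    soi <- seasonal_index_mean(index, "soi_ond")
    names(soi)[2] <- "soi_ond"
    peaks <- do.call(rbind, lapply(chl_files, function(f) {
      fld <- read_chl_csv(f)
      data.frame(jan_year = fld$year,
                 chl_peak_latitude = as.numeric(
                   chlorophyll_peak_latitude(fld, method = config$peak_method)))
    }))
    cov <- merge(soi, peaks, by.x = "year", by.y = "jan_year",
                 all.x = TRUE)
    # the OND index of calendar year y describes bird-year y, whose January
    # falls in y + 1; align the chlorophyll January accordingly
    cov$chl_peak_latitude <- peaks$chl_peak_latitude[
      match(cov$year + 1, peaks$jan_year)]
    utils::write.csv(cov, file.path(d, "covariates.csv"), row.names = FALSE)
  })
  covariates <- utils::read.csv(file.path(config$out_dir, "environment",
                                          "covariates.csv"))

  # ---- stage 6: summary -----------------------------------------------------
  .run_stage(config, "summary", key = list(),
             inputs = c(file.path(geo_d, "january.csv"),
                        file.path(config$out_dir, "phenology", "phenology.csv"),
                        file.path(beh_d, "behaviour.csv"),
                        file.path(config$out_dir, "environment",
                                  "covariates.csv")),
             log_level = log_level, fn = function(d) {
    s <- merge(january, phen[, setdiff(names(phen), "reason")],
               by = c("bird", "year"), all = TRUE)
    s <- merge(s, behaviour, by = c("bird", "year"), all = TRUE)
    s <- merge(s, covariates, by = "year", all.x = TRUE)
    s <- s[order(s$bird, s$year), ]
    doy <- function(x) as.integer(strftime(as.Date(x), "%j"))
    s$southbound_start_doy <- doy(s$southbound_start)
    s$northbound_start_doy <- doy(s$northbound_start)
    s$northbound_end_doy <- doy(s$northbound_end)
    # previous bird-year carry-over covariates (consecutive years only)
    prev <- s[, c("bird", "year", "august_foraging", "august_visits")]
    prev$year <- prev$year + 1
    names(prev)[3:4] <- c("august_foraging_prev", "august_visits_prev")
    s <- merge(s, prev, by = c("bird", "year"), all.x = TRUE)
    utils::write.csv(s, file.path(d, "bird_year_summary.csv"),
                     row.names = FALSE)
  })
  summary <- utils::read.csv(file.path(config$out_dir, "summary",
                                       "bird_year_summary.csv"))

  # ---- stage 7: infer -------------------------------------------------------
  .run_stage(config, "infer", key = config["nboot"],
             inputs = file.path(config$out_dir, "summary",
                                "bird_year_summary.csv"),
             log_level = log_level, fn = function(d) {
    cen <- subject_centring(summary, x = "soi_ond", y = "january_latitude",
                            id = "bird", nboot = config$nboot,
                            seed = config$seed)
    jsonlite::write_json(
      list(between = cen$between, within = cen$within,
           difference = cen$difference,
           lrt_within = cen$lrt_within[c("chisq", "df", "p")],
           n = cen$n, n_birds = cen$n_birds),
      file.path(d, "centring.json"), auto_unbox = TRUE, digits = NA)
    spec <- path_model_spec()
    pd <- data.frame(
      soi_ond = summary$soi_ond,
      january_latitude = summary$january_latitude,
      january_foraging = summary$january_foraging,
      august_foraging = summary$august_foraging,
      august_visits = summary$august_visits,
      august_foraging_prev = summary$august_foraging_prev,
      southbound_start = summary$southbound_start_doy,
      northbound_start = summary$northbound_start_doy,
      northbound_end = summary$northbound_end_doy)
    pm <- tryCatch(fit_path_model(spec, pd), error = function(e) NULL)
    if (!is.null(pm)) {
      utils::write.csv(pm$coefficients,
                       file.path(d, "path_coefficients.csv"),
                       row.names = FALSE)
      jsonlite::write_json(c(pm$fit, n = pm$n),
                           file.path(d, "fit_indices.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  })
  inf_d <- file.path(config$out_dir, "infer")
  centring <- jsonlite::read_json(file.path(inf_d, "centring.json"),
                                  simplifyVector = TRUE)
  path <- NULL
  if (file.exists(file.path(inf_d, "path_coefficients.csv"))) {
    path <- list(
      coefficients = utils::read.csv(file.path(inf_d,
                                               "path_coefficients.csv")),
      fit = jsonlite::read_json(file.path(inf_d, "fit_indices.json"),
                                simplifyVector = TRUE))
  }

  utils::write.csv(accounting, file.path(config$out_dir, "accounting.csv"),
                   row.names = FALSE)
  stopifnot(all(accounting$rows_in - accounting$rows_excluded ==
                  accounting$rows_out))
  list(summary = summary, centring = centring, path = path,
       accounting = accounting, out_dir = config$out_dir)
}

# behaviour metrics for one bird-year: January effort at the January mean
# position, August effort/visits at the colony, incubation evidence
.behaviour_bird_year <- function(imm, bird, year, colony, january, config) {
  jrow <- january[january$bird == bird & january$year == year, ]
  jan_dates <- seq(as.Date(sprintf("%d-01-01", year + 1)),
                   as.Date(sprintf("%d-01-31", year + 1)), by = "day")
  january_foraging <- NA_real_
  if (nrow(jrow) == 1 && !is.na(jrow$january_latitude)) {
    sun_jan <- sunrise_sunset(c(jan_dates, max(jan_dates) + 1),
                              jrow$january_latitude, jrow$january_longitude)
    imm_jan <- imm[as.Date(imm$bin_start, tz = "UTC") %in% jan_dates, ]
    eff <- foraging_effort(imm_jan, sun_jan)
    january_foraging <- attr(eff, "mean_proportion")
  }

  # breeding season at the colony: June-August of calendar `year`
  bs_dates <- seq(as.Date(sprintf("%d-06-01", year)),
                  as.Date(sprintf("%d-09-01", year)), by = "day")
  sun_col <- sunrise_sunset(bs_dates, colony$lat, colony$lon)
  imm_bs <- imm[as.Date(imm$bin_start, tz = "UTC") %in% bs_dates, ]
  ns <- night_summaries(imm_bs, sun_col)
  ns <- ns[!is.na(ns$wet_event_count), ]
  fit <- fit_night_mixture(ns$wet_event_count)
  ns <- classify_night_visits(ns, fit)
  burrow <- detect_daytime_burrow(imm_bs, sun_col,
                                  min_dry_hours = config$min_dry_hours)
  inc <- detect_incubation(imm_bs)
  august_visits <- count_colony_visits(
    ns, burrow, month = 8, year = year,
    include_daytime = config$count_daytime_burrow)

  # colony mask for August effort: visit nights, burrow stays, incubation
  mask <- rep(FALSE, nrow(imm_bs))
  vn <- ns$night_date[ns$is_visit]
  for (dte in as.list(vn)) {
    i <- match(dte, sun_col$date)
    if (!is.na(i) && i < nrow(sun_col)) {
      mask <- mask | (imm_bs$bin_start >= sun_col$sunset[i] &
                        imm_bs$bin_start < sun_col$sunrise[i + 1])
    }
  }
  iv <- rbind(burrow[, c("start", "end")], inc$intervals[, c("start", "end")])
  for (k in seq_len(nrow(iv))) {
    mask <- mask | (imm_bs$bin_start >= iv$start[k] &
                      imm_bs$bin_start < iv$end[k])
  }
  aug <- as.integer(format(imm_bs$bin_start, "%m", tz = "UTC")) == 8
  eff_aug <- foraging_effort(imm_bs[aug, ], sun_col, mask[aug])
  data.frame(bird = bird, year = year,
             january_foraging = january_foraging,
             august_foraging = attr(eff_aug, "mean_proportion"),
             august_visits = august_visits,
             incubation_evidence = inc$evidence,
             mixture_mu_dry = fit$means[1], mixture_mu_sea = fit$means[2])
}
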