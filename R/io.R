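#' Read an SPD from CSV
#'
#' Expects the two-column dialect `wavelength_nm,irradiance_w_m2_nm`
#' with a 1 or 5 nm step.
#'
#' @param path CSV file.
#' @return An [spd()].
#' @export
read_spd <- function(path) {
  header <- readLines(path, n = 1)
  if (!identical(trimws(header), "wavelength_nm,irradiance_w_m2_nm"))
    stop("line 1: expected header 'wavelength_nm,irradiance_w_m2_nm', got '",
         header, "'", call. = FALSE)
  tab <- utils::read.csv(path)
  w <- tab$wavelength_nm
  if (any(diff(w) <= 0)) {
    bad <- which(diff(w) <= 0)[1] + 1L
    stop("line ", bad + 1L,
         ": wavelengths not strictly increasing", call. = FALSE)
  }
  spd(w, tab$irradiance_w_m2_nm)
}

#' Write an SPD to CSV
#'
#' Full double precision (17 significant digits), so a write/read
#' round-trip is lossless.
#'
#' @param x an [spd()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_spd <- function(x, path) {
  stopifnot(is_spd(x))
  lines <- c("wavelength_nm,irradiance_w_m2_nm",
             paste(format(x$wavelength, digits = 17, trim = TRUE),
                   format(x$irradiance, digits = 17, trim = TRUE),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

sensor_log_columns <- function() {
  c("timestamp", "lux_raw", "cct_raw", "r_wm2", "g_wm2", "b_wm2",
    "ir_wm2", "motion")
}

#' Read a wearable sensor log from CSV
#'
#' Timestamps are ISO-8601 with timezone designator (e.g.
#' `2024-10-01T06:00:00+0000`); rows must be in strictly increasing
#' time order.
#'
#' @param path CSV file.
#' @return data.frame in the sensor-log schema with POSIXct
#'   `timestamp`.
#' @export
read_sensor_log <- function(path) {
  tab <- utils::read.csv(path)
  missing <- setdiff(sensor_log_columns(), names(tab))
  if (length(missing) > 0)
    stop("sensor log lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ts <- as.POSIXct(tab$timestamp, format = "%Y-%m-%dT%H:%M:%S%z",
                   tz = "UTC")
  if (anyNA(ts))
    stop("unparseable ISO-8601 timestamps at rows ",
         paste(utils::head(which(is.na(ts)), 5), collapse = ", "),
         call. = FALSE)
  if (is.unsorted(as.numeric(ts), strictly = TRUE)) {
    bad <- which(diff(as.numeric(ts)) <= 0) + 1L
    stop("timestamps out of order at: ",
         paste(utils::head(tab$timestamp[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  tab$timestamp <- ts
  tab$motion <- as.logical(tab$motion)
  tab
}

#' Write a wearable sensor log to CSV
#'
#' @param log sensor-log data.frame.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_sensor_log <- function(log, path) {
  out <- log[sensor_log_columns()]
  out$timestamp <- format(log$timestamp, "%Y-%m-%dT%H:%M:%S%z",
                          tz = "UTC")
  for (cc in c("lux_raw", "cct_raw", "r_wm2", "g_wm2", "b_wm2",
               "ir_wm2"))
    out[[cc]] <- format(out[[cc]], digits = 17, trim = TRUE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects every tunable of the simulate-calibrate-train-analyze
#' pipeline with its documented default.  Round-trips losslessly
#' through YAML ([write_run_config()] / [read_run_config()]).
#'
#' @param seed top-level seed; per-stage seeds are derived from it
#'   deterministically (stage index offsets).
#' @param protocol `"lab"` or `"field"`.
#' @param n_scenarios,reps protocol sizes.
#' @param train_frac,alpha calibration split and feature-selection
#'   level.
#' @param cv_folds folds for CS-model cross-validation.
#' @param n_trees,min_leaf forest hyperparameters.
#' @param days,cadence_min simulated deployment length and cadence.
#' @param day_window_start,day_window_end local clock hours bounding
#'   daytime.
#' @param lux_floor dim-light CCT reliability floor (lux).
#' @param day_threshold_h,night_threshold_h nonwear duration
#'   thresholds (hours).
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, protocol = "lab", n_scenarios = 100,
                       reps = 5, train_frac = 0.7, alpha = 0.05,
                       cv_folds = 5, n_trees = 500, min_leaf = 2,
                       days = 7, cadence_min = 5,
                       day_window_start = 6, day_window_end = 18,
                       lux_floor = 10, day_threshold_h = 2,
                       night_threshold_h = 4) {
  structure(list(seed = seed, protocol = protocol,
                 n_scenarios = n_scenarios, reps = reps,
                 train_frac = train_frac, alpha = alpha,
                 cv_folds = cv_folds, n_trees = n_trees,
                 min_leaf = min_leaf, days = days,
                 cadence_min = cadence_min,
                 day_window_start = day_window_start,
                 day_window_end = day_window_end,
                 lux_floor = lux_floor,
                 day_threshold_h = day_threshold_h,
                 night_threshold_h = night_threshold_h),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

# derive a stage seed from the top-level seed; stages are numbered so
# each is independently reproducible
stage_seed <- function(config, stage) {
  (config$seed * 101 + stage) %% 2147483647
}

#' Run the full measurement pipeline
#'
#' simulate scenes -> simulate sensor readings -> fit lux and CCT
#' calibrations -> fit and cross-validate CS models -> simulate a
#' multi-day deployment log -> annotate, mask dim CCT and summarize.
#' Every artifact is written under `out_dir` along with a manifest of
#' seeds and file checksums; the run is a deterministic function of
#' the config.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the fitted models, the weekly
#'   summary and the manifest.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE))
  }
  records <- step("simulate-scenes", {
    proto <- if (config$protocol == "lab") lab_protocol else
      field_protocol
    proto(config$n_scenarios, config$reps, stage_seed(config, 1))
  })
  message(sprintf("[simulate-scenes] %d readings from %d scenarios",
                  length(records), config$n_scenarios))
  scene_dir <- file.path(out_dir, "scenes")
  dir.create(scene_dir, showWarnings = FALSE)
  for (rec in records[!duplicated(vapply(records, `[[`, integer(1),
                                         "scenario_id"))]) {
    write_spd(rec$spd, file.path(scene_dir,
                                 sprintf("scene_%03d.csv",
                                         rec$scenario_id)))
  }
  paired <- step("simulate-readings",
                 paired_table(records, seed = stage_seed(config, 2)))
  utils::write.csv(paired, file.path(out_dir, "paired_readings.csv"),
                   row.names = FALSE)
  lux_model <- step("calibrate-lux",
                    fit_calibration(paired, "photopic_lux",
                                    train_frac = config$train_frac,
                                    seed = stage_seed(config, 3),
                                    alpha = config$alpha))
  cct_model <- step("calibrate-cct",
                    fit_calibration(paired, "cct",
                                    train_frac = config$train_frac,
                                    seed = stage_seed(config, 3),
                                    alpha = config$alpha))
  write_calibration_json(lux_model,
                         file.path(out_dir, "calibration_lux.json"))
  write_calibration_json(cct_model,
                         file.path(out_dir, "calibration_cct.json"))
  message(sprintf("[calibrate] lux test R2 %.3f, cct test R2 %.3f",
                  lux_model$metrics$test$r2,
                  cct_model$metrics$test$r2))
  ttab <- step("train-cs",
               build_training_table(records,
                                    seed = stage_seed(config, 2)))
  csm <- step("train-cs",
              fit_cs_model(ttab, "random_forest",
                           seed = stage_seed(config, 4),
                           train_frac = config$train_frac,
                           n_trees = config$n_trees,
                           min_leaf = config$min_leaf))
  cv <- step("train-cs",
             cross_validate(ttab, "random_forest",
                            k = config$cv_folds,
                            seed = stage_seed(config, 4),
                            n_trees = config$n_trees,
                            min_leaf = config$min_leaf))
  imp <- step("train-cs", feature_importance(csm,
                                             seed = stage_seed(config, 5)))
  utils::write.csv(imp, file.path(out_dir, "cs_importance.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(method = csm$method, hyperparams = csm$hyperparams,
         test = unclass(csm$metrics$test), cv_mean = cv$mean),
    file.path(out_dir, "cs_model.json"), auto_unbox = TRUE,
    digits = NA, pretty = TRUE)
  log <- step("simulate-log", {
    day_pool <- records[vapply(records, function(r)
      r$scenario$target_lux >= 300, logical(1))]
    night_pool <- records[vapply(records, function(r)
      r$scenario$target_lux < 300, logical(1))]
    if (length(day_pool) == 0) day_pool <- records
    if (length(night_pool) == 0) night_pool <- records
    generate_log(day_pool, night_pool, days = config$days,
                 cadence_min = config$cadence_min,
                 day_window = c(config$day_window_start,
                                config$day_window_end),
                 seed = stage_seed(config, 6))
  })
  write_sensor_log(log, file.path(out_dir, "sensor_log.csv"))
  series <- step("analyze-exposure", {
    s <- annotate(log, lux_model, cct_model, csm,
                  day_window = c(config$day_window_start,
                                 config$day_window_end),
                  day_threshold_h = config$day_threshold_h,
                  night_threshold_h = config$night_threshold_h)
    mask_dim_cct(s, config$lux_floor)
  })
  summary_tab <- step("analyze-exposure", weekly_summary(series))
  utils::write.csv(summary_tab, file.path(out_dir,
                                          "weekly_summary.csv"),
                   row.names = FALSE)
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.txt"))
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- c(sprintf("seed: %d", config$seed),
                sprintf("protocol: %s", config$protocol),
                sprintf("package_version: %s",
                        as.character(utils::packageVersion("cswear"))),
                paste0(files, ": ", unname(sums)))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(list(lux_model = lux_model, cct_model = cct_model,
                 cs_model = csm, cv = cv, importance = imp,
                 summary = summary_tab, manifest = manifest))
}
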