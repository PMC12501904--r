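#' Wearable sensor channel set
#'
#' Four irradiance channels with Gaussian responsivities,
#' peak-normalized, centered at 465, 525, 615 and 1100 nm.  Channel
#' names follow the logger's printed labels, in which "r" is the 465 nm
#' channel and "b" the 615 nm channel (the labels are physically
#' inverted relative to the wavelengths; the implementation keys
#' everything on the center wavelength and only maps labels at I/O).
#'
#' @param fwhm_visible,fwhm_ir full width at half maximum of the
#'   visible and infrared channel responsivities, nm.
#' @return A list of class `channel_set` with named `centers` and
#'   `fwhm`.
#' @export
channel_set <- function(fwhm_visible = 50, fwhm_ir = 100) {
  structure(list(centers = c(r = 465, g = 525, b = 615, ir = 1100),
                 fwhm = c(r = fwhm_visible, g = fwhm_visible,
                          b = fwhm_visible, ir = fwhm_ir)),
            class = "channel_set")
}

#' Channel irradiances of an SPD
#'
#' Each channel integrates the SPD against its Gaussian responsivity
#' (rectangle rule): `sum(resp(lambda) * E(lambda)) * dlambda`.  Linear
#' in the SPD.  The SPD grid must cover each channel center +/- 2
#' standard deviations (the IR channel therefore needs coverage to
#' about 1185 nm -- the default [scene_grid()] suffices).
#'
#' @param x an [spd()] on a grid covering the channel supports.
#' @param channels a [channel_set()].
#' @return Named numeric vector `r`, `g`, `b`, `ir` in W m^-2.
#' @export
channel_response <- function(x, channels = channel_set()) {
  stopifnot(is_spd(x), inherits(channels, "channel_set"))
  sigma <- channels$fwhm / (2 * sqrt(2 * log(2)))
  lo <- channels$centers - 2 * sigma
  hi <- channels$centers + 2 * sigma
  if (min(x$wavelength) > min(lo) || max(x$wavelength) < max(hi))
    stop(sprintf("SPD grid [%g, %g] nm does not cover channel supports [%g, %g] nm",
                 min(x$wavelength), max(x$wavelength), min(lo), max(hi)),
         call. = FALSE)
  out <- vapply(seq_along(channels$centers), function(i) {
    resp <- exp(-0.5 * ((x$wavelength - channels$centers[i]) / sigma[i])^2)
    sum(resp * x$irradiance) * x$step
  }, numeric(1))
  names(out) <- names(channels$centers)
  out
}

#' Sensor distortion specification
#'
#' The simulated logger derives its raw illuminance and raw CCT as an
#' invertible linear mixture of the true illuminance, true CCT and IR
#' channel irradiance, then adds noise and clamps to the instrument
#' ranges.  The mixture is parameterized by its *inverse*: the
#' no-intercept linear correction that maps (raw CCT, IR, raw lux) back
#' to truth.  The defaults follow the published wearable-logger
#' correction -- `lux = 0.0596*CCT' + a*IR + 0.8432*lux'` and
#' `cct = 1.048*CCT' - b*IR + 0.1761*lux'` -- so the optimal linear
#' calibration of the simulated sensor has exactly that functional
#' form (same features, same signs, no intercept).  The two IR
#' coefficients are rescaled to this simulator's radiometric channel
#' units (the 1100 nm channel reports a fraction of a W m^-2 per 1000
#' daylight lux, so published magnitudes of order one would make the
#' IR daylight correction numerically immaterial).
#'
#' @param lux_coef,cct_coef named numeric vectors with elements
#'   `cct_raw`, `ir`, `lux_raw`: the inverse (calibration) coefficients.
#'   The implied 2x2 mixing of (cct_raw, lux_raw) must be invertible.
#' @param noise_cv named multiplicative noise coefficients of variation
#'   for `lux`, `cct` and `channel` outputs (>= 0).
#' @param noise_floor named additive noise standard deviations (same
#'   names).
#' @param lux_range,cct_range instrument validity ranges used for
#'   clamping (defaults: 0.1--100,000 lux and 1800--10,000 K).
#' @return A list of class `distortion_spec`.
#' @export
distortion_spec <- function(
    lux_coef = c(cct_raw = 0.0596, ir = 500, lux_raw = 0.8432),
    cct_coef = c(cct_raw = 1.048, ir = -500, lux_raw = 0.1761),
    noise_cv = c(lux = 0.10, cct = 0.03, channel = 0.03),
    noise_floor = c(lux = 0.5, cct = 20, channel = 1e-4),
    lux_range = c(0.1, 1e5), cct_range = c(1800, 10000)) {
  m <- rbind(lux_coef[c("cct_raw", "lux_raw")],
             cct_coef[c("cct_raw", "lux_raw")])
  if (abs(det(m)) < 1e-12)
    stop("distortion mixing is not invertible", call. = FALSE)
  if (any(noise_cv < 0) || any(noise_floor < 0))
    stop("noise scales must be nonnegative", call. = FALSE)
  structure(list(lux_coef = lux_coef, cct_coef = cct_coef,
                 noise_cv = noise_cv, noise_floor = noise_floor,
                 lux_range = lux_range, cct_range = cct_range),
            class = "distortion_spec")
}

#' A noise-free distortion specification
#'
#' Convenience wrapper: [distortion_spec()] with all noise scales zero.
#' @param ... passed to [distortion_spec()].
#' @export
distortion_spec_noiseless <- function(...) {
  distortion_spec(noise_cv = c(lux = 0, cct = 0, channel = 0),
                  noise_floor = c(lux = 0, cct = 0, channel = 0), ...)
}

# solve the 2x2 system for (cct_raw, lux_raw) given truth and ir
forward_mix <- function(lux, cct, ir, spec) {
  A <- rbind(spec$lux_coef[c("cct_raw", "lux_raw")],
             spec$cct_coef[c("cct_raw", "lux_raw")])
  rhs <- rbind(lux - spec$lux_coef[["ir"]] * ir,
               cct - spec$cct_coef[["ir"]] * ir)
  sol <- solve(A, rhs)
  list(cct_raw = sol[1, ], lux_raw = sol[2, ])
}

#' Simulate sensor readings from ground-truth scene values
#'
#' Applies the inverse of the calibration mixing to produce raw lux and
#' raw CCT, adds multiplicative-plus-floor Gaussian noise to every
#' output, then clamps raw lux and raw CCT to the instrument ranges,
#' flagging clamped rows.  Deterministic for a fixed seed.
#'
#' @param truth data.frame with columns `lux`, `cct`, `r`, `g`, `b`,
#'   `ir` (ground-truth illuminance, CCT and channel irradiances).
#' @param spec a [distortion_spec()].
#' @param seed integer seed for the noise stream.
#' @return data.frame with `lux_raw`, `cct_raw`, `r`, `g`, `b`, `ir`
#'   (noisy channels) and logical `clamped`.
#' @export
distort <- function(truth, spec = distortion_spec(), seed = 1) {
  need <- c("lux", "cct", "r", "g", "b", "ir")
  stopifnot(is.data.frame(truth), all(need %in% names(truth)))
  n <- nrow(truth)
  # darkness gives an undefined true CCT; the instrument still emits an
  # in-range reading there, modeled as the bottom of its validity range
  cct_in <- ifelse(is.na(truth$cct), spec$cct_range[1], truth$cct)
  with_seed(seed, {
    noisy <- function(v, kind) {
      v * (1 + spec$noise_cv[[kind]] * rnorm(n)) +
        spec$noise_floor[[kind]] * rnorm(n)
    }
    ch <- lapply(truth[c("r", "g", "b", "ir")],
                 function(v) noisy(v, "channel"))
    mix <- forward_mix(truth$lux, cct_in, ch$ir, spec)
    lux_raw <- noisy(mix$lux_raw, "lux")
    cct_raw <- noisy(mix$cct_raw, "cct")
    lux_cl <- pmin(pmax(lux_raw, spec$lux_range[1]), spec$lux_range[2])
    cct_cl <- pmin(pmax(cct_raw, spec$cct_range[1]), spec$cct_range[2])
    data.frame(lux_raw = lux_cl, cct_raw = cct_cl,
               r = ch$r, g = ch$g, b = ch$b, ir = ch$ir,
               clamped = lux_cl != lux_raw | cct_cl != cct_raw)
  })
}

#' Ground-truth scene table for a protocol run
#'
#' Evaluates every protocol record's SPD: photopic lux, CCT, CL_A, CS
#' and the four channel irradiances.
#'
#' @param records output of [lab_protocol()] or [field_protocol()].
#' @param tables,params,channels spectral machinery defaults.
#' @return data.frame with one row per record: `scenario_id`, `rep`,
#'   `lux`, `cct`, `cla`, `cs`, `r`, `g`, `b`, `ir`,
#'   `daylight_fraction`.
#' @export
scene_truth_table <- function(records, tables = observer_tables(),
                              params = circadian_params(),
                              channels = channel_set()) {
  rows <- lapply(records, function(rec) {
    m <- spd_to_metrics(rec$spd, tables, params)
    ch <- channel_response(rec$spd, channels)
    data.frame(scenario_id = rec$scenario_id, rep = rec$rep,
               lux = m$lux, cct = m$cct, cla = m$cla, cs = m$cs,
               r = ch[["r"]], g = ch[["g"]], b = ch[["b"]],
               ir = ch[["ir"]],
               daylight_fraction = rec$scenario$daylight_fraction)
  })
  do.call(rbind, rows)
}

#' Paired ground-truth / sensor table
#'
#' Combines [scene_truth_table()] with [distort()] into the paired
#' table the calibration and prediction modules consume.
#'
#' @inheritParams scene_truth_table
#' @param spec a [distortion_spec()].
#' @param seed noise seed.
#' @return data.frame with reference columns `lux_ref`, `cct_ref`,
#'   `cla_ref`, `cs_ref` and sensor columns `lux_raw`, `cct_raw`,
#'   `r_wm2`, `g_wm2`, `b_wm2`, `ir_wm2`, `clamped`.
#' @export
paired_table <- function(records, spec = distortion_spec(), seed = 1,
                         tables = observer_tables(),
                         params = circadian_params(),
                         channels = channel_set()) {
  tr <- scene_truth_table(records, tables, params, channels)
  sr <- distort(tr, spec, seed)
  data.frame(scenario_id = tr$scenario_id, rep = tr$rep,
             lux_ref = tr$lux, cct_ref = tr$cct, cla_ref = tr$cla,
             cs_ref = tr$cs, lux_raw = sr$lux_raw,
             cct_raw = sr$cct_raw, r_wm2 = sr$r, g_wm2 = sr$g,
             b_wm2 = sr$b, ir_wm2 = sr$ir, clamped = sr$clamped,
             daylight_fraction = tr$daylight_fraction)
}

#' Simulate a multi-day wearable sensor log
#'
#' Emits one reading per cadence step across `days` days starting at
#' `start`.  Each reading samples a scene from the daytime or nighttime
#' pool (by the local-clock day window), applies a lognormal
#' illuminance jitter, and passes through the sensor distortion.
#' During scheduled nonwear episodes the light values are held constant
#' at the episode's first reading and motion is FALSE, emulating a
#' sensor lying face-up on a table.
#'
#' @param day_pool,night_pool protocol records (see [lab_protocol()])
#'   sampled during day and night periods.
#' @param start POSIXct start time.
#' @param days number of days covered (>= 1).
#' @param cadence_min minutes between readings.
#' @param nonwear data.frame with POSIXct `start`, `end` columns of
#'   nonwear episodes; must not overlap.
#' @param spec a [distortion_spec()].
#' @param day_window numeric `c(start_hour, end_hour)` local clock
#'   hours defining daytime (default 06:00--18:00).
#' @param motion_prob probability of a motion event per reading during
#'   wear, `c(day, night)`.
#' @param seed integer seed.
#' @return data.frame sensor log: `timestamp`, `lux_raw`, `cct_raw`,
#'   `r_wm2`, `g_wm2`, `b_wm2`, `ir_wm2`, `motion`.
#' @export
generate_log <- function(day_pool, night_pool,
                         start = as.POSIXct("2024-10-01 00:00:00",
                                            tz = "UTC"),
                         days = 1, cadence_min = 5,
                         nonwear = NULL, spec = distortion_spec(),
                         day_window = c(6, 18),
                         motion_prob = c(0.6, 0.15), seed = 1) {
  stopifnot(days >= 1, cadence_min > 0)
  if (!is.null(nonwear) && nrow(nonwear) > 1) {
    o <- order(nonwear$start)
    if (any(nonwear$start[o][-1] < nonwear$end[o][-nrow(nonwear)]))
      stop("nonwear episodes overlap", call. = FALSE)
  }
  n <- as.integer(days * 24 * 60 / cadence_min)
  ts <- start + seq(0, by = cadence_min * 60, length.out = n)
  hours <- as.numeric(format(ts, "%H")) + as.numeric(format(ts, "%M")) / 60
  is_day <- hours >= day_window[1] & hours < day_window[2]
  day_truth <- scene_truth_table(day_pool)
  night_truth <- scene_truth_table(night_pool)
  with_seed(seed, {
    pick <- ifelse(is_day,
                   sample(nrow(day_truth), n, replace = TRUE),
                   sample(nrow(night_truth), n, replace = TRUE))
    jit <- rlnorm(n, 0, 0.3)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      base <- if (is_day[i]) day_truth[pick[i], ] else night_truth[pick[i], ]
      tr <- data.frame(lux = base$lux * jit[i], cct = base$cct,
                       r = base$r * jit[i], g = base$g * jit[i],
                       b = base$b * jit[i], ir = base$ir * jit[i])
      sr <- distort(tr, spec, seed = seed + i)
      rows[[i]] <- data.frame(
        timestamp = ts[i], lux_raw = sr$lux_raw, cct_raw = sr$cct_raw,
        r_wm2 = sr$r, g_wm2 = sr$g, b_wm2 = sr$b, ir_wm2 = sr$ir,
        motion = runif(1) < (if (is_day[i]) motion_prob[1] else motion_prob[2]))
    }
    log <- do.call(rbind, rows)
    if (!is.null(nonwear) && nrow(nonwear) > 0) {
      for (k in seq_len(nrow(nonwear))) {
        inside <- which(log$timestamp >= nonwear$start[k] &
                          log$timestamp < nonwear$end[k])
        if (length(inside) > 0) {
          first <- inside[1]
          cols <- c("lux_raw", "cct_raw", "r_wm2", "g_wm2", "b_wm2",
                    "ir_wm2")
          for (cc in cols) log[[cc]][inside] <- log[[cc]][first]
          log$motion[inside] <- FALSE
        }
      }
    }
    log
  })
}
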