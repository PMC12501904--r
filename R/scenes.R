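#' Planckian (blackbody) source SPD
#'
#' Planck's law evaluated on the simulation grid and normalized to unit
#' photopic illuminance, so that scaling the result by a lux value gives
#' a scene of that illuminance.
#'
#' @param T color temperature in kelvin, in `[1000, 20000]`.
#' @param grid wavelength grid in nm (default [scene_grid()],
#'   360--1200 nm at 5 nm).
#' @return An [spd()] on `grid` with photopic illuminance 1 lux.
#' @export
planckian_spd <- function(T, grid = scene_grid()) {
  if (!is.numeric(T) || length(T) != 1L || T < 1000 || T > 20000)
    stop("Planckian temperature must be in [1000, 20000] K", call. = FALSE)
  shape <- planck_shape(grid, T)
  s <- spd(grid, shape / max(shape))
  spd_scale(s, 1 / photopic_illuminance(s))
}

# Near-IR emission envelope for indoor electric sources.  Indoor
# luminaires emit little power near 1100 nm, whereas daylight carries a
# strong near-IR component -- the physical fact that makes the IR
# channel a daylight signature.  Electric sources therefore keep their
# Planckian visible spectrum but roll off smoothly beyond 780 nm.
electric_ir_envelope <- function(grid) {
  ifelse(grid <= 780, 1, exp(-(grid - 780) / 60))
}

#' Indoor electric source SPD
#'
#' A Planckian radiator of the stated CCT over the visible range, with
#' near-infrared emission suppressed beyond 780 nm (see
#' `electric_ir_envelope`): visible-range photometry and circadian
#' content are exactly Planckian, while the 1100 nm channel sees almost
#' nothing, emulating indoor luminaires.  Normalized to unit photopic
#' illuminance.
#'
#' @inheritParams planckian_spd
#' @return An [spd()] with photopic illuminance 1 lux.
#' @export
electric_spd <- function(T, grid = scene_grid()) {
  s <- planckian_spd(T, grid)
  s <- spd(grid, s$irradiance * electric_ir_envelope(grid))
  spd_scale(s, 1 / photopic_illuminance(s))
}

# CIE daylight-locus chromaticity target for a nominal CCT
daylight_xy <- function(cct) {
  t <- cct / 1000
  xd <- if (cct <= 7000)
    0.244063 + 0.09911 / t + 2.9678 / t^2 - 4.6070 / t^3
  else
    0.237040 + 0.24748 / t + 1.9018 / t^2 - 2.0064 / t^3
  yd <- -3.000 * xd^2 + 2.870 * xd - 0.275
  c(x = xd, y = yd)
}

#' Daylight SPD at a nominal CCT
#'
#' Three-component reconstruction `S0 + M1*S1 + M2*S2` in the spirit of
#' the CIE daylight series: the basis curves are Planckian radiators at
#' 6500, 4000 and 25000 K (smooth, strictly positive over the full
#' 360--1200 nm grid, so the near-IR channel is covered without any
#' splice), and the weights `M1`, `M2` are solved so that the spectrum's
#' chromaticity under the bundled color-matching functions lands exactly
#' on the CIE daylight locus at the requested CCT.  Normalized to unit
#' photopic illuminance.
#'
#' @param cct nominal daylight CCT in kelvin, in `[4000, 25000]` (the
#'   daylight locus is undefined below 4000 K).
#' @param grid wavelength grid (default [scene_grid()]).
#' @return An [spd()] with photopic illuminance 1 lux.
#' @export
daylight_spd <- function(cct, grid = scene_grid()) {
  if (!is.numeric(cct) || length(cct) != 1L || cct < 4000 || cct > 25000)
    stop("daylight CCT must be in [4000, 25000] K", call. = FALSE)
  tab <- observer_tables()
  l <- tab$wavelength_nm
  basis_T <- c(6500, 4000, 25000)
  b_grid <- lapply(basis_T, function(tt) {
    v <- planck_shape(grid, tt); v / max(v)
  })
  b_vis <- lapply(seq_along(basis_T), function(i) {
    idx <- match(l, grid)
    b_grid[[i]][idx]
  })
  xyz <- vapply(b_vis, function(e) {
    c(sum(tab$xbar * e), sum(tab$ybar * e), sum(tab$zbar * e))
  }, numeric(3))
  target <- daylight_xy(cct)
  # solve X_i - x*(X+Y+Z) = 0 and Y_i - y*(X+Y+Z) = 0 for M1, M2
  f <- function(i, w) xyz[i, 1] + w[1] * xyz[i, 2] + w[2] * xyz[i, 3]
  A <- rbind(
    c(xyz[1, 2] - target["x"] * colSums(xyz)[2],
      xyz[1, 3] - target["x"] * colSums(xyz)[3]),
    c(xyz[2, 2] - target["y"] * colSums(xyz)[2],
      xyz[2, 3] - target["y"] * colSums(xyz)[3]))
  rhs <- c(target["x"] * colSums(xyz)[1] - xyz[1, 1],
           target["y"] * colSums(xyz)[1] - xyz[2, 1])
  m <- solve(A, rhs)
  vals <- b_grid[[1]] + m[1] * b_grid[[2]] + m[2] * b_grid[[3]]
  if (any(vals < 0)) {
    # small negative excursions occur only outside the visible band
    # (the colorimetric solve constrains 380-780 nm); clip them
    visible <- grid >= 380 & grid <= 780
    if (any(vals[visible] < -1e-6 * max(vals)))
      warning("daylight reconstruction clipped inside the visible band",
              call. = FALSE)
    vals <- pmax(vals, 0)
  }
  s <- spd(grid, vals)
  spd_scale(s, 1 / photopic_illuminance(s))
}

#' Lighting scenario description
#'
#' A scenario mixes weighted indoor electric sources with a daylight
#' component modulated by window-blind slat angle, distance from the
#' window and viewing angle, and is rescaled to a target illuminance.
#'
#' @param sources data.frame with columns `cct` (kelvin) and `weight`
#'   (>= 0); weights are relative illuminance contributions.  May have
#'   zero rows when `daylight_fraction > 0`.
#' @param daylight_fraction fraction in `[0, 1]` of scene illuminance
#'   contributed by daylight before attenuation.
#' @param daylight_cct nominal CCT of the daylight component (kelvin).
#' @param blind_angle one of `"retracted"`, `"45"`, `"90"`, `"135"`.
#' @param window_distance distance from the window in feet, `[0, 9]`.
#' @param view_angle viewing angle in degrees, `[0, 270]` (0 = facing
#'   the window).
#' @param target_lux scene photopic illuminance in lux.
#' @return A list of class `scenario`.
#' @export
scenario <- function(sources = data.frame(cct = 3000, weight = 1),
                     daylight_fraction = 0, daylight_cct = 6500,
                     blind_angle = "retracted", window_distance = 0,
                     view_angle = 0, target_lux = 300) {
  stopifnot(is.data.frame(sources),
            all(c("cct", "weight") %in% names(sources)))
  if (nrow(sources) > 0 && any(sources$weight < 0))
    stop("source weights must be nonnegative", call. = FALSE)
  if (daylight_fraction < 0 || daylight_fraction > 1)
    stop("daylight_fraction must be in [0, 1]", call. = FALSE)
  blind_angle <- match.arg(as.character(blind_angle),
                           c("retracted", "45", "90", "135"))
  if (window_distance < 0 || window_distance > 9)
    stop("window_distance must be in [0, 9] feet", call. = FALSE)
  if (view_angle < 0 || view_angle > 270)
    stop("view_angle must be in [0, 270] degrees", call. = FALSE)
  if (target_lux < 0) stop("target_lux must be >= 0", call. = FALSE)
  structure(list(sources = sources,
                 daylight_fraction = daylight_fraction,
                 daylight_cct = daylight_cct, blind_angle = blind_angle,
                 window_distance = window_distance,
                 view_angle = view_angle, target_lux = target_lux),
            class = "scenario")
}

#' Daylight attenuation factor of a scenario
#'
#' Product of the blind-slat factor (retracted 1.0, 45 deg 0.6, 90 deg
#' 0.3, 135 deg 0.15), an inverse-square-with-floor distance falloff
#' `1 / (1 + (d / 3)^2)`, and a cosine-shaped view-angle factor floored
#' at 0.25.  The individual constants are engineering stand-ins; only
#' their monotonicity (non-increasing in distance, in slat closure and
#' in off-axis angle) is load-bearing.
#'
#' @param sc a [scenario()].
#' @return Attenuation in `[0, 1]`.
#' @export
daylight_attenuation <- function(sc) {
  blind <- c(retracted = 1.0, `45` = 0.6, `90` = 0.3, `135` = 0.15)
  dist <- 1 / (1 + (sc$window_distance / 3)^2)
  a <- min(sc$view_angle, 180)
  view <- 0.25 + 0.75 * (1 + cospi(a / 180)) / 2
  unname(blind[sc$blind_angle] * dist * view)
}

#' Realize a scenario as an SPD
#'
#' Electric sources are combined in proportion to their weights
#' (illuminance shares); the daylight component, weighted by
#' `daylight_fraction` and multiplied by the scenario's attenuation
#' factor, is added; the mixture is rescaled to `target_lux`.
#'
#' @param sc a [scenario()].
#' @param grid wavelength grid.
#' @return An [spd()] whose photopic illuminance equals
#'   `sc$target_lux`.
#' @export
mix_scene <- function(sc, grid = scene_grid()) {
  stopifnot(inherits(sc, "scenario"))
  wsum <- if (nrow(sc$sources) > 0) sum(sc$sources$weight) else 0
  df <- sc$daylight_fraction * daylight_attenuation(sc)
  if (wsum <= 0 && df <= 0)
    stop("empty scene: no electric weight and no daylight", call. = FALSE)
  acc <- numeric(length(grid))
  if (wsum > 0) {
    for (i in seq_len(nrow(sc$sources))) {
      s <- electric_spd(sc$sources$cct[i], grid)
      acc <- acc + (1 - sc$daylight_fraction) *
        sc$sources$weight[i] / wsum * s$irradiance
    }
  }
  if (df > 0) {
    d <- daylight_spd(sc$daylight_cct, grid)
    acc <- acc + df * d$irradiance
  }
  s <- spd(grid, acc)
  lux <- photopic_illuminance(s)
  if (lux <= 0) stop("scene has zero illuminance", call. = FALSE)
  spd_scale(s, sc$target_lux / lux)
}

# run expr with a private, seeded RNG stream; restores caller RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Laboratory lighting protocol
#'
#' Generates the laboratory measurement campaign: `n_scenarios`
#' scenarios, each read `reps` times, with target illuminances drawn
#' from a bimodal distribution (a dim mode typical of indoor electric
#' lighting and a bright, daylight-accessible mode), spanning
#' 10--10,000 lux, and CCTs spanning 1500--10,500 K produced by four
#' electric sources (1500, 3000, 4200, 6500 K) used alone or in
#' combination plus window daylight.  The first two scenarios pin the
#' coverage extremes (a pure 1500 K source at 10 lux; pure high-CCT
#' daylight at 10,000 lux); the rest are sampled.
#'
#' @param n_scenarios number of distinct scenarios (default 100).
#' @param reps readings per scenario (default 5).
#' @param seed integer seed; the scenario list is a deterministic
#'   function of it.
#' @param grid wavelength grid.
#' @return A list of records, each a list with `scenario_id`, `rep`,
#'   `scenario` and `spd`; length `n_scenarios * reps`.
#' @export
lab_protocol <- function(n_scenarios = 100, reps = 5, seed = 1,
                         grid = scene_grid()) {
  stopifnot(n_scenarios >= 1, reps >= 1)
  source_ccts <- c(1500, 3000, 4200, 6500)
  scens <- with_seed(seed, {
    lapply(seq_len(n_scenarios), function(i) {
      if (i == 1L)
        return(scenario(data.frame(cct = 1500, weight = 1),
                        daylight_fraction = 0, target_lux = 10))
      if (i == 2L)
        return(scenario(data.frame(cct = numeric(0), weight = numeric(0)),
                        daylight_fraction = 1, daylight_cct = 12000,
                        target_lux = 10000))
      bright <- runif(1) < 0.5
      k <- sample(1:3, 1)
      src <- data.frame(cct = sample(source_ccts, k),
                        weight = runif(k, 0.2, 1))
      # two density modes: dim electric interiors around ~100 lux and
      # daylight-accessible spaces around ~1500 lux; window daylight
      # can contribute in either, at typical overcast-to-clear sky CCT
      lux <- if (bright) min(10000, max(300, rlnorm(1, log(1500), 0.5)))
      else min(300, max(10, rlnorm(1, log(100), 0.5)))
      df <- if (runif(1) < 0.8) runif(1, 0, 0.95) else 0
      scenario(src, daylight_fraction = df,
               daylight_cct = runif(1, 5000, 8000), target_lux = lux)
    })
  })
  emit_protocol(scens, reps, grid)
}

#' Field (nursing-home) lighting protocol
#'
#' On-site measurement campaign: warm electric sources (1800, 2700,
#' 4000 K), the full grid of four blind-slat angles, window distances
#' spanning 0--9 feet and view angles 0--270 degrees, with a
#' warm-dominant CCT distribution and a daylight-driven high tail.
#'
#' @inheritParams lab_protocol
#' @return As [lab_protocol()].
#' @export
field_protocol <- function(n_scenarios = 100, reps = 5, seed = 1,
                           grid = scene_grid()) {
  stopifnot(n_scenarios >= 1, reps >= 1)
  source_ccts <- c(1800, 2700, 4000)
  blinds <- c("retracted", "45", "90", "135")
  scens <- with_seed(seed, {
    lapply(seq_len(n_scenarios), function(i) {
      k <- sample(1:2, 1)
      src <- data.frame(cct = sample(source_ccts, k),
                        weight = runif(k, 0.2, 1))
      daylight_mode <- runif(1) < 0.4
      df <- if (daylight_mode) runif(1, 0.4, 0.95) else
        if (runif(1) < 0.3) runif(1, 0.02, 0.3) else 0
      lux <- if (daylight_mode)
        min(10000, max(200, rlnorm(1, log(1200), 0.7)))
      else
        min(400, max(5, rlnorm(1, log(60), 0.7)))
      scenario(src, daylight_fraction = df,
               daylight_cct = runif(1, 5000, 11000),
               blind_angle = blinds[1 + (i - 1) %% 4],
               window_distance = runif(1, 0, 9),
               view_angle = runif(1, 0, 270),
               target_lux = lux)
    })
  })
  emit_protocol(scens, reps, grid)
}

emit_protocol <- function(scens, reps, grid) {
  out <- vector("list", length(scens) * reps)
  idx <- 1L
  for (i in seq_along(scens)) {
    s <- mix_scene(scens[[i]], grid)
    for (r in seq_len(reps)) {
      out[[idx]] <- list(scenario_id = i, rep = r,
                         scenario = scens[[i]], spd = s)
      idx <- idx + 1L
    }
  }
  out
}
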