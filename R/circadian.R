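#' Model constants for circadian light and circadian stimulus
#'
#' Defaults are the published constants of the Rea circadian
#' phototransduction model: the blue-yellow opponent constant
#' `k = 0.2616`, opponent gain `a_by = 0.7`, rod gain `a_rod = 3.3`,
#' rod half-saturation irradiance `rod_sat = 6.5` W m^-2, overall scale
#' `cla_scale = 1548`, and the saturating stimulus transform with
#' asymptote `cs_max = 0.7`, half-saturation `cla_half = 355.7` and
#' exponent `cs_exponent = 1.1026`.
#'
#' @param k,a_by,a_rod,rod_sat,cla_scale,cs_max,cla_half,cs_exponent
#'   strictly positive model constants; see Details.
#' @return A list of class `circadian_params`.
#' @export
circadian_params <- function(k = 0.2616, a_by = 0.7, a_rod = 3.3,
                             rod_sat = 6.5, cla_scale = 1548,
                             cs_max = 0.7, cla_half = 355.7,
                             cs_exponent = 1.1026) {
  p <- list(k = k, a_by = a_by, a_rod = a_rod, rod_sat = rod_sat,
            cla_scale = cla_scale, cs_max = cs_max, cla_half = cla_half,
            cs_exponent = cs_exponent)
  if (any(vapply(p, function(x) !is.numeric(x) || length(x) != 1L || x <= 0,
                 logical(1))))
    stop("all circadian parameters must be positive scalars", call. = FALSE)
  structure(p, class = "circadian_params")
}

#' Photopic illuminance of an SPD
#'
#' Illuminance as 683 * sum(V(lambda) * E(lambda) * dlambda) over the
#' canonical 380--780 nm grid (rectangle rule, dlambda = 5 nm).
#'
#' @param x an [spd()].
#' @param tables observer tables from [observer_tables()].
#' @return Illuminance in lux (>= 0).
#' @export
photopic_illuminance <- function(x, tables = observer_tables()) {
  x <- spd_on_canonical_grid(x)
  683 * sum(tables$v * x$irradiance) * x$step
}

#' Circadian light (CL_A) of an SPD
#'
#' Evaluates the Rea model.  With rectangle-rule integrals over the
#' 380--780 nm, 5 nm grid,
#' `b-y = sum((S/mp) E) dl - k * sum((V/mp) E) dl`.  When `b-y > 0`,
#' `CL_A = cla_scale * (sum(Mc E) dl + a_by * (b-y) -
#'  a_rod * (1 - exp(-sum(V' E) dl / rod_sat)))`; otherwise
#' `CL_A = cla_scale * sum(Mc E) dl`.  The rod subtraction can drive the
#' bracket negative for dim, blue-depleted light; the result is then
#' clamped to zero and flagged, since the stimulus transform is undefined
#' for negative circadian light.
#'
#' @param x an [spd()] (1 nm inputs are rebinned to 5 nm first).
#' @param tables observer tables.
#' @param params model constants from [circadian_params()].
#' @return A list of class `cla_result`: `cla` (clamped at 0), `branch`
#'   (`"positive"` or `"nonpositive"`, the sign of b-y), `clamped`
#'   (logical), and `integrals` (`mc`, `by`, `rod` = sum(V' E) dl,
#'   `s_over_mp`, `v_over_mp`).
#' @export
cla <- function(x, tables = observer_tables(),
                params = circadian_params()) {
  x <- spd_on_canonical_grid(x)
  if (length(x$wavelength) != nrow(tables) ||
      any(abs(x$wavelength - tables$wavelength_nm) > 1e-9))
    stop("SPD and observer tables are on different grids", call. = FALSE)
  dl <- x$step
  e <- x$irradiance
  mc_i <- sum(tables$mc * e) * dl
  s_mp <- sum(tables$scone / tables$mp * e) * dl
  v_mp <- sum(tables$v / tables$mp * e) * dl
  rod_i <- sum(tables$vprime * e) * dl
  by <- s_mp - params$k * v_mp
  if (by > 0) {
    raw <- params$cla_scale *
      (mc_i + params$a_by * by -
         params$a_rod * (1 - exp(-rod_i / params$rod_sat)))
    branch <- "positive"
  } else {
    raw <- params$cla_scale * mc_i
    branch <- "nonpositive"
  }
  structure(list(cla = max(0, raw), raw = raw, branch = branch,
                 clamped = raw < 0,
                 integrals = list(mc = mc_i, by = by, rod = rod_i,
                                  s_over_mp = s_mp, v_over_mp = v_mp)),
            class = "cla_result")
}

#' @export
print.cla_result <- function(x, ...) {
  cat(sprintf("CL_A = %.4g (%s branch%s)\n", x$cla, x$branch,
              if (x$clamped) ", clamped at 0" else ""))
  invisible(x)
}

#' @export
as.numeric.cla_result <- function(x, ...) x$cla

#' Circadian stimulus from circadian light
#'
#' The saturating transform
#' `CS = cs_max * (1 - 1 / (1 + (CL_A / cla_half)^cs_exponent))`:
#' zero at zero, strictly increasing, approaching `cs_max = 0.7` --
#' the model's estimate of maximal fractional nocturnal melatonin
#' suppression.
#'
#' @param cla_value numeric vector of CL_A values (>= 0), or a
#'   `cla_result` from [cla()].
#' @param params model constants.
#' @return CS values in `[0, cs_max)`.
#' @export
cs <- function(cla_value, params = circadian_params()) {
  if (inherits(cla_value, "cla_result")) cla_value <- cla_value$cla
  if (!is.numeric(cla_value) || any(is.na(cla_value)))
    stop("cla_value must be numeric", call. = FALSE)
  if (any(cla_value < 0))
    stop("CS is undefined for negative CL_A", call. = FALSE)
  params$cs_max *
    (1 - 1 / (1 + (cla_value / params$cla_half)^params$cs_exponent))
}

#' All ground-truth metrics of an SPD in one call
#'
#' Bundles [photopic_illuminance()], [cct_of_spd()], [cla()] and [cs()],
#' all computed on the canonical 5 nm grid.  Used as the ground-truth
#' generator for the calibration and CS-prediction fixtures.
#'
#' @inheritParams cla
#' @return A list: `lux`, `cct` (NA when chromaticity is undefined),
#'   `cct_flag` (`"ok"`, `"undefined"` or `"out_of_gamut"`), `cla`,
#'   `cs`, `branch`, `clamped`.
#' @export
spd_to_metrics <- function(x, tables = observer_tables(),
                           params = circadian_params()) {
  x <- spd_on_canonical_grid(x)
  lux <- photopic_illuminance(x, tables)
  cct <- tryCatch(cct_of_spd(x, tables),
                  cswear_undefined_chromaticity = function(e) {
                    structure(NA_real_, flag = "undefined")
                  })
  cl <- cla(x, tables, params)
  list(lux = lux, cct = as.numeric(cct),
       cct_flag = attr(cct, "flag") %||% "ok",
       cla = cl$cla, cs = cs(cl$cla, params),
       branch = cl$branch, clamped = cl$clamped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
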