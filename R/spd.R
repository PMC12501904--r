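#' Spectral power distribution
#'
#' Construct an `spd` object: spectral irradiance (W m^-2 nm^-1) tabulated
#' on a strictly increasing, uniformly spaced wavelength grid.  All
#' photometric and circadian computation in the package starts from this
#' container.  Grids at 1 nm or 5 nm step are supported; circadian and
#' photometric operations work on the canonical 380--780 nm, 5 nm grid
#' (see [resample_to_5nm()] and [spd_on_canonical_grid()]).
#'
#' @param wavelength numeric vector of wavelengths in nm, strictly
#'   increasing with uniform step.
#' @param irradiance numeric vector of spectral irradiance in
#'   W m^-2 nm^-1, same length as `wavelength`, all values >= 0.
#' @return An object of class `spd`: a list with elements `wavelength`,
#'   `irradiance` and `step` (nm).
#' @examples
#' s <- spd(380:780, rep(0.01, 401))
#' photopic_illuminance(s)
#' @export
spd <- function(wavelength, irradiance) {
  wavelength <- as.numeric(wavelength)
  irradiance <- as.numeric(irradiance)
  if (length(wavelength) == 0L)
    stop("empty SPD: no wavelength samples", call. = FALSE)
  if (length(wavelength) != length(irradiance))
    stop("wavelength and irradiance lengths differ", call. = FALSE)
  if (anyNA(wavelength) || anyNA(irradiance))
    stop("SPD contains missing values", call. = FALSE)
  if (any(irradiance < 0))
    stop("SPD irradiance must be nonnegative", call. = FALSE)
  if (length(wavelength) > 1L) {
    d <- diff(wavelength)
    if (any(d <= 0))
      stop("wavelengths must be strictly increasing", call. = FALSE)
    step <- d[1L]
    if (any(abs(d - step) > 1e-9))
      stop("wavelength grid must be uniform (to 1e-9 nm)", call. = FALSE)
  } else {
    step <- NA_real_
  }
  structure(list(wavelength = wavelength, irradiance = irradiance,
                 step = step),
            class = "spd")
}

#' @export
print.spd <- function(x, ...) {
  cat(sprintf("<spd> %d samples, %g-%g nm, step %g nm\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              x$step))
  cat(sprintf("  total irradiance: %.6g W m^-2\n",
              sum(x$irradiance) * x$step))
  invisible(x)
}

is_spd <- function(x) inherits(x, "spd")

#' Scale an SPD by a nonnegative factor
#'
#' @param x an [spd()] object.
#' @param factor nonnegative scalar.
#' @return The scaled `spd`.
#' @export
spd_scale <- function(x, factor) {
  stopifnot(is_spd(x), is.numeric(factor), length(factor) == 1L,
            factor >= 0)
  spd(x$wavelength, x$irradiance * factor)
}

#' Add SPDs defined on the same grid
#'
#' @param ... two or more [spd()] objects on identical grids.
#' @return Their sum as an `spd`.
#' @export
spd_add <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1L, all(vapply(xs, is_spd, logical(1))))
  w <- xs[[1L]]$wavelength
  for (x in xs[-1L]) {
    if (length(x$wavelength) != length(w) ||
        any(abs(x$wavelength - w) > 1e-9))
      stop("SPD grids differ; cannot add", call. = FALSE)
  }
  spd(w, Reduce(`+`, lapply(xs, `[[`, "irradiance")))
}

#' Rebin a 1 nm SPD to the 5 nm grid
#'
#' Bins are centered on multiples of 5 nm; the bin at center c averages
#' the five 1 nm samples c-2 .. c+2.  Samples missing at the edges of the
#' input range are treated as zero, so total integrated irradiance is
#' conserved exactly (sum(out) * 5 == sum(in) * 1); edge bins whose
#' support is only partly covered are correspondingly diluted.
#'
#' @param x an [spd()] at 1 nm step with integer-valued wavelengths.
#' @return An `spd` at 5 nm step.
#' @export
resample_to_5nm <- function(x) {
  stopifnot(is_spd(x))
  if (is.na(x$step) || abs(x$step - 1) > 1e-9)
    stop("resample_to_5nm() requires a 1 nm input step", call. = FALSE)
  w <- x$wavelength
  if (any(abs(w - round(w)) > 1e-6))
    stop("resample_to_5nm() requires integer nm wavelengths",
         call. = FALSE)
  w <- round(w)
  centers <- seq(5 * ceiling((w[1L] - 2) / 5), 5 * floor((w[length(w)] + 2) / 5), by = 5)
  # assign each 1 nm sample to the nearest multiple of 5
  bin <- 5 * round(w / 5)
  sums <- vapply(centers, function(cc) sum(x$irradiance[bin == cc]),
                 numeric(1))
  spd(centers, sums / 5)
}

#' Restrict / zero-fill an SPD onto the canonical 380--780 nm, 5 nm grid
#'
#' Circadian and photometric operations are defined on 380--780 nm at
#' 5 nm.  Coverage outside that window is discarded; wavelengths inside
#' the window that the SPD does not cover are zero-filled with a warning.
#' A 1 nm input is first rebinned with [resample_to_5nm()].
#'
#' @param x an [spd()] at 1 or 5 nm step.
#' @return An `spd` on the grid `seq(380, 780, by = 5)`.
#' @export
spd_on_canonical_grid <- function(x) {
  stopifnot(is_spd(x))
  if (!is.na(x$step) && abs(x$step - 1) < 1e-9) x <- resample_to_5nm(x)
  if (is.na(x$step) || abs(x$step - 5) > 1e-9)
    stop("SPD step must be 1 or 5 nm", call. = FALSE)
  grid <- canonical_grid()
  idx <- match(grid, round(x$wavelength))
  if (anyNA(idx))
    warning("SPD does not cover 380-780 nm fully; missing wavelengths zero-filled",
            call. = FALSE)
  vals <- ifelse(is.na(idx), 0, x$irradiance[idx])
  spd(grid, vals)
}

canonical_grid <- function() seq(380, 780, by = 5)

#' The full simulation grid used for scene synthesis
#'
#' Scenes are synthesized on 360--1200 nm at 5 nm so that the 1100 nm
#' infrared sensor channel is computable; circadian and photometric math
#' still uses only 380--780 nm.
#' @return Numeric vector `seq(360, 1200, by = 5)`.
#' @export
scene_grid <- function() seq(360, 1200, by = 5)
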