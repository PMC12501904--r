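#' Observer spectral-weighting tables
#'
#' The circadian-light model weights a spectral irradiance by five
#' pre-receptoral/receptoral functions -- lens-corrected melanopsin
#' sensitivity (Mc), the S-cone fundamental (S), macular pigment
#' transmittance (mp), the photopic luminous efficiency function (V) and
#' the scotopic luminous efficiency function (V') -- and computes
#' chromaticity from the CIE 1931 2-degree color-matching functions
#' (xbar, ybar, zbar).  All tables live on the shared canonical grid
#' 380--780 nm at 5 nm.
#'
#' The tables shipped in `inst/extdata/observer_tables_5nm.csv` are
#' generated from published analytic forms (multi-Gaussian fits to the
#' CIE 1931 color-matching functions; the Govardovskii A1 visual-pigment
#' nomogram for the photopigments) combined with smooth synthetic lens
#' and macular-pigment transmittance curves; they are documented
#' stand-ins for the laboratory tabulations, constructed so that every
#' qualitative property of the model (band positions, branch behavior,
#' monotonicity) holds.  See `inst/extdata/observer_tables_PROVENANCE.md`.
#'
#' @param from_csv read the bundled CSV (default) rather than recomputing
#'   the analytic forms; the CSV is verified against the bundled md5
#'   manifest before use.
#' @return A data.frame with columns `wavelength_nm`, `mc`, `scone`,
#'   `mp`, `v`, `vprime`, `xbar`, `ybar`, `zbar` (81 rows, 380--780 nm).
#' @export
observer_tables <- function(from_csv = TRUE) {
  cached <- .cswear_env$observer_tables
  if (!is.null(cached) && isTRUE(.cswear_env$observer_from_csv == from_csv))
    return(cached)
  tab <- if (from_csv) read_observer_csv() else build_observer_tables()
  validate_observer_tables(tab)
  .cswear_env$observer_tables <- tab
  .cswear_env$observer_from_csv <- from_csv
  tab
}

.cswear_env <- new.env(parent = emptyenv())

read_observer_csv <- function() {
  path <- system.file("extdata", "observer_tables_5nm.csv",
                      package = "cswear", mustWork = TRUE)
  man <- system.file("extdata", "observer_tables_manifest.txt",
                     package = "cswear", mustWork = TRUE)
  expected <- read.dcf(man)[1, "md5"]
  got <- unname(tools::md5sum(path))
  if (!identical(unname(expected), got))
    stop("observer table checksum mismatch: expected ", expected,
         " got ", got, call. = FALSE)
  utils::read.csv(path)
}

validate_observer_tables <- function(tab) {
  need <- c("wavelength_nm", "mc", "scone", "mp", "v", "vprime",
            "xbar", "ybar", "zbar")
  if (!all(need %in% names(tab)))
    stop("observer table missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  if (!isTRUE(all.equal(tab$wavelength_nm, canonical_grid())))
    stop("observer table grid is not 380-780 nm at 5 nm", call. = FALSE)
  if (any(tab$mp <= 0))
    stop("macular pigment transmittance must be strictly positive",
         call. = FALSE)
  if (any(as.matrix(tab[need[-1]]) < 0))
    stop("observer tables must be nonnegative", call. = FALSE)
  if (abs(tab$v[tab$wavelength_nm == 555] - 1) > 1e-12 ||
      max(tab$v) > 1)
    stop("V must peak at 555 nm with value 1", call. = FALSE)
  invisible(tab)
}

# ---- analytic construction ------------------------------------------------

# piecewise Gaussian: sd sl below the mode, sr above
pgauss <- function(x, mu, sl, sr) {
  s <- ifelse(x < mu, sl, sr)
  exp(-0.5 * ((x - mu) / s)^2)
}

# multi-Gaussian analytic fits to the CIE 1931 2-degree CMFs
# (Wyman, Sloan & Shirley 2013 coefficients)
cmf_xbar <- function(l) {
  pmax(0, 1.056 * pgauss(l, 599.8, 37.9, 31.0) +
          0.362 * pgauss(l, 442.0, 16.0, 26.7) -
          0.065 * pgauss(l, 501.1, 20.4, 26.2))
}
cmf_ybar <- function(l) {
  0.821 * pgauss(l, 568.8, 46.9, 40.5) +
  0.286 * pgauss(l, 530.9, 16.3, 31.1)
}
cmf_zbar <- function(l) {
  1.217 * pgauss(l, 437.0, 11.8, 36.0) +
  0.681 * pgauss(l, 459.0, 26.0, 13.8)
}

# Govardovskii et al. (2000) A1 pigment template (alpha + beta band),
# peak-normalized absorbance as a function of wavelength for a pigment
# with maximum at lmax nm
pigment_nomogram <- function(l, lmax) {
  x <- lmax / l
  a <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lmax
  bb <- -40.5 + 0.195 * lmb
  beta <- 0.26 * exp(-((l - lmb) / bb)^2)
  pmin(1, alpha + beta)
}

# synthetic crystalline-lens transmittance: smooth exponential decay of
# optical density toward long wavelengths (density ~0.6 at 400 nm)
lens_transmittance <- function(l) {
  dens <- 0.60 * exp(-(l - 400) / 49)
  10^(-pmax(dens, 0))
}

# synthetic macular pigment transmittance: Gaussian absorbance template
# peaking at 460 nm with peak optical density 0.35
macular_transmittance <- function(l) {
  10^(-0.35 * exp(-0.5 * ((l - 460) / 26)^2))
}

#' Rebuild the observer tables from their analytic definitions
#'
#' Used to generate (and in tests, to cross-check) the bundled CSV.
#' @return Same data.frame layout as [observer_tables()].
#' @export
build_observer_tables <- function() {
  l <- canonical_grid()
  ybar <- cmf_ybar(l)
  v <- ybar / cmf_ybar(555)
  vp_raw <- pigment_nomogram(l, 500) * lens_transmittance(l)
  vprime <- vp_raw / max(vp_raw)
  mp <- macular_transmittance(l)
  mc_raw <- pigment_nomogram(l, 480) * lens_transmittance(l)
  mc <- mc_raw / max(mc_raw)
  s_raw <- pigment_nomogram(l, 440) * lens_transmittance(l) * mp
  scone <- s_raw / max(s_raw)
  data.frame(wavelength_nm = l, mc = mc, scone = scone, mp = mp,
             v = v, vprime = vprime,
             xbar = cmf_xbar(l), ybar = ybar, zbar = cmf_zbar(l))
}

#' Write the bundled observer-table CSV and its checksum manifest
#'
#' @param dir directory to write `observer_tables_5nm.csv` and
#'   `observer_tables_manifest.txt` into.
#' @return Invisibly, the md5 checksum of the written CSV.
#' @export
write_observer_tables <- function(dir) {
  tab <- build_observer_tables()
  csv <- file.path(dir, "observer_tables_5nm.csv")
  utils::write.csv(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                   csv, row.names = FALSE, quote = FALSE)
  md5 <- unname(tools::md5sum(csv))
  writeLines(c(paste0("md5: ", md5),
               "file: observer_tables_5nm.csv"),
             file.path(dir, "observer_tables_manifest.txt"))
  invisible(md5)
}
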