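#' Chromaticity coordinates of an SPD
#'
#' CIE 1931 (x, y) and CIE 1960 (u, v) chromaticity from the bundled
#' color-matching functions on the canonical grid.
#'
#' @param x an [spd()].
#' @param tables observer tables.
#' @return A list with `X`, `Y`, `Z`, `x`, `y`, `u`, `v`.
#' @export
chromaticity <- function(x, tables = observer_tables()) {
  x <- spd_on_canonical_grid(x)
  e <- x$irradiance
  X <- sum(tables$xbar * e) * x$step
  Y <- sum(tables$ybar * e) * x$step
  Z <- sum(tables$zbar * e) * x$step
  s <- X + Y + Z
  if (s <= 0)
    stop(structure(class = c("cswear_undefined_chromaticity", "error",
                             "condition"),
                   list(message = "zero visible energy: chromaticity undefined",
                        call = sys.call(-1))))
  d <- X + 15 * Y + 3 * Z
  list(X = X, Y = Y, Z = Z, x = X / s, y = Y / s,
       u = 4 * X / d, v = 6 * Y / d)
}

# Planck spectral radiance shape (arbitrary scale) at wavelength nm,
# temperature K: lambda^-5 / (exp(c2/(lambda T)) - 1), c2 = 1.4388e7 nm K
planck_shape <- function(lambda_nm, T) {
  c2 <- 1.4388e7
  lambda_nm^-5 / expm1(c2 / (lambda_nm * T))
}

# uv coordinates of the Planckian radiator at temperature T (vectorized)
planck_uv <- function(T, tables = observer_tables()) {
  l <- tables$wavelength_nm
  out <- vapply(T, function(tt) {
    e <- planck_shape(l, tt)
    X <- sum(tables$xbar * e); Y <- sum(tables$ybar * e)
    Z <- sum(tables$zbar * e)
    d <- X + 15 * Y + 3 * Z
    c(4 * X / d, 6 * Y / d)
  }, numeric(2))
  list(u = out[1, ], v = out[2, ])
}

planck_locus <- function(tables = observer_tables()) {
  key <- "planck_locus"
  if (!is.null(.cswear_env[[key]])) return(.cswear_env[[key]])
  T <- seq(1000, 20000, by = 10)
  uv <- planck_uv(T, tables)
  .cswear_env[[key]] <- list(T = T, u = uv$u, v = uv$v)
  .cswear_env[[key]]
}

#' Correlated color temperature of an SPD
#'
#' Nearest point on the Planckian locus in the CIE 1960 uv plane,
#' searched over 1000--20000 K (10 K table, then 1 K local refinement).
#' Preferred over polynomial CCT approximations because the scenes of
#' interest span 1500--10500 K, where those approximations degrade.
#'
#' @param x an [spd()] with nonzero visible energy.
#' @param tables observer tables.
#' @return CCT in kelvin.  If the chromaticity lies further than
#'   Duv = 0.05 from the locus, the result carries
#'   `attr(, "flag") = "out_of_gamut"`; the Duv distance is always
#'   attached as `attr(, "duv")`.  Zero visible energy raises a
#'   condition of class `cswear_undefined_chromaticity`.
#' @export
cct_of_spd <- function(x, tables = observer_tables()) {
  ch <- chromaticity(x, tables)
  locus <- planck_locus(tables)
  d2 <- (locus$u - ch$u)^2 + (locus$v - ch$v)^2
  i <- which.min(d2)
  T0 <- locus$T[i]
  # 1 K refinement around the coarse minimum
  Tfine <- seq(max(1000, T0 - 10), min(20000, T0 + 10), by = 1)
  uv <- planck_uv(Tfine, tables)
  d2f <- (uv$u - ch$u)^2 + (uv$v - ch$v)^2
  j <- which.min(d2f)
  cct <- Tfine[j]
  duv <- sqrt(d2f[j])
  flag <- if (duv > 0.05) "out_of_gamut" else "ok"
  structure(cct, duv = duv,
            flag = if (flag == "ok") NULL else flag)
}
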