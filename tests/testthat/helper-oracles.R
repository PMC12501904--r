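# Independent oracle implementations used to cross-check the package's
# production code paths.  These are deliberately written as plain loops
# over the printed formulas, sharing nothing with the implementations
# they verify.

# straight-loop evaluation of the circadian-light model
oracle_cla <- function(x, tab = observer_tables(),
                       p = circadian_params()) {
  stopifnot(abs(x$step - 5) < 1e-9)
  idx <- match(tab$wavelength_nm, round(x$wavelength))
  e <- ifelse(is.na(idx), 0, x$irradiance[idx])
  dl <- 5
  mc <- 0; s_mp <- 0; v_mp <- 0; rod <- 0
  for (i in seq_along(e)) {
    mc <- mc + tab$mc[i] * e[i] * dl
    s_mp <- s_mp + tab$scone[i] / tab$mp[i] * e[i] * dl
    v_mp <- v_mp + tab$v[i] / tab$mp[i] * e[i] * dl
    rod <- rod + tab$vprime[i] * e[i] * dl
  }
  by <- s_mp - p$k * v_mp
  raw <- if (by > 0) {
    p$cla_scale * (mc + p$a_by * by -
                     p$a_rod * (1 - exp(-rod / p$rod_sat)))
  } else {
    p$cla_scale * mc
  }
  list(cla = max(0, raw), by = by)
}

# brute-force 1 nm -> 5 nm binning: for each multiple-of-5 center,
# average the (zero-padded) five samples c-2 .. c+2
oracle_bin_5nm <- function(w, v) {
  centers <- seq(5 * ceiling((min(w) - 2) / 5),
                 5 * floor((max(w) + 2) / 5), by = 5)
  out <- numeric(length(centers))
  for (i in seq_along(centers)) {
    acc <- 0
    for (d in -2:2) {
      k <- which(w == centers[i] + d)
      if (length(k) == 1) acc <- acc + v[k]
    }
    out[i] <- acc / 5
  }
  list(wavelength = centers, value = out)
}

# trapezoid-rule photopic illuminance
oracle_lux_trapz <- function(x, tab = observer_tables()) {
  idx <- match(tab$wavelength_nm, round(x$wavelength))
  e <- ifelse(is.na(idx), 0, x$irradiance[idx])
  f <- tab$v * e
  683 * sum((f[-1] + f[-length(f)]) / 2 * diff(tab$wavelength_nm))
}

# dense brute-force Planckian locus scan for CCT (1 K steps)
oracle_cct_scan <- function(x, tab = observer_tables()) {
  idx <- match(tab$wavelength_nm, round(x$wavelength))
  e <- ifelse(is.na(idx), 0, x$irradiance[idx])
  X <- sum(tab$xbar * e); Y <- sum(tab$ybar * e); Z <- sum(tab$zbar * e)
  d <- X + 15 * Y + 3 * Z
  u0 <- 4 * X / d; v0 <- 6 * Y / d
  Ts <- seq(1000, 20000, by = 1)
  best <- Inf; bestT <- NA
  c2 <- 1.4388e7
  l <- tab$wavelength_nm
  for (T in Ts) {
    b <- l^-5 / (exp(c2 / (l * T)) - 1)
    Xb <- sum(tab$xbar * b); Yb <- sum(tab$ybar * b)
    Zb <- sum(tab$zbar * b)
    db <- Xb + 15 * Yb + 3 * Zb
    dd <- (4 * Xb / db - u0)^2 + (6 * Yb / db - v0)^2
    if (dd < best) { best <- dd; bestT <- T }
  }
  bestT
}

# O(n^2) sliding-window nonwear oracle: union of all windows that are
# motion-free, lux-flat, and longer than the applicable threshold
oracle_nonwear <- function(series, day_threshold_h = 2,
                           night_threshold_h = 4, lux_tol = 1,
                           day_window = c(6, 18)) {
  n <- nrow(series)
  lux <- if ("lux_cal" %in% names(series)) series$lux_cal else
    series$lux_raw
  tsec <- as.numeric(series$timestamp)
  hours <- as.numeric(format(series$timestamp, "%H")) +
    as.numeric(format(series$timestamp, "%M")) / 60
  is_day <- hours >= day_window[1] & hours < day_window[2]
  flagged <- logical(n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (any(series$motion[i:j])) break
      if (diff(range(lux[i:j])) >= lux_tol) break
      thr <- if (any(is_day[i:j])) day_threshold_h else
        night_threshold_h
      if ((tsec[j] - tsec[i]) / 3600 > thr) flagged[i:j] <- TRUE
    }
  }
  flagged
}
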