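#' Annotate a sensor log with calibrated values, CS and flags
#'
#' Applies the fitted lux and CCT calibrations and the CS prediction
#' model to every record, labels records as day or night by the local
#' clock window, and marks nonwear intervals via [detect_nonwear()].
#'
#' @param log sensor-log data.frame (`timestamp`, `lux_raw`,
#'   `cct_raw`, `r_wm2`, `g_wm2`, `b_wm2`, `ir_wm2`, `motion`).
#' @param lux_model,cct_model fitted `light_calibration` objects.
#' @param cs_model fitted `cs_model`.
#' @param person_id identifier carried into the result.
#' @param day_window `c(start_hour, end_hour)` local clock hours
#'   (default 06:00--18:00).
#' @param ... passed to [detect_nonwear()].
#' @return An `exposure_series` data.frame: the input plus `lux_cal`,
#'   `cct_cal`, `cs`, `day_flag`, `wear_flag`, with attribute
#'   `person_id`.
#' @export
annotate <- function(log, lux_model, cct_model, cs_model,
                     person_id = "p1", day_window = c(6, 18), ...) {
  need <- c("timestamp", "lux_raw", "cct_raw", "r_wm2", "g_wm2",
            "b_wm2", "ir_wm2", "motion")
  missing <- setdiff(need, names(log))
  if (length(missing) > 0)
    stop("sensor log lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- log
  if (nrow(log) > 0) {
    if (is.unsorted(as.numeric(log$timestamp), strictly = TRUE))
      stop("timestamps must be strictly increasing", call. = FALSE)
    out$lux_cal <- predict(lux_model, log)
    out$cct_cal <- predict(cct_model, log)
    out$cs <- predict(cs_model, log)
    hours <- as.numeric(format(log$timestamp, "%H")) +
      as.numeric(format(log$timestamp, "%M")) / 60
    out$day_flag <- hours >= day_window[1] & hours < day_window[2]
    nw <- detect_nonwear(out, day_window = day_window, ...)
    out$wear_flag <- !nw$flagged
  } else {
    out$lux_cal <- out$cct_cal <- out$cs <- numeric(0)
    out$day_flag <- out$wear_flag <- logical(0)
  }
  attr(out, "person_id") <- person_id
  class(out) <- c("exposure_series", class(out))
  out
}

#' Detect nonwear / malfunction intervals
#'
#' A stretch of readings is flagged when both the light signal is flat
#' (rolling range of lux below `lux_tol`) and no motion events occur,
#' for longer than the applicable duration threshold: 2 hours when the
#' stretch touches daytime, 4 hours when it lies entirely at night.
#' The flagged set is the union of all qualifying windows, reported as
#' maximal non-overlapping intervals.
#'
#' @param series data.frame with `timestamp`, `motion` and a lux
#'   column (`lux_cal` if present, else `lux_raw`); cadence must be
#'   30 minutes or finer.
#' @param day_threshold_h,night_threshold_h duration thresholds in
#'   hours (defaults 2 and 4).
#' @param lux_tol flatness tolerance in lux (default 1).
#' @param day_window local clock day window.
#' @return A list: `flagged` (logical per record) and `intervals`
#'   (data.frame `start`, `end`, row indices `from`, `to`).
#' @export
detect_nonwear <- function(series, day_threshold_h = 2,
                           night_threshold_h = 4, lux_tol = 1,
                           day_window = c(6, 18)) {
  n <- nrow(series)
  lux <- if ("lux_cal" %in% names(series)) series$lux_cal else
    series$lux_raw
  empty <- list(flagged = logical(n),
                intervals = data.frame(start = series$timestamp[0],
                                       end = series$timestamp[0],
                                       from = integer(0),
                                       to = integer(0)))
  if (n < 2) return(empty)
  tsec <- as.numeric(series$timestamp)
  if (max(diff(tsec)) > 30 * 60 + 1)
    stop("nonwear detection needs a cadence of 30 min or finer",
         call. = FALSE)
  hours <- as.numeric(format(series$timestamp, "%H")) +
    as.numeric(format(series$timestamp, "%M")) / 60
  is_day <- hours >= day_window[1] & hours < day_window[2]
  flagged <- logical(n)
  j <- 1L
  for (i in seq_len(n)) {
    if (j < i) j <- i
    # extend the window from i as far as flatness and stillness allow
    while (j < n && !series$motion[j + 1] &&
           !series$motion[i] &&
           diff(range(lux[i:(j + 1)])) < lux_tol) {
      j <- j + 1L
    }
    if (series$motion[i]) next
    dur_h <- (tsec[j] - tsec[i]) / 3600
    thr <- if (any(is_day[i:j])) day_threshold_h else night_threshold_h
    if (dur_h > thr) flagged[i:j] <- TRUE
  }
  if (!any(flagged)) return(empty)
  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  list(flagged = flagged,
       intervals = data.frame(start = series$timestamp[starts[keep]],
                              end = series$timestamp[ends[keep]],
                              from = starts[keep], to = ends[keep]))
}

#' Mask unreliable CCT values in dim light
#'
#' Spectral color-temperature estimates are unreliable at low light;
#' CCT is therefore set to missing for all nighttime records and for
#' any record whose calibrated illuminance falls below `lux_floor`.
#' Illuminance and CS are untouched.
#'
#' @param series an annotated `exposure_series`.
#' @param lux_floor reliability floor in lux (default 10).
#' @return The series with `cct_cal` masked to `NA` where unreliable.
#' @export
mask_dim_cct <- function(series, lux_floor = 10) {
  stopifnot(all(c("cct_cal", "lux_cal", "day_flag") %in% names(series)))
  mask <- !series$day_flag | series$lux_cal < lux_floor
  series$cct_cal[mask] <- NA_real_
  series
}

#' Weekly day/night exposure summary
#'
#' Sample mean and unbiased variance of illuminance, CCT and CS per
#' week (7-day blocks aligned to the series start) and period (day /
#' night), over wear-time records only.  Weeks with no wear-time
#' records in a period yield an `n = 0` row with missing statistics.
#'
#' @param series an annotated `exposure_series` (optionally after
#'   [mask_dim_cct()]; masked CCT values are dropped from the CCT
#'   cells).
#' @return data.frame: `week`, `period`, `metric`, `mean`, `variance`,
#'   `n`.
#' @export
weekly_summary <- function(series) {
  stopifnot(all(c("timestamp", "lux_cal", "cct_cal", "cs", "day_flag",
                  "wear_flag") %in% names(series)))
  if (nrow(series) == 0) stop("empty series", call. = FALSE)
  t0 <- as.numeric(series$timestamp[1])
  week <- floor((as.numeric(series$timestamp) - t0) / (7 * 86400)) + 1
  metrics <- c(lux = "lux_cal", cct = "cct_cal", cs = "cs")
  rows <- list()
  for (w in sort(unique(week))) {
    for (period in c("day", "night")) {
      sel <- week == w & series$wear_flag &
        (series$day_flag == (period == "day"))
      for (m in names(metrics)) {
        v <- series[[metrics[[m]]]][sel]
        v <- v[!is.na(v)]
        rows[[length(rows) + 1L]] <- data.frame(
          week = w, period = period, metric = m,
          mean = if (length(v) > 0) mean(v) else NA_real_,
          variance = if (length(v) > 1) stats::var(v) else NA_real_,
          n = length(v))
      }
    }
  }
  do.call(rbind, rows)
}

#' Paired t test on weekly summaries
#'
#' Two-tailed paired t test on per-week values:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `df = n - 1`, where
#' `d = a - b`.
#'
#' @param values_a,values_b equal-length (n >= 2) numeric vectors
#'   paired by week.
#' @return A list: `t`, `df`, `p_two_tailed`, `mean_diff`.
#' @export
paired_t <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b),
            length(values_a) >= 2)
  d <- values_a - values_b
  if (anyNA(d)) stop("missing values in paired differences",
                     call. = FALSE)
  if (all(d == 0))
    return(list(t = 0, df = length(d) - 1, p_two_tailed = 1,
                mean_diff = 0))
  s <- stats::sd(d)
  if (s == 0)
    stop("zero variance in paired differences: t undefined",
         call. = FALSE)
  n <- length(d)
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1,
       p_two_tailed = 2 * stats::pt(-abs(t), n - 1),
       mean_diff = mean(d))
}

#' Post hoc power of a t test
#'
#' Power computed from the noncentral t distribution with
#' noncentrality `d * sqrt(n)` and `df = n - 1` (the one-sample /
#' paired t family).  With `tails = 1` the power at `d -> 0`
#' approaches `alpha`.
#'
#' @param n sample size (>= 2).
#' @param d Cohen's d effect size (> 0).
#' @param alpha significance level in (0, 1).
#' @param tails 1 or 2.
#' @return Power in `[0, 1]`.
#' @export
post_hoc_power <- function(n, d, alpha = 0.05, tails = 1) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  stopifnot(n >= 2, d > 0, tails %in% c(1, 2))
  df <- n - 1
  ncp <- d * sqrt(n)
  if (tails == 1) {
    crit <- stats::qt(1 - alpha, df)
    1 - stats::pt(crit, df, ncp)
  } else {
    crit <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(crit, df, ncp) + stats::pt(-crit, df, ncp)
  }
}
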