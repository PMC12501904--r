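fitted_models <- function() {
  fixture("fitted_models", function() {
    pt <- lab_paired_noiseless()
    tt <- lab_training_table()
    list(lux = suppressWarnings(fit_calibration(pt, "photopic_lux",
                                                seed = 2)),
         cct = suppressWarnings(fit_calibration(pt, "cct", seed = 2)),
         cs = fit_cs_model(tt, "random_forest", seed = 2,
                           n_trees = 100))
  })
}

test_that("annotation preserves records and applies the fitted models per row", {
  m <- fitted_models()
  log <- scripted_log(100, seed = 12)
  series <- annotate(log, m$lux, m$cct, m$cs)
  expect_equal(nrow(series), nrow(log))
  expect_true(all(c("lux_cal", "cct_cal", "cs", "day_flag",
                    "wear_flag") %in% names(series)))
  i <- 37
  expect_equal(series$lux_cal[i], predict(m$lux, log[i, ]))
  expect_equal(series$cs[i], predict(m$cs, log[i, ]))
  empty <- log[0, ]
  s0 <- annotate(empty, m$lux, m$cct, m$cs)
  expect_equal(nrow(s0), 0)
  shuffled <- log[c(2, 1, 3:100), ]
  expect_error(annotate(shuffled, m$lux, m$cct, m$cs),
               "strictly increasing")
  expect_error(annotate(log["lux_raw"], m$lux, m$cct, m$cs),
               "lacks columns")
})

test_that("nonwear flags scripted flat episodes with day/night thresholds", {
  start <- as.POSIXct("2024-10-01 00:00:00", tz = "UTC")
  ts <- start + seq(0, by = 600, length.out = 144)   # one day, 10 min
  lux <- rep(200, 144) + seq_len(144) %% 7   # varying baseline
  motion <- rep(TRUE, 144)
  # 3 h flat daytime block (10:00-13:00)
  day_idx <- 61:79
  lux[day_idx] <- 150
  motion[day_idx] <- FALSE
  # 3 h flat night block (00:00-03:00): below the 4 h night threshold
  night_idx <- 1:19
  lux[night_idx] <- 3
  motion[night_idx] <- FALSE
  series <- data.frame(timestamp = ts, lux_raw = lux, motion = motion)
  out <- detect_nonwear(series)
  expect_true(all(out$flagged[day_idx]))
  expect_false(any(out$flagged[night_idx]))
  expect_equal(nrow(out$intervals), 1)
  expect_equal(out$intervals$from, 61)
  expect_equal(out$intervals$to, 79)
})

test_that("nonwear detection equals the quadratic sliding-window oracle", {
  for (seed in 1:20) {
    log <- scripted_log(140, seed = 100 + seed)
    got <- detect_nonwear(log)$flagged
    want <- oracle_nonwear(log)
    expect_equal(got, want, label = paste("seed", seed))
  }
})

test_that("dim-light CCT masking hits exactly the unreliable rows", {
  m <- fitted_models()
  log <- scripted_log(200, seed = 55)
  series <- annotate(log, m$lux, m$cct, m$cs)
  masked <- mask_dim_cct(series, lux_floor = 10)
  want_mask <- !series$day_flag | series$lux_cal < 10
  expect_equal(is.na(masked$cct_cal), want_mask)
  expect_equal(masked$lux_cal, series$lux_cal)
  expect_equal(masked$cs, series$cs)
  bright_day <- series
  bright_day$day_flag <- TRUE
  bright_day$lux_cal <- pmax(bright_day$lux_cal, 20)
  expect_equal(mask_dim_cct(bright_day, 10)$cct_cal,
               bright_day$cct_cal)
  all_night <- series
  all_night$day_flag <- FALSE
  expect_true(all(is.na(mask_dim_cct(all_night, 10)$cct_cal)))
})

test_that("weekly summaries aggregate day/night cells with exact statistics", {
  start <- as.POSIXct("2024-10-07 00:00:00", tz = "UTC")
  n <- 5 * 7 * 24   # five weeks, hourly
  ts <- start + seq(0, by = 3600, length.out = n)
  hours <- as.numeric(format(ts, "%H"))
  day <- hours >= 6 & hours < 18
  set.seed(9)
  series <- data.frame(timestamp = ts,
                       lux_cal = ifelse(day, 400, 40) + rnorm(n),
                       cct_cal = ifelse(day, 4500, 2500) + rnorm(n),
                       cs = ifelse(day, 0.4, 0.1),
                       day_flag = day, wear_flag = TRUE)
  out <- weekly_summary(series)
  expect_equal(sort(unique(out$week)), 1:5)
  expect_equal(nrow(out), 5 * 2 * 3)
  day_cs <- out[out$period == "day" & out$metric == "cs", ]
  expect_equal(day_cs$mean, rep(0.4, 5))
  expect_equal(day_cs$variance, rep(0, 5))
  # hand-computable 4-record week
  ts4 <- as.POSIXct("2024-10-01 07:00:00", tz = "UTC") +
    3600 * (0:3)
  s4 <- data.frame(timestamp = ts4, lux_cal = c(100, 200, 300, 400),
                   cct_cal = c(3000, 3100, 3200, 3300),
                   cs = c(0.1, 0.2, 0.3, 0.4),
                   day_flag = TRUE, wear_flag = TRUE)
  out4 <- weekly_summary(s4)
  lux_cell <- out4[out4$period == "day" & out4$metric == "lux", ]
  expect_equal(lux_cell$mean, 250)
  expect_equal(lux_cell$variance, sum((c(100, 200, 300, 400) - 250)^2) / 3)
  expect_equal(lux_cell$n, 4)
  night_cell <- out4[out4$period == "night" & out4$metric == "lux", ]
  expect_equal(night_cell$n, 0)
  expect_true(is.na(night_cell$mean))
})

test_that("excluding a flagged interval shifts summaries by exactly its records", {
  start <- as.POSIXct("2024-10-07 00:00:00", tz = "UTC")
  ts <- start + seq(0, by = 3600, length.out = 7 * 24)
  hours <- as.numeric(format(ts, "%H"))
  day <- hours >= 6 & hours < 18
  series <- data.frame(timestamp = ts, lux_cal = ifelse(day, 300, 30),
                       cct_cal = 4000, cs = 0.2, day_flag = day,
                       wear_flag = TRUE)
  series$lux_cal[10:13] <- 9999   # night hours 09:00? indices 10-13 are 09:00-12:00
  flagged <- series
  flagged$wear_flag[10:13] <- FALSE
  manual <- series[-(10:13), ]
  a <- weekly_summary(flagged)
  b <- weekly_summary(manual)
  expect_equal(a$mean, b$mean)
  expect_equal(a$n, b$n)
})

test_that("the paired t statistic matches hand arithmetic and base R", {
  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_two_tailed, 1)
  expect_error(paired_t(1:5, 0:4), "zero variance")
  a <- c(5, 6, 7, 8, 9); b <- c(4, 6, 6, 9, 7)
  got <- paired_t(a, b)
  expect_equal(got$t, 1.1767, tolerance = 1e-4)
  expect_equal(got$df, 4)
  expect_equal(got$p_two_tailed, 0.3046, tolerance = 1e-3)
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_two_tailed, ref$p.value, tolerance = 1e-12)
  swapped <- paired_t(b, a)
  expect_equal(swapped$t, -got$t)
  expect_equal(swapped$p_two_tailed, got$p_two_tailed)
})

test_that("post hoc power follows the noncentral t distribution", {
  expect_equal(post_hoc_power(29, 0.53, 0.05, tails = 1), 0.87,
               tolerance = 0.01 / 0.87)
  expect_equal(post_hoc_power(29, 1e-9, 0.05, tails = 1), 0.05,
               tolerance = 1e-6)
  expect_gt(post_hoc_power(29, 5, 0.05, tails = 1), 0.999)
  # agrees with the one-sample power function in base R
  ref <- stats::power.t.test(n = 29, delta = 0.53, sd = 1,
                             sig.level = 0.05, type = "one.sample",
                             alternative = "one.sided")$power
  expect_equal(post_hoc_power(29, 0.53, 0.05, tails = 1), ref,
               tolerance = 1e-6)
  ns <- c(5, 10, 20, 40, 80)
  pw_n <- vapply(ns, function(n) post_hoc_power(n, 0.4), numeric(1))
  expect_true(all(diff(pw_n) > 0))
  ds <- c(0.1, 0.3, 0.5, 0.8, 1.2)
  pw_d <- vapply(ds, function(d) post_hoc_power(25, d), numeric(1))
  expect_true(all(diff(pw_d) > 0))
  expect_error(post_hoc_power(29, 0.5, alpha = 1.2), "alpha")
})
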