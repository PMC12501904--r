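test_that("evaluation metrics follow the printed formulas", {
  m <- compute_metrics(c(1, 2, 3), c(1, 2, 3), 1)
  expect_equal(m$mae, 0); expect_equal(m$mse, 0); expect_equal(m$r2, 1)
  m2 <- compute_metrics(c(1, 2, 3, 4), rep(2.5, 4), 1)
  expect_equal(m2$r2, 0)
  m3 <- compute_metrics(c(1, 2, 3), c(1, 2, 4), 1)
  expect_equal(m3$mae, 1 / 3)
  expect_equal(m3$mse, 1 / 3)
  expect_equal(m3$r2, 0.5)
  expect_equal(m3$rmse, sqrt(1 / 3))
  expect_lte(m3$adjusted_r2, m3$r2)
  expect_error(compute_metrics(c(2, 2, 2), c(1, 2, 3)), "undefined")
})

test_that("screening removes exactly the physically invalid rows", {
  tab <- data.frame(lux_ref = c(5, 5, 5), lux_raw = c(1, 1, 1),
                    cct_raw = c(2000, 2000, 2000))
  out <- screen_data(tab)
  expect_equal(nrow(out$data), 3)
  expect_true(all(out$report == 0))
  tab10 <- data.frame(lux_ref = rep(10, 10),
                      lux_raw = c(-1, 1:8, -3),
                      cct_raw = rep(2000, 10))
  out10 <- screen_data(tab10)
  expect_equal(nrow(out10$data), 8)
  expect_equal(unname(out10$report[["lux_raw"]]), 2)
  # mixed invalids across columns, checked against a full row scan
  set.seed(14)
  big <- data.frame(lux_ref = rnorm(200, 100, 80),
                    cct_raw = rnorm(200, 3000, 2500),
                    ir_wm2 = rnorm(200, 0.1, 0.3),
                    lux_raw = rnorm(200, 100, 120))
  out_big <- screen_data(big)
  cols <- c("lux_ref", "cct_raw", "ir_wm2", "lux_raw")
  keep <- apply(big[cols], 1, function(r) all(r >= 0))
  expect_equal(nrow(out_big$data), sum(keep))
  for (cc in cols)
    expect_equal(unname(out_big$report[[cc]]), sum(big[[cc]] < 0))
  expect_error(screen_data(data.frame(lux_raw = c(-1, -2))),
               "no rows left")
})

test_that("significance screening finds the generating feature set", {
  set.seed(6)
  n <- 200
  tab <- data.frame(cct_raw = runif(n, 1800, 9000),
                    ir_wm2 = runif(n), lux_raw = runif(n, 10, 1000),
                    r_wm2 = runif(n), g_wm2 = runif(n),
                    b_wm2 = runif(n))
  tab$lux_ref <- 2 * tab$lux_raw + rnorm(n, 0, 1)
  sel <- select_features(tab, "lux_ref", alpha = 0.01)
  expect_equal(sel, "lux_raw")
  sel_all <- select_features(tab, "lux_ref", alpha = 1)
  expect_setequal(sel_all, cswear:::calibration_candidates())
  # a perfect duplicate is dropped in favor of the earlier candidate
  tab$dup <- tab$lux_raw
  sel_dup <- select_features(tab, "lux_ref", alpha = 0.01,
                             candidates = c("lux_raw", "dup"))
  expect_equal(sel_dup, "lux_raw")
})

test_that("the no-intercept calibration recovers a noiseless generating model", {
  pt <- lab_paired_noiseless()
  spec <- distortion_spec()
  m <- suppressWarnings(fit_calibration(pt, "photopic_lux", seed = 2))
  co <- coef(m)
  expect_equal(unname(co[c("cct_raw", "ir_wm2", "lux_raw")]),
               unname(spec$lux_coef), tolerance = 1e-8)
  m2 <- suppressWarnings(fit_calibration(pt, "cct", seed = 2))
  expect_equal(unname(coef(m2)[c("cct_raw", "ir_wm2", "lux_raw")]),
               unname(spec$cct_coef), tolerance = 1e-8)
  # degenerate split: all data in training, no test metrics
  m3 <- suppressWarnings(fit_calibration(pt, "photopic_lux",
                                         train_frac = 1, seed = 2))
  expect_null(m3$metrics$test)
  expect_equal(m3$metrics$train$r2, m3$metrics$overall$r2,
               tolerance = 1e-12)
  expect_error(fit_calibration(pt[1:6, ], "photopic_lux"),
               "at least 10 rows")
})

test_that("train/test partitioning is a pure function of the seed", {
  pt <- lab_paired_noiseless()
  spec5 <- distortion_spec(noise_cv = c(lux = 0.05, cct = 0.05,
                                        channel = 0.05))
  pt_n <- paired_table(lab_records(), spec5, seed = 9)
  a <- fit_calibration(pt_n, "photopic_lux", seed = 33)
  b <- fit_calibration(pt_n, "photopic_lux", seed = 33)
  expect_identical(coef(a), coef(b))
  expect_identical(a$metrics$test$mae, b$metrics$test$mae)
})

test_that("applying a calibration is the stated dot product", {
  published <- structure(
    list(target = "photopic_lux", response = "lux_ref",
         features = c("cct_raw", "ir_wm2", "lux_raw"),
         coefficients = c(cct_raw = 0.0596, ir_wm2 = 1.6064,
                          lux_raw = 0.8432),
         intercept = FALSE),
    class = "light_calibration")
  reading <- data.frame(cct_raw = 1000, ir_wm2 = 10, lux_raw = 100)
  expect_equal(predict(published, reading), 159.984)
  zero <- data.frame(cct_raw = 0, ir_wm2 = 0, lux_raw = 0)
  expect_equal(predict(published, zero), 0)
  cct_pub <- structure(
    list(target = "cct", response = "cct_ref",
         features = c("cct_raw", "ir_wm2", "lux_raw"),
         coefficients = c(cct_raw = 1.048, ir_wm2 = -0.5427,
                          lux_raw = 0.1761),
         intercept = FALSE),
    class = "light_calibration")
  expect_equal(predict(cct_pub, data.frame(cct_raw = 4000, ir_wm2 = 0,
                                           lux_raw = 0)), 4192)
  expect_error(predict(published, data.frame(cct_raw = 1)),
               "lacks feature")
})

test_that("coefficients are recovered within 5% under 5% reference noise", {
  beta <- c(cct_raw = 0.0596, ir_wm2 = 500, lux_raw = 0.8432)
  for (sd in 1:20) {
    set.seed(sd)
    n <- 500
    d <- data.frame(cct_raw = runif(n, 1800, 10000),
                    ir_wm2 = runif(n, 0, 2),
                    lux_raw = 10^runif(n, 1, 3))
    y <- drop(as.matrix(d) %*% beta)
    d$lux_ref <- y * (1 + 0.05 * rnorm(n))
    d$cct_ref <- runif(n, 1800, 10000)
    m <- fit_calibration(d, "photopic_lux", seed = sd,
                         candidates = names(beta))
    expect_lt(max(abs(coef(m)[names(beta)] - beta) / beta), 0.05)
    expect_gt(m$metrics$test$r2, 0.95)
  }
})

test_that("a distortion-free calibration is the identity on illuminance", {
  recs <- lab_records()[seq(1, 500, by = 10)]
  ident <- distortion_spec_noiseless(
    lux_coef = c(cct_raw = 0, ir = 0, lux_raw = 1),
    cct_coef = c(cct_raw = 1, ir = 0, lux_raw = 0))
  pt <- paired_table(recs, ident, seed = 2)
  m <- suppressWarnings(fit_calibration(pt, "photopic_lux", seed = 5))
  pred <- predict(m, pt)
  expect_equal(pred, pt$lux_ref, tolerance = 1e-6)
})
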