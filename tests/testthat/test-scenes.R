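test_that("Planckian SPDs obey Planck's law", {
  p5000 <- planckian_spd(5000)
  # Wien displacement: spectral peak at 2.898e6 / T, nearest grid point
  expect_equal(p5000$wavelength[which.max(p5000$irradiance)],
               round((2.898e6 / 5000) / 5) * 5)
  expect_true(all(p5000$irradiance > 0))
  expect_equal(photopic_illuminance(p5000), 1)
  # ratio at two wavelengths against direct Planck arithmetic
  p6500 <- planckian_spd(6500)
  c2 <- 1.4388e7
  want <- (400^-5 / expm1(c2 / (400 * 6500))) /
    (700^-5 / expm1(c2 / (700 * 6500)))
  got <- p6500$irradiance[p6500$wavelength == 400] /
    p6500$irradiance[p6500$wavelength == 700]
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(planckian_spd(500), "1000")
})

test_that("electric sources match the Planckian visible band but lack near-IR", {
  e <- electric_spd(3000)
  p <- planckian_spd(3000)
  vis <- e$wavelength <= 780
  expect_equal(e$irradiance[vis] / p$irradiance[vis],
               rep(e$irradiance[10] / p$irradiance[10], sum(vis)),
               tolerance = 1e-9)
  expect_equal(as.numeric(cct_of_spd(e)), 3000, tolerance = 2 / 3000)
  ch_e <- channel_response(e)
  ch_p <- channel_response(p)
  expect_lt(ch_e[["ir"]], 0.05 * ch_p[["ir"]])
})

test_that("daylight reconstruction lands on the daylight locus", {
  d65 <- daylight_spd(6504)
  ch <- chromaticity(d65)
  expect_equal(ch$x, 0.3127, tolerance = 0.002 / 0.3127)
  expect_equal(ch$y, 0.3290, tolerance = 0.002 / 0.3290)
  expect_equal(as.numeric(cct_of_spd(daylight_spd(5000))), 5000,
               tolerance = 100 / 5000)
  for (cct in c(4000, 6500, 10000, 25000))
    expect_true(all(daylight_spd(cct)$irradiance >= 0))
  expect_error(daylight_spd(3500), "4000")
})

test_that("scene mixing is linear and respects its target illuminance", {
  single <- scenario(data.frame(cct = 3000, weight = 1),
                     target_lux = 250)
  s <- mix_scene(single)
  expect_equal(photopic_illuminance(s), 250)
  expect_equal(s$irradiance,
               spd_scale(electric_spd(3000), 250)$irradiance,
               tolerance = 1e-12)
  # illuminance adds across summed scenes
  a <- mix_scene(scenario(data.frame(cct = 4200, weight = 1),
                          target_lux = 100))
  b <- mix_scene(scenario(data.frame(cct = numeric(0),
                                     weight = numeric(0)),
                          daylight_fraction = 1, target_lux = 40))
  expect_equal(photopic_illuminance(spd_add(a, b)), 140,
               tolerance = 1e-9)
  # a warm/daylight mixture sits between its endpoint CCTs
  half <- mix_scene(scenario(data.frame(cct = 1500, weight = 1),
                             daylight_fraction = 0.5,
                             daylight_cct = 6500, target_lux = 500))
  cct_mix <- as.numeric(cct_of_spd(half))
  expect_gt(cct_mix, 1500)
  expect_lt(cct_mix, 6500)
  expect_error(mix_scene(scenario(data.frame(cct = numeric(0),
                                             weight = numeric(0)),
                                  daylight_fraction = 0)),
               "empty scene")
})

test_that("daylight attenuation is monotone in distance and slat closure", {
  base <- scenario(daylight_fraction = 1)
  dists <- vapply(c(0, 3, 6, 9), function(d)
    daylight_attenuation(scenario(daylight_fraction = 1,
                                  window_distance = d)),
    numeric(1))
  expect_true(all(diff(dists) < 0))
  blinds <- vapply(c("retracted", "45", "90", "135"), function(b)
    daylight_attenuation(scenario(daylight_fraction = 1,
                                  blind_angle = b)), numeric(1))
  expect_true(all(diff(blinds) < 0))
  expect_true(all(blinds >= 0 & blinds <= 1))
})

test_that("the laboratory protocol reproduces the stated campaign shape", {
  recs <- lab_records()
  expect_length(recs, 500)
  recs2 <- lab_protocol(100, 5, seed = 7)
  expect_equal(vapply(recs, function(r) r$scenario$target_lux,
                      numeric(1)),
               vapply(recs2, function(r) r$scenario$target_lux,
                      numeric(1)))
  tr <- fixture("lab_truth", function() scene_truth_table(recs))
  expect_true(all(is.finite(tr$lux) & is.finite(tr$cla) &
                    is.finite(tr$cs)))
  expect_lte(min(tr$lux), 10)
  expect_gte(max(tr$lux), 10000)
  expect_lte(min(tr$cct), 1500)
  expect_gte(max(tr$cct), 10500)
  # bimodal illuminance: two separated density peaks on the log scale
  h <- hist(log10(tr$lux), breaks = seq(0.9, 4.1, by = 0.2),
            plot = FALSE)
  peaks <- which(diff(sign(diff(h$counts))) == -2) + 1
  expect_gte(length(peaks), 2)
})

test_that("the field protocol covers its scenario grid deterministically", {
  recs <- field_protocol(40, 2, seed = 9)
  expect_length(recs, 80)
  recs2 <- field_protocol(40, 2, seed = 9)
  expect_equal(vapply(recs, function(r) r$scenario$view_angle,
                      numeric(1)),
               vapply(recs2, function(r) r$scenario$view_angle,
                      numeric(1)))
  blinds <- unique(vapply(recs, function(r) r$scenario$blind_angle,
                          character(1)))
  expect_setequal(blinds, c("retracted", "45", "90", "135"))
  ccts <- unlist(lapply(recs, function(r) r$scenario$sources$cct))
  expect_true(all(ccts %in% c(1800, 2700, 4000)))
})

test_that("windowless field scenes stay at or below the warmest source CCT", {
  set.seed(3)
  for (cct_mix in 1:5) {
    k <- sample(1:2, 1)
    sc <- scenario(data.frame(cct = sample(c(1800, 2700, 4000), k),
                              weight = runif(k, 0.2, 1)),
                   daylight_fraction = 0, target_lux = 200)
    expect_lte(as.numeric(cct_of_spd(mix_scene(sc))), 4050)
  }
})
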