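# Shared fixtures, built once per test run and cached; all synthetic,
# derived from package generators under fixed seeds.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]]))
    .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# standard laboratory campaign used across calibration / CS tests
lab_records <- function() {
  fixture("lab_records", function() lab_protocol(100, 5, seed = 7))
}

lab_paired_noiseless <- function() {
  fixture("lab_paired_noiseless", function()
    paired_table(lab_records(), distortion_spec_noiseless(), seed = 3))
}

lab_training_table <- function() {
  fixture("lab_training_table", function()
    build_training_table(lab_records(), distortion_spec(), seed = 11))
}

# a small mixed bag of SPDs exercising both model branches
random_scene_spds <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    warm <- runif(1) < 0.5
    base <- if (warm) electric_spd(runif(1, 1200, 2400)) else
      spd_add(spd_scale(electric_spd(runif(1, 3000, 6500)),
                        runif(1, 0.2, 1)),
              spd_scale(daylight_spd(runif(1, 5000, 8000)),
                        runif(1, 0.2, 1)))
    spd_scale(base, 10^runif(1, 0.5, 3.5))
  })
}

# synthetic sensor log with scripted flat (candidate-nonwear) episodes
scripted_log <- function(n, seed, cadence_min = 10,
                         start = as.POSIXct("2024-10-01 00:00:00",
                                            tz = "UTC")) {
  set.seed(seed)
  ts <- start + seq(0, by = cadence_min * 60, length.out = n)
  lux <- 10^runif(n, 0, 3.5)
  motion <- runif(n) < 0.5
  i <- 1
  while (i < n) {
    if (runif(1) < 0.08) {
      len <- sample(3:40, 1)
      j <- min(n, i + len - 1)
      lux[i:j] <- lux[i] + runif(j - i + 1, 0, 0.5)
      motion[i:j] <- FALSE
      i <- j + 1
    } else i <- i + 1
  }
  data.frame(timestamp = ts, lux_raw = lux,
             cct_raw = runif(n, 1800, 8000),
             r_wm2 = runif(n), g_wm2 = runif(n), b_wm2 = runif(n),
             ir_wm2 = runif(n), motion = motion)
}
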