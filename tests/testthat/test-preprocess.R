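test_that("band-pass attenuation matches the forward-backward magnitude oracle", {
  fs <- 128
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  for (f in c(0.2, 2, 4)) {
    x <- ppg_record(sin(2 * pi * f * t), fs)
    y <- bandpass(x)
    # discard settling edges before measuring
    core <- (10 * fs):(50 * fs)
    gain_meas <- sqrt(mean(y$samples[core]^2)) / sqrt(mean(x$samples[core]^2))
    expect_equal(gain_meas, filtfilt_gain(f, fs), tolerance = 0.02)
  }
})

test_that("band-pass rejects wander and DC but preserves the pulse band", {
  fs <- 128
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  core <- (10 * fs):(50 * fs)
  rms <- function(v) sqrt(mean(v^2))
  slow <- bandpass(ppg_record(sin(2 * pi * 0.2 * t), fs))
  expect_lt(rms(slow$samples[core]), 0.05)
  mid <- bandpass(ppg_record(sin(2 * pi * 2 * t), fs))
  expect_gt(rms(mid$samples[core]) / rms(sin(2 * pi * 2 * t)[core]), 0.8)
  # DC is fully rejected once the filter's edge transient has settled
  const <- bandpass(ppg_record(rep(3.7, 60 * fs), fs))
  expect_lt(max(abs(const$samples[core])), 1e-6)
})

test_that("band-pass validates cutoffs and is linear", {
  rec <- ppg_record(rnorm(256), 128)
  expect_error(bandpass(rec, high_hz = 70), class = "pulsewedge_invalid_parameter")
  expect_error(bandpass(rec, low_hz = 5, high_hz = 2),
               class = "pulsewedge_invalid_parameter")
  set.seed(4)
  x <- ppg_record(rnorm(2048), 128)
  y <- ppg_record(rnorm(2048), 128)
  lhs <- bandpass(ppg_record(2 * x$samples - 3 * y$samples, 128))$samples
  rhs <- 2 * bandpass(x)$samples - 3 * bandpass(y)$samples
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("trim_transient removes the settling segment", {
  expect_equal(length(trim_transient(ppg_record(numeric(70 * 128) + 1, 128))$samples),
               7680)
  expect_equal(length(trim_transient(ppg_record(numeric(70 * 64) + 1, 64))$samples),
               3840)
  expect_equal(trim_transient(ppg_record(1:1280, 128), 5)$t0_s, 5)
  expect_error(trim_transient(ppg_record(numeric(8 * 128) + 1, 128)),
               class = "pulsewedge_insufficient_data")
})

test_that("select_window takes the latest clean window before the measurement", {
  rr <- render_recording(beat_template(), rhythm_spec(60, 0.02), noise_none(),
                         duration_s = 120, fs_hz = 128, seed = 2)
  out <- select_window(rr$record, pcwp_time_s = 120)
  expect_equal(out$selection$start_s, 50)
  expect_equal(out$selection$end_s, 120)
  expect_equal(out$selection$advanced_by_s, 0)
  expect_false(out$selection$artifact_flagged)
  expect_equal(length(out$record$samples), 70 * 128)
})

test_that("select_window advances past an artifact burst", {
  rr <- render_recording(beat_template(), rhythm_spec(60, 0.02), noise_none(),
                         duration_s = 400, fs_hz = 128, seed = 2)
  y <- rr$record$samples
  burst <- which(seq_along(y) / 128 >= 380 & seq_along(y) / 128 < 390)
  set.seed(1)
  y[burst] <- y[burst] + runif(length(burst), -8, 8)
  rec <- ppg_record(y, 128)
  out <- select_window(rec, pcwp_time_s = 400)
  expect_gt(out$selection$advanced_by_s, 0)
  expect_lte(out$selection$advanced_by_s, 300)
  expect_false(out$selection$artifact_flagged)
  # the burst lies outside the chosen window
  expect_lte(out$selection$end_s, 380)
})

test_that("select_window flags when no candidate is clean", {
  set.seed(8)
  t <- seq(0, 90 - 1 / 128, by = 1 / 128)
  y <- sin(2 * pi * t)
  spikes <- round(seq(5, 85, by = 3) * 128)
  y[spikes] <- 40
  out <- select_window(ppg_record(y, 128), pcwp_time_s = 90)
  expect_true(out$selection$artifact_flagged)
})

test_that("select_window needs at least one full window", {
  rec <- ppg_record(rnorm(60 * 128), 128)
  expect_error(select_window(rec, pcwp_time_s = 60),
               class = "pulsewedge_insufficient_data")
})

test_that("preprocessing preserves the systolic peaks of the analysis minute", {
  rr <- render_recording(beat_template(), rhythm_spec(60, 0.02),
                         noise_spec(0.25, 0.25, 0.02, 0),
                         duration_s = 80, fs_hz = 128, seed = 6)
  pre <- preprocess_record(rr$record, pcwp_time_s = 80)
  pk <- detect_systolic_peaks(pre$record)
  t_pk <- pre$record$t0_s + (pk - 1) / 128
  gt <- rr$fiducials$sys_s
  inside <- gt >= min(t_pk) - 0.5 & gt <= max(t_pk) + 0.5
  expect_lte(abs(length(pk) - sum(inside)), 1)
})
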