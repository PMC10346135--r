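# steady-state gain of a filter at frequency f, measured on a long sinusoid
measure_gain <- function(f, fs, fc = 5, order = 3) {
  t <- (0:(20 * fs)) / fs
  y <- lowpass_butterworth(sin(2 * pi * f * t), fs, fc = fc, order = order)
  tail_idx <- (length(y) %/% 2):length(y)
  sqrt(mean(y[tail_idx]^2)) * sqrt(2)
}

test_that("Butterworth filter has unit DC gain and the textbook response", {
  y <- lowpass_butterworth(rep(3, 600), 30, fc = 5)
  expect_close(y[300:600], 3, 1e-6)                   # steady-state DC gain 1
  expect_error(lowpass_butterworth(1:10, 30, fc = 20), "Nyquist")

  fs <- 1000 # high rate so bilinear warping is negligible vs the analog form
  expect_close(measure_gain(5, fs), 1 / sqrt(2), 0.01 / sqrt(2))
  # transfer-function oracle |H| = 1/sqrt(1 + (f/fc)^6) at 3 fc
  oracle <- 1 / sqrt(1 + 3^6)
  g3 <- measure_gain(15, fs)
  expect_lt(abs(g3 - oracle) / oracle, 0.01)
})

test_that("downsampling preserves band-limited content and rejects aliases", {
  const <- angle_trace(rep(10, 1000), rate = 100)
  d <- downsample_to_imu_rate(const)
  expect_equal(d$rate, 30)
  expect_length(d$values, 300)
  expect_close(d$values, 10, 1e-9)

  t <- (0:2999) / 100
  s1 <- downsample_to_imu_rate(angle_trace(20 * sin(2 * pi * t), rate = 100))
  amp <- sqrt(mean(s1$values^2)) * sqrt(2)
  expect_lt(abs(amp - 20) / 20, 0.01)

  s14 <- downsample_to_imu_rate(angle_trace(20 * sin(2 * pi * 14 * t),
                                            rate = 100))
  amp14 <- sqrt(mean(s14$values^2)) * sqrt(2)
  expect_lt(amp14 / 20, 0.05)

  expect_error(downsample_to_imu_rate(angle_trace(1:10, rate = 30)),
               "must exceed")
})

test_that("artifact windows bracket the spike cluster", {
  x <- spiky_signal(n = 300, rate = 30, t0 = 1.0, amplitude = 10)
  w <- isolate_artifact_window(x, 30, pad = 0.5)
  # spikes span 1.0-1.2 s -> samples ~31-37; pad 0.5 s = 15 samples
  expect_lte(w[1], 31 - 10)
  expect_gte(w[2], 37 + 10)
  expect_error(isolate_artifact_window(rep(1, 100), 30), "manual")

  set.seed(21)
  xn <- spiky_signal(n = 300, rate = 30, t0 = 1.0, amplitude = 10,
                     noise_sd = 1)
  wn <- isolate_artifact_window(xn, 30, pad = 0.5)
  expect_lt(abs(wn[1] - w[1]), 6)
  expect_lt(abs(wn[2] - w[2]), 6)
})

test_that("cross-correlation recovers constructed integer shifts", {
  x <- spiky_signal(n = 240, rate = 30)
  expect_identical(xcorr_lag(x, x), 0L)
  shifted <- c(rep(0, 15), x)[1:240]
  expect_identical(xcorr_lag(x, shifted), 15L)
  expect_identical(xcorr_lag(shifted, x), -15L)
  expect_error(xcorr_lag(1:2, 1:2), "3 samples")
  expect_error(xcorr_lag(rep(1, 50), rep(1, 50)), "constant")
})

test_that("alignment removes constant offsets and recovers generator truth", {
  x <- angle_trace(c(rep(0, 60), rep(20, 60), rep(0, 60)), rate = 30)
  r <- align_and_remove_offset(x, x, lag = 0)
  expect_identical(r$lag_samples, 0L)
  expect_equal(r$offset, 0)
  expect_equal(r$aligned$imu$values, x$values)

  shifted_up <- angle_trace(x$values + 4, rate = 30)
  r4 <- align_and_remove_offset(shifted_up, x, lag = 0)
  expect_equal(r4$offset, 4)
  expect_close(r4$aligned$imu$values - r4$aligned$mocap$values, 0, 1e-9)

  # full stage on a generated session with known lag and offset
  cfg <- sim_config(make_template("hip_flexion"),
                    angle_noise_sd_imu = 0.2, angle_noise_sd_mocap = 0.1,
                    inter_system_offset = 2, lag = 0.5, rng_seed = 5)
  sy <- sync_session(generate_session(cfg))
  expect_identical(sy$lag_samples, 15L)
  expect_lt(abs(abs(sy$offset) - 2), 0.1)

  # idempotence: re-syncing an aligned pair finds nothing left to fix
  r2 <- align_and_remove_offset(sy$aligned$imu, sy$aligned$mocap, lag = 0)
  expect_lt(abs(r2$offset), 0.1)
  expect_identical(xcorr_lag(sy$aligned$mocap$values, sy$aligned$imu$values),
                   0L)
})

test_that("native 30 Hz rendering and the downsampled path agree on truth", {
  cfg <- clean_config("semi-squat")
  s <- generate_session(cfg)
  mc30 <- downsample_to_imu_rate(s$mocap_trace)
  imu <- segment_angle_trace(s$imu_stream)
  n <- min(length(mc30$values), length(imu$values))
  rms_diff <- sqrt(mean((mc30$values[1:n] - imu$values[1:n])^2))
  rms_sig <- sqrt(mean(mc30$values[1:n]^2))
  expect_lt(rms_diff / rms_sig, 0.02)
})
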