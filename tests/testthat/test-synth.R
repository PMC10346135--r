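test_that("templates default to the published reference ROM per task", {
  expect_equal(make_template("semi-squat")$target_rom, 34.80)
  expect_equal(make_template("hip_extension")$target_rom, 23.40)
  expect_equal(make_template("knee_extension")$n_repetitions, 10L)
  expect_true(make_template("hip_flexion")$bilateral)
  expect_false(make_template("semi-squat")$bilateral)
  expect_error(make_template("moonwalk"), "valid tasks are")
})

test_that("ground-truth profile is rest/ramp/hold cycles with the right extrema", {
  tpl <- make_template("hip_flexion", target_rom = 30)
  expect_equal(ground_truth_angle(tpl, 0.5), 0)           # lead-in rest
  mid <- tpl$lead_in + tpl$ramp_duration + tpl$hold_duration / 2
  expect_equal(ground_truth_angle(tpl, mid), 30)          # plateau midpoint
  expect_error(ground_truth_angle(tpl, session_duration(tpl) + 1),
               "outside session span")

  # exhaustive-scan oracle: count connected runs at the plateau level
  t <- seq(0, session_duration(tpl), by = 0.01)
  a <- ground_truth_angle(tpl, t)
  at_top <- a > 0.99 * tpl$target_rom
  n_runs <- sum(diff(c(FALSE, at_top)) == 1)
  expect_identical(n_runs, tpl$n_repetitions)
})

test_that("sessions are deterministic under the seed, down to exported bytes", {
  cfg <- sim_config(make_template("semi-squat"), rng_seed = 42L)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1$imu_stream$quat, s2$imu_stream$quat)
  expect_identical(s1$mocap_trace$values, s2$mocap_trace$values)

  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_imu_csv(s1$imu_stream, f1)
  write_imu_csv(s2$imu_stream, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  s3 <- generate_session(sim_config(make_template("semi-squat"),
                                    rng_seed = 43L))
  expect_false(identical(s1$mocap_trace$values, s3$mocap_trace$values))
})

test_that("simulation configs reject impossible settings", {
  tpl <- make_template("hip_flexion")
  expect_error(sim_config(tpl, imu_rate = 0), "positive")
  expect_error(sim_config(tpl, angle_noise_sd_imu = -1), "non-negative")
  expect_error(sim_config(tpl, lag = tpl$lead_in + 1), "lead-in")
  expect_error(sim_config(tpl, misplacement_angle = 95), "90")
})

test_that("axial misplacement attenuates sagittal motion like the rotation oracle", {
  # closed-form sagittal excursion rendered as quaternions
  alpha <- c(seq(0, 30, by = 2), seq(30, 0, by = -2))
  q <- t(vapply(alpha, function(a) quat_about_axis(a, "z"),
                numeric(4)))
  stream <- quat_stream((seq_along(alpha) - 1) / 30, q)

  expect_identical(apply_misplacement(stream, 0)$quat, stream$quat)

  theta <- 11.459
  # rotation-composition oracle: Rx(theta) %*% Rz(alpha), ZYX yaw extracted
  oracle_peak <- max(vapply(alpha, function(a) {
    m <- rot_axis_mat(theta, "x") %*% rot_axis_mat(a, "z")
    atan2(m[2, 1], m[1, 1]) * 180 / pi
  }, numeric(1)))

  for (th in c(theta, -theta)) {
    mis <- apply_misplacement(stream, th)
    tr <- segment_angle_trace(mis)
    expect_close(max(tr$values), oracle_peak, 1e-8)
  }
  # cos-projection approximation of the same geometry
  expect_close(oracle_peak, 30 * cos(theta * pi / 180), 0.2)
})

test_that("in-plane excursion is non-increasing in |misplacement| (0-60 deg)", {
  alpha <- seq(0, 30, length.out = 40)
  q <- t(vapply(alpha, function(a) quat_about_axis(a, "z"),
                numeric(4)))
  stream <- quat_stream((seq_along(alpha) - 1) / 30, q)
  peaks <- vapply(seq(0, 60, by = 5), function(th) {
    max(segment_angle_trace(apply_misplacement(stream, th))$values)
  }, numeric(1))
  expect_true(all(diff(peaks) <= 1e-9))
})

test_that("repetition count is preserved under moderate angle noise", {
  # property over seeds: detectable cycles == n_repetitions up to 2 deg SD
  tpl <- make_template("semi-squat")
  for (seed in 1:6) {
    cfg <- sim_config(tpl, angle_noise_sd_imu = 2, angle_noise_sd_mocap = 2,
                      rng_seed = seed)
    s <- generate_session(cfg)
    sy <- sync_session(s)
    reps <- detect_repetitions(sy$aligned$imu, expected_n = 10)
    expect_length(reps$cycles, 10)
  }
})
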