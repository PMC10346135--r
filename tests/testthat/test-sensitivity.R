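test_that("the correct arm reproduces the placement-free pipeline", {
  cfg <- clean_config("hip_flexion")
  arm <- suppressWarnings(run_misplacement_arm(cfg, "correct"))
  sy <- sync_session(generate_session(cfg))
  direct <- trace_to_rom(sy$aligned$imu, expected_n = 10)
  expect_equal(arm$per_rep_rom, direct$per_rep_rom, tolerance = 1e-12)
  expect_error(run_misplacement_arm(cfg, "sideways"), "arg")
  expect_warning(
    run_misplacement_arm(clean_config("semi-squat"), "correct"),
    "protocol"
  )
})

test_that("noise-free lateral misplacement attenuates by the rotation model", {
  cfg <- clean_config("hip_flexion", target_rom = 30)
  theta <- misplacement_angle_from_displacement() # ~11.46 deg
  lat <- run_misplacement_arm(cfg, "lateral", theta)
  # rotation-composition oracle for the plateau angle
  m <- rot_axis_mat(theta, "x") %*% rot_axis_mat(30, "z")
  oracle <- atan2(m[2, 1], m[1, 1]) * 180 / pi
  expect_lt(abs(lat$mean_rom - oracle), 0.15)
  expect_lt(abs(lat$mean_rom - 30 * cos(theta * pi / 180)), 0.3)

  med <- run_misplacement_arm(cfg, "medial", theta)
  expect_equal(med$mean_rom, lat$mean_rom, tolerance = 1e-6)
})

test_that("cross-plane coupling breaks the medial/lateral symmetry", {
  tpl <- make_template("hip_extension")
  cfg <- sim_config(tpl, angle_noise_sd_imu = 0, angle_noise_sd_mocap = 0,
                    rep_rom_sd = 0, inter_system_offset = 0, lag = 0,
                    coupling_deg = 8, rng_seed = 2)
  med <- run_misplacement_arm(cfg, "medial")
  lat <- run_misplacement_arm(cfg, "lateral")
  expect_gt(abs(med$mean_rom - lat$mean_rom), 0.5)
})

test_that("misplacement comparisons satisfy their identities", {
  expect_equal(compare_misplacement(c(1, 2, 3), c(1, 2, 3)),
               list(rmse = 0, delta = 0))
  cmp <- compare_misplacement(c(10, 20, 30), c(13, 23, 33))
  expect_equal(cmp$rmse, 3)
  expect_equal(cmp$delta, 3)
  expect_error(compare_misplacement(1:3, 1:4), "matched")

  set.seed(6)
  for (i in 1:20) {
    a <- rnorm(10, 30, 3); b <- a + rnorm(10, -1, 2)
    cmp <- compare_misplacement(a, b)
    expect_gte(cmp$rmse, abs(cmp$delta) - 1e-12)
  }
})

test_that("the cohort comparison emits the report schema", {
  cmp <- run_misplacement_study("hip_extension", n = 4, seed = 2)
  row <- misplacement_comparison_row(cmp)
  expect_identical(
    names(row),
    c("task", "rom_correct_mean", "rom_correct_sd", "rom_medial_mean",
      "rom_medial_sd", "rom_lateral_mean", "rom_lateral_sd",
      "rmse_medial", "rmse_lateral")
  )
  expect_gte(cmp$rmse_medial, abs(cmp$delta_medial) - 1e-12)
  expect_gte(cmp$rmse_lateral, abs(cmp$delta_lateral) - 1e-12)
  # displaced arms read lower than correct under the symmetric model
  expect_lt(cmp$rom_lateral$mean_rom, cmp$rom_correct$mean_rom)
  expect_lt(cmp$rom_medial$mean_rom, cmp$rom_correct$mean_rom)
})
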