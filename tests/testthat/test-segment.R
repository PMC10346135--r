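# trapezoidal cycle fixture: rest - ramp - plateau - ramp - rest
# coarse ramps (5 steps) deliberately skip the tau = 0.9 band so the
# working phase is exactly the plateau
trapezoid_cycle <- function(plateau = 30, n_rest = 20, n_ramp = 5,
                            n_hold = 21) {
  c(rep(0, n_rest), seq(0, plateau, length.out = n_ramp + 2)[2:(n_ramp + 1)],
    rep(plateau, n_hold),
    seq(plateau, 0, length.out = n_ramp + 2)[2:(n_ramp + 1)], rep(0, n_rest))
}

test_that("repetitions are detected at the local minima between peaks", {
  cfg <- clean_config("hip_flexion")
  sy <- sync_session(generate_session(cfg))
  reps <- detect_repetitions(sy$aligned$imu, expected_n = 10)
  expect_length(reps$cycles, 10)
  expect_true(all(diff(reps$boundaries) > 0))
  expect_true(all(vapply(reps$cycles, length, integer(1)) == 101L))

  expect_error(detect_repetitions(angle_trace(rep(1, 100), rate = 30)),
               "no excursion")
  expect_warning(
    detect_repetitions(sy$aligned$imu, expected_n = 12),
    "expected 12"
  )
})

test_that("detection is stable under 1 degree of added noise (seeded)", {
  cfg <- clean_config("hip_flexion")
  base <- sync_session(generate_session(cfg))$aligned$imu
  for (seed in 1:10) {
    set.seed(seed)
    noisy <- angle_trace(base$values + rnorm(length(base$values), 0, 1),
                         rate = 30)
    reps <- detect_repetitions(noisy, expected_n = 10)
    expect_length(reps$cycles, 10)
  }
})

test_that("cycle resampling is exact on affine data and preserves extrema", {
  cyc <- trapezoid_cycle(n_rest = 25, n_ramp = 5, n_hold = 41) # 101 samples
  expect_equal(resample_cycle(cyc, n_points = 101), cyc)

  ramp <- seq(0, 30, length.out = 57)
  rs <- resample_cycle(ramp, n_points = 101)
  expect_close(rs, seq(0, 30, length.out = 101), 1e-9)
  expect_equal(max(rs), 30)

  # dense-grid oracle: extrema preserved within one inter-sample step
  u <- seq(0, 1, length.out = 41)
  bumpy <- sin(2 * pi * u) + 0.3 * sin(6 * pi * u)
  dense <- sin(2 * pi * seq(0, 1, length.out = 4001)) +
    0.3 * sin(6 * pi * seq(0, 1, length.out = 4001))
  rs2 <- resample_cycle(bumpy, n_points = 101)
  step <- max(abs(diff(bumpy)))
  expect_lt(abs(max(rs2) - max(dense)), step)
  expect_lt(abs(min(rs2) - min(dense)), step)
  expect_error(resample_cycle(1:3), "too short")
})

test_that("working phase isolates the plateau", {
  cyc <- trapezoid_cycle(n_rest = 19, n_ramp = 5, n_hold = 21)
  # plateau occupies samples 25-45 of this 69-sample cycle
  expect_equal(working_phase(cyc, tau = 0.9), c(25, 45))

  # closed-form sinusoid oracle: sin(pi u) >= 0.9 over the arcsin band
  u <- seq(0, 1, length.out = 101)
  halfsine <- sin(pi * u)
  w <- working_phase(halfsine, tau = 0.9)
  u_lo <- asin(0.9) / pi
  expect_lt(abs(u[w[1]] - u_lo), 0.015)
  expect_lt(abs(u[w[2]] - (1 - u_lo)), 0.015)

  w1 <- working_phase(halfsine, tau = 1)
  expect_equal(w1[1], which.max(halfsine))
  expect_equal(w1[2], which.max(halfsine))
  expect_error(working_phase(rep(2, 50)), "flat")
})

test_that("working-phase ROM matches closed-form and integral oracles", {
  expect_equal(compute_rom(trapezoid_cycle(30), rest_value = 0), 30)

  # plateau oscillating symmetrically about 30 (even hold length)
  osc <- trapezoid_cycle(30, n_hold = 20)
  hold_idx <- which(osc == 30)
  osc[hold_idx] <- 30 + rep_len(c(-1, 1), length(hold_idx))
  expect_equal(compute_rom(osc, rest_value = 0), 30)

  # numeric-integration oracle for the half-sine working mean
  u <- seq(0, 1, length.out = 2001)
  halfsine <- 30 * sin(pi * u)
  u_lo <- asin(0.9) / pi
  dense <- seq(u_lo, 1 - u_lo, length.out = 1e5)
  oracle <- mean(30 * sin(pi * dense))
  expect_lt(abs(compute_rom(halfsine, rest_value = 0) - oracle), 0.05)

  # secondary diagnostics
  expect_equal(compute_rom(trapezoid_cycle(30), mode = "max_min"), 30)
  expect_equal(compute_rom(trapezoid_cycle(30), rest_value = 0,
                           mode = "final_position"), 30)

  # negative-excursion cycle yields a positive ROM
  expect_equal(compute_rom(-trapezoid_cycle(30), rest_value = 0), 30)
})

test_that("ROM is invariant to time shifts and baseline constants", {
  cyc <- trapezoid_cycle(25)
  rom0 <- compute_rom(cyc, rest_value = 0)
  expect_equal(compute_rom(c(rep(0, 13), cyc), rest_value = 0), rom0,
               tolerance = 1e-9)
  expect_equal(compute_rom(cyc + 7, rest_value = 7), rom0, tolerance = 1e-9)
})

test_that("raising tau narrows the working phase and raises unimodal ROM", {
  u <- seq(0, 1, length.out = 201)
  cyc <- 30 * sin(pi * u)
  widths <- vapply(c(0.5, 0.7, 0.9, 0.99, 1), function(tau) {
    w <- working_phase(cyc, tau)
    w[2] - w[1]
  }, numeric(1))
  expect_true(all(diff(widths) <= 0))
  expect_gte(compute_rom(cyc, tau = 1), compute_rom(cyc, tau = 0.9))
})

test_that("side pooling concatenates repetitions after the pre-test", {
  set.seed(77)
  l <- rom_estimate(rnorm(10, 30, 1), "hip_flexion", "IMU")
  r <- rom_estimate(rnorm(10, 30, 1), "hip_flexion", "IMU")
  p <- pool_sides(l, r)
  expect_length(p$per_rep_rom, 20)
  expect_true(p$pooled)
  expect_gte(p$mean_rom, min(l$mean_rom, r$mean_rom))
  expect_lte(p$mean_rom, max(l$mean_rom, r$mean_rom))

  other <- rom_estimate(rnorm(10, 30, 1), "semi-squat", "IMU")
  expect_error(pool_sides(l, other), "share task")
  expect_error(rom_estimate(numeric(0)), "at least one")

  far <- rom_estimate(rnorm(10, 45, 1), "hip_flexion", "IMU")
  expect_warning(pool_sides(l, far), "pre-test significant")
})
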