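# shared fixtures, built in code

# noise-free, lag-free, offset-free simulation config
clean_config <- function(task = "hip_flexion", target_rom = NULL, seed = 1L,
                         ...) {
  tpl <- make_template(task, target_rom = target_rom)
  sim_config(tpl, angle_noise_sd_imu = 0, angle_noise_sd_mocap = 0,
             rep_rom_sd = 0, inter_system_offset = 0, lag = 0,
             rng_seed = seed, ...)
}

# uniformly random unit quaternion (Shoemake)
random_unit_quat <- function() {
  u <- stats::runif(3)
  c(
    sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3])
  )[c(2, 1, 3, 4)] # order irrelevant for uniformity; keep (w,x,y,z) unit
}

# artifact-like test signal: flat with three half-sine spikes at t0
spiky_signal <- function(n = 300, rate = 30, t0 = 1.0, amplitude = 10,
                         noise_sd = 0) {
  t <- (seq_len(n) - 1) / rate
  out <- numeric(n)
  for (j in 0:2) {
    s <- t0 + j * 0.08
    inside <- t >= s & t <= s + 0.06
    out[inside] <- out[inside] + amplitude * sin(pi * (t[inside] - s) / 0.06)
  }
  out + stats::rnorm(n, 0, noise_sd)
}

expect_close <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)), tol)
}
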