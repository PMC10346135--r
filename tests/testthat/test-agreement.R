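test_that("accuracy reproduces the published worked examples", {
  expect_equal(round(rom_accuracy(33.92, 34.80), 1), 97.5)
  expect_equal(round(rom_accuracy(17.08, 23.40), 1), 73.0)
  expect_equal(rom_accuracy(28.4, 28.4), 100)
  expect_error(rom_accuracy(10, 0), "nonzero")

  # scale invariance
  set.seed(1)
  for (i in 1:20) {
    a <- runif(1, 10, 80); b <- runif(1, 10, 80); k <- runif(1, 0.1, 10)
    expect_equal(rom_accuracy(k * a, k * b), rom_accuracy(a, b),
                 tolerance = 1e-12)
  }
})

test_that("RMSE matches hand-computed cases", {
  expect_equal(rom_rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rom_rmse(5, 2), 3)                    # single pair |d|
  expect_equal(rom_rmse(c(3, -4), c(0, 0)), sqrt(25 / 2))  # 3.5355...
  expect_error(rom_rmse(1:3, 1:4), "equal length")
})

test_that("Pearson correlation agrees with the textbook formula", {
  x <- c(31.2, 28.7, 35.1, 30.0, 33.4)
  y <- c(30.1, 27.9, 36.0, 31.2, 32.8)
  # direct formula oracle
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- pearson_cor(x, y)
  expect_equal(res$estimate, r_oracle, tolerance = 1e-12)
  expect_lt(res$p_value, 0.05)

  expect_equal(pearson_cor(x, x)$estimate, 1)
  expect_equal(pearson_cor(x, -2 * x + 5)$estimate, -1)
  expect_error(pearson_cor(x, rep(1, 5)), "zero variance")
})

test_that("Lin's CCC matches the moment decomposition and is below |PCC|", {
  x <- c(31.2, 28.7, 35.1, 30.0, 33.4)
  y <- c(30.1, 27.9, 36.0, 31.2, 32.8)
  # independent route: CCC = r * C_b with C_b = 2 / (v + 1/v + u^2)
  n <- length(x)
  sx <- sqrt(mean((x - mean(x))^2)); sy <- sqrt(mean((y - mean(y))^2))
  r <- pearson_cor(x, y)$estimate
  v <- sx / sy; u <- (mean(x) - mean(y)) / sqrt(sx * sy)
  oracle <- r * 2 / (v + 1 / v + u^2)
  expect_equal(lin_ccc(x, y), oracle, tolerance = 1e-12)

  expect_equal(lin_ccc(x, x), 1)
  expect_lt(lin_ccc(x, x + 10), 1)      # location-shift penalty
  expect_equal(pearson_cor(x, x + 10)$estimate, 1)

  set.seed(8)
  for (i in 1:200) {
    a <- rnorm(10, 30, 5); b <- a * runif(1, 0.5, 1.5) + rnorm(10, 2, 3)
    expect_lte(abs(lin_ccc(a, b)), abs(pearson_cor(a, b)$estimate) + 1e-12)
  }
})

test_that("Bland-Altman limits match the Gaussian closed form", {
  x <- c(30, 31, 32.5)
  expect_equal(unlist(bland_altman(x, x)[c("bias", "loa_low", "loa_high")]),
               c(bias = 0, loa_low = 0, loa_high = 0))
  ba_c <- bland_altman(x + 2, x)
  expect_equal(c(ba_c$bias, ba_c$loa_low, ba_c$loa_high), c(2, 2, 2))

  set.seed(3)
  d <- rnorm(1e4, 2, 1)
  ba <- bland_altman(d, rep(0, 1e4))
  expect_equal(ba$bias, 2, tolerance = 0.05)
  expect_equal(ba$loa_low, 2 - 1.96, tolerance = 0.08)
  expect_equal(ba$loa_high, 2 + 1.96, tolerance = 0.08)
  expect_identical(names(ba$points), c("mean", "diff"))
})

test_that("SEM and MCID follow the clamped pooled-SD rule", {
  expect_equal(sem_mcid(2, 2)$sem, 0)            # equal SDs -> R = 1
  # pooled SD 2, reliability 0.75 -> SEM exactly 1
  sdi <- sqrt(32 / 7); sdm <- sqrt(24 / 7)
  res <- sem_mcid(sdi, sdm)
  expect_equal(res$reliability, 0.75)
  expect_equal(res$sem, 1)
  # clamping is symmetric in the variance ratio
  expect_equal(sem_mcid(3, 5)$sem, sem_mcid(5, 3)$sem)
  expect_lte(sem_mcid(3, 5)$reliability, 1)
  expect_error(sem_mcid(-1, 2), "non-negative")
  expect_true(sem_mcid(3, 5, mean_diff = 10)$mcid_exceeded)
})

test_that("Anderson-Darling test holds its size and detects non-normality", {
  expect_error(ad_normality(rnorm(5)), "n >= 8")
  expect_error(ad_normality(rep(1, 50)), "constant")

  set.seed(12)
  rejections <- sum(vapply(1:60, function(i) {
    ad_normality(rnorm(200))$p_value < 0.05
  }, logical(1)))
  expect_gte(rejections, 1)
  expect_lte(rejections, 8)     # ~5% of 60

  power_hits <- sum(vapply(1:20, function(i) {
    ad_normality(runif(200))$p_value < 0.01
  }, logical(1)))
  expect_gte(power_hits, 19)
})

test_that("the full report is coherent and serializes losslessly", {
  x <- c(30.2, 31.5, 28.9, 33.0, 29.4, 30.8)
  perfect <- build_agreement_report(paired_rom_sample(x, x, "semi-squat"))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$pcc, 1)
  expect_equal(perfect$ccc, 1)
  expect_equal(c(perfect$ba_bias, perfect$ba_loa_low, perfect$ba_loa_high),
               c(0, 0, 0))

  set.seed(10)
  mocap <- rnorm(21, 30, 5)
  rep6 <- build_agreement_report(paired_rom_sample(mocap + 6, mocap, "t"))
  expect_identical(rep6$mcid_exceeded, 6 > rep6$mcid)
  expect_lte(rep6$ba_loa_low, rep6$ba_bias)
  expect_gte(rep6$ba_loa_high, rep6$ba_bias)
  expect_gte(rep6$rmse, abs(rep6$ba_bias))

  row <- agreement_report_row(rep6)
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(row, csv, row.names = FALSE)
  back <- utils::read.csv(csv)
  expect_equal(back$accuracy, row$accuracy, tolerance = 1e-9)
  expect_equal(back$ccc, row$ccc, tolerance = 1e-9)
  js <- jsonlite::fromJSON(jsonlite::toJSON(row, digits = NA))
  expect_equal(js$rmse, row$rmse, tolerance = 1e-12)
})

test_that("population identity RMSE^2 = bias^2 + var(d) holds at large n", {
  set.seed(5)
  imu <- rnorm(1e4, 32, 4); mocap <- rnorm(1e4, 30, 4)
  d <- imu - mocap
  rmse <- rom_rmse(imu, mocap)
  expect_equal(rmse^2, mean(d)^2 + mean((d - mean(d))^2), tolerance = 1e-9)
})
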