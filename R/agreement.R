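#' Paired per-participant ROM sample
#'
#' Agreement statistics are computed on per-participant mean ROMs: one
#' (IMU, reference) pair per participant for a given task.
#'
#' @param imu,mocap equal-length numeric vectors of per-participant mean
#'   ROMs, degrees
#' @param task_name task label
#' @return an object of class `paired_rom_sample`
#' @export
paired_rom_sample <- function(imu, mocap, task_name = NA_character_) {
  imu <- as.numeric(imu); mocap <- as.numeric(mocap)
  if (length(imu) != length(mocap)) stop("paired vectors must have equal length")
  if (length(imu) < 2) stop("need at least 2 participants")
  if (any(!is.finite(imu)) || any(!is.finite(mocap))) {
    stop("ROM values must be finite")
  }
  structure(list(imu = imu, mocap = mocap, n = length(imu),
                 task_name = task_name),
            class = "paired_rom_sample")
}

#' ROM accuracy of the IMU against the reference
#'
#' `(1 - |ROM_IMU - ROM_MoCap| / ROM_MoCap) * 100`, in percent: 100 for
#' identical means, decreasing with the relative absolute difference. The
#' statistic is scale-invariant (multiplying both ROMs by k > 0 leaves it
#' unchanged) and can go negative when the absolute difference exceeds the
#' reference ROM.
#'
#' @param rom_imu_mean,rom_mocap_mean mean ROMs, degrees; the reference
#'   mean must be nonzero
#' @return accuracy in percent
#' @export
#' @examples
#' rom_accuracy(33.92, 34.80) # 97.5 (to one decimal)
rom_accuracy <- function(rom_imu_mean, rom_mocap_mean) {
  if (any(rom_mocap_mean == 0)) stop("reference ROM must be nonzero")
  (1 - abs(rom_imu_mean - rom_mocap_mean) / rom_mocap_mean) * 100
}

#' Root mean square error between paired ROM vectors
#'
#' `sqrt(mean((imu - mocap)^2))` over participants (population 1/n form).
#'
#' @param imu_values,mocap_values equal-length numeric vectors
#' @return RMSE in the input unit (degrees)
#' @export
rom_rmse <- function(imu_values, mocap_values) {
  if (length(imu_values) != length(mocap_values)) {
    stop("paired vectors must have equal length")
  }
  if (!length(imu_values)) stop("need at least one pair")
  sqrt(mean((as.numeric(imu_values) - as.numeric(mocap_values))^2))
}

#' Pearson correlation of paired ROMs
#'
#' Sample product-moment correlation with the two-sided p-value from the t
#' transform (via [stats::cor.test()]).
#'
#' @param imu_values,mocap_values equal-length numeric vectors, n >= 3,
#'   both with nonzero variance
#' @return list with `estimate` and `p_value`
#' @export
pearson_cor <- function(imu_values, mocap_values) {
  x <- as.numeric(imu_values); y <- as.numeric(mocap_values)
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance input")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(estimate = unname(ct$estimate), p_value = ct$p.value)
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 s_xy / (s_x^2 + s_y^2 + (mean_x - mean_y)^2)` with biased (1/n)
#' sample moments, the original estimator's convention. CCC equals the
#' Pearson correlation multiplied by a bias-correction factor in (0, 1], so
#' `|CCC| <= |PCC|` always; it penalizes location and scale shifts that
#' Pearson ignores.
#'
#' @param imu_values,mocap_values equal-length numeric vectors, n >= 3, not
#'   both constant
#' @return CCC in `[-1, 1]`
#' @export
lin_ccc <- function(imu_values, mocap_values) {
  x <- as.numeric(imu_values); y <- as.numeric(mocap_values)
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) stop("concordance undefined: both inputs constant and equal")
  2 * sxy / denom
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences `d_i = imu_i - mocap_i`; bias is their mean and the limits
#' of agreement are `bias +/- 1.96 sd(d)`. The returned object also carries
#' the per-pair `(mean_i, d_i)` plot payload (pair means on x, differences
#' on y).
#'
#' @param imu_values,mocap_values equal-length numeric vectors, n >= 3
#' @return list of class `bland_altman`: `bias`, `loa_low`, `loa_high`,
#'   `sd_diff`, and `points` (data.frame with `mean` and `diff`)
#' @export
bland_altman <- function(imu_values, mocap_values) {
  x <- as.numeric(imu_values); y <- as.numeric(mocap_values)
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  structure(
    list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
         sd_diff = s,
         points = data.frame(mean = (x + y) / 2, diff = d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.3f deg, LoA [%.3f, %.3f] (n = %d)\n",
              x$bias, x$loa_low, x$loa_high, nrow(x$points)))
  invisible(x)
}

#' Standard error of measurement and MCID threshold
#'
#' `SEM = SD * sqrt(1 - R)` with the pooled between-participant SD
#' `sqrt((SD_imu^2 + SD_mocap^2) / 2)` and the reliability `R` taken as the
#' variance ratio of the two systems, clamped to `min(ratio, 1/ratio)` so
#' that `0 <= R <= 1` and the square root stays real regardless of which
#' system is more variable. The minimal clinically important difference is
#' set at 1 SEM; inter-system mean differences above it are flagged.
#'
#' @param sd_imu,sd_mocap per-system between-participant SDs, degrees
#'   (non-negative)
#' @param mean_diff optional inter-system mean difference used for the MCID
#'   exceedance flag
#' @return list: `sem`, `mcid` (= sem), `reliability`, and `mcid_exceeded`
#'   (NA if `mean_diff` missing)
#' @export
sem_mcid <- function(sd_imu, sd_mocap, mean_diff = NA_real_) {
  if (sd_imu < 0 || sd_mocap < 0) stop("SDs must be non-negative")
  if (sd_imu == 0 && sd_mocap == 0) {
    r <- 1
  } else if (sd_imu == 0 || sd_mocap == 0) {
    r <- 0
  } else {
    ratio <- sd_mocap^2 / sd_imu^2
    r <- min(ratio, 1 / ratio)
  }
  sd_pooled <- sqrt((sd_imu^2 + sd_mocap^2) / 2)
  sem <- sd_pooled * sqrt(1 - r)
  list(sem = sem, mcid = sem, reliability = r,
       mcid_exceeded = if (is.na(mean_diff)) NA else abs(mean_diff) > sem)
}

#' Anderson-Darling test for composite normality
#'
#' Anderson-Darling statistic against the normal family with estimated mean
#' and SD, with Stephens' small-sample correction
#' `A* = A^2 (1 + 0.75/n + 2.25/n^2)` and the standard piecewise p-value
#' approximation for the composite-normal case.
#'
#' @param values numeric vector, n >= 8, nonconstant
#' @return list with `statistic` (A*), `p_value`
#' @export
ad_normality <- function(values) {
  x <- sort(as.numeric(values))
  n <- length(x)
  if (n < 8) stop("Anderson-Darling normality test needs n >= 8")
  if (stats::sd(x) == 0) stop("Anderson-Darling test undefined for constant input")
  z <- (x - mean(x)) / stats::sd(x)
  logp <- stats::pnorm(z, log.p = TRUE)
  logq <- stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)
  i <- seq_len(n)
  a2 <- -n - mean((2 * i - 1) * (logp + rev(logq)))
  a <- a2 * (1 + 0.75 / n + 2.25 / n^2)
  p <- if (a >= 0.6) {
    exp(1.2937 - 5.709 * a + 0.0186 * a^2)
  } else if (a >= 0.34) {
    exp(0.9177 - 4.279 * a - 1.38 * a^2)
  } else if (a >= 0.2) {
    1 - exp(-8.318 + 42.796 * a - 59.938 * a^2)
  } else {
    1 - exp(-13.436 + 101.14 * a - 223.73 * a^2)
  }
  list(statistic = a, p_value = min(1, max(0, p)))
}

#' Full agreement report for one task
#'
#' Computes the complete agreement suite between the paired per-participant
#' mean ROMs of the two systems: per-system mean/SD, absolute difference of
#' the means, accuracy, RMSE, Pearson and Lin concordance correlations,
#' Bland-Altman bias and limits of agreement, SEM with the MCID exceedance
#' flag, and an Anderson-Darling normality check on the differences (NA for
#' n < 8).
#'
#' @param paired a [paired_rom_sample()]
#' @return an object of class `agreement_report` (a one-row-per-task list;
#'   see [agreement_report_row()] for the flat form)
#' @export
build_agreement_report <- function(paired) {
  stopifnot(inherits(paired, "paired_rom_sample"))
  x <- paired$imu; y <- paired$mocap
  mean_imu <- mean(x); mean_mocap <- mean(y)
  sd_imu <- stats::sd(x); sd_mocap <- stats::sd(y)
  acc <- rom_accuracy(mean_imu, mean_mocap)
  rmse <- rom_rmse(x, y)
  identical_pair <- isTRUE(all.equal(x, y, tolerance = 1e-12))
  pcc <- if (paired$n >= 3 && sd_imu > 0 && sd_mocap > 0 && !identical_pair) {
    pearson_cor(x, y)
  } else if (identical_pair && sd_imu > 0) {
    list(estimate = 1, p_value = 0)
  } else {
    list(estimate = NA_real_, p_value = NA_real_)
  }
  ccc <- if (paired$n >= 3 && (sd_imu > 0 || sd_mocap > 0 ||
                               mean_imu != mean_mocap)) {
    lin_ccc(x, y)
  } else {
    NA_real_
  }
  ba <- bland_altman(x, y)
  sm <- sem_mcid(sd_imu, sd_mocap, mean_diff = mean_imu - mean_mocap)
  nt <- if (paired$n >= 8 && stats::sd(x - y) > 0) {
    ad_normality(x - y)
  } else {
    list(statistic = NA_real_, p_value = NA_real_)
  }
  structure(
    list(
      task_name = paired$task_name, n = paired$n,
      mean_rom_imu = mean_imu, sd_imu = sd_imu,
      mean_rom_mocap = mean_mocap, sd_mocap = sd_mocap,
      abs_diff = abs(mean_imu - mean_mocap),
      accuracy = acc, rmse = rmse,
      pcc = pcc$estimate, pcc_p = pcc$p_value, ccc = ccc,
      ba_bias = ba$bias, ba_loa_low = ba$loa_low, ba_loa_high = ba$loa_high,
      sem = sm$sem, mcid = sm$mcid, mcid_exceeded = sm$mcid_exceeded,
      normality_stat = nt$statistic, normality_p = nt$p_value,
      bland_altman = ba
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement_report> %s (n = %d)\n  IMU %.2f (%.2f) vs ref %.2f (%.2f) deg; |diff| %.2f\n  accuracy %.1f%%, RMSE %.2f, PCC %.2f (p = %.3g), CCC %.2f\n  Bland-Altman bias %.2f, LoA [%.2f, %.2f]; MCID %.2f%s\n",
    x$task_name, x$n, x$mean_rom_imu, x$sd_imu, x$mean_rom_mocap, x$sd_mocap,
    x$abs_diff, x$accuracy, x$rmse, x$pcc, x$pcc_p, x$ccc,
    x$ba_bias, x$ba_loa_low, x$ba_loa_high, x$mcid,
    if (isTRUE(x$mcid_exceeded)) " (exceeded)" else ""
  ))
  invisible(x)
}

#' Flatten an agreement report to a one-row data.frame
#' @param report an `agreement_report`
#' @return one-row data.frame (no nested plot payload)
#' @export
agreement_report_row <- function(report) {
  stopifnot(inherits(report, "agreement_report"))
  flat <- report[setdiff(names(report), "bland_altman")]
  as.data.frame(flat, stringsAsFactors = FALSE)
}
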