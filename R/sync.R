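#' Isolate the stomp-artifact window of a signal
#'
#' Finds the largest cluster of spikes (samples whose absolute deviation
#' from the signal median exceeds `threshold` times the largest absolute
#' deviation) and returns a contiguous index window bracketing it, padded by
#' `pad` seconds. Used on the filtered IMU x-acceleration and on the
#' reference sync-marker trajectory before cross-correlation.
#'
#' @param x numeric signal
#' @param rate sampling rate, Hz
#' @param threshold spike detection threshold as a fraction of the maximum
#'   absolute deviation (default 0.5); the deviation must also exceed
#'   `min_prominence` absolute units to reject flat signals
#' @param pad window padding, seconds (default 0.5)
#' @param min_prominence minimum absolute spike size (default 6 robust
#'   scale units, i.e. 6 * mad(x))
#' @return integer vector `c(start, end)` of window sample indices
#' @export
isolate_artifact_window <- function(x, rate, threshold = 0.5, pad = 0.5,
                                    min_prominence = NULL) {
  x <- as.numeric(x)
  dev <- abs(x - stats::median(x))
  peak <- max(dev)
  if (is.null(min_prominence)) {
    scale <- stats::mad(x)
    min_prominence <- 6 * max(scale, 1e-12)
  }
  if (peak < min_prominence || peak == 0) {
    stop("no spike exceeds the prominence threshold; select the artifact window manually")
  }
  idx <- which(dev >= threshold * peak)
  # largest contiguous cluster (gaps up to 0.2 s merged)
  gap <- ceiling(0.2 * rate)
  breaks <- which(diff(idx) > gap)
  starts <- c(1, breaks + 1)
  ends <- c(breaks, length(idx))
  sizes <- idx[ends] - idx[starts]
  best <- which.max(sizes + 1)
  lo <- idx[starts[best]]; hi <- idx[ends[best]]
  pad_n <- round(pad * rate)
  c(max(1L, lo - pad_n), min(length(x), hi + pad_n))
}

#' Integer lag maximizing the normalized cross-correlation
#'
#' Both signals are z-normalized, then the normalized cross-correlation is
#' evaluated over integer lags in `[-max_lag, max_lag]`; the returned lag is
#' the one maximizing the correlation, ties broken toward the smallest
#' `|lag|`. A positive lag means `b` is delayed relative to `a`
#' (`b[i + lag] ~ a[i]`).
#'
#' @param sig_a,sig_b numeric signals at the same rate (at least 3 samples)
#' @param max_lag largest |lag| searched, samples (default: 60, i.e. 2 s at
#'   30 Hz)
#' @return integer lag in samples
#' @export
xcorr_lag <- function(sig_a, sig_b, max_lag = 60L) {
  a <- as.numeric(sig_a); b <- as.numeric(sig_b)
  if (length(a) < 3L || length(b) < 3L) {
    stop("cross-correlation windows must have at least 3 samples")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("cannot cross-correlate a constant window")
  }
  a <- (a - mean(a)) / stats::sd(a)
  b <- (b - mean(b)) / stats::sd(b)
  lags <- -max_lag:max_lag
  score <- vapply(lags, function(l) {
    # overlap of a[i] with b[i + l]
    ia <- max(1, 1 - l):min(length(a), length(b) - l)
    if (length(ia) < 3L) return(-Inf)
    ib <- ia + l
    sum(a[ia] * b[ib]) / length(ia)
  }, numeric(1))
  best <- max(score)
  cand <- lags[score >= best - 1e-12]
  cand[which.min(abs(cand))]
}

#' Estimate the inter-stream delay from the stomp artifact
#'
#' Runs the full artifact synchronization recipe: the reference marker
#' channel (100 Hz) is down-sampled to the IMU rate; both artifact channels
#' are low-pass filtered with the same causal 3rd-order 5 Hz Butterworth
#' filter (applying the identical filter to both sides cancels its group
#' delay in the lag estimate); the spike windows are isolated; and the
#' normalized cross-correlation of the windows gives the integer lag at the
#' IMU rate.
#'
#' @param imu_accel_x raw IMU x-acceleration at `imu_rate`
#' @param marker_y reference sync-marker trajectory at `marker_rate`
#' @param imu_rate IMU rate, Hz (default 30)
#' @param marker_rate marker rate, Hz (default 100)
#' @param fc artifact filter cutoff, Hz (default 5)
#' @param max_lag_s largest delay searched, seconds (default 2)
#' @return integer lag in samples at `imu_rate`: the number of samples the
#'   IMU stream is delayed relative to the reference stream
#' @export
estimate_stream_lag <- function(imu_accel_x, marker_y, imu_rate = 30,
                                marker_rate = 100, fc = 5, max_lag_s = 2) {
  mk30 <- downsample_signal(marker_y, marker_rate, imu_rate)
  # remove each channel's baseline first: the causal filter starts from zero
  # initial conditions and a large DC level would swamp the spikes with its
  # start-up transient
  af <- lowpass_butterworth(imu_accel_x - stats::median(imu_accel_x),
                            imu_rate, fc = fc)
  mf <- lowpass_butterworth(mk30 - stats::median(mk30), imu_rate, fc = fc)
  isolate_artifact_window(af, imu_rate)   # validates the IMU spike exists
  wm <- isolate_artifact_window(mf, imu_rate)
  # identical index ranges from both signals around the reference artifact,
  # extended by the search range, so the xcorr lag IS the inter-stream delay
  L <- ceiling(max_lag_s * imu_rate)
  n <- min(length(af), length(mf))
  lo <- max(1L, wm[1] - L)
  hi <- min(n, wm[2] + L)
  xcorr_lag(mf[lo:hi], af[lo:hi], max_lag = L)
}

#' Align two 30 Hz traces and remove the inter-system offset
#'
#' Shifts the IMU trace by the estimated lag, crops both traces to their
#' common support, estimates the constant inter-system offset as the
#' difference of the rest-phase means (the first `rest_window` seconds of
#' the aligned pair, which fall in the pre-task rest), and subtracts it from
#' the IMU trace.
#'
#' @param imu_trace [angle_trace] at 30 Hz (IMU clock)
#' @param mocap_trace [angle_trace] at 30 Hz (reference clock)
#' @param lag integer delay of the IMU stream in samples (as returned by
#'   [estimate_stream_lag()])
#' @param rest_window length of the rest window used for the offset
#'   estimate, seconds (default 1)
#' @return an object of class `sync_result`: `lag_samples`, `lag_seconds`,
#'   `offset` (degrees, IMU minus reference at rest), and `aligned` (a list
#'   of the two cropped, offset-corrected [angle_trace]s of equal length)
#' @export
align_and_remove_offset <- function(imu_trace, mocap_trace, lag,
                                    rest_window = 1) {
  stopifnot(inherits(imu_trace, "angle_trace"),
            inherits(mocap_trace, "angle_trace"))
  if (imu_trace$rate != mocap_trace$rate) {
    stop("both traces must be at the same (IMU) rate")
  }
  rate <- imu_trace$rate
  lag <- as.integer(round(lag))
  iv <- imu_trace$values
  mv <- mocap_trace$values
  # imu[i + lag] corresponds to mocap[i]
  i0 <- max(1L, 1L + lag)
  m0 <- i0 - lag
  n <- min(length(iv) - i0 + 1L, length(mv) - m0 + 1L)
  if (n < 2L) stop("no overlap between the traces after shifting")
  iu <- iv[i0:(i0 + n - 1L)]
  mu <- mv[m0:(m0 + n - 1L)]
  k <- max(2L, min(n, round(rest_window * rate)))
  offset <- mean(iu[1:k]) - mean(mu[1:k])
  iu <- iu - offset
  structure(
    list(
      lag_samples = lag, lag_seconds = lag / rate, offset = offset,
      aligned = list(
        imu = angle_trace(iu, rate = rate, t0 = mocap_trace$t0 + (m0 - 1) / rate,
                          system = "IMU", task_name = imu_trace$task_name),
        mocap = angle_trace(mu, rate = rate,
                            t0 = mocap_trace$t0 + (m0 - 1) / rate,
                            system = "MoCap", task_name = mocap_trace$task_name)
      )
    ),
    class = "sync_result"
  )
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf(
    "<sync_result> lag %d samples (%.3f s), offset %.3f deg, %d aligned samples\n",
    x$lag_samples, x$lag_seconds, x$offset, length(x$aligned$imu$values)
  ))
  invisible(x)
}

#' Synchronize a full synthetic or imported session
#'
#' Convenience wrapper running the complete sync stage on a session: extract
#' the IMU segment-angle trace, down-sample the reference angle trace to the
#' IMU rate, estimate the stomp-artifact lag, and align/offset-correct the
#' pair.
#'
#' @param session a `synthetic_session` (or a list with the same fields)
#' @param plane_axis Euler component of the task's motion plane (default "z")
#' @param rest_window rest window for the offset estimate, seconds
#' @return a `sync_result` (see [align_and_remove_offset()])
#' @export
sync_session <- function(session, plane_axis = "z", rest_window = 1) {
  imu_tr <- segment_angle_trace(session$imu_stream, plane_axis)
  mc30 <- downsample_to_imu_rate(session$mocap_trace,
                                 new_rate = session$imu_stream$rate)
  lag <- estimate_stream_lag(session$imu_stream$accel[, 1], session$marker_y,
                             imu_rate = session$imu_stream$rate,
                             marker_rate = session$mocap_trace$rate)
  align_and_remove_offset(imu_tr, mc30, lag, rest_window = rest_window)
}
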