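#' Uniformly sampled body-segment angle trace
#'
#' The central time-series container: a scalar joint/segment angle (degrees)
#' sampled at a constant rate, tagged with the measuring system and the motor
#' task. Both the 100 Hz optoelectronic reference and the 30 Hz IMU-derived
#' traces are represented this way.
#'
#' @param values numeric vector of angle samples, degrees
#' @param rate sampling rate in Hz (30 for the IMU, 100 for motion capture)
#' @param t0 time of the first sample, seconds (default 0)
#' @param system `"IMU"` or `"MoCap"`
#' @param task_name motor-task label (free text; see [task_names()])
#' @return an object of class `angle_trace`
#' @export
#' @examples
#' tr <- angle_trace(sin(seq(0, 2 * pi, length.out = 90)), rate = 30)
#' tr
angle_trace <- function(values, rate, t0 = 0, system = c("IMU", "MoCap"),
                        task_name = NA_character_) {
  system <- match.arg(system)
  values <- as.numeric(values)
  if (length(values) < 1L) stop("angle_trace needs at least one sample")
  if (any(!is.finite(values))) stop("angle_trace values must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("rate must be a positive scalar (Hz)")
  }
  structure(
    list(values = values, rate = rate, t0 = t0,
         system = system, task_name = task_name),
    class = "angle_trace"
  )
}

#' @export
print.angle_trace <- function(x, ...) {
  cat(sprintf(
    "<angle_trace> %s%s: %d samples @ %g Hz (%.2f s), range [%.2f, %.2f] deg\n",
    x$system,
    if (is.na(x$task_name)) "" else paste0(" / ", x$task_name),
    length(x$values), x$rate, length(x$values) / x$rate,
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @export
length.angle_trace <- function(x) length(x$values)

#' Sample times of an angle trace
#' @param trace an [angle_trace]
#' @return numeric vector of sample times, seconds
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "angle_trace"))
  trace$t0 + (seq_along(trace$values) - 1) / trace$rate
}

#' 30 Hz device-style orientation stream
#'
#' Emulates the device's CSV export: time stamps, unit orientation
#' quaternions, and raw tri-axial accelerometer and gyroscope samples.
#'
#' @param t sample times, seconds (uniform)
#' @param quat `n x 4` matrix of unit quaternions `(w, x, y, z)`
#' @param accel `n x 3` matrix of accelerations (m/s^2), sensor frame
#' @param gyro `n x 3` matrix of angular rates (deg/s), sensor frame
#' @param rate sampling rate in Hz (default 30)
#' @param task_name motor-task label
#' @return an object of class `quat_stream`
#' @export
quat_stream <- function(t, quat, accel = NULL, gyro = NULL, rate = 30,
                        task_name = NA_character_) {
  quat <- as.matrix(quat)
  n <- length(t)
  if (nrow(quat) != n || ncol(quat) != 4L) {
    stop("quat must be an n x 4 matrix matching length(t)")
  }
  if (n >= 2 && any(diff(t) <= 0)) stop("time stamps must be strictly increasing")
  nrm <- sqrt(rowSums(quat^2))
  bad <- which(abs(nrm - 1) > 1e-6)
  if (length(bad)) {
    stop(sprintf("non-unit quaternion at row %d (|q| = %.6f)",
                 bad[1], nrm[bad[1]]))
  }
  if (is.null(accel)) accel <- matrix(0, n, 3)
  if (is.null(gyro)) gyro <- matrix(0, n, 3)
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  stopifnot(nrow(accel) == n, ncol(accel) == 3L,
            nrow(gyro) == n, ncol(gyro) == 3L)
  structure(
    list(t = as.numeric(t), quat = unname(quat), accel = unname(accel),
         gyro = unname(gyro), rate = rate, task_name = task_name),
    class = "quat_stream"
  )
}

#' @export
print.quat_stream <- function(x, ...) {
  cat(sprintf(
    "<quat_stream>%s: %d samples @ %g Hz (%.2f s)\n",
    if (is.na(x$task_name)) "" else paste0(" ", x$task_name),
    length(x$t), x$rate, length(x$t) / x$rate
  ))
  invisible(x)
}

#' @export
length.quat_stream <- function(x) length(x$t)
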