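#' Euler angle conversions under the two systems' conventions
#'
#' The IMU-based device extracts Euler angles from its orientation
#' quaternions with an intrinsic ZYX rotation sequence; the optoelectronic
#' reference software decomposes segment rotation matrices with an intrinsic
#' YXZ sequence. Both are implemented here, with the matrix-composition
#' round trips used as correctness oracles in the test suite.
#'
#' Angles are reported in degrees (the field's working unit); radians appear
#' only inside the trigonometry.
#'
#' @name euler-conversions
NULL

GIMBAL_LOCK_DEG <- 89.99

new_euler_angles <- function(angles_deg, sequence, gimbal_lock = FALSE) {
  names(angles_deg) <- strsplit(tolower(sequence), "")[[1]]
  structure(
    list(angles = angles_deg, sequence = sequence, gimbal_lock = gimbal_lock),
    class = "euler_angles"
  )
}

#' @export
print.euler_angles <- function(x, ...) {
  cat(sprintf("<euler_angles %s> %s%s\n", x$sequence,
              paste(sprintf("%s = %.3f", names(x$angles), x$angles),
                    collapse = ", "),
              if (x$gimbal_lock) "  [gimbal-lock proximity]" else ""))
  invisible(x)
}

#' Quaternion to intrinsic ZYX Euler angles
#'
#' Decomposes a unit quaternion as `Rz(z) %*% Ry(y) %*% Rx(x)` (intrinsic
#' Z-then-Y-then-X, i.e. yaw-pitch-roll). Under the device's convention the
#' first (Z) angle is the flexion/extension component, the middle (Y) angle
#' internal/external rotation, and the last (X) angle adduction/abduction.
#'
#' @param q unit quaternion `(w, x, y, z)`; norm must be within `tol` of 1
#' @param tol unit-norm tolerance (default 1e-6)
#' @return an `euler_angles` object with angles in degrees and a
#'   `gimbal_lock` flag set when the middle angle is within 0.01 degrees of
#'   +/-90 (where the outer angles become degenerate)
#' @export
#' @examples
#' quat_to_euler_zyx(quat_about_axis(90, "z"))
quat_to_euler_zyx <- function(q, tol = 1e-6) {
  assert_unit_quat(q, tol)
  q <- q / quat_norm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  sin_y <- 2 * (w * y - z * x)
  sin_y <- min(1, max(-1, sin_y))
  pitch <- asin(sin_y)
  lock <- abs(rad2deg(pitch)) > GIMBAL_LOCK_DEG
  if (lock) {
    # outer angles degenerate: fix roll = 0, attribute the rest to yaw
    roll <- 0
    yaw <- atan2(sign(sin_y) * 2 * (y * z - w * x), 1 - 2 * (x^2 + z^2))
  } else {
    yaw <- atan2(2 * (w * z + x * y), 1 - 2 * (y^2 + z^2))
    roll <- atan2(2 * (w * x + y * z), 1 - 2 * (x^2 + y^2))
  }
  new_euler_angles(rad2deg(c(yaw, pitch, roll)), "ZYX", lock)
}

#' Intrinsic ZYX Euler angles to quaternion
#'
#' Inverse of [quat_to_euler_zyx()]; round trips are exact up to the q/-q
#' sign ambiguity away from gimbal lock.
#'
#' @param z,y,x angles in degrees (applied in intrinsic Z, Y, X order)
#' @return unit quaternion `(w, x, y, z)`
#' @export
euler_zyx_to_quat <- function(z, y, x) {
  q <- quat_multiply(quat_about_axis(z, "z"),
                     quat_multiply(quat_about_axis(y, "y"),
                                   quat_about_axis(x, "x")))
  q / quat_norm(q)
}

#' Rotation matrix to intrinsic YXZ Euler angles
#'
#' Decomposes a proper rotation matrix as `Ry(y) %*% Rx(x) %*% Rz(z)`, the
#' reference system's sequence: the first (Y) angle is flexion/extension,
#' the middle (X) angle adduction/abduction, the last (Z) angle
#' internal/external rotation.
#'
#' @param m 3x3 proper orthogonal matrix (checked: orthogonality and
#'   `det = +1` within `tol`)
#' @param tol orthogonality tolerance (default 1e-9)
#' @return an `euler_angles` object, degrees
#' @export
rotmat_to_euler_yxz <- function(m, tol = 1e-9) {
  assert_rotation_matrix(m, tol)
  sin_x <- -m[2, 3]
  sin_x <- min(1, max(-1, sin_x))
  bx <- asin(sin_x)
  lock <- abs(rad2deg(bx)) > GIMBAL_LOCK_DEG
  if (lock) {
    ay <- atan2(-m[3, 1], m[1, 1])
    cz <- 0
  } else {
    ay <- atan2(m[1, 3], m[3, 3])
    cz <- atan2(m[2, 1], m[2, 2])
  }
  new_euler_angles(rad2deg(c(ay, bx, cz)), "YXZ", lock)
}

#' Intrinsic YXZ Euler angles to rotation matrix
#'
#' @param y,x,z angles in degrees (applied in intrinsic Y, X, Z order)
#' @return 3x3 rotation matrix
#' @export
euler_yxz_to_rotmat <- function(y, x, z) {
  rot_axis_mat(y, "y") %*% rot_axis_mat(x, "x") %*% rot_axis_mat(z, "z")
}

#' Single-axis rotation matrix
#' @param angle_deg angle in degrees
#' @param axis `"x"`, `"y"` or `"z"`
#' @return 3x3 rotation matrix
#' @export
rot_axis_mat <- function(angle_deg, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  a <- deg2rad(angle_deg); ca <- cos(a); sa <- sin(a)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, ca, -sa, 0, sa, ca), 3, byrow = TRUE),
    y = matrix(c(ca, 0, sa, 0, 1, 0, -sa, 0, ca), 3, byrow = TRUE),
    z = matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, byrow = TRUE)
  )
}

#' Extract an absolute segment-angle trace from an orientation stream
#'
#' Converts each quaternion of a 30 Hz stream to intrinsic ZYX Euler angles
#' and returns the scalar component about `plane_axis` as an [angle_trace].
#' For the predominantly uniplanar tasks in scope this is the absolute
#' body-segment angle in the task's motion plane. Sign flips q -> -q leave
#' the result unchanged. Samples flagged for gimbal-lock proximity carry the
#' last well-defined angle forward.
#'
#' @param stream a [quat_stream]
#' @param plane_axis which Euler component to extract: `"z"` (default,
#'   flexion/extension under the ZYX convention), `"y"` or `"x"`
#' @return an [angle_trace] at the stream's rate, degrees, tagged `"IMU"`
#' @export
segment_angle_trace <- function(stream, plane_axis = c("z", "y", "x")) {
  stopifnot(inherits(stream, "quat_stream"))
  plane_axis <- match.arg(plane_axis)
  n <- length(stream$t)
  if (n == 0L) stop("empty orientation stream")
  out <- numeric(n)
  last_ok <- 0
  for (i in seq_len(n)) {
    e <- quat_to_euler_zyx(stream$quat[i, ])
    v <- unname(e$angles[plane_axis])
    if (e$gimbal_lock && plane_axis != "y") {
      v <- last_ok
    } else {
      last_ok <- v
    }
    out[i] <- v
  }
  angle_trace(out, rate = stream$rate, t0 = stream$t[1], system = "IMU",
              task_name = stream$task_name)
}
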