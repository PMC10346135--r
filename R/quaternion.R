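#' Quaternion utilities
#'
#' Unit quaternions are stored as length-4 numeric vectors `c(w, x, y, z)`
#' (scalar first). Streams store one quaternion per row of an `n x 4` matrix.
#' `q` and `-q` encode the same orientation; all angle-extraction code in the
#' package is invariant under that sign flip.
#'
#' @name quaternion-utils
#' @keywords internal
NULL

quat_norm <- function(q) sqrt(sum(q^2))

#' Check a quaternion is unit length
#' @param q numeric length-4 `(w, x, y, z)`
#' @param tol allowed deviation of the norm from 1
#' @keywords internal
assert_unit_quat <- function(q, tol = 1e-6) {
  if (!is.numeric(q) || length(q) != 4L || any(!is.finite(q))) {
    stop("quaternion must be a finite numeric vector of length 4 (w, x, y, z)")
  }
  nrm <- quat_norm(q)
  if (abs(nrm - 1) > tol) {
    stop(sprintf("quaternion is not unit length (|q| = %.6f)", nrm))
  }
  invisible(q)
}

#' Hamilton product of two quaternions
#' @param a,b quaternions `(w, x, y, z)`
#' @return the product `a * b`
#' @export
quat_multiply <- function(a, b) {
  c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Quaternion for a rotation about a coordinate axis
#'
#' @param angle_deg rotation angle in degrees
#' @param axis one of `"x"`, `"y"`, `"z"`
#' @return unit quaternion `(w, x, y, z)`
#' @export
quat_about_axis <- function(angle_deg, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  half <- angle_deg * pi / 360
  v <- c(x = 0, y = 0, z = 0)
  v[axis] <- sin(half)
  c(cos(half), unname(v))
}

#' Convert a unit quaternion to a rotation matrix
#' @param q unit quaternion `(w, x, y, z)`
#' @return 3x3 proper orthogonal matrix
#' @export
quat_to_rotmat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Convert a rotation matrix to a unit quaternion (Shepperd's method)
#' @param m 3x3 proper orthogonal matrix
#' @return unit quaternion with non-negative scalar part
#' @keywords internal
rotmat_to_quat <- function(m) {
  assert_rotation_matrix(m)
  tr <- m[1, 1] + m[2, 2] + m[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (m[3, 2] - m[2, 3]) / s,
           (m[1, 3] - m[3, 1]) / s,
           (m[2, 1] - m[1, 2]) / s)
  } else if (m[1, 1] > m[2, 2] && m[1, 1] > m[3, 3]) {
    s <- sqrt(1 + m[1, 1] - m[2, 2] - m[3, 3]) * 2
    q <- c((m[3, 2] - m[2, 3]) / s, 0.25 * s,
           (m[1, 2] + m[2, 1]) / s, (m[1, 3] + m[3, 1]) / s)
  } else if (m[2, 2] > m[3, 3]) {
    s <- sqrt(1 + m[2, 2] - m[1, 1] - m[3, 3]) * 2
    q <- c((m[1, 3] - m[3, 1]) / s, (m[1, 2] + m[2, 1]) / s,
           0.25 * s, (m[2, 3] + m[3, 2]) / s)
  } else {
    s <- sqrt(1 + m[3, 3] - m[1, 1] - m[2, 2]) * 2
    q <- c((m[2, 1] - m[1, 2]) / s, (m[1, 3] + m[3, 1]) / s,
           (m[2, 3] + m[3, 2]) / s, 0.25 * s)
  }
  q <- q / quat_norm(q)
  if (q[1] < 0) q <- -q
  q
}

#' Validate a proper rotation matrix
#' @param m candidate matrix
#' @param tol orthogonality / determinant tolerance
#' @keywords internal
assert_rotation_matrix <- function(m, tol = 1e-9) {
  if (!is.matrix(m) || !all(dim(m) == c(3L, 3L)) || any(!is.finite(m))) {
    stop("expected a finite 3x3 matrix")
  }
  if (max(abs(crossprod(m) - diag(3))) > max(tol, 1e-9) * 10 ||
      abs(det(m) - 1) > max(tol, 1e-9) * 10) {
    stop("matrix is not a proper rotation (orthogonal, det = +1)")
  }
  invisible(m)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
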