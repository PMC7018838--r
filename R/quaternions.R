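# Minimal quaternion utilities for head orientation. Quaternions are stored
# row-wise as (w, x, y, z), scalar first, and represent rotations of world
# vectors (active convention): v_world = R(q) v_head.

#' Normalize quaternion rows
#'
#' @param q numeric matrix with columns (w, x, y, z).
#' @return matrix of unit quaternions.
#' @keywords internal
quat_normalize <- function(q) {
  q <- as.matrix(q)
  n <- sqrt(rowSums(q^2))
  if (any(n < 1e-12)) stop("zero-norm quaternion")
  q / n
}

#' Rotate vectors by quaternions
#'
#' Applies `R(q[i, ]) %*% v[i, ]` row-wise without forming rotation matrices.
#'
#' @param q n x 4 matrix of unit quaternions (w, x, y, z).
#' @param v n x 3 matrix of vectors.
#' @return n x 3 matrix of rotated vectors.
#' @export
quat_rotate <- function(q, v) {
  q <- as.matrix(q); v <- as.matrix(v)
  if (nrow(q) != nrow(v)) stop("quaternion and vector counts differ")
  w <- q[, 1]; u <- q[, 2:4, drop = FALSE]
  # v' = v + 2 w (u x v) + 2 u x (u x v)
  uv <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  uuv <- cbind(u[, 2] * uv[, 3] - u[, 3] * uv[, 2],
               u[, 3] * uv[, 1] - u[, 1] * uv[, 3],
               u[, 1] * uv[, 2] - u[, 2] * uv[, 1])
  v + 2 * w * uv + 2 * uuv
}

#' Quaternion conjugate
#' @param q n x 4 quaternion matrix.
#' @keywords internal
quat_conjugate <- function(q) {
  q <- as.matrix(q)
  cbind(q[, 1], -q[, 2:4, drop = FALSE])
}

#' Hamilton product of quaternion rows
#' @param a,b n x 4 quaternion matrices.
#' @keywords internal
quat_multiply <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  cbind(a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
        a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
        a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
        a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1])
}

#' Axis-angle to quaternion
#'
#' @param axis length-3 axis (need not be unit) or n x 3 matrix.
#' @param angle rotation angle(s) in radians, right-handed about `axis`.
#' @return n x 4 quaternion matrix.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- matrix(axis, ncol = 3)
  if (nrow(axis) == 1 && length(angle) > 1)
    axis <- axis[rep(1, length(angle)), , drop = FALSE]
  n <- sqrt(rowSums(axis^2))
  n[n < 1e-15] <- 1
  u <- axis / n
  cbind(cos(angle / 2), u * sin(angle / 2))
}

#' Rotation angle between consecutive quaternions
#'
#' @param q1,q2 quaternion matrices of equal size.
#' @return rotation angle in radians of the relative rotation, in [0, pi].
#' @keywords internal
quat_angle <- function(q1, q2) {
  d <- abs(rowSums(as.matrix(q1) * as.matrix(q2)))
  2 * acos(pmin(1, d))
}

#' Spherical linear interpolation of a quaternion time series
#'
#' Resamples head orientations onto a new time base, e.g. to bring a 100 Hz
#' IMU stream onto 120 Hz eye-tracker timestamps before the velocity
#' pipeline. Interpolation is geodesic (slerp) between bracketing samples;
#' query times outside the source range are clamped to the endpoints.
#'
#' @param q n x 4 matrix of unit quaternions.
#' @param t_from source timestamps, strictly increasing, length n.
#' @param t_to query timestamps.
#' @return length(t_to) x 4 matrix of unit quaternions.
#' @export
quat_slerp <- function(q, t_from, t_to) {
  q <- quat_normalize(q)
  if (nrow(q) != length(t_from)) stop("timestamps do not match quaternions")
  idx <- findInterval(t_to, t_from, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(t_from) - 1L)
  q0 <- q[idx, , drop = FALSE]
  q1 <- q[idx + 1L, , drop = FALSE]
  u <- (t_to - t_from[idx]) / (t_from[idx + 1L] - t_from[idx])
  u <- pmin(pmax(u, 0), 1)
  # take the short arc
  d <- rowSums(q0 * q1)
  q1[d < 0, ] <- -q1[d < 0, , drop = FALSE]
  d <- abs(d)
  theta <- acos(pmin(1, d))
  s <- sin(theta)
  w0 <- ifelse(s < 1e-8, 1 - u, sin((1 - u) * theta) / s)
  w1 <- ifelse(s < 1e-8, u, sin(u * theta) / s)
  quat_normalize(w0 * q0 + w1 * q1)
}

#' Intrinsic Z-Y-X Euler angles (degrees) to quaternions
#'
#' Convention used by common IMU exports: yaw about world z (up), then pitch
#' about the intermediate y, then roll about the new x.
#'
#' @param yaw,pitch,roll angles in degrees (vectors of equal length).
#' @return n x 4 quaternion matrix.
#' @export
quat_from_euler <- function(yaw, pitch, roll = 0) {
  d2r <- pi / 180
  qz <- quat_from_axis_angle(c(0, 0, 1), yaw * d2r)
  qy <- quat_from_axis_angle(c(0, 1, 0), pitch * d2r)
  qx <- quat_from_axis_angle(c(1, 0, 0), rep(roll, length.out = length(yaw)) * d2r)
  quat_multiply(quat_multiply(qz, qy), qx)
}
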