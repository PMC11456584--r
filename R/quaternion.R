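#' Quaternion utilities
#'
#' Unit quaternions in Hamilton convention, stored as length-4 numeric
#' vectors \code{c(w, x, y, z)} (or n x 4 matrices for time series). A
#' quaternion \code{q} represents the rotation taking sensor-frame vectors
#' into the world frame: \code{v_world = R(q) \%*\% v_sensor}.
#'
#' @name quaternion
#' @keywords internal
NULL

quat_normalize <- function(q) {
  if (is.matrix(q)) {
    n <- sqrt(rowSums(q^2))
    q / n
  } else {
    q / sqrt(sum(q^2))
  }
}

quat_conjugate <- function(q) {
  if (is.matrix(q)) {
    q[, 2:4] <- -q[, 2:4]
    q
  } else {
    c(q[1], -q[2], -q[3], -q[4])
  }
}

#' Hamilton product of two quaternions
#' @param a,b length-4 quaternions \code{c(w, x, y, z)}
#' @return length-4 quaternion \code{a \%*\% b}
#' @keywords internal
quat_multiply <- function(a, b) {
  c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

# rotation of `angle` radians about unit `axis`
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

# exponential map: rotation vector (axis * angle, radians) -> quaternion
quat_exp <- function(rv) {
  theta <- sqrt(sum(rv^2))
  if (theta < 1e-12) {
    quat_normalize(c(1, rv / 2))
  } else {
    c(cos(theta / 2), sin(theta / 2) * rv / theta)
  }
}

# log map: quaternion -> rotation vector (axis * angle, radians)
quat_log <- function(q) {
  q <- quat_normalize(q)
  if (q[1] < 0) q <- -q
  v <- q[2:4]
  s <- sqrt(sum(v^2))
  if (s < 1e-12) return(c(0, 0, 0))
  2 * atan2(s, q[1]) * v / s
}

#' Convert a unit quaternion to a rotation matrix
#'
#' @param q unit quaternion \code{c(w, x, y, z)}, Hamilton convention. Inputs
#'   within 1e-3 of unit norm are renormalized; anything further off is
#'   rejected.
#' @return 3 x 3 rotation matrix (orthonormal, determinant +1) mapping
#'   sensor-frame vectors into the world frame.
#' @examples
#' quat_to_rotmat(c(1, 0, 0, 0))           # identity
#' quat_to_rotmat(c(cos(pi / 4), 0, 0, sin(pi / 4)))  # 90 degrees about z
#' @export
quat_to_rotmat <- function(q) {
  stopifnot(is.numeric(q), length(q) == 4)
  n <- sqrt(sum(q^2))
  if (abs(n - 1) > 1e-3) {
    stop("quaternion is not unit norm (|q| = ", format(n), ")")
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# rotation matrix -> quaternion (Shepperd's method)
rotmat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  quat_normalize(q)
}

# rotate a sensor-frame vector into the world frame
quat_rotate <- function(q, v) {
  drop(quat_to_rotmat(q) %*% v)
}

# angular distance between two unit quaternions, degrees
quat_angle_deg <- function(a, b) {
  d <- abs(sum(a * b))
  2 * acos(min(1, d)) * 180 / pi
}
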