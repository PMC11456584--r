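#' Orientation traces and trunk compensation angles
#'
#' Chest-worn and table-reference IMUs sampled at 64 Hz are converted to unit
#' quaternions; the relative rotation between sensor and reference yields
#' forward-lean and leftward-bend angle traces at the hip, and compensation is
#' scored as the maximum absolute angle deviation within an attempt window.
#'
#' Axis conventions (fixed, documented): x anterior, y left, z up. Forward
#' lean is the intrinsic pitch (trunk vertical tilting anteriorly), leftward
#' bend the intrinsic roll (vertical tilting toward +y), extracted by applying
#' the relative rotation to the vertical unit vector.
#'
#' @name imu
NULL

#' Construct an orientation trace
#'
#' @param quaternions n x 4 matrix of unit quaternions \code{(w, x, y, z)},
#'   Hamilton convention, sensor-to-world
#' @param fs sampling rate, Hz
#' @param frame sensor identity label (\code{"chest"}, \code{"bicep"},
#'   \code{"reference"})
#' @return object of class \code{"orientation_trace"}
#' @export
orientation_trace <- function(quaternions, fs, frame = "chest") {
  quaternions <- as.matrix(quaternions)
  stopifnot(ncol(quaternions) == 4, fs > 0)
  norms <- sqrt(rowSums(quaternions^2))
  if (any(abs(norms - 1) > 1e-6)) {
    stop("quaternions must be unit norm within 1e-6")
  }
  structure(list(quaternions = quaternions, fs = fs, frame = frame),
            class = "orientation_trace")
}

#' @export
print.orientation_trace <- function(x, ...) {
  cat(sprintf("Orientation trace (%s): %d samples at %g Hz (%.2f s)\n",
              x$frame, nrow(x$quaternions), x$fs,
              nrow(x$quaternions) / x$fs))
  invisible(x)
}

# initial attitude from one accel + mag sample pair (TRIAD)
triad_init <- function(a, m, mag_world) {
  a <- a / sqrt(sum(a^2))
  m <- m / sqrt(sum(m^2))
  z_w <- c(0, 0, 1)
  w2 <- cross3(z_w, mag_world); w2 <- w2 / sqrt(sum(w2^2))
  w3 <- cross3(z_w, w2)
  s2 <- cross3(a, m)
  if (sum(s2^2) < 1e-12) return(c(1, 0, 0, 0))
  s2 <- s2 / sqrt(sum(s2^2))
  s3 <- cross3(a, s2)
  W <- cbind(z_w, w2, w3)
  S <- cbind(a, s2, s3)
  rotmat_to_quat(W %*% t(S))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# world-frame magnetic reference used by synthesis and fusion:
# horizontal component along +x (anterior), 60-degree inclination
.mag_world <- function() c(0.5, 0, -sqrt(3) / 2)

#' Complementary-filter orientation fusion
#'
#' Integrates the rate gyro and continuously corrects the attitude toward the
#' accelerometer gravity direction and magnetometer heading. The blend weight
#' \code{gyro_weight} (default 0.98) is the per-sample fraction of the
#' orientation carried by gyro integration; \code{1 - gyro_weight} scales the
#' accel/mag error feedback. The initial attitude is a TRIAD solution from the
#' first accel/mag sample. Accelerometer samples with (near-)zero norm
#' contribute no correction for that step.
#'
#' @param accel n x 3 accelerometer stream (specific force, m/s^2)
#' @param gyro n x 3 rate-gyro stream (rad/s, sensor frame)
#' @param mag n x 3 magnetometer stream (arbitrary units)
#' @param fs sampling rate, Hz
#' @param gyro_weight complementary blend weight in (0, 1)
#' @return an [orientation_trace()]
#' @export
fuse_imu <- function(accel, gyro, mag, fs, gyro_weight = 0.98) {
  accel <- as.matrix(accel); gyro <- as.matrix(gyro); mag <- as.matrix(mag)
  n <- nrow(accel)
  stopifnot(n >= 1, nrow(gyro) == n, nrow(mag) == n, fs > 0,
            gyro_weight > 0, gyro_weight < 1)
  dt <- 1 / fs
  kp <- 1 - gyro_weight
  mref <- .mag_world()
  q <- triad_init(accel[1, ], mag[1, ], mref)
  out <- matrix(0, n, 4)
  out[1, ] <- q
  for (k in seq_len(n - 1)) {
    # gyro prediction (sensor-frame rate, forward integration)
    q <- quat_multiply(q, quat_exp(gyro[k, ] * dt))
    R <- quat_to_rotmat(q)
    e <- c(0, 0, 0)
    a <- accel[k + 1, ]
    na <- sqrt(sum(a^2))
    if (na > 1e-6) {
      v_meas <- a / na
      v_pred <- R[3, ]                      # world z in sensor frame
      e <- e + cross3(v_meas, v_pred)
    }
    m <- mag[k + 1, ]
    nm <- sqrt(sum(m^2))
    if (nm > 1e-6) {
      m_meas <- m / nm
      b <- drop(R %*% m_meas)               # measured field, world frame
      b_ref <- c(sqrt(b[1]^2 + b[2]^2), 0, b[3])
      v_pred <- drop(t(R) %*% (b_ref / sqrt(sum(b_ref^2))))
      e <- e + cross3(m_meas, v_pred)
    }
    q <- quat_normalize(quat_multiply(q, quat_exp(kp * e)))
    out[k + 1, ] <- q
  }
  orientation_trace(out, fs, frame = "chest")
}

# third column of the rotation matrix for each quaternion row:
# image of the body vertical axis, vectorized
vertical_axis_image <- function(Q) {
  w <- Q[, 1]; x <- Q[, 2]; y <- Q[, 3]; z <- Q[, 4]
  cbind(2 * (x * z + w * y),
        2 * (y * z - w * x),
        1 - 2 * (x^2 + y^2))
}

# rowwise Hamilton product conj(A) * B for n x 4 matrices
quat_rel_rows <- function(A, B) {
  aw <- A[, 1]; ax <- -A[, 2]; ay <- -A[, 3]; az <- -A[, 4]
  bw <- B[, 1]; bx <- B[, 2]; by <- B[, 3]; bz <- B[, 4]
  cbind(aw * bw - ax * bx - ay * by - az * bz,
        aw * bx + ax * bw + ay * bz - az * by,
        aw * by - ax * bz + ay * bw + az * bx,
        aw * bz + ax * by - ay * bx + az * bw)
}

#' Forward-lean and leftward-bend angle traces
#'
#' Computes the relative rotation \code{R_rel = R_ref^-1 R_sensor} per frame,
#' applies it to the vertical unit vector, and extracts intrinsic pitch
#' (forward lean, vertical tilting anteriorly) and roll (leftward bend,
#' vertical tilting toward the left). The mean pose over the first
#' \code{baseline} seconds is subtracted from each angle trace so deviations
#' are relative to the attempt's starting posture. Frames with |lean| above
#' 85 degrees are gimbal-proximal and flagged with a warning.
#'
#' @param sensor an [orientation_trace()] for the chest sensor
#' @param reference an [orientation_trace()] for the fixed reference, or
#'   \code{NULL} for an identity reference
#' @param baseline baseline window, seconds (0 disables subtraction)
#' @return data frame with columns \code{time}, \code{lean}, \code{bend}
#'   (degrees)
#' @export
lean_bend_angles <- function(sensor, reference = NULL, baseline = 0.5) {
  stopifnot(inherits(sensor, "orientation_trace"))
  Q <- sensor$quaternions
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "orientation_trace"),
              nrow(reference$quaternions) == nrow(Q))
    Q <- quat_rel_rows(reference$quaternions, Q)
  }
  v <- vertical_axis_image(Q)
  lean <- atan2(v[, 1], v[, 3]) * 180 / pi
  bend <- asin(pmin(1, pmax(-1, v[, 2]))) * 180 / pi
  if (any(abs(lean) > 85)) {
    warning("gimbal-proximal poses: |forward lean| > 85 degrees")
  }
  if (baseline > 0) {
    nb <- max(1, min(nrow(Q), round(baseline * sensor$fs)))
    lean <- lean - mean(lean[seq_len(nb)])
    bend <- bend - mean(bend[seq_len(nb)])
  }
  data.frame(time = (seq_len(nrow(Q)) - 1) / sensor$fs,
             lean = lean, bend = bend)
}

#' Maximum absolute angle deviation within an attempt window
#'
#' @param angle numeric angle trace, degrees (already baseline-referenced)
#' @param window integer sample indices of the attempt; default whole trace
#' @return maximum of |angle| over the window, degrees (>= 0)
#' @export
max_abs_deviation <- function(angle, window = seq_along(angle)) {
  if (length(window) == 0) stop("empty attempt window")
  stopifnot(all(window >= 1), all(window <= length(angle)))
  max(abs(angle[window]))
}

#' Per-attempt compensation maxima
#'
#' Runs [lean_bend_angles()] and scores the maximum absolute forward lean and
#' leftward bend over the attempt window.
#'
#' @inheritParams lean_bend_angles
#' @param window sample indices of the attempt; default whole trace
#' @return named numeric vector \code{c(max_forward_lean, max_leftward_bend)}
#'   in degrees
#' @export
compensation_maxima <- function(sensor, reference = NULL, baseline = 0.5,
                                window = NULL) {
  ang <- lean_bend_angles(sensor, reference, baseline)
  if (is.null(window)) window <- seq_len(nrow(ang))
  c(max_forward_lean = max_abs_deviation(ang$lean, window),
    max_leftward_bend = max_abs_deviation(ang$bend, window))
}
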