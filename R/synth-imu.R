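#' Synthetic trunk orientation and raw IMU streams
#'
#' Each simulated attempt embeds one smooth forward-lean excursion and one
#' leftward-bend excursion (raised-cosine bumps of 1.5 s), with peak angles
#' drawn from the condition's Normal(mean, sd^2) truncated at 0 degrees. The
#' ground-truth peaks are stored alongside the quaternions so recovery through
#' the angle pipeline can be checked. Raw accelerometer / gyroscope /
#' magnetometer streams consistent with the orientation can be synthesized for
#' round-trip tests of the fusion filter.
#'
#' @name synth_imu
NULL

# raised-cosine bump: 0 -> peak -> 0 over [t0, t0 + dur]
raised_cosine_bump <- function(t, t0, dur, peak) {
  u <- (t - t0) / dur
  out <- numeric(length(t))
  in_bump <- u >= 0 & u <= 1
  out[in_bump] <- peak * 0.5 * (1 - cos(2 * pi * u[in_bump]))
  out
}

#' Generate synthetic trunk-orientation trials
#'
#' @param params a [condition_params()] object supplying the lean/bend peak
#'   distributions
#' @param n_trials number of attempts to simulate (>= 1)
#' @param config a [sim_config()]; supplies the IMU sampling rate
#' @param seed integer seed (default: the config seed)
#' @param trial_duration attempt duration, seconds
#' @return list of trials; each trial is a list with elements \code{sensor}
#'   and \code{reference} ([orientation_trace()] objects) and \code{truth}
#'   (list with \code{peak_lean}, \code{peak_bend}, and the noise-free
#'   \code{lean}/\code{bend} angle traces in degrees)
#' @export
generate_orientation_trace <- function(params, n_trials, config = sim_config(),
                                       seed = config$seed,
                                       trial_duration = 5) {
  stopifnot(inherits(params, "condition_params"), inherits(config, "sim_config"))
  if (n_trials < 1) stop("n_trials must be >= 1")
  fs <- config$imu_fs
  n <- round(trial_duration * fs)
  t <- (seq_len(n) - 1) / fs
  with_local_seed(seed, {
    lapply(seq_len(n_trials), function(i) {
      peak_lean <- rtruncnorm_lower(1, params$lean_mean, params$lean_sd, 0)
      peak_bend <- rtruncnorm_lower(1, params$bend_mean, params$bend_sd, 0)
      # excursions are separated in time; first 0.5 s stays at baseline
      lean <- raised_cosine_bump(t, 0.75, 1.5, peak_lean)
      bend <- raised_cosine_bump(t, 2.75, 1.5, peak_bend)
      Q <- matrix(0, n, 4)
      for (k in seq_len(n)) {
        # intrinsic pitch (about +y, forward) then roll (leftward: about -x)
        qp <- quat_from_axis_angle(c(0, 1, 0), lean[k] * pi / 180)
        qr <- quat_from_axis_angle(c(1, 0, 0), -bend[k] * pi / 180)
        Q[k, ] <- quat_multiply(qp, qr)
      }
      list(
        sensor = orientation_trace(quat_normalize(Q), fs, "chest"),
        reference = orientation_trace(
          matrix(rep(c(1, 0, 0, 0), n), ncol = 4, byrow = TRUE), fs,
          "reference"),
        truth = list(peak_lean = peak_lean, peak_bend = peak_bend,
                     lean = lean, bend = bend)
      )
    })
  })
}

#' Synthesize raw IMU streams from a ground-truth orientation
#'
#' Accelerometer samples are the rotated gravity vector (pure attitude, no
#' linear acceleration), the gyro is the finite-difference angular velocity of
#' the quaternion trace (sensor frame), and the magnetometer is the rotated
#' world magnetic reference; independent Gaussian noise is added per axis.
#'
#' @param trace an [orientation_trace()] holding the true orientation
#' @param accel_noise_sd accelerometer noise SD, m/s^2
#' @param gyro_noise_sd gyro noise SD, rad/s
#' @param mag_noise_sd magnetometer noise SD (field units)
#' @param seed integer seed for the noise draws
#' @param gravity gravitational acceleration, m/s^2
#' @return list with n x 3 matrices \code{accel}, \code{gyro}, \code{mag} and
#'   the sampling rate \code{fs}
#' @export
generate_raw_imu <- function(trace, accel_noise_sd = 0, gyro_noise_sd = 0,
                             mag_noise_sd = 0, seed = 1L, gravity = 9.81) {
  stopifnot(inherits(trace, "orientation_trace"))
  Q <- trace$quaternions
  n <- nrow(Q)
  fs <- trace$fs
  g_w <- c(0, 0, gravity)
  m_w <- .mag_world()
  accel <- matrix(0, n, 3)
  mag <- matrix(0, n, 3)
  gyro <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    R <- quat_to_rotmat(Q[k, ])
    accel[k, ] <- drop(t(R) %*% g_w)
    mag[k, ] <- drop(t(R) %*% m_w)
  }
  for (k in seq_len(n - 1)) {
    dq <- quat_multiply(quat_conjugate(Q[k, ]), Q[k + 1, ])
    gyro[k, ] <- quat_log(dq) * fs
  }
  if (n > 1) gyro[n, ] <- gyro[n - 1, ]
  with_local_seed(seed, {
    if (accel_noise_sd > 0) {
      accel <- accel + matrix(stats::rnorm(3 * n, 0, accel_noise_sd), n, 3)
    }
    if (gyro_noise_sd > 0) {
      gyro <- gyro + matrix(stats::rnorm(3 * n, 0, gyro_noise_sd), n, 3)
    }
    if (mag_noise_sd > 0) {
      mag <- mag + matrix(stats::rnorm(3 * n, 0, mag_noise_sd), n, 3)
    }
    list(accel = accel, gyro = gyro, mag = mag, fs = fs)
  })
}
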