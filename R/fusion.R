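# Complementary-filter sensor fusion and neutral-pose calibration.
#
# Orientation is propagated by integrating the gyroscope and continuously
# corrected toward the accelerometer-derived gravity direction (tilt) and the
# magnetometer-derived heading (yaw). A single gain sets the correction
# bandwidth; the filter is deterministic and adequate for the slow head
# motions of a seated tracking task.

#' Fusion filter parameters
#'
#' @param gain unitless blend factor in \[0, 1\]: the fraction of the
#'   measured attitude error corrected at each sample. At sample rate `f`
#'   the correction time constant is roughly `1 / (gain * f)` seconds.
#' @param sample_rate nominal sampling rate in Hz (> 0). Timestamps are
#'   carried explicitly, so the filter works at any actual rate; this value
#'   is used for configuration bookkeeping only.
#' @param mag_enabled use the magnetometer for heading correction. When
#'   `FALSE`, yaw is stabilized by the gyroscope alone.
#' @return an object of class `fusion_params`.
#' @export
fusion_params <- function(gain = 0.02, sample_rate = 50, mag_enabled = TRUE) {
  if (!is.numeric(gain) || length(gain) != 1L || gain < 0 || gain > 1)
    abort_validation("gain must be a single number in [0, 1]")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    abort_validation("sample_rate must be a single positive number")
  structure(list(gain = gain, sample_rate = sample_rate,
                 mag_enabled = isTRUE(mag_enabled)),
            class = "fusion_params")
}

# TRIAD-style absolute attitude from one accel + mag sample.
# accel gives -Z_world in head coords (gravity), mag gives X_world (north);
# the mag component along gravity is removed before orthonormalization.
triad_attitude <- function(accel, mag = NULL) {
  up_h <- accel / sqrt(sum(accel^2))       # world +Z expressed in head frame
  if (is.null(mag)) {
    # tilt only: pick any horizontal reference, yaw is arbitrary (set to 0
    # by aligning the projection of head X)
    north_h <- c(1, 0, 0) - sum(c(1, 0, 0) * up_h) * up_h
    if (sqrt(sum(north_h^2)) < 1e-8) north_h <- c(0, 1, 0) - sum(c(0, 1, 0) * up_h) * up_h
  } else {
    north_h <- mag - sum(mag * up_h) * up_h
  }
  nn <- sqrt(sum(north_h^2))
  if (nn < 1e-8) return(diag(3))
  north_h <- north_h / nn
  # rows = world axes expressed in head coordinates (right-handed:
  # Y = Z x X); this matrix maps head-frame vectors to world coordinates
  R <- rbind(north_h, cross3(up_h, north_h), up_h)
  dimnames(R) <- NULL
  project_so3(R)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Fuse an IMU stream into an orientation time series
#'
#' Complementary filter: the orientation is initialized from the first
#' accelerometer/magnetometer sample, propagated between samples by the
#' gyroscope (exact exponential-map integration of the measured rate), and
#' corrected at every sample by a fraction `gain` of (a) the tilt error
#' between the predicted and measured gravity direction and (b) the heading
#' error between the predicted and measured horizontal magnetic field.
#'
#' @param stream an [imu_stream()].
#' @param params a [fusion_params()].
#' @return an object of class `orientation_series`: a list with `t` (seconds)
#'   and `dcm`, a `3 x 3 x n` array of head-to-world DCMs.
#' @seealso [as_euler()] to extract YZX angles, [calibrate_neutral()].
#' @export
fuse_imu <- function(stream, params = fusion_params()) {
  if (!inherits(stream, "imu_stream")) stream <- as_imu_stream(stream)
  n <- nrow(stream)
  if (n == 0L) abort_validation("empty IMU stream")
  if (n > 1L && any(diff(stream$t) <= 0))
    abort_validation("IMU timestamps must be strictly increasing")
  g <- params$gain
  gyro <- cbind(stream$gx, stream$gy, stream$gz)
  acc <- cbind(stream$ax, stream$ay, stream$az)
  mag <- cbind(stream$mx, stream$my, stream$mz)

  out <- array(NA_real_, c(3, 3, n))
  R <- triad_attitude(acc[1, ], if (params$mag_enabled) mag[1, ] else NULL)
  out[, , 1] <- R
  if (n == 1L) return(structure(list(t = stream$t, dcm = out), class = "orientation_series"))

  for (k in 2:n) {
    dt <- stream$t[k] - stream$t[k - 1]
    # gyro propagation (rate held over [t_{k-1}, t_k))
    R <- R %*% rotvec_to_dcm(gyro[k - 1, ] * dt)
    # tilt correction toward measured gravity
    a <- acc[k, ]
    an <- sqrt(sum(a^2))
    if (an > 1e-6) {
      m_meas <- a / an
      p_pred <- as.numeric(crossprod(R, c(0, 0, 1)))  # R^T e3
      ax <- cross3(p_pred, m_meas)
      s <- sqrt(sum(ax^2))
      if (s > 1e-12) {
        ang <- atan2(s, sum(p_pred * m_meas)) * RAD2DEG
        R <- R %*% rot_axis_angle(ax, -g * ang)
      }
    }
    # heading correction toward magnetic north (world-frame yaw)
    if (params$mag_enabled) {
      m_w <- as.numeric(R %*% mag[k, ])
      if (m_w[1]^2 + m_w[2]^2 > 1e-12) {
        psi <- atan2(m_w[2], m_w[1]) * RAD2DEG
        R <- rot_z(-g * psi) %*% R
      }
    }
    if (k %% 256L == 0L) R <- project_so3(R)
    out[, , k] <- R
  }
  structure(list(t = stream$t, dcm = out), class = "orientation_series")
}

#' @export
print.orientation_series <- function(x, ...) {
  cat(sprintf("<orientation_series> %d orientations, t in [%.2f, %.2f] s\n",
              length(x$t), min(x$t), max(x$t)))
  invisible(x)
}

#' Extract YZX Euler angles from an orientation series
#'
#' @param series an `orientation_series` from [fuse_imu()].
#' @return a data frame with columns `t, alpha, rot, incl` (degrees).
#' @export
as_euler <- function(series) {
  n <- length(series$t)
  out <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    e <- decompose_yzx(series$dcm[, , k])
    out[k, ] <- c(e$alpha, e$rot, e$incl)
  }
  data.frame(t = series$t, alpha = out[, 1], rot = out[, 2], incl = out[, 3])
}

#' Neutral-pose calibration
#'
#' Estimates the calibration DCM `R_cal` (the orientation in neutral,
#' upright posture) from a stream in which the subject holds still: the
#' stream is fused, the orientations in the trailing `window_s` seconds are
#' averaged with the chordal mean, and the result is re-orthonormalized. If
#' the head moved by more than `max_motion_deg` from the mean during the
#' window the calibration is rejected.
#'
#' @param stream an [imu_stream()] spanning at least `window_s` seconds.
#' @param params a [fusion_params()].
#' @param window_s averaging window in seconds (default 2, the hold time
#'   asked of the subject).
#' @param max_motion_deg maximum angular deviation from the window mean
#'   tolerated before calibration fails (degrees).
#' @return a [rotation_state()]: the calibration rotation `R_cal`.
#' @export
calibrate_neutral <- function(stream, params = fusion_params(), window_s = 2,
                              max_motion_deg = 5) {
  if (!inherits(stream, "imu_stream")) stream <- as_imu_stream(stream)
  span <- diff(range(stream$t))
  if (span < window_s)
    abort_validation(sprintf(
      "calibration stream spans %.2f s, shorter than the %.2f s window", span, window_s))
  series <- fuse_imu(stream, params)
  keep <- series$t >= max(series$t) - window_s
  mean_rot <- rotation_mean(series$dcm[, , keep, drop = FALSE])
  dev <- vapply(which(keep), function(k) rotation_angle(series$dcm[, , k], mean_rot),
                numeric(1))
  if (max(dev) > max_motion_deg)
    abort_validation(sprintf(
      "calibration failed: head moved %.1f deg during the window (limit %.1f deg)",
      max(dev), max_motion_deg))
  mean_rot
}
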