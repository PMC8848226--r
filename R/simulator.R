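# Synthetic-user module: simulated head kinematics of a target-pursuit user
# and the raw IMU signals that motion would produce. This is the package's
# data generator — every other module can be exercised end-to-end without
# hardware.
#
# The user model: after a reaction delay from each target spawn the head
# angles approach the target's required angles along a rate-limited
# first-order path (time constant `time_constant`); an Ornstein-Uhlenbeck
# motor-noise process (stationary sd `motor_noise_sd`, correlation time
# `noise_corr_time`) rides on top, so aiming errors persist long enough to
# cause real misses. Session-to-session learning multiplies the noise sd by
# `learning_rate` each session.

#' Simulated-user model
#'
#' Default values describe an older adult doing the seated tracking task at
#' the pilot's easy difficulty: ~0.4 s reaction time, a comfortable
#' 60 deg/s cervical speed cap, and a motor-noise level chosen so that the
#' first session scores roughly 69% under the default protocol, rising with
#' practice.
#'
#' @param reaction_delay seconds between a target spawn and the start of its
#'   pursuit.
#' @param max_angular_speed angular speed cap, deg/s (`Inf` allowed).
#' @param motor_noise_sd stationary sd of the motor-noise process, degrees.
#' @param hit_commitment probability that a given target is pursued at all.
#' @param learning_rate multiplicative per-session reduction of
#'   `motor_noise_sd` (1 = no learning).
#' @param time_constant pursuit time constant, seconds.
#' @param noise_corr_time correlation time of the motor-noise process,
#'   seconds: how long an aiming error persists before being re-drawn.
#' @return an object of class `user_model`.
#' @export
user_model <- function(reaction_delay = 0.4, max_angular_speed = 60,
                       motor_noise_sd = 9, hit_commitment = 1,
                       learning_rate = 0.88, time_constant = 0.3,
                       noise_corr_time = 2) {
  vals <- c(reaction_delay = reaction_delay, motor_noise_sd = motor_noise_sd,
            learning_rate = learning_rate, time_constant = time_constant)
  if (any(vals < 0) || max_angular_speed < 0)
    abort_validation("user model parameters must be non-negative")
  if (hit_commitment < 0 || hit_commitment > 1)
    abort_validation("hit_commitment must be in [0, 1]")
  if (time_constant <= 0)
    abort_validation("time_constant must be positive")
  if (noise_corr_time < 0)
    abort_validation("noise_corr_time must be non-negative")
  structure(list(reaction_delay = reaction_delay,
                 max_angular_speed = max_angular_speed,
                 motor_noise_sd = motor_noise_sd,
                 hit_commitment = hit_commitment,
                 learning_rate = learning_rate,
                 time_constant = time_constant,
                 noise_corr_time = noise_corr_time),
            class = "user_model")
}

#' IMU noise model
#'
#' Gaussian sensor noise, uncorrelated across axes; the gyroscope bias is
#' drawn once per stream and held constant. Defaults are typical consumer
#' MEMS figures.
#'
#' @param gyro_sd gyroscope white-noise sd, deg/s.
#' @param gyro_bias sd of the constant per-stream gyroscope bias, deg/s.
#' @param accel_sd accelerometer noise sd, g.
#' @param mag_sd magnetometer noise sd (normalized units).
#' @return an object of class `imu_noise`.
#' @export
imu_noise <- function(gyro_sd = 0.3, gyro_bias = 0.2, accel_sd = 0.01,
                      mag_sd = 0.01) {
  v <- c(gyro_sd, gyro_bias, accel_sd, mag_sd)
  if (any(v < 0)) abort_validation("noise parameters must be non-negative")
  structure(list(gyro_sd = gyro_sd, gyro_bias = gyro_bias,
                 accel_sd = accel_sd, mag_sd = mag_sd),
            class = "imu_noise")
}

#' Simulate a user's angular pursuit of a target schedule
#'
#' Produces the ground-truth head-angle trajectory of a simulated user
#' playing one session: for each target, after `reaction_delay` from its
#' spawn, the flexion-extension and horizontal driving angles approach the
#' target's required angles (first-order, rate-limited), with persistent
#' motor noise added. Axial rotation is held at 0 (the horizontal axis is
#' driven by whichever motion `cfg$horizontal_source` names).
#'
#' @param targets a [generate_targets()] schedule.
#' @param user a [user_model()].
#' @param cfg a [mapping_config()] (defines the angle-to-screen geometry the
#'   user is implicitly playing against).
#' @param rate sampling rate, Hz.
#' @param duration trajectory length in seconds; defaults to the schedule's
#'   last deadline.
#' @return a data frame with columns `t, alpha, rot, incl` (degrees):
#'   `alpha` is flexion-extension; the horizontal driving angle is stored in
#'   `incl` or (sign-flipped) `rot` per `cfg$horizontal_source`.
#' @export
simulate_pursuit <- function(targets, user, cfg, rate = 50,
                             duration = max(targets$deadline_t)) {
  stopifnot(inherits(user, "user_model"), inherits(cfg, "mapping_config"))
  if (nrow(targets) == 0L) abort_validation("no targets scheduled")
  dt <- 1 / rate
  t <- seq(0, duration, by = dt)
  # commitment: decide once per target whether it is pursued at all
  committed <- if (user$hit_commitment >= 1) rep(TRUE, nrow(targets))
               else runif(nrow(targets)) < user$hit_commitment
  # active target per sample: latest spawned, shifted by the reaction delay
  idx <- findInterval(t - user$reaction_delay, targets$spawn_t)
  tgt_a <- ifelse(idx >= 1 & committed[pmax(idx, 1)], targets$alpha[pmax(idx, 1)], NA_real_)
  tgt_b <- ifelse(idx >= 1 & committed[pmax(idx, 1)], targets$beta[pmax(idx, 1)], NA_real_)
  ang <- pursuit_core(tgt_a, tgt_b, dt, user$time_constant,
                      user$max_angular_speed, user$motor_noise_sd,
                      user$noise_corr_time)
  out <- data.frame(t = t, alpha = ang[, 1], rot = 0, incl = 0)
  if (cfg$horizontal_source == "inclination") out$incl <- ang[, 2]
  else out$rot <- -ang[, 2]  # beta = -rot for rotation control
  out
}

#' Synthesize raw IMU signals from an angle trajectory
#'
#' Inverse of the fusion step: per-sample DCMs are built from the Euler
#' trajectory; the gyroscope reading is the axis-angle rate of the relative
#' rotation between consecutive samples (head frame, deg/s) plus a constant
#' bias and white noise; the accelerometer is gravity rotated into the head
#' frame plus noise; the magnetometer is the north reference rotated into
#' the head frame plus noise.
#'
#' @param trajectory a data frame with columns `t, alpha, rot, incl`
#'   (degrees), monotone in `t`, at least 2 rows.
#' @param noise an [imu_noise()].
#' @return an [imu_stream()].
#' @export
synthesize_imu <- function(trajectory, noise = imu_noise()) {
  need <- c("t", "alpha", "rot", "incl")
  if (!all(need %in% names(trajectory)))
    abort_validation("trajectory must have columns t, alpha, rot, incl")
  n <- nrow(trajectory)
  if (n < 2L) abort_validation("trajectory needs at least 2 samples")
  if (any(diff(trajectory$t) <= 0))
    abort_validation("trajectory timestamps must be strictly increasing")

  dcms <- vector("list", n)
  for (k in seq_len(n))
    dcms[[k]] <- (compose_yzx(trajectory$alpha[k], trajectory$rot[k],
                              trajectory$incl[k]))$dcm
  gyro <- matrix(0, n, 3)
  for (k in seq_len(n - 1)) {
    dt <- trajectory$t[k + 1] - trajectory$t[k]
    w <- dcm_to_rotvec(crossprod(dcms[[k]], dcms[[k + 1]]))  # head-frame, deg
    gyro[k, ] <- w / dt
  }
  gyro[n, ] <- gyro[n - 1, ]
  accel <- t(vapply(dcms, function(R) as.numeric(crossprod(R, c(0, 0, 1))), numeric(3)))
  mag <- t(vapply(dcms, function(R) as.numeric(crossprod(R, c(1, 0, 0))), numeric(3)))

  bias <- rnorm(3, 0, noise$gyro_bias)
  gyro <- gyro + matrix(bias, n, 3, byrow = TRUE) +
    matrix(rnorm(3 * n, 0, noise$gyro_sd), n, 3)
  accel <- accel + matrix(rnorm(3 * n, 0, noise$accel_sd), n, 3)
  mag <- mag + matrix(rnorm(3 * n, 0, noise$mag_sd), n, 3)
  imu_stream(trajectory$t, gyro, accel, mag)
}

#' Simulate a multi-session treatment protocol
#'
#' Runs `n_sessions` game sessions for one simulated user. Learning is
#' modeled as a multiplicative decay of the motor-noise sd: session `s`
#' uses `motor_noise_sd * learning_rate^(s-1)`. Each session draws a fresh
#' target schedule and pursuit realization from the ambient RNG stream, so
#' a single `set.seed()` call makes the whole protocol reproducible.
#'
#' @param user a [user_model()].
#' @param cfg a [game_config()].
#' @param n_sessions number of sessions (>= 1); the pilot protocol has 8.
#' @param rate simulation sampling rate, Hz.
#' @return numeric vector of session scores (percent).
#' @export
simulate_protocol <- function(user, cfg, n_sessions = 8, rate = 50) {
  stopifnot(inherits(user, "user_model"), inherits(cfg, "game_config"))
  if (n_sessions < 1) abort_validation("n_sessions must be >= 1")
  vapply(seq_len(n_sessions), function(s) {
    u <- user
    u$motor_noise_sd <- user$motor_noise_sd * user$learning_rate^(s - 1)
    targets <- generate_targets(cfg, seed = NA)
    traj <- simulate_pursuit(targets, u, cfg$mapping, rate = rate)
    beta <- if (cfg$mapping$horizontal_source == "inclination") traj$incl else -traj$rot
    cursor <- cbind(t = traj$t, cursor_from_angles(traj$alpha, beta, cfg$mapping))
    score_session(run_session(cfg, cursor, targets = targets))
  }, numeric(1))
}
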