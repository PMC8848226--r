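# Shared fixtures and independent oracles used across the suite.

# --- brute-force 3x3 matrix product (element-wise triple loop), kept
# deliberately independent of %*% so it can oracle the rotation algebra
mat_mult_brute <- function(A, B) {
  C <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) for (k in 1:3)
    C[i, j] <- C[i, j] + A[i, k] * B[k, j]
  C
}

# single-axis rotation matrices written out long-hand (degrees)
oracle_ry <- function(a) {
  r <- a * pi / 180
  matrix(c(cos(r), 0, -sin(r),  0, 1, 0,  sin(r), 0, cos(r)), 3, 3)
}
oracle_rz <- function(a) {
  r <- a * pi / 180
  matrix(c(cos(r), sin(r), 0,  -sin(r), cos(r), 0,  0, 0, 1), 3, 3)
}
oracle_rx <- function(a) {
  r <- a * pi / 180
  matrix(c(1, 0, 0,  0, cos(r), sin(r),  0, -sin(r), cos(r)), 3, 3)
}

# --- static, noiseless, world-aligned IMU stream
static_stream <- function(duration_s = 5, rate = 50) {
  n <- duration_s * rate + 1
  t <- (seq_len(n) - 1) / rate
  imu_stream(t,
             gyro = matrix(0, n, 3),
             accel = cbind(rep(0, n), 0, 1),
             mag = cbind(rep(1, n), 0, 0))
}

# noiseless IMU stream for a constant-orientation hold at given Euler angles
hold_stream <- function(alpha = 0, rot = 0, incl = 0, duration_s = 3, rate = 50) {
  t <- seq(0, duration_s, by = 1 / rate)
  traj <- data.frame(t = t, alpha = alpha, rot = rot, incl = incl)
  synthesize_imu(traj, imu_noise(0, 0, 0, 0))
}

# --- hand-built target schedule (bypasses the RNG) from angle pairs
make_targets <- function(alpha, beta, cfg) {
  n <- length(alpha)
  xy <- cursor_from_angles(alpha, beta, cfg$mapping)
  spawn <- (seq_len(n) - 1) * cfg$inter_target_s
  out <- data.frame(index = seq_len(n),
                    series = rep(1L, n),
                    alpha = alpha, beta = beta, x = xy$x, y = xy$y,
                    spawn_t = spawn, deadline_t = spawn + cfg$inter_target_s)
  class(out) <- c("target_spec", "data.frame")
  out
}

# cursor trajectory pinned at one point for a whole session
frozen_cursor <- function(cfg, x = 0, y = 0, rate = 50) {
  t <- seq(0, session_duration(cfg), by = 1 / rate)
  data.frame(t = t, x = x, y = y)
}

# map a simulated angle trajectory to cursor coordinates
cursor_from_traj <- function(traj, mapping) {
  beta <- if (mapping$horizontal_source == "inclination") traj$incl else -traj$rot
  cbind(t = traj$t, cursor_from_angles(traj$alpha, beta, mapping))
}

# --- from-scratch sums-of-squares oracle for one-way repeated-measures ANOVA
rm_anova_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_session <- n * sum((colMeans(m) - grand)^2)
  ss_subject <- k * sum((rowMeans(m) - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_session - ss_subject
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  (ss_session / df1) / (ss_err / df2)
}

# small synthetic crossover dataset: per-subject baselines plus
# treatment/period/carryover shifts, gaussian noise
make_crossover <- function(n = 13, effect_a = 0, effect_b = 0, carryover = 0,
                           period = 0, baseline_mean = 5, sd = 1) {
  seqs <- rep(c("A-B", "B-A"), length.out = n)
  base <- rnorm(n, baseline_mean, sd)
  first_a <- seqs == "A-B"
  w4 <- base + ifelse(first_a, effect_a, effect_b) + rnorm(n, 0, sd)
  w8 <- base + carryover + rnorm(n, 0, sd)
  w12 <- w8 + ifelse(first_a, effect_b, effect_a) + period + rnorm(n, 0, sd)
  w16 <- w12 + rnorm(n, 0, sd)
  crossover_dataset(data.frame(
    subject = sprintf("P%02d", seq_len(n)), sequence = seqs,
    week0 = base, week4 = w4, week8 = w8, week12 = w12, week16 = w16))
}
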