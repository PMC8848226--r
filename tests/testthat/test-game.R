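# Target scheduling, hit detection, scoring and trajectory logging.

test_that("the pilot protocol schedules 42 targets over 210 seconds", {
  cfg <- game_config(seed = 4)  # defaults: 21 per series, 2 series, 5 s
  tg <- generate_targets(cfg)
  expect_equal(nrow(tg), 42L)
  expect_equal(tg$spawn_t, seq(0, 205, by = 5))
  expect_equal(tg$deadline_t, tg$spawn_t + 5)
  expect_equal(session_duration(cfg), 210)
  expect_equal(tg$series, rep(1:2, each = 21))
})

test_that("target generation is reproducible under a fixed seed", {
  cfg <- game_config(seed = 12)
  expect_identical(generate_targets(cfg), generate_targets(cfg))
  # and differs under another seed
  expect_false(isTRUE(all.equal(generate_targets(cfg),
                                generate_targets(cfg, seed = 13))))
})

test_that("generated positions stay in the ROM box at the required separation", {
  cfg <- game_config(targets_per_series = 10000, n_series = 1,
                     required_rom = 20, min_separation = 5, seed = 9)
  tg <- generate_targets(cfg)
  expect_true(all(abs(tg$alpha) <= 20 & abs(tg$beta) <= 20))
  sep <- sqrt(diff(tg$alpha)^2 + diff(tg$beta)^2)
  expect_true(all(sep >= 5))
  # pixel positions respect the mapping of the ROM box
  expect_true(all(abs(tg$y) <= cfg$mapping$R_V * 20 / cfg$mapping$alpha_T + 1e-9))
})

test_that("infeasible separation constraints raise an error", {
  expect_error(game_config(required_rom = 2, min_separation = 30),
               class = "cervgame_validation_error")
  cfg <- game_config(required_rom = 3, min_separation = 8, seed = 1)
  expect_error(generate_targets(cfg, max_retries = 5),
               class = "cervgame_validation_error")
})

test_that("a perfect tracker scores 100% and a frozen cursor 0%", {
  cfg <- game_config(seed = 2)
  tg <- generate_targets(cfg)
  # teleporting cursor: lands on each target right at spawn
  cur <- rbind(data.frame(t = tg$spawn_t + 1e-3, x = tg$x, y = tg$y),
               data.frame(t = session_duration(cfg), x = 0, y = 0))
  expect_equal(score_session(run_session(cfg, cur, targets = tg)), 100)

  # frozen at center, all targets pushed off-center by construction
  ang <- ifelse(seq_len(42) %% 2 == 0, 15, -15)
  tg_off <- make_targets(ang, -ang, cfg)
  log0 <- run_session(cfg, frozen_cursor(cfg), targets = tg_off)
  expect_equal(score_session(log0), 0)
})

test_that("hits require entering the radius within the target's window", {
  cfg <- game_config(targets_per_series = 3, n_series = 1, seed = 6,
                     target_radius = 40)
  tg <- make_targets(c(10, -10, 5), c(0, 5, -5), cfg)
  # reach target 1 in its window; target 2 too late; never reach target 3
  cur <- data.frame(
    t = c(0.5, 2.0, 5.5, 10.2, 12, 15),
    x = c(tg$x[1], 0, 0, tg$x[2], 0, 0),
    y = c(tg$y[1], 0, 0, tg$y[2], 0, 0))
  log <- run_session(cfg, cur, targets = tg)
  expect_equal(log$outcomes$reached, c(TRUE, FALSE, FALSE))
  expect_equal(log$outcomes$time_to_hit[1], 0.5)
  expect_equal(score_session(log), 100 * 1 / 3, tolerance = 1e-12)
})

test_that("series scores are percentages of their own series", {
  cfg <- game_config(targets_per_series = 21, n_series = 1, seed = 3)
  tg <- generate_targets(cfg)
  # construct a cursor that reaches exactly 17 of the 21 targets
  hit <- tg[1:17, ]
  cur <- rbind(data.frame(t = hit$spawn_t + 1e-3, x = hit$x, y = hit$y),
               data.frame(t = session_duration(cfg), x = 1e5, y = 1e5))
  log <- run_session(cfg, cur, targets = tg)
  expect_equal(unname(log$series_scores[1]), 100 * 17 / 21, tolerance = 1e-9)
  expect_equal(score_session(log), 80.95, tolerance = 0.01)
})

test_that("score arithmetic matches reached/total", {
  cfg <- game_config(seed = 5)
  tg <- generate_targets(cfg)
  hit <- tg[1:29, ]
  cur <- rbind(data.frame(t = hit$spawn_t + 1e-3, x = hit$x, y = hit$y),
               data.frame(t = session_duration(cfg), x = 1e5, y = 1e5))
  log <- run_session(cfg, cur, targets = tg)
  expect_equal(score_session(log), 100 * 29 / 42, tolerance = 1e-9)
  expect_equal(score_session(log), 69.05, tolerance = 0.01)
})

test_that("reached + missed always equals the scheduled target count", {
  set.seed(64)
  cfg <- game_config(seed = NA)
  for (i in 1:5) {
    tg <- generate_targets(cfg)
    traj <- simulate_pursuit(tg, user_model(), cfg$mapping)
    log <- run_session(cfg, cursor_from_traj(traj, cfg$mapping), targets = tg)
    expect_equal(sum(log$outcomes$reached) + sum(!log$outcomes$reached), 42L)
  }
})

test_that("a session log replayed through run_session reproduces itself", {
  set.seed(77)
  cfg <- game_config(seed = 31)
  tg <- generate_targets(cfg)
  traj <- simulate_pursuit(tg, user_model(), cfg$mapping)
  log1 <- run_session(cfg, cursor_from_traj(traj, cfg$mapping), targets = tg)
  log2 <- run_session(cfg, log1$trajectory, targets = log1$targets)
  expect_identical(log1$outcomes, log2$outcomes)
  expect_identical(log1$score_percent, log2$score_percent)
})

test_that("session logs round-trip through JSON", {
  set.seed(14)
  cfg <- game_config(seed = 8, targets_per_series = 4, n_series = 2)
  tg <- generate_targets(cfg)
  traj <- simulate_pursuit(tg, user_model(), cfg$mapping, rate = 20)
  log <- run_session(cfg, cursor_from_traj(traj, cfg$mapping), targets = tg)
  path <- withr::local_tempfile(fileext = ".json")
  write_session_log(log, path)
  back <- read_session_log(path)
  expect_equal(back$outcomes, log$outcomes, tolerance = 1e-12)
  expect_equal(back$score_percent, log$score_percent)
  expect_equal(back$targets$alpha, log$targets$alpha, tolerance = 1e-12)
  expect_equal(back$config$targets_per_series, 4L)
})

test_that("trajectory metrics match a direct recomputation", {
  cfg <- game_config(targets_per_series = 2, n_series = 1, seed = 1)
  tg <- make_targets(c(10, -10), c(5, -5), cfg)
  # square path of side 100 px, then hold
  sq <- data.frame(t = c(0, 1, 2, 3, 4, 10),
                   x = c(0, 100, 100, 0, 0, 0),
                   y = c(0, 0, 100, 100, 0, 0))
  log <- run_session(cfg, sq, targets = tg)
  m <- trajectory_metrics(log)
  expect_equal(m$path_length_px, 400)
  # stationary trajectory: zero path length, fully idle
  log0 <- run_session(cfg, frozen_cursor(cfg), targets = tg)
  m0 <- trajectory_metrics(log0)
  expect_equal(m0$path_length_px, 0)
  expect_equal(m0$idle_fraction, 1)
  # independent two-line recomputation on a simulated session
  set.seed(6)
  tg2 <- generate_targets(cfg, seed = NA)
  traj <- simulate_pursuit(tg2, user_model(), cfg$mapping)
  log2 <- run_session(cfg, cursor_from_traj(traj, cfg$mapping), targets = tg2)
  m2 <- trajectory_metrics(log2)
  tr <- log2$trajectory
  expect_equal(m2$path_length_px, sum(sqrt(diff(tr$x)^2 + diff(tr$y)^2)))
  expect_equal(m2$mean_time_to_hit_s,
               mean(log2$outcomes$time_to_hit[log2$outcomes$reached]))
})

test_that("sessions shorter than the schedule are rejected", {
  cfg <- game_config(seed = 2)
  short <- data.frame(t = seq(0, 100, by = 0.1), x = 0, y = 0)
  expect_error(run_session(cfg, short), "shorter",
               class = "cervgame_validation_error")
})
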