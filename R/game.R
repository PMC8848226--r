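# Headless game engine: target scheduling, hit detection, scoring and
# trajectory logging. The protocol defaults mirror the pilot intervention:
# two series of 21 targets, one target every 5 seconds, 210 s per session.

#' Game configuration
#'
#' @param targets_per_series number of targets in one series (>= 1).
#' @param n_series number of series per session (>= 1).
#' @param inter_target_s seconds between target spawns (> 0); each target's
#'   deadline is its spawn time plus this interval.
#' @param target_radius hit radius in pixels (> 0).
#' @param mapping a [mapping_config()].
#' @param required_rom maximum angular offset of targets from the center,
#'   degrees; must not exceed the mapping ROM (`alpha_T`, `beta_T`) so all
#'   targets stay inside the reachable box.
#' @param min_separation minimum angular distance between consecutive
#'   targets, degrees.
#' @param seed RNG seed recorded with the session; `NA` to draw from the
#'   ambient RNG stream.
#' @param difficulty_label free-text difficulty tag.
#' @return an object of class `game_config`.
#' @export
game_config <- function(targets_per_series = 21, n_series = 2,
                        inter_target_s = 5, target_radius = 40,
                        mapping = mapping_config(), required_rom = 20,
                        min_separation = 5, seed = NA_integer_,
                        difficulty_label = "easy") {
  if (targets_per_series < 1 || targets_per_series != round(targets_per_series))
    abort_validation("targets_per_series must be a positive integer")
  if (n_series < 1 || n_series != round(n_series))
    abort_validation("n_series must be a positive integer")
  if (!is.numeric(inter_target_s) || inter_target_s <= 0)
    abort_validation("inter_target_s must be positive")
  if (!is.numeric(target_radius) || target_radius <= 0)
    abort_validation("target_radius must be positive")
  stopifnot(inherits(mapping, "mapping_config"))
  if (required_rom <= 0)
    abort_validation("required_rom must be positive")
  if (required_rom > mapping$alpha_T || required_rom > mapping$beta_T)
    abort_validation("required_rom exceeds the mapping ROM (alpha_T/beta_T): targets would be unreachable")
  if (min_separation < 0) abort_validation("min_separation must be non-negative")
  if (min_separation > 2 * required_rom * sqrt(2))
    abort_validation("min_separation is infeasible for the given required_rom")
  structure(list(targets_per_series = as.integer(targets_per_series),
                 n_series = as.integer(n_series),
                 inter_target_s = inter_target_s,
                 target_radius = target_radius, mapping = mapping,
                 required_rom = required_rom, min_separation = min_separation,
                 seed = seed, difficulty_label = difficulty_label),
            class = "game_config")
}

#' @export
print.game_config <- function(x, ...) {
  cat(sprintf(
    "<game_config> %d series x %d targets, one every %g s (%g s session); radius %g px, ROM %g deg, difficulty '%s'\n",
    x$n_series, x$targets_per_series, x$inter_target_s, session_duration(x),
    x$target_radius, x$required_rom, x$difficulty_label))
  invisible(x)
}

#' Total scheduled session duration in seconds
#' @param cfg a [game_config()].
#' @export
session_duration <- function(cfg) {
  cfg$targets_per_series * cfg$n_series * cfg$inter_target_s
}

#' Generate the target schedule for a session
#'
#' Target positions are drawn uniformly over the angular ROM box
#' (`[-required_rom, required_rom]` on each driven axis, one axis pinned to
#' 0 in 1D modes), rejecting draws closer than `min_separation` degrees to
#' the previous target. Spawn times sit at multiples of `inter_target_s`;
#' each deadline is the next spawn time. The schedule is reproducible under
#' a fixed seed.
#'
#' @param cfg a [game_config()].
#' @param seed overrides `cfg$seed`; `NA` draws from the ambient RNG.
#' @param max_retries rejection-sampling cap per target.
#' @return a data frame of class `target_spec` with columns
#'   `index, series, alpha, beta, x, y, spawn_t, deadline_t`.
#' @export
generate_targets <- function(cfg, seed = cfg$seed, max_retries = 1000L) {
  stopifnot(inherits(cfg, "game_config"))
  if (!is.na(seed)) return(with_local_seed(seed, generate_targets(cfg, seed = NA)))
  n <- cfg$targets_per_series * cfg$n_series
  rom <- cfg$required_rom
  alpha <- numeric(n); beta <- numeric(n)
  pin_beta <- cfg$mapping$mode == "1D-vertical"
  pin_alpha <- cfg$mapping$mode == "1D-horizontal"
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      a <- if (pin_alpha) 0 else runif(1, -rom, rom)
      b <- if (pin_beta) 0 else runif(1, -rom, rom)
      if (i == 1L || sqrt((a - alpha[i - 1])^2 + (b - beta[i - 1])^2) >= cfg$min_separation) {
        alpha[i] <- a; beta[i] <- b; ok <- TRUE; break
      }
    }
    if (!ok)
      abort_validation(sprintf(
        "could not place target %d at min_separation %.1f deg after %d tries",
        i, cfg$min_separation, max_retries))
  }
  xy <- cursor_from_angles(alpha, beta, cfg$mapping)
  spawn <- (seq_len(n) - 1) * cfg$inter_target_s
  out <- data.frame(index = seq_len(n),
                    series = rep(seq_len(cfg$n_series), each = cfg$targets_per_series),
                    alpha = alpha, beta = beta, x = xy$x, y = xy$y,
                    spawn_t = spawn, deadline_t = spawn + cfg$inter_target_s)
  class(out) <- c("target_spec", "data.frame")
  out
}

#' Run a session against a cursor trajectory
#'
#' Hit rule: a target is reached by the first cursor sample that falls
#' strictly inside its radius during `[spawn_t, deadline_t)`; otherwise it
#' is missed at its deadline. One target is active at a time; a reached
#' target disappears but the next still spawns on schedule, so the session
#' always lasts `targets_per_series * n_series * inter_target_s` seconds.
#'
#' @param cfg a [game_config()].
#' @param cursor a data frame with columns `t, x, y`: the cursor trajectory,
#'   covering the whole session (from any source: mapped IMU fusion, a
#'   replayed log, or the user simulator).
#' @param targets an optional pre-generated [generate_targets()] schedule;
#'   by default generated from `cfg` (using `cfg$seed` when set).
#' @return an object of class `session_log`: a list with `config`,
#'   `targets`, `trajectory`, `outcomes` (per-target `reached` flag and
#'   `time_to_hit`), `series_scores`, `score_percent` and `seed`.
#' @export
run_session <- function(cfg, cursor, targets = NULL) {
  stopifnot(inherits(cfg, "game_config"))
  if (!all(c("t", "x", "y") %in% names(cursor)))
    abort_validation("cursor trajectory must have columns t, x, y")
  if (nrow(cursor) == 0L) abort_validation("empty cursor trajectory")
  if (is.unsorted(cursor$t, strictly = FALSE))
    abort_validation("cursor timestamps must be monotone")
  if (is.null(targets)) targets <- generate_targets(cfg)
  dur <- session_duration(cfg)
  if (max(cursor$t) < dur - 1e-9)
    abort_validation(sprintf(
      "cursor stream ends at %.2f s, shorter than the %.2f s session", max(cursor$t), dur))

  n <- nrow(targets)
  reached <- logical(n); tth <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    win <- cursor$t >= targets$spawn_t[i] & cursor$t < targets$deadline_t[i]
    if (!any(win)) next
    d2 <- (cursor$x[win] - targets$x[i])^2 + (cursor$y[win] - targets$y[i])^2
    hit <- which(d2 < cfg$target_radius^2)
    if (length(hit)) {
      reached[i] <- TRUE
      tth[i] <- cursor$t[win][hit[1]] - targets$spawn_t[i]
    }
  }
  outcomes <- data.frame(index = targets$index, series = targets$series,
                         reached = reached, time_to_hit = tth)
  series_scores <- vapply(split(reached, targets$series),
                          function(r) 100 * mean(r), numeric(1))
  log <- structure(list(
    config = cfg,
    targets = targets,
    trajectory = data.frame(t = cursor$t, x = cursor$x, y = cursor$y),
    outcomes = outcomes,
    series_scores = series_scores,
    score_percent = 100 * sum(reached) / n,
    seed = cfg$seed
  ), class = "session_log")
  log
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> %d/%d targets reached (%.2f%%); series: %s\n",
              sum(x$outcomes$reached), nrow(x$outcomes), x$score_percent,
              paste(sprintf("%.2f%%", x$series_scores), collapse = ", ")))
  invisible(x)
}

#' Session score as a percentage
#'
#' The performance score of a session: targets reached over targets
#' scheduled, all series pooled, times 100. With equal-length series this
#' equals the mean of the per-series percentages recorded as the day's
#' score.
#'
#' @param log a `session_log` from [run_session()].
#' @return a single number in \[0, 100\].
#' @export
score_session <- function(log) {
  stopifnot(inherits(log, "session_log"))
  if (nrow(log$outcomes) == 0L) abort_validation("empty session log")
  100 * sum(log$outcomes$reached) / nrow(log$outcomes)
}

#' Summary metrics of a logged trajectory
#'
#' @param log a `session_log`.
#' @param idle_speed_px_s speed threshold (px/s) under which a sample counts
#'   as idle.
#' @return a list with `path_length_px` (sum of segment lengths),
#'   `mean_time_to_hit_s` (over reached targets; `NA` if none) and
#'   `idle_fraction` (share of segments slower than the threshold).
#' @export
trajectory_metrics <- function(log, idle_speed_px_s = 10) {
  stopifnot(inherits(log, "session_log"))
  tr <- log$trajectory
  if (nrow(tr) == 0L) abort_validation("empty trajectory")
  if (nrow(tr) == 1L)
    return(list(path_length_px = 0, mean_time_to_hit_s = NA_real_, idle_fraction = 1))
  seg <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  dt <- diff(tr$t)
  speed <- seg / pmax(dt, .Machine$double.eps)
  hits <- log$outcomes$time_to_hit[log$outcomes$reached]
  list(path_length_px = sum(seg),
       mean_time_to_hit_s = if (length(hits)) mean(hits) else NA_real_,
       idle_fraction = mean(speed < idle_speed_px_s))
}

#' Serialize / load a session log
#'
#' The log is written as JSON (config, targets, outcomes, scores, seed) with
#' the trajectory embedded; [read_session_log()] restores an equivalent
#' `session_log`.
#'
#' @param log a `session_log`.
#' @param path output file path.
#' @return `write_session_log` returns `path` invisibly; `read_session_log`
#'   returns a `session_log`.
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  cfg <- log$config
  payload <- list(
    config = list(
      targets_per_series = cfg$targets_per_series, n_series = cfg$n_series,
      inter_target_s = cfg$inter_target_s, target_radius = cfg$target_radius,
      required_rom = cfg$required_rom, min_separation = cfg$min_separation,
      seed = cfg$seed, difficulty_label = cfg$difficulty_label,
      mapping = unclass(cfg$mapping)),
    targets = log$targets, outcomes = log$outcomes,
    series_scores = as.list(log$series_scores),
    score_percent = log$score_percent, seed = log$seed,
    trajectory = log$trajectory)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  if (!file.exists(path)) abort_validation("session log not found: ", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- p$config$mapping
  mapping <- mapping_config(m$R_H, m$R_V, m$alpha_T, m$beta_T,
                            m$horizontal_source, m$mode, unlist(m$screen))
  cfg <- game_config(p$config$targets_per_series, p$config$n_series,
                     p$config$inter_target_s, p$config$target_radius,
                     mapping, p$config$required_rom, p$config$min_separation,
                     if (is.null(p$config$seed)) NA_integer_ else p$config$seed,
                     p$config$difficulty_label)
  targets <- as.data.frame(p$targets)
  class(targets) <- c("target_spec", "data.frame")
  structure(list(config = cfg, targets = targets,
                 trajectory = as.data.frame(p$trajectory),
                 outcomes = as.data.frame(p$outcomes),
                 series_scores = unlist(p$series_scores),
                 score_percent = p$score_percent,
                 seed = if (is.null(p$seed)) NA_integer_ else p$seed),
            class = "session_log")
}
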