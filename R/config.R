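# Protocol configuration: a single human-editable YAML file bundling the
# game, mapping and fusion parameters plus subject/session identifiers.
# The defaults reproduce the pilot protocol: 2 series x 21 targets, one
# target every 5 s (210 s session), easy-level ROM, horizontal coordinate
# driven by lateral inclination (axial rotation unworked).

CONFIG_TOP_KEYS <- c("subject", "session", "out_dir", "game", "mapping", "fusion")
CONFIG_GAME_KEYS <- c("targets_per_series", "n_series", "inter_target_s",
                      "target_radius", "required_rom", "min_separation",
                      "seed", "difficulty_label")
CONFIG_MAPPING_KEYS <- c("R_H", "R_V", "alpha_T", "beta_T",
                         "horizontal_source", "mode", "screen")
CONFIG_FUSION_KEYS <- c("gain", "sample_rate", "mag_enabled")

#' Protocol configuration
#'
#' @param subject subject identifier.
#' @param session session number.
#' @param out_dir output directory for logs.
#' @param game a [game_config()].
#' @param fusion a [fusion_params()].
#' @return an object of class `protocol_config`.
#' @seealso [default_protocol_config()], [load_config()], [write_config()].
#' @export
protocol_config <- function(subject = "S01", session = 1L,
                            out_dir = ".", game = game_config(),
                            fusion = fusion_params()) {
  stopifnot(inherits(game, "game_config"), inherits(fusion, "fusion_params"))
  if (!is.character(subject) || length(subject) != 1L || !nzchar(subject))
    abort_validation("subject must be a non-empty string")
  if (session < 1 || session != round(session))
    abort_validation("session must be a positive integer")
  structure(list(subject = subject, session = as.integer(session),
                 out_dir = out_dir, game = game, fusion = fusion),
            class = "protocol_config")
}

#' The pilot protocol defaults
#'
#' 21 targets per series, 2 series, 5 s between targets (42 targets, 210 s
#' per session), easy difficulty with a 20-30 degree mobility requirement
#' (alpha_T = beta_T = 25), horizontal control by lateral inclination.
#'
#' @param seed optional RNG seed recorded in the game config.
#' @return a [protocol_config()].
#' @export
default_protocol_config <- function(seed = NA_integer_) {
  protocol_config(game = game_config(seed = seed))
}

#' @export
print.protocol_config <- function(x, ...) {
  cat(sprintf("<protocol_config> subject %s, session %d, out_dir '%s'\n",
              x$subject, x$session, x$out_dir))
  print(x$game)
  print(x$game$mapping)
  invisible(x)
}

#' Load a protocol configuration from YAML
#'
#' Strict: unknown keys are rejected with a field-level message, and every
#' value passes the constructors' validation. Keys omitted from the file
#' keep their pilot-protocol defaults.
#'
#' @param path YAML file path.
#' @return a [protocol_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort_validation("config file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    abort_validation("config parse failure: ", conditionMessage(e)))
  if (is.null(raw)) raw <- list()
  check_keys(raw, CONFIG_TOP_KEYS, "top level")
  check_keys(raw$game, CONFIG_GAME_KEYS, "game")
  check_keys(raw$mapping, CONFIG_MAPPING_KEYS, "mapping")
  check_keys(raw$fusion, CONFIG_FUSION_KEYS, "fusion")

  m_args <- modifyList(formals_defaults(mapping_config), raw$mapping %||% list())
  mapping <- do.call(mapping_config, m_args)
  g_args <- raw$game %||% list()
  if (!is.null(g_args$seed)) g_args$seed <- as.integer(g_args$seed)
  game <- do.call(game_config, c(g_args, list(mapping = mapping)))
  fusion <- do.call(fusion_params, raw$fusion %||% list())
  protocol_config(subject = raw$subject %||% "S01",
                  session = raw$session %||% 1L,
                  out_dir = raw$out_dir %||% ".",
                  game = game, fusion = fusion)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_keys <- function(x, allowed, where) {
  if (is.null(x)) return(invisible(NULL))
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    abort_validation(sprintf("unknown %s config key(s): %s", where,
                             paste(bad, collapse = ", ")))
  invisible(NULL)
}

# defaults of a constructor's simple (non-language) formals
formals_defaults <- function(f) {
  fm <- formals(f)
  fm <- fm[!vapply(fm, is.language, logical(1))]
  lapply(fm, identity)
}

#' Write a protocol configuration as YAML
#'
#' Inverse of [load_config()]; a write-then-read round trip reproduces the
#' configuration exactly.
#'
#' @param cfg a [protocol_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "protocol_config"))
  g <- cfg$game
  payload <- list(
    subject = cfg$subject, session = cfg$session, out_dir = cfg$out_dir,
    game = list(targets_per_series = g$targets_per_series,
                n_series = g$n_series, inter_target_s = g$inter_target_s,
                target_radius = g$target_radius, required_rom = g$required_rom,
                min_separation = g$min_separation,
                seed = if (is.na(g$seed)) NULL else g$seed,
                difficulty_label = g$difficulty_label),
    mapping = unclass(g$mapping),
    fusion = unclass(cfg$fusion))
  yaml::write_yaml(payload, path)
  invisible(path)
}
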