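# Absolute angular-to-screen mapping: the rotation relative to the
# calibrated neutral pose is decomposed into YZX Euler angles and mapped
# linearly onto screen coordinates. Absolute mapping means the same head
# orientation always lands the cursor on the same pixel.

#' Mapping configuration
#'
#' Parameters of the linear angle-to-pixel law. `R_H` and `R_V` are the
#' horizontal and vertical screen half-extents reachable by the cursor
#' (pixels from the screen center); `alpha_T` and `beta_T` are the ranges of
#' motion (degrees) required to reach them, so the mapping slopes are
#' `R_H / beta_T` and `R_V / alpha_T` pixels per degree. The vertical
#' coordinate is always driven by flexion-extension; the horizontal
#' coordinate by lateral inclination or axial rotation, per
#' `horizontal_source`.
#'
#' @param R_H horizontal half-extent, pixels (> 0).
#' @param R_V vertical half-extent, pixels (> 0).
#' @param alpha_T flexion-extension range of motion required to reach the
#'   vertical extent, degrees in (0, 90\].
#' @param beta_T range of motion required to reach the horizontal extent,
#'   degrees in (0, 90\].
#' @param horizontal_source which cervical motion drives the horizontal
#'   coordinate: `"inclination"` or `"rotation"`.
#' @param mode `"2D"`, `"1D-vertical"` or `"1D-horizontal"`; in 1D modes the
#'   unused coordinate is pinned to 0.
#' @param screen screen size `c(width, height)` in pixels; the extents must
#'   fit inside it.
#' @return an object of class `mapping_config`.
#' @export
mapping_config <- function(R_H = 640, R_V = 360, alpha_T = 25, beta_T = 25,
                           horizontal_source = c("inclination", "rotation"),
                           mode = c("2D", "1D-vertical", "1D-horizontal"),
                           screen = c(1280, 720)) {
  horizontal_source <- match.arg(horizontal_source)
  mode <- match.arg(mode)
  for (nm in c("R_H", "R_V", "alpha_T", "beta_T")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      abort_validation(nm, " must be a single positive number")
  }
  if (alpha_T > 90 || beta_T > 90)
    abort_validation("alpha_T and beta_T must be at most 90 degrees")
  screen <- as.numeric(screen)
  if (length(screen) != 2L || any(screen <= 0))
    abort_validation("screen must be c(width, height) with positive entries")
  if (R_H > screen[1] / 2 || R_V > screen[2] / 2)
    abort_validation("extents R_H/R_V must fit inside the screen half-size")
  structure(list(R_H = R_H, R_V = R_V, alpha_T = alpha_T, beta_T = beta_T,
                 horizontal_source = horizontal_source, mode = mode,
                 screen = screen),
            class = "mapping_config")
}

#' @export
print.mapping_config <- function(x, ...) {
  cat(sprintf(
    "<mapping_config> %s, horizontal: %s; extents %g x %g px for %g / %g deg ROM; screen %g x %g\n",
    x$mode, x$horizontal_source, x$R_H, x$R_V, x$beta_T, x$alpha_T,
    x$screen[1], x$screen[2]))
  invisible(x)
}

#' Rotation relative to the calibrated neutral pose
#'
#' Computes `R_T = R_cal^-1 %*% R_S`, the head rotation relative to neutral:
#' when the current orientation equals the calibration pose the result is
#' the identity, which anchors the cursor at the screen center.
#'
#' @param R_cal calibration rotation (neutral pose), a [rotation_state()].
#' @param R_S current sample rotation, a [rotation_state()].
#' @return a [rotation_state()] `R_T`.
#' @export
relative_rotation <- function(R_cal, R_S) {
  A <- if (inherits(R_cal, "rotation_state")) R_cal$dcm else check_dcm(R_cal)
  B <- if (inherits(R_S, "rotation_state")) R_S$dcm else check_dcm(R_S)
  rotation_state(dcm = crossprod(A, B))  # t(A) %*% B
}

#' Cursor position from head orientation
#'
#' Decomposes the relative rotation `R_T` with the YZX convention and applies
#' the linear law: `y = -R_V * alpha / alpha_T` (flexion, positive alpha,
#' moves the cursor down) and `x = R_H * beta / beta_T`, where `beta` is the
#' lateral inclination or axial rotation angle depending on
#' `horizontal_source` (signed so that tilting or looking toward the
#' subject's right moves the cursor right). Coordinates are clamped to the
#' screen bounds; in 1D modes the unused coordinate is 0.
#'
#' @param R_T relative rotation from [relative_rotation()].
#' @param cfg a [mapping_config()].
#' @return a named numeric vector `c(x, y)` in pixels, origin at screen
#'   center, y positive up.
#' @export
cursor_from_orientation <- function(R_T, cfg) {
  stopifnot(inherits(cfg, "mapping_config"))
  e <- decompose_yzx(R_T)
  beta <- switch(cfg$horizontal_source, inclination = e$incl, rotation = -e$rot)
  xy <- cursor_from_angles(e$alpha, beta, cfg)
  c(x = xy$x, y = xy$y)
}

#' Cursor positions from Euler angle trajectories
#'
#' Vectorized form of the linear mapping law for trajectories where the
#' relative Euler angles are already known (simulator ground truth, target
#' placement). `beta` must already be the signed horizontal driving angle.
#'
#' @param alpha flexion-extension angles, degrees (vector).
#' @param beta horizontal driving angles, degrees (vector).
#' @param cfg a [mapping_config()].
#' @return a data frame with columns `x`, `y` (pixels, clamped to screen).
#' @export
cursor_from_angles <- function(alpha, beta, cfg) {
  stopifnot(inherits(cfg, "mapping_config"))
  x <- cfg$R_H * beta / cfg$beta_T
  y <- -cfg$R_V * alpha / cfg$alpha_T
  if (cfg$mode == "1D-vertical") x <- rep(0, length(y))
  if (cfg$mode == "1D-horizontal") y <- rep(0, length(x))
  hw <- cfg$screen[1] / 2; hh <- cfg$screen[2] / 2
  data.frame(x = pmin(hw, pmax(-hw, x)), y = pmin(hh, pmax(-hh, y)))
}
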