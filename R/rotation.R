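# Rotation algebra: DCM/quaternion states and the YZX Euler convention used
# to read cervical motion off a head-mounted sensor. Angles are degrees
# throughout the public API; radians never leak out.

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi
GIMBAL_TOL <- 1e-7  # tolerance on the middle-angle cosine

#' Orientation state (unit quaternion + direction cosine matrix)
#'
#' A rotation of the head frame relative to the world frame, carried in two
#' equivalent representations: a unit quaternion `q = (w, x, y, z)` and a
#' 3x3 direction cosine matrix (DCM). The DCM maps head-frame vectors into
#' the world frame. World frame: Z up (gravity along -Z), X magnetic north;
#' head frame: X anterior, Y left, Z up.
#'
#' @param dcm a 3x3 orthonormal matrix with determinant +1, or `NULL`.
#' @param quaternion a numeric 4-vector `(w, x, y, z)` of unit norm, or
#'   `NULL`. Exactly one of `dcm` and `quaternion` must be supplied.
#' @return an object of class `rotation_state` with elements `dcm` and
#'   `quaternion`.
#' @examples
#' rotation_state(dcm = diag(3))
#' @export
rotation_state <- function(dcm = NULL, quaternion = NULL) {
  if (is.null(dcm) == is.null(quaternion))
    abort_validation("supply exactly one of `dcm` or `quaternion`")
  if (is.null(dcm)) {
    q <- as.numeric(quaternion)
    if (length(q) != 4L || any(!is.finite(q)))
      abort_validation("quaternion must be a finite numeric 4-vector")
    nrm <- sqrt(sum(q^2))
    if (abs(nrm - 1) > 1e-6)
      abort_validation(sprintf("quaternion norm %.8f is not 1", nrm))
    q <- q / nrm
    dcm <- quat_to_dcm(q)
  } else {
    dcm <- unname(as.matrix(dcm))
    check_dcm(dcm)
    q <- dcm_to_quat(dcm)
  }
  structure(list(dcm = dcm, quaternion = q), class = "rotation_state")
}

check_dcm <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || !identical(dim(R), c(3L, 3L)) || any(!is.finite(R)))
    abort_validation("dcm must be a finite 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > tol)
    abort_validation("dcm is not orthonormal")
  if (abs(det(R) - 1) > tol)
    abort_validation("dcm determinant is not +1 (improper rotation)")
  invisible(R)
}

#' @export
print.rotation_state <- function(x, ...) {
  e <- tryCatch(decompose_yzx(x), error = function(e) NULL)
  cat("<rotation_state>\n")
  if (!is.null(e)) {
    cat(sprintf("  YZX Euler (deg): flexion-extension %.3f, axial rotation %.3f, lateral inclination %.3f\n",
                e$alpha, e$rot, e$incl))
  } else {
    cat("  (gimbal-locked orientation; no YZX decomposition)\n")
  }
  invisible(x)
}

#' @export
format.rotation_state <- function(x, ...) {
  paste0("rotation_state(q = [", paste(sprintf("%.6f", x$quaternion), collapse = ", "), "])")
}

# ---- single-axis rotation matrices (theta in degrees) ----

rot_x <- function(theta) {
  a <- theta * DEG2RAD; c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_y <- function(theta) {
  a <- theta * DEG2RAD; c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rot_z <- function(theta) {
  a <- theta * DEG2RAD; c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

# Rodrigues: rotation about unit axis `u` by `angle_deg`
rot_axis_angle <- function(u, angle_deg) {
  th <- angle_deg * DEG2RAD
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# exp of a rotation vector (degrees): rotate by |w| degrees about w
rotvec_to_dcm <- function(w) {
  ang <- sqrt(sum(w^2))
  if (ang < 1e-12) return(diag(3))
  rot_axis_angle(w / ang, ang)
}

# log map: rotation vector in degrees
dcm_to_rotvec <- function(R) {
  c_ang <- (sum(diag(R)) - 1) / 2
  c_ang <- min(1, max(-1, c_ang))
  ang <- acos(c_ang)
  if (ang < 1e-12) return(c(0, 0, 0))
  if (ang > pi - 1e-6) {
    # near 180 deg: extract axis from R + I
    B <- (R + diag(3)) / 2
    u <- sqrt(pmax(diag(B), 0))
    # fix signs from off-diagonal terms
    i <- which.max(u)
    if (i == 1L) u <- c(u[1], sign(B[1, 2]) * u[2], sign(B[1, 3]) * u[3])
    if (i == 2L) u <- c(sign(B[1, 2]) * u[1], u[2], sign(B[2, 3]) * u[3])
    if (i == 3L) u <- c(sign(B[1, 3]) * u[1], sign(B[2, 3]) * u[2], u[3])
    u <- u / sqrt(sum(u^2))
    return(u * ang * RAD2DEG)
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(ang))
  ax * ang * RAD2DEG
}

# ---- quaternion <-> DCM (Shepperd's method) ----

quat_to_dcm <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

dcm_to_quat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  if (q[1] < 0) q <- -q  # canonical hemisphere
  q / sqrt(sum(q^2))
}

# ---- YZX Euler convention ----

#' YZX Euler angle triple for cervical motion
#'
#' The three cervical degrees of freedom, in degrees:
#' `alpha` flexion-extension (rotation about the head's lateral Y axis,
#' first factor of the YZX sequence; positive = flexion, nose down),
#' `rot` axial rotation (about the vertical Z axis, second factor; positive =
#' looking left), and `incl` lateral inclination (about the anterior X axis,
#' third factor; positive = right ear toward right shoulder).
#'
#' @param alpha flexion-extension angle in degrees.
#' @param rot axial rotation angle in degrees.
#' @param incl lateral inclination angle in degrees.
#' @return an object of class `euler_yzx` (a named list).
#' @examples
#' euler_yzx(30, 0, -10)
#' @export
euler_yzx <- function(alpha = 0, rot = 0, incl = 0) {
  v <- c(alpha = alpha, rot = rot, incl = incl)
  if (any(!is.finite(v))) abort_validation("Euler angles must be finite")
  structure(list(alpha = unname(alpha), rot = unname(rot), incl = unname(incl)),
            class = "euler_yzx")
}

#' @export
print.euler_yzx <- function(x, ...) {
  cat(sprintf("<euler_yzx> flexion-extension %.3f deg, axial rotation %.3f deg, lateral inclination %.3f deg\n",
              x$alpha, x$rot, x$incl))
  invisible(x)
}

#' Compose a rotation from YZX Euler angles
#'
#' Builds `R = R_Y(alpha) %*% R_Z(rot) %*% R_X(incl)`: flexion-extension
#' applied first, then axial rotation, then lateral inclination.
#'
#' @param e an [euler_yzx()] object, or the `alpha` angle in degrees if
#'   `rot`/`incl` are given separately.
#' @param rot,incl axial rotation and lateral inclination in degrees, used
#'   when `e` is numeric.
#' @return a [rotation_state()].
#' @examples
#' compose_yzx(30, 0, 0)        # pure 30 deg flexion
#' compose_yzx(euler_yzx(10, 20, 30))
#' @export
compose_yzx <- function(e, rot = 0, incl = 0) {
  if (!inherits(e, "euler_yzx")) e <- euler_yzx(e, rot, incl)
  R <- rot_y(e$alpha) %*% rot_z(e$rot) %*% rot_x(e$incl)
  rotation_state(dcm = R)
}

#' Decompose a rotation into YZX Euler angles
#'
#' Inverse of [compose_yzx()]. The decomposition is unique (and numerically
#' stable) while the middle axial-rotation angle stays away from +/-90
#' degrees; at gimbal lock the Y and X axes align and the factorization
#' degenerates, which is signalled as an error.
#'
#' @param R a [rotation_state()] (or a bare 3x3 DCM).
#' @return an [euler_yzx()] with angles in degrees, `alpha` and `incl` in
#'   (-180, 180], `rot` in \[-90, 90\].
#' @examples
#' decompose_yzx(compose_yzx(10, 20, 30))
#' @export
decompose_yzx <- function(R) {
  M <- if (inherits(R, "rotation_state")) R$dcm else check_dcm(unname(as.matrix(R)))
  s_rot <- min(1, max(-1, M[2, 1]))
  c_rot <- sqrt(max(0, 1 - s_rot^2))
  if (c_rot <= GIMBAL_TOL)
    stop(structure(
      class = c("cervgame_gimbal_lock", "error", "condition"),
      list(message = paste0(
        "gimbal lock: axial rotation (middle Z angle) at ",
        ifelse(s_rot > 0, "+90", "-90"),
        " degrees; the Y (flexion-extension) and X (inclination) axes are aligned"),
        call = sys.call(-1))))
  euler_yzx(
    alpha = atan2(-M[3, 1], M[1, 1]) * RAD2DEG,
    rot   = asin(s_rot) * RAD2DEG,
    incl  = atan2(-M[2, 3], M[2, 2]) * RAD2DEG
  )
}

#' Geodesic angle between two rotations
#'
#' @param R1,R2 [rotation_state()] objects (or DCMs).
#' @return the rotation angle in degrees needed to carry `R1` onto `R2`.
#' @export
rotation_angle <- function(R1, R2 = diag(3)) {
  A <- if (inherits(R1, "rotation_state")) R1$dcm else R1
  B <- if (inherits(R2, "rotation_state")) R2$dcm else R2
  c_ang <- (sum(diag(crossprod(A, B))) - 1) / 2
  acos(min(1, max(-1, c_ang))) * RAD2DEG
}

#' Chordal mean of a set of rotations
#'
#' Averages rotations by taking the element-wise mean DCM and projecting it
#' back onto SO(3) with an orthogonal Procrustes step (SVD). This is the
#' standard chordal mean; it is deterministic and invariant to the order of
#' the inputs.
#'
#' @param rotations a list of [rotation_state()] objects or 3x3 DCMs, or a
#'   `3 x 3 x n` array.
#' @return a [rotation_state()].
#' @export
rotation_mean <- function(rotations) {
  if (is.array(rotations) && length(dim(rotations)) == 3L) {
    M <- apply(rotations, c(1, 2), mean)
  } else {
    if (length(rotations) == 0L) abort_validation("no rotations to average")
    mats <- lapply(rotations, function(r) if (inherits(r, "rotation_state")) r$dcm else r)
    M <- Reduce(`+`, mats) / length(mats)
  }
  rotation_state(dcm = project_so3(M))
}

# nearest rotation matrix in Frobenius norm (orthogonal Procrustes)
project_so3 <- function(M) {
  sv <- svd(M)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) R <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
  R
}
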