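#' Rigid-body transform (3 rotations + 3 translations)
#'
#' A 6-parameter rigid-body head motion: extrinsic rotations about the Z, then
#' Y, then X axis (counterclockwise positive, degrees) and a translation in mm,
#' applied translate-then-rotate about the volume centre. Acting on a physical
#' point `p` (mm, relative to an arbitrary but shared centre `c`):
#'
#'   `M(p) = R (p - c + t) + c`,  with  `R = Rx Ry Rz`.
#'
#' Because parameters are centre-relative, [compose()] and [invert()] do not
#' depend on the actual centre coordinates, only on both operands sharing the
#' same centre convention.
#'
#' @param rot_deg rotations about Z, Y, X in degrees (length 3).
#' @param trans_mm translations in mm (length 3).
#' @param center centre convention tag; `"volume_center"` is the only built-in.
#' @return An object of class `rigid_transform`.
#' @examples
#' t <- rigid_transform(rot_deg = c(10, 0, 0), trans_mm = c(3, 4, 0))
#' motion_score(t)
#' @export
rigid_transform <- function(rot_deg = c(0, 0, 0), trans_mm = c(0, 0, 0),
                            center = "volume_center") {
  rot_deg <- as.numeric(rot_deg)
  trans_mm <- as.numeric(trans_mm)
  if (length(rot_deg) != 3L || length(trans_mm) != 3L ||
      !all(is.finite(c(rot_deg, trans_mm))))
    stop("`rot_deg` and `trans_mm` must be finite length-3 numerics")
  structure(list(rot_deg = rot_deg, trans_mm = trans_mm, center = center),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rot ZYX = (%s) deg, trans = (%s) mm, center = %s\n",
              paste(format(x$rot_deg, digits = 4, trim = TRUE), collapse = ", "),
              paste(format(x$trans_mm, digits = 4, trim = TRUE), collapse = ", "),
              x$center))
  invisible(x)
}

#' Rotation matrix for Z, Y, X extrinsic Euler angles
#'
#' Returns `R = Rx(ax) %*% Ry(ay) %*% Rz(az)` for angles in degrees, i.e. the
#' net matrix of rotating about Z first, then Y, then X (column vectors,
#' counterclockwise positive looking down each axis).
#'
#' @param rot_deg angles about Z, Y, X in degrees.
#' @return 3x3 orthonormal matrix with determinant +1.
#' @export
rotation_matrix_zyx <- function(rot_deg) {
  a <- rot_deg * pi / 180
  cz <- cos(a[1]); sz <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cx <- cos(a[3]); sx <- sin(a[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rx %*% Ry %*% Rz
}

# ZYX Euler angles (degrees) from a rotation matrix; inverse of
# rotation_matrix_zyx away from the gimbal lock |pitch| = 90 deg.
euler_zyx_from_matrix <- function(R) {
  sy <- max(-1, min(1, R[1, 3]))
  if (abs(sy) < 1 - 1e-10) {
    ay <- asin(sy)
    az <- atan2(-R[1, 2], R[1, 1])
    ax <- atan2(-R[2, 3], R[3, 3])
  } else {
    # gimbal lock: only az + ax (or az - ax) is determined; put it all in ax
    ay <- asin(sy)
    az <- 0
    ax <- atan2(R[2, 1], R[2, 2])
  }
  c(az, ay, ax) * 180 / pi
}

rt_matrix <- function(t) rotation_matrix_zyx(t$rot_deg)

check_same_center <- function(a, b) {
  if (!identical(a$center, b$center))
    stop("transforms use different center conventions: ",
         a$center, " vs ", b$center)
}

#' Compose and invert rigid transforms
#'
#' `compose(a, b)` is the transform equivalent to applying `b` first, then `a`
#' (matrix product `a %*% b` in homogeneous form); `invert(t)` is the exact
#' rigid inverse. Both operate in centre-relative parameters, so they are
#' valid whenever both transforms share the same centre convention.
#'
#' @param a,b,t [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @examples
#' t <- rigid_transform(c(5, -3, 2), c(1, 2, 3))
#' compose(t, invert(t)) # identity to machine precision
#' @export
compose <- function(a, b) {
  check_same_center(a, b)
  Ra <- rt_matrix(a); Rb <- rt_matrix(b)
  Rc <- Ra %*% Rb
  tc <- b$trans_mm + as.numeric(t(Rb) %*% a$trans_mm)
  rigid_transform(euler_zyx_from_matrix(Rc), tc, a$center)
}

#' @rdname compose
#' @export
invert <- function(t) {
  R <- rt_matrix(t)
  rigid_transform(euler_zyx_from_matrix(base::t(R)),
                  -as.numeric(R %*% t$trans_mm), t$center)
}

#' Worst-case rotational displacement on a sphere
#'
#' Maximum displacement `|R p - p|` over points `p` on a sphere of the given
#' radius centred at the rotation centre. For a rotation of total angle
#' `theta` this is `2 * radius * sin(theta / 2)`, attained on the great circle
#' perpendicular to the rotation axis. The default 64 mm radius is a standard
#' proxy for the human head.
#'
#' @param t a [rigid_transform()].
#' @param radius_mm sphere radius in mm.
#' @return displacement in mm.
#' @export
rotation_displacement <- function(t, radius_mm = 64) {
  if (radius_mm <= 0) stop("`radius_mm` must be positive")
  R <- rt_matrix(t)
  ctheta <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
  2 * radius_mm * sin(acos(ctheta) / 2)
}

#' Motion score of a rigid transform
#'
#' Tisdall-style scalar severity of a head motion: the worst-case displacement
#' of a point on a 64 mm-radius sphere due to the rotation, plus the Euclidean
#' norm of the translation,
#' `score = deltaR + sqrt(dx^2 + dy^2 + dz^2)` (mm). Higher is worse.
#'
#' @inheritParams rotation_displacement
#' @return A list of class `motion_score_report` with elements `delta_R`,
#'   `translation_norm` and `score`, all in mm.
#' @examples
#' motion_score(rigid_transform(trans_mm = c(3, 4, 0)))$score # 5
#' @export
motion_score <- function(t, radius_mm = 64) {
  dR <- rotation_displacement(t, radius_mm)
  tn <- sqrt(sum(t$trans_mm^2))
  structure(list(delta_R = dR, translation_norm = tn, score = dR + tn),
            class = "motion_score_report")
}

#' @export
print.motion_score_report <- function(x, ...) {
  cat(sprintf("motion score %.3f mm (deltaR %.3f + |t| %.3f)\n",
              x$score, x$delta_R, x$translation_norm))
  invisible(x)
}

#' Residual motion score against ground truth
#'
#' Motion score of the residual transform `T_residual = T_detected *
#' T_ground_truth^-1`: zero exactly when the detected transform equals the
#' ground truth, and a physically interpretable registration error (mm)
#' otherwise.
#'
#' @param detected,ground_truth [rigid_transform()] objects with the same
#'   centre convention.
#' @inheritParams rotation_displacement
#' @return residual motion score in mm.
#' @export
residual_motion_score <- function(detected, ground_truth, radius_mm = 64) {
  check_same_center(detected, ground_truth)
  motion_score(compose(detected, invert(ground_truth)), radius_mm)$score
}

#' Read / write a rigid transform as JSON
#'
#' The on-disk schema records the parameters together with the conventions:
#' `{"rot_deg": [rz, ry, rx], "trans_mm": [tx, ty, tz], "order": "ZYX",
#'   "center": "volume_center", "convention": "translate_then_rotate"}`.
#'
#' @param path file path.
#' @return `read_transform` returns a [rigid_transform()]; `write_transform`
#'   returns `path` invisibly.
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$order) && !identical(x$order, "ZYX"))
    stop("unsupported rotation order: ", x$order)
  rigid_transform(x$rot_deg, x$trans_mm,
                  if (is.null(x$center)) "volume_center" else x$center)
}

#' @rdname read_transform
#' @param t a [rigid_transform()].
#' @export
write_transform <- function(t, path) {
  jsonlite::write_json(
    list(rot_deg = t$rot_deg, trans_mm = t$trans_mm, order = "ZYX",
         center = t$center, convention = "translate_then_rotate"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
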