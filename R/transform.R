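#' Rigid transform
#'
#' A rigid-body transform parameterized by three Euler angles (degrees,
#' intrinsic Z-X-Z: phi about z, theta about the new x, psi about the new
#' z) and a translation in voxels.  Acting on a point `p` (0-based voxel
#' coordinates) about the rotation centre `c = floor(N/2)`:
#' `T(p) = R %*% (p - c) + c + shift`.
#'
#' @param phi,theta,psi Euler angles in degrees.
#' @param shift numeric length-3 translation in voxels.
#' @return an object of class `RigidTransform`.
#' @export
rigid_transform <- function(phi = 0, theta = 0, psi = 0, shift = c(0, 0, 0)) {
  stopifnot(length(shift) == 3)
  if (!all(is.finite(c(phi, theta, psi, shift))))
    stop("rigid_transform: non-finite transform parameters")
  structure(list(phi = phi, theta = theta, psi = psi,
                 shift = as.numeric(shift)),
            class = "RigidTransform")
}

#' @export
print.RigidTransform <- function(x, ...) {
  cat(sprintf("RigidTransform: phi=%.3f theta=%.3f psi=%.3f shift=(%.3f, %.3f, %.3f)\n",
              x$phi, x$theta, x$psi, x$shift[1], x$shift[2], x$shift[3]))
  invisible(x)
}

#' Rotation matrix from Z-X-Z Euler angles
#'
#' `R = Rz(phi) %*% Rx(theta) %*% Rz(psi)` with right-handed rotations.
#'
#' @param phi,theta,psi angles in degrees.
#' @return 3x3 rotation matrix.
#' @export
euler_to_matrix <- function(phi, theta, psi) {
  d <- pi / 180
  cf <- cos(phi * d); sf <- sin(phi * d)
  ct <- cos(theta * d); st <- sin(theta * d)
  cp <- cos(psi * d); sp <- sin(psi * d)
  matrix(c(cf * cp - sf * ct * sp, sf * cp + cf * ct * sp, st * sp,
           -cf * sp - sf * ct * cp, -sf * sp + cf * ct * cp, st * cp,
           sf * st, -cf * st, ct), nrow = 3)
}

#' Z-X-Z Euler angles from a rotation matrix
#'
#' Inverse of [euler_to_matrix()]; at the gimbal singularity
#' (theta near 0 or 180 degrees) psi is set to 0 and the full in-plane
#' rotation is assigned to phi.
#'
#' @param R 3x3 rotation matrix.
#' @return numeric vector `c(phi, theta, psi)` in degrees.
#' @export
matrix_to_euler <- function(R) {
  d <- 180 / pi
  ct <- max(-1, min(1, R[3, 3]))
  theta <- acos(ct) * d
  if (abs(R[3, 3]) > 1 - 1e-14) {
    # R is an in-plane rotation to machine precision: Rz(phi); theta is
    # snapped exactly to 0 or 180 (acos cannot resolve below ~1e-8 rad)
    phi <- atan2(R[2, 1], R[1, 1]) * d
    c(phi = phi, theta = if (R[3, 3] < 0) 180 else 0, psi = 0)
  } else {
    phi <- atan2(R[1, 3], -R[2, 3]) * d
    psi <- atan2(R[3, 1], R[3, 2]) * d
    c(phi = phi, theta = theta, psi = psi)
  }
}

#' Compose two rigid transforms
#'
#' `compose(a, b)` is the transform equivalent to applying `b` first and
#' `a` second: `apply_transform(v, compose(a, b))` equals
#' `apply_transform(apply_transform(v, b), a)` up to interpolation error.
#'
#' @param t_outer,t_inner `RigidTransform` objects.
#' @return the composed `RigidTransform`.
#' @export
compose <- function(t_outer, t_inner) {
  Ra <- euler_to_matrix(t_outer$phi, t_outer$theta, t_outer$psi)
  Rb <- euler_to_matrix(t_inner$phi, t_inner$theta, t_inner$psi)
  ang <- matrix_to_euler(Ra %*% Rb)
  rigid_transform(ang[1], ang[2], ang[3],
                  as.numeric(Ra %*% t_inner$shift) + t_outer$shift)
}

#' Invert a rigid transform
#'
#' @param t a `RigidTransform`.
#' @return the inverse transform such that `compose(t, invert(t))` is the
#'   identity within 1e-9 on angles and shift.
#' @export
invert <- function(t) {
  R <- euler_to_matrix(t$phi, t$theta, t$psi)
  ang <- matrix_to_euler(t(R))
  rigid_transform(ang[1], ang[2], ang[3], as.numeric(-t(R) %*% t$shift))
}

#' Geodesic angle between the rotations of two transforms
#'
#' @param a,b `RigidTransform` objects (or 3x3 rotation matrices).
#' @return rotation angle of `a %*% t(b)` in degrees, in `[0, 180]`.
#' @export
rotation_distance <- function(a, b) {
  Ra <- if (is.matrix(a)) a else euler_to_matrix(a$phi, a$theta, a$psi)
  Rb <- if (is.matrix(b)) b else euler_to_matrix(b$phi, b$theta, b$psi)
  tr <- sum(diag(Ra %*% t(Rb)))
  acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
}

#' Rotation distance modulo an n-fold symmetry axis
#'
#' Pose error against a reference that is n-fold symmetric about its z
#' axis: alignment can only determine the pose up to a rotation by
#' multiples of `360/n_fold` degrees, so the error is the minimum
#' geodesic distance over the symmetry-related copies of the truth.
#'
#' @param a estimated transform (or rotation matrix).
#' @param b true transform (or rotation matrix).
#' @param n_fold symmetry order of the reference (8 for the NPC).
#' @return angle in degrees.
#' @export
sym_rotation_distance <- function(a, b, n_fold = 8L) {
  Rb <- if (is.matrix(b)) b else euler_to_matrix(b$phi, b$theta, b$psi)
  min(vapply(seq_len(n_fold) - 1L, function(k) {
    rotation_distance(a, Rb %*% euler_to_matrix(360 * k / n_fold, 0, 0))
  }, numeric(1)))
}
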