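#' Euler angles to rotation matrix (ZYZ convention)
#'
#' Composes the rotation `R = Rz(psi) %*% Ry(tilt) %*% Rz(rot)` from the
#' three Euler angles of a particle, in degrees.  The projection direction
#' associated with the rotation is the rotated z-axis: the 2D Fourier
#' transform of a particle's projection samples the 3D transform of the
#' reference on the plane spanned by the first two rows of `R`.
#'
#' @param rot,tilt,psi Euler angles in degrees (any finite values; angles
#'   are taken modulo 360).
#' @return 3x3 orthonormal rotation matrix with determinant +1.
#' @seealso [matrix_to_euler()]
#' @export
euler_to_matrix <- function(rot, tilt, psi) {
  d2r <- pi / 180
  rz <- function(a) {
    ca <- cos(a); sa <- sin(a)
    matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
  }
  ry <- function(a) {
    ca <- cos(a); sa <- sin(a)
    matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
  }
  stopifnot(is.finite(rot), is.finite(tilt), is.finite(psi))
  rz(psi * d2r) %*% ry(tilt * d2r) %*% rz(rot * d2r)
}

#' Rotation matrix to ZYZ Euler angles
#'
#' Inverse of [euler_to_matrix()].  At the gimbal-locked poles
#' (tilt = 0 or 180) the split between `rot` and `psi` is not unique; the
#' convention here puts the whole in-plane rotation into `psi` and sets
#' `rot = 0`.
#'
#' @param R 3x3 rotation matrix.
#' @return numeric vector `c(rot, tilt, psi)` in degrees, with
#'   `tilt` in `[0, 180]` and `rot`, `psi` in `[-180, 180)`.
#' @export
matrix_to_euler <- function(R) {
  r2d <- 180 / pi
  ct <- max(-1, min(1, R[3, 3]))
  tilt <- acos(ct) * r2d
  if (abs(ct) > 1 - 1e-12) {
    # pole: only psi -/+ rot is determined; put it all into psi
    rot <- 0
    psi <- if (ct > 0) atan2(R[2, 1], R[1, 1]) * r2d
           else        atan2(-R[2, 1], -R[1, 1]) * r2d
  } else {
    rot <- atan2(R[3, 2], -R[3, 1]) * r2d
    psi <- atan2(R[2, 3], R[1, 3]) * r2d
  }
  c(rot = wrap_angle(rot), tilt = tilt, psi = wrap_angle(psi))
}

# rotation matrices for a whole particle set, as a 3 x 3 x n array
particle_rotations <- function(particles) {
  n <- nrow(particles)
  out <- array(0, dim = c(3, 3, n))
  for (i in seq_len(n))
    out[, , i] <- euler_to_matrix(particles$rot[i], particles$tilt[i],
                                  particles$psi[i])
  out
}
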