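# Euler angle conventions. Intrinsic ZXZ (phi, theta, psi), degrees.
# R = Rz(psi) %*% Rx(theta) %*% Rz(phi); x_tomo = R %*% x_ref + position.
# phi is the in-plane spin about the reference z axis: R %*% c(0,0,1) depends
# only on (theta, psi), which is why contour picking computes theta/psi from
# the local axis and randomizes phi.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

rot_z <- function(a) {
  a <- deg2rad(a)
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_x <- function(a) {
  a <- deg2rad(a)
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

rot_y <- function(a) {
  a <- deg2rad(a)
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' Euler angles to rotation matrix
#'
#' Intrinsic ZXZ convention: `R = Rz(psi) %*% Rx(theta) %*% Rz(phi)`, angles in
#' degrees, acting on column vectors. The rotated z axis `R %*% c(0,0,1)`
#' depends only on `theta` and `psi`; `phi` is the spin about the reference z.
#'
#' @param phi,theta,psi Euler angles in degrees, or `phi` may be a length-3
#'   vector `(phi, theta, psi)`.
#' @return 3x3 rotation matrix.
#' @export
euler_to_matrix <- function(phi, theta = NULL, psi = NULL) {
  if (is.null(theta)) {
    theta <- phi[2]; psi <- phi[3]; phi <- phi[1]
  }
  rot_z(psi) %*% rot_x(theta) %*% rot_z(phi)
}

#' Rotation matrix to Euler angles
#'
#' Inverse of [euler_to_matrix()]. Returns canonical ranges: `theta` in
#' `[0, 180]`, `phi` and `psi` in `[0, 360)`. At the gimbal singularities
#' (`theta` 0 or 180) the spin is assigned to `phi` and `psi = 0`.
#'
#' @param R 3x3 rotation matrix.
#' @return Named numeric vector `(phi, theta, psi)` in degrees.
#' @export
matrix_to_euler <- function(R) {
  ct <- max(-1, min(1, R[3, 3]))
  theta <- acos(ct)
  if (abs(ct) > 1 - 1e-10) {
    # theta ~ 0 or 180: R = Rz(psi +/- phi); put everything into phi
    psi <- 0
    phi <- atan2(R[2, 1], R[1, 1])
    if (ct < 0) phi <- -phi
  } else {
    # R = Rz(psi) Rx(theta) Rz(phi):
    # R[1,3] = sin(psi) sin(theta); R[2,3] = -cos(psi) sin(theta)
    # R[3,1] = sin(phi) sin(theta); R[3,2] =  cos(phi) sin(theta)
    psi <- atan2(R[1, 3], -R[2, 3])
    phi <- atan2(R[3, 1], R[3, 2])
  }
  out <- c(phi = rad2deg(phi) %% 360, theta = rad2deg(theta),
           psi = rad2deg(psi) %% 360)
  out
}

# Canonicalize an euler triple via its matrix
canonical_euler <- function(phi, theta, psi) {
  matrix_to_euler(euler_to_matrix(phi, theta, psi))
}

# Orientation with z along `tangent` (unit) and given in-plane spin phi.
# theta/psi computed so R %*% c(0,0,1) == tangent.
euler_from_tangent <- function(tangent, phi = 0) {
  n <- sqrt(sum(tangent^2))
  if (n < 1e-12) stop("zero-length axis vector")
  t <- tangent / n
  theta <- rad2deg(acos(max(-1, min(1, t[3]))))
  psi <- if (abs(abs(t[3]) - 1) < 1e-12) 0 else rad2deg(atan2(t[1], -t[2])) %% 360
  c(phi = phi %% 360, theta = theta, psi = psi)
}

# Rotation mapping local orthonormal frame (ex', ey', ez') -> columns
frame_to_matrix <- function(ex, ey, ez) {
  cbind(ex, ey, ez)
}
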