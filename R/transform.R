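# Rigid transforms in homogeneous coordinates.
#
# The parameterised constructor follows the convention used for placing a
# model in the neck frame: translation composed with three elemental
# rotations applied right-to-left,
#   M = T(p, q, r) %*% Rz(phi) %*% Ry(omega) %*% Rx(theta),
# where each elemental block is
#   Rz(phi)   = [ cos  sin 0; -sin cos 0; 0 0 1 ]
#   Ry(omega) = [ cos 0 -sin; 0 1 0; sin 0 cos ]
#   Rx(theta) = [ 1 0 0; 0 cos sin; 0 -sin cos ]
# (the transposes of the usual counter-clockwise matrices, i.e. clockwise
# rotations about +z, +y, +x).

rot_z <- function(phi) {
  c_ <- cos(phi); s_ <- sin(phi)
  matrix(c(c_, -s_, 0, s_, c_, 0, 0, 0, 1), 3L, 3L)
}
rot_y <- function(omega) {
  c_ <- cos(omega); s_ <- sin(omega)
  matrix(c(c_, 0, s_, 0, 1, 0, -s_, 0, c_), 3L, 3L)
}
rot_x <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(1, 0, 0, 0, c_, -s_, 0, s_, c_), 3L, 3L)
}

#' Rigid transform from displacements and rotation angles
#'
#' Builds the 4x4 homogeneous matrix
#' `T(p,q,r) \%*\% Rz(phi) \%*\% Ry(omega) \%*\% Rx(theta)` (angles in
#' radians, rotations applied right-to-left to column points).
#'
#' @param p,q,r displacements along x, y, z (mm)
#' @param phi,omega,theta rotation angles (radians) of the z-, y- and
#'   x-blocks respectively
#' @return object of class `rigid_transform` with elements `matrix` (4x4),
#'   `translation`, `angles`
#' @export
rigid_transform <- function(p = 0, q = 0, r = 0,
                            phi = 0, omega = 0, theta = 0) {
  R <- rot_z(phi) %*% rot_y(omega) %*% rot_x(theta)
  rigid_from_matrix(R, c(p, q, r))
}

#' Rigid transform from a rotation matrix and translation
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1
#' @param translation length-3 displacement (mm)
#' @return a `rigid_transform`
#' @export
rigid_from_matrix <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- vec3(translation, "translation")
  if (!all(dim(rotation) == c(3L, 3L))) {
    abort_validation("rotation must be 3 x 3")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9) {
    abort_validation("rotation block is not orthonormal with det +1")
  }
  m <- diag(4)
  m[1:3, 1:3] <- rotation
  m[1:3, 4L] <- translation
  structure(list(matrix = m,
                 translation = translation,
                 angles = decompose_angles(rotation)),
            class = "rigid_transform")
}

# recover (phi, omega, theta) with R = Rz(phi) Ry(omega) Rx(theta);
# from the composed product: R[3,1] = sin(omega), R[2,1] = -sin(phi)cos(omega),
# R[1,1] = cos(phi)cos(omega), R[3,2] = -cos(omega)sin(theta),
# R[3,3] = cos(omega)cos(theta)
decompose_angles <- function(R) {
  sw <- max(-1, min(1, R[3L, 1L]))
  omega <- asin(sw)
  if (abs(abs(sw) - 1) > 1e-12) {
    phi <- atan2(-R[2L, 1L], R[1L, 1L])
    theta <- atan2(-R[3L, 2L], R[3L, 3L])
  } else {
    # gimbal lock (omega = +-pi/2): only phi +- theta is determined;
    # fold everything into phi (at omega = +pi/2, R[1,2] = sin(phi+theta))
    phi <- atan2(R[1L, 2L], R[2L, 2L])
    theta <- 0
  }
  c(phi = phi, omega = omega, theta = theta)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform: t = (%.4g, %.4g, %.4g), angles (phi, omega, theta) = (%.4g, %.4g, %.4g) rad>\n",
              x$translation[1L], x$translation[2L], x$translation[3L],
              x$angles[1L], x$angles[2L], x$angles[3L]))
  invisible(x)
}

#' Apply a rigid transform to a matrix of points
#'
#' @param transform a `rigid_transform`
#' @param points n x 3 matrix (or length-3 vector)
#' @return transformed points, same shape
#' @export
transform_points <- function(transform, points) {
  single <- is.null(dim(points))
  if (single) points <- matrix(points, 1L, 3L)
  R <- transform$matrix[1:3, 1:3]
  t_ <- transform$matrix[1:3, 4L]
  out <- points %*% t(R)
  out <- sweep(out, 2L, -t_)
  if (single) out[1L, ] else out
}

#' Inverse of a rigid transform
#' @param transform a `rigid_transform`
#' @return the inverse `rigid_transform`
#' @export
transform_invert <- function(transform) {
  R <- transform$matrix[1:3, 1:3]
  t_ <- transform$matrix[1:3, 4L]
  rigid_from_matrix(t(R), -t(R) %*% t_)
}

# minimal (geodesic) rotation taking unit vector `from` onto unit `to`
rotation_between <- function(from, to) {
  f <- from / sqrt(sum(from^2))
  t_ <- to / sqrt(sum(to^2))
  v <- cross3(f, t_)
  c_ <- sum(f * t_)
  if (c_ < -1 + 1e-12) {
    # antipodal: rotate pi about any axis orthogonal to `from`
    ax <- cross3(f, c(1, 0, 0))
    if (sum(ax^2) < 1e-12) ax <- cross3(f, c(0, 1, 0))
    ax <- ax / sqrt(sum(ax^2))
    K <- matrix(c(0, ax[3L], -ax[2L], -ax[3L], 0, ax[1L],
                  ax[2L], -ax[1L], 0), 3L, 3L)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, v[3L], -v[2L], -v[3L], 0, v[1L], v[2L], -v[1L], 0), 3L, 3L)
  diag(3) + K + K %*% K / (1 + c_)
}
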