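# Small rotation-matrix toolbox used throughout the package. All rotations
# are 3x3 proper orthonormal matrices acting on column vectors.

#' Elementary rotation matrices
#'
#' Right-handed rotations about the global x, y and z axes.
#'
#' @param theta Rotation angle in radians.
#' @return A 3x3 rotation matrix.
#' @keywords internal
#' @name elementary-rotations
NULL

#' @rdname elementary-rotations
#' @export
rot_x <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(1, 0, 0,
           0, c, s,
           0, -s, c), 3, 3)
}

#' @rdname elementary-rotations
#' @export
rot_y <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, 0, -s,
           0, 1, 0,
           s, 0, c), 3, 3)
}

#' @rdname elementary-rotations
#' @export
rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0,
           -s, c, 0,
           0, 0, 1), 3, 3)
}

#' Rotation about an arbitrary axis (Rodrigues formula)
#'
#' @param axis Length-3 axis vector; normalized internally.
#' @param angle Rotation angle in radians.
#' @return A 3x3 rotation matrix.
#' @export
rot_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n == 0) return(diag(3))
  u <- axis / n
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Check that a matrix is a proper rotation
#'
#' @param R 3x3 matrix.
#' @param tol Tolerance on orthonormality and on det(R) - 1.
#' @return Logical scalar.
#' @export
is_rotation <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3, 3)) && all(is.finite(R)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

#' Project a matrix onto the nearest rotation
#'
#' Orthogonal Procrustes projection via SVD: the closest (Frobenius norm)
#' proper rotation to an arbitrary 3x3 matrix. Used to re-orthonormalize
#' time-averaged or interpolated orientation matrices.
#'
#' @param M 3x3 matrix with positive determinant "near" SO(3).
#' @return A 3x3 rotation matrix.
#' @export
nearest_rotation <- function(M) {
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u
    u[, 3] <- -u[, 3]
    R <- u %*% t(s$v)
  }
  R
}

#' Geodesic angle between two rotations
#'
#' The rotation angle of `t(Ra) %*% Rb`, i.e. the geodesic distance on SO(3).
#'
#' @param Ra,Rb 3x3 rotation matrices.
#' @return Angle in radians, in `[0, pi]`.
#' @export
rotation_angle <- function(Ra, Rb) {
  tr <- sum(Ra * Rb)  # trace(t(Ra) %*% Rb)
  acos(pmin(1, pmax(-1, (tr - 1) / 2)))
}

#' Uniformly random rotation matrix
#'
#' Drawn from the Haar measure on SO(3) via quaternions.
#'
#' @param n Number of rotations.
#' @return A single 3x3 matrix when `n = 1`, else a list of matrices.
#' @export
random_rotation <- function(n = 1) {
  one <- function() {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    quat_to_matrix(q)
  }
  if (n == 1) one() else replicate(n, one(), simplify = FALSE)
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# Small random perturbation rotations: angle ~ |N(0, sd_rad)|, axis uniform
# on the sphere. Returns a list of n matrices.
random_small_rotations <- function(n, sd_rad) {
  if (sd_rad <= 0) return(replicate(n, diag(3), simplify = FALSE))
  angles <- abs(stats::rnorm(n, 0, sd_rad))
  axes <- matrix(stats::rnorm(3 * n), n, 3)
  lapply(seq_len(n), function(i) rot_axis_angle(axes[i, ], angles[i]))
}
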