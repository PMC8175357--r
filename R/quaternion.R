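# Quaternion helpers. Convention: q = (w, x, y, z), unit norm, acting as the
# body -> lab rotation. Kept in plain numeric vectors; these are internal
# plumbing for poses, not a user-facing class.

#' Convert a unit quaternion to a rotation matrix
#'
#' @param q Numeric length-4 quaternion `(w, x, y, z)`.
#' @return A 3x3 rotation matrix mapping body-frame to lab-frame vectors.
#' @export
quat_to_matrix <- function(q) {
  stopifnot(length(q) == 4)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Quaternion from an axis-angle rotation vector
#'
#' The exponential map: the direction of `phi` is the rotation axis and its
#' norm the rotation angle in radians.
#'
#' @param phi Numeric length-3 rotation vector.
#' @return Unit quaternion `(w, x, y, z)`.
#' @export
quat_from_rotvec <- function(phi) {
  a <- sqrt(sum(phi^2))
  if (a < 1e-14) return(c(1, 0, 0, 0))
  c(cos(a / 2), sin(a / 2) * phi / a)
}

#' Hamilton product of two quaternions
#'
#' @param a,b Quaternions `(w, x, y, z)`.
#' @return The product `a * b` (apply `b` first, then `a`).
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Random uniform unit quaternion
#'
#' Shoemake's subgroup algorithm; draws from the Haar measure on SO(3) using
#' R's RNG stream.
#'
#' @return Unit quaternion `(w, x, y, z)`.
#' @export
quat_random <- function() {
  u <- runif(3)
  c(sqrt(u[1]) * cos(2 * pi * u[3]),
    sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]))
}

# apply a pose (translation t, quaternion q) to body-frame coordinates
# (n x 3 matrix, already relative to the body's reference COM)
pose_apply <- function(coords, t, q) {
  R <- quat_to_matrix(q)
  sweep(coords %*% t(R), 2, t, "+")
}
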