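# Small geometry helpers shared across modules.

unit3 <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Angle between two vectors in degrees
#' @noRd
vec_angle <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na < 1e-12 || nb < 1e-12) stop("angle undefined for zero-length vector")
  acos(max(-1, min(1, sum(a * b) / (na * nb)))) * 180 / pi
}

rowdist <- function(a, b) sqrt(rowSums((a - b)^2))

#' Random proper rotation matrix (uniform over SO(3))
#' @noRd
random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    n <- sqrt(sum(q^2))
    if (n > 1e-8) break
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Rotation matrix about an arbitrary axis
#' @noRd
rotation_about_axis <- function(axis, degrees) {
  u <- unit3(axis)
  th <- degrees * pi / 180
  ct <- cos(th); st <- sin(th)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + st * K + (1 - ct) * (K %*% K)
}

# Apply rigid transform to an n x 3 coordinate matrix.
transform_xyz <- function(xyz, R = diag(3), t = c(0, 0, 0)) {
  sweep(xyz %*% t(R), 2, t, "+")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
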