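#' Draw a uniformly distributed random rotation
#'
#' Samples a rotation uniformly over SO(3) (Haar measure) via a uniform
#' unit quaternion (four standard normals, normalized) and reports it as
#' ZYZ Euler angles. Naive uniform sampling of Euler triples is biased
#' towards the poles; the quaternion route is the standard fix.
#'
#' Consumes four draws from the current RNG stream; seed the stream for
#' reproducibility.
#'
#' @return list with \code{euler} = c(alpha, beta, gamma) in radians (ZYZ
#'   convention) and \code{R} the corresponding 3 x 3 rotation matrix
#' @export
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  R <- quat_to_matrix(q)
  list(euler = matrix_to_zyz(R), R = R)
}

#' Convert a unit quaternion to a rotation matrix
#' @param q numeric length-4 (w, x, y, z), assumed unit norm
#' @return 3 x 3 rotation matrix
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Extract ZYZ Euler angles from a rotation matrix
#' @param R 3 x 3 rotation matrix
#' @return numeric length-3: alpha, beta, gamma (radians), with
#'   \code{R = Rz(alpha) Ry(beta) Rz(gamma)}
#' @export
matrix_to_zyz <- function(R) {
  beta <- acos(max(-1, min(1, R[3, 3])))
  if (sin(beta) > 1e-10) {
    alpha <- atan2(R[2, 3], R[1, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
  } else {
    # gimbal: fold everything into alpha
    alpha <- atan2(R[2, 1], R[1, 1])
    gamma <- 0
  }
  c(alpha = alpha, beta = beta, gamma = gamma)
}

#' Build a rotation matrix from ZYZ Euler angles
#' @param euler numeric length-3: alpha, beta, gamma (radians)
#' @return 3 x 3 rotation matrix
#' @export
zyz_to_matrix <- function(euler) {
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                             0, 0, 1), 3, 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                             sin(t), 0, cos(t)), 3, 3)
  rz(euler[1]) %*% ry(euler[2]) %*% rz(euler[3])
}

#' Draw a uniformly distributed random unit direction
#'
#' Normalized standard-normal 3-vector; consumes three RNG draws.
#' @return unit 3-vector
#' @export
random_direction <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}
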