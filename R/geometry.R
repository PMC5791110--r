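# Small geometry helpers shared by the chain builder and assembly code.

.normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotation matrix sending unit vector a onto unit vector b (Rodrigues).
.rotation_between <- function(a, b) {
  a <- .normalize(a); b <- .normalize(b)
  v <- .cross3(a, b)
  c2 <- sum(a * b)
  if (c2 > 1 - 1e-12) return(diag(3))
  if (c2 < -1 + 1e-12) {
    # opposite vectors: rotate pi about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- .normalize(.cross3(a, p))
    return(.axis_angle(ax, pi))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c2)
}

.axis_angle <- function(axis, theta) {
  axis <- .normalize(axis)
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  c1 <- cos(theta); s <- sin(theta); C <- 1 - c1
  matrix(c(c1 + x * x * C, x * y * C + z * s, x * z * C - y * s,
           x * y * C - z * s, c1 + y * y * C, y * z * C + x * s,
           x * z * C + y * s, y * z * C - x * s, c1 + z * z * C), 3, 3)
}

# Given the unit directions u1 (and optionally u2) of existing bonds at a
# tetrahedral center, return the remaining ideal bond directions.
.tetra_directions <- function(u1, u2 = NULL, ref = c(0, 0, 1)) {
  th <- acos(-1 / 3)            # 109.471 deg
  if (!is.null(u2)) {
    b1 <- .normalize(u1 + u2)
    n <- .normalize(.cross3(u1, u2))
    list(-cos(th / 2) * b1 + sin(th / 2) * n,
         -cos(th / 2) * b1 - sin(th / 2) * n)
  } else {
    # three directions completing a tetrahedron around -u1
    u1 <- .normalize(u1)
    p <- ref - sum(ref * u1) * u1
    if (sqrt(sum(p^2)) < 1e-6) {
      alt <- if (abs(u1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      p <- alt - sum(alt * u1) * u1
    }
    p <- .normalize(p)
    q <- .cross3(u1, p)
    lapply(c(0, 2 * pi / 3, 4 * pi / 3), function(phi) {
      cos(th) * u1 + sin(th) * (cos(phi) * p + sin(phi) * q)
    })
  }
}

# All-pairs Euclidean distance matrix between two coordinate matrices.
.cdist <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
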