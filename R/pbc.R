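# Minimum-image distance machinery for periodic boxes.

# Squared minimum-image distances between rows of A and rows of B under
# an orthorhombic box (length-3 vector, Angstrom). Returns an
# nrow(A) x nrow(B) matrix.
.pbc_dist2 <- function(A, B, box) {
  out <- 0
  for (k in 1:3) {
    d <- outer(A[, k], B[, k], "-")
    d <- d - box[k] * round(d / box[k])
    out <- out + d * d
  }
  out
}

.pbc_cdist <- function(A, B, box) sqrt(.pbc_dist2(A, B, box))

# Minimum-image displacement vectors from a (length-3) to rows of B.
.pbc_disp <- function(a, B, box) {
  d <- sweep(B, 2, a)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

# Wrap coordinates into [0, box).
.pbc_wrap <- function(X, box) {
  for (k in 1:3) X[, k] <- X[, k] - box[k] * floor(X[, k] / box[k])
  X
}

# Brute-force 27-image squared distance (test oracle for the minimum
# image convention on small systems).
.pbc_dist2_brute <- function(A, B, box) {
  shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1))
  best <- NULL
  for (s in seq_len(nrow(shifts))) {
    Bs <- sweep(B, 2, shifts[s, ] * box, "+")
    a2 <- rowSums(A^2); b2 <- rowSums(Bs^2)
    d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, Bs)
    best <- if (is.null(best)) d2 else pmin(best, d2)
  }
  pmax(best, 0)
}
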