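#' Place a mobile molecule at van der Waals contact with a static one
#'
#' Implements the contact step of the rigid-body sampling protocol: both
#' molecules are centered on their mass centers, the mobile molecule is
#' rotated by the given ZYZ Euler angles, then translated along the given
#' direction by the smallest distance at which the two van der Waals
#' surfaces touch without overlapping.
#'
#' The translation magnitude is solved analytically: for every atom pair
#' (i static, j mobile) the condition |p_i - (R q_j + t u)| = r_i + r_j
#' is a quadratic in t; pairs with no real root never touch along the ray
#' and are ignored; the contact distance is the maximum over pairs of the
#' larger root. At the returned pose the minimum surface gap is zero to
#' within 1e-6 Angstrom and no pair overlaps.
#'
#' @param static_mol a \code{molecule} (kept fixed)
#' @param mobile_mol a \code{molecule} (rotated and translated)
#' @param euler ZYZ Euler angles, radians
#' @param direction translation direction (need not be normalized)
#' @return list with \code{pose} (list: \code{euler}, \code{direction}
#'   unit vector, \code{contact_t} Angstrom) and \code{mobile}, the
#'   positioned copy of \code{mobile_mol}
#' @export
place_at_contact <- function(static_mol, mobile_mol, euler, direction) {
  u <- .normalize(as.numeric(direction))
  R <- zyz_to_matrix(euler)
  P <- sweep(coords(static_mol), 2, center_of_mass(static_mol))
  Q0 <- sweep(coords(mobile_mol), 2, center_of_mass(mobile_mol))
  Q <- Q0 %*% t(R)
  t_contact <- .contact_distance(P, static_mol$atoms$vdw,
                                 Q, mobile_mol$atoms$vdw, u)
  if (!is.finite(t_contact)) {
    stop("contact failure: no atom pair intersects along the ray",
         call. = FALSE)
  }
  mob <- set_coords(mobile_mol, sweep(Q, 2, t_contact * u, "+"))
  list(pose = list(euler = euler, direction = u, contact_t = t_contact),
       mobile = mob)
}

# Analytic contact distance: max over pairs of the larger quadratic root.
# P (n1 x 3) static coords, Q (n2 x 3) rotated mobile coords (centered),
# u unit direction. Returns -Inf if no pair has a real root.
.contact_distance <- function(P, rP, Q, rQ, u) {
  pu <- drop(P %*% u)              # n1
  qu <- drop(Q %*% u)              # n2
  # a_ij . u  with a_ij = p_i - q_j
  au <- outer(pu, qu, "-")
  a2 <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * tcrossprod(P, Q)
  Rsum <- outer(rP, rQ, "+")
  disc <- au^2 - a2 + Rsum^2
  ok <- disc >= 0
  if (!any(ok)) return(-Inf)
  max(au[ok] + sqrt(disc[ok]))
}
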