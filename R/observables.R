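# A "frame" for the observable functions is a list with elements
# `xyz` (n x 3), `topology` (see hs_trajectory) and `box` (length 3);
# molecules can be passed where noted via the convenience wrappers.

.as_frame <- function(x) {
  if (inherits(x, "molecule")) {
    topo <- topology_from_molecules(list(x))
    list(xyz = coords(x), topology = topo, box = NULL)
  } else x
}

# Body-fixed orthonormal frame from the coordinate covariance, with a
# deterministic sign convention; rotating the structure rotates the
# frame identically, which makes lattice-based estimates rigid-motion
# invariant. Falls back to the identity for degenerate selections.
.principal_frame <- function(xyz) {
  if (nrow(xyz) < 3) return(diag(3))
  X <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)
  if (min(abs(diff(ev$values))) < 1e-9) return(diag(3))
  V <- ev$vectors
  # orient each axis by the sign of the third moment along it, a
  # body-fixed (rotation-covariant) convention
  for (k in 1:3) {
    m3 <- sum((X %*% V[, k])^3)
    if (abs(m3) < 1e-9) return(diag(3))
    if (m3 < 0) V[, k] <- -V[, k]
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  V
}

# deterministic Fibonacci-lattice unit sphere point set
.fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the selection: each atom's sphere of
#' radius \code{r_vdw + probe_radius} is sampled with a deterministic
#' Fibonacci lattice of \code{n_points} points, and the area is the
#' exposed fraction times the sphere area, summed over atoms. Occlusion
#' is computed within the selection only (the selection is treated as
#' the solute in isolation), without periodic images. The lattice is
#' expressed in the selection's principal-axis frame, so the estimate
#' is exactly invariant under rigid motion of the structure.
#'
#' @param frame a frame (list with \code{xyz}, \code{topology}) or a
#'   \code{molecule}
#' @param selection atom row indices (default: all atoms)
#' @param probe_radius probe radius, Angstrom (water: 1.4)
#' @param n_points lattice points per atom
#' @return area, Angstrom^2
#' @export
sasa <- function(frame, selection = NULL, probe_radius = 1.4,
                 n_points = 960) {
  fr <- .as_frame(frame)
  if (is.null(selection)) selection <- seq_len(nrow(fr$xyz))
  if (length(selection) < 1) stop("sasa: empty selection", call. = FALSE)
  xyz <- fr$xyz[selection, , drop = FALSE]
  rad <- vdw_radius(fr$topology$element[selection]) + probe_radius
  pts <- .fib_sphere(n_points) %*% t(.principal_frame(xyz))
  n <- nrow(xyz)
  total <- 0
  # neighbour prefilter: only atoms whose expanded spheres can intersect
  d2 <- .pbc_dist2(xyz, xyz, box = rep(1e9, 3))
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    p_i <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      occluded <- rep(FALSE, n_points)
      for (j in nb) {
        dj <- sweep(p_i, 2, xyz[j, ])
        occluded <- occluded | (rowSums(dj * dj) < rad[j]^2)
        if (all(occluded)) break
      }
      exposed <- sum(!occluded) / n_points
    } else {
      exposed <- 1
    }
    total <- total + exposed * 4 * pi * rad[i]^2
  }
  total
}

#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of the selected atoms from
#' their center of mass,
#' \eqn{R_g = \sqrt{\sum_i m_i |r_i - r_{com}|^2 / \sum_i m_i}}.
#'
#' @inheritParams sasa
#' @return Angstrom
#' @export
rgyr <- function(frame, selection = NULL) {
  fr <- .as_frame(frame)
  if (is.null(selection)) selection <- seq_len(nrow(fr$xyz))
  if (length(selection) < 1) stop("rgyr: empty selection", call. = FALSE)
  xyz <- fr$xyz[selection, , drop = FALSE]
  m <- atomic_mass(fr$topology$element[selection])
  com <- drop(crossprod(xyz, m) / sum(m))
  sqrt(sum(m * rowSums(sweep(xyz, 2, com)^2)) / sum(m))
}

#' Water molecules in the hydration shell of the hydrogel
#'
#' Counts water molecules whose oxygen lies within
#' \code{backbone_cutoff} of any hydrogel heavy atom \emph{or} within
#' \code{com_radius} of the hydrogel center of mass (union criterion),
#' using minimum-image distances when the frame has a box. The
#' center-of-mass radius is conventionally set to the hydrogel's radius
#' of gyration.
#'
#' @param frame a frame with waters and hydrogel atoms in its topology
#' @param backbone_cutoff Angstrom (default 3.0)
#' @param com_radius Angstrom (> 0)
#' @return integer count
#' @export
water_shell_count <- function(frame, backbone_cutoff = 3.0, com_radius) {
  fr <- .as_frame(frame)
  if (!is.numeric(com_radius) || com_radius <= 0) {
    stop("com_radius must be positive", call. = FALSE)
  }
  topo <- fr$topology
  box <- if (is.null(fr$box)) rep(1e9, 3) else fr$box
  wat_o <- which(topo$role == "water" & topo$element == "O")
  if (!length(wat_o)) return(0L)
  gel <- which(topo$role == "hydrogel")
  gel_heavy <- gel[topo$element[gel] != "H"]
  m <- atomic_mass(topo$element[gel])
  com <- drop(crossprod(fr$xyz[gel, , drop = FALSE], m) / sum(m))
  W <- fr$xyz[wat_o, , drop = FALSE]
  near_backbone <- if (length(gel_heavy)) {
    d2 <- .pbc_dist2(W, fr$xyz[gel_heavy, , drop = FALSE], box)
    apply(d2 <= backbone_cutoff^2, 1, any)
  } else rep(FALSE, nrow(W))
  d2c <- drop(.pbc_dist2(W, matrix(com, 1), box))
  sum(near_backbone | d2c <= com_radius^2)
}

#' Pesticide capture percentage
#'
#' A pesticide molecule counts as captured when any of its atoms lies
#' within \code{cutoff} of any hydrogel heavy atom (minimum image).
#' Returns \code{100 * captured / total}.
#'
#' @param frame a frame with at least one DMT molecule
#' @param cutoff contact distance, Angstrom (default 4.5)
#' @return percent in [0, 100]
#' @export
capture_fraction <- function(frame, cutoff = 4.5) {
  fr <- .as_frame(frame)
  topo <- fr$topology
  box <- if (is.null(fr$box)) rep(1e9, 3) else fr$box
  dmt <- which(topo$role == "DMT")
  if (!length(dmt)) stop("capture_fraction: no DMT molecules in topology",
                         call. = FALSE)
  gel <- which(topo$role == "hydrogel" & topo$element != "H")
  mols <- unique(topo$mol_id[dmt])
  d2 <- .pbc_dist2(fr$xyz[dmt, , drop = FALSE],
                   fr$xyz[gel, , drop = FALSE], box)
  near <- apply(d2 <= cutoff^2, 1, any)
  captured <- vapply(mols, function(mid) {
    any(near[topo$mol_id[dmt] == mid])
  }, logical(1))
  100 * sum(captured) / length(mols)
}

#' Geometric hydrogen-bond count between hydrogel and pesticide
#'
#' Counts donor-hydrogen-acceptor triples (D-H...A) crossing the
#' hydrogel/DMT boundary (either direction) that satisfy the geometric
#' criterion: donor-acceptor distance at most \code{d_cut} (extended to
#' \code{d_cut_s} for sulfur acceptors) and deviation of the D-H...A
#' angle from linearity at most \code{angle_cut} degrees. Donors are
#' O/N/S atoms bearing a hydrogen; acceptors are O, N and S.
#'
#' @param frame a frame with donor/acceptor flags in its topology
#' @param d_cut donor-acceptor cutoff, Angstrom
#' @param d_cut_s cutoff when the acceptor is sulfur, Angstrom
#' @param angle_cut linearity tolerance, degrees
#' @return integer count of (D, H, A) triples
#' @export
hbond_count <- function(frame, d_cut = 3.0, d_cut_s = 3.5,
                        angle_cut = 30) {
  fr <- .as_frame(frame)
  topo <- fr$topology
  box <- if (is.null(fr$box)) rep(1e9, 3) else fr$box
  hydro <- topo$role == "hydrogel"
  dmtm <- topo$role == "DMT"
  hs <- which(topo$element == "H" & !is.na(topo$h_parent))
  hs <- hs[topo$is_donor[topo$h_parent[hs]]]
  if (any(topo$is_donor & (hydro | dmtm)) && !length(hs)) {
    stop("hbond topology error: donors are flagged but no hydrogen ",
         "positions are attached to them", call. = FALSE)
  }
  count <- 0L
  for (h in hs) {
    don <- topo$h_parent[h]
    acc_pool <- if (hydro[don]) which(dmtm & topo$is_acceptor)
                else if (dmtm[don]) which(hydro & topo$is_acceptor)
                else integer(0)
    if (!length(acc_pool)) next
    dpos <- fr$xyz[don, ]
    hpos <- fr$xyz[h, ]
    da <- .pbc_disp(dpos, fr$xyz[acc_pool, , drop = FALSE], box)
    dd <- sqrt(rowSums(da * da))
    lim <- ifelse(topo$element[acc_pool] == "S", d_cut_s, d_cut)
    cand <- which(dd <= lim)
    for (k in cand) {
      a <- acc_pool[k]
      hd <- drop(.pbc_disp(hpos, matrix(dpos, 1), box))
      ha <- drop(.pbc_disp(hpos, fr$xyz[a, , drop = FALSE], box))
      cosang <- sum(hd * ha) / sqrt(sum(hd^2) * sum(ha^2))
      theta <- acos(max(-1, min(1, cosang))) * 180 / pi
      if (180 - theta <= angle_cut) count <- count + 1L
    }
  }
  count
}
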