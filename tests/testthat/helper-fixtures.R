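# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except the package's own shipped templates/tables.

# a bare molecule from an element/coordinate spec, zero charges unless
# given
toy_molecule <- function(elements, xyz, charges = NULL, bonds = NULL,
                         name = "toy", label = "other") {
  xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  molecule(data.frame(atom_id = seq_along(elements), element = elements,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      charge = charges %||% rep(0, length(elements)),
                      label = label, stringsAsFactors = FALSE),
           bonds, name = name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single atom molecule at a position
one_atom <- function(element = "C", at = c(0, 0, 0), charge = 0) {
  toy_molecule(element, at, charges = charge)
}

# brute-force 1-D oracle for the contact distance of two rigid
# molecules along direction u: scan down from far away for the largest
# t at which the surfaces interpenetrate, then bisect the sign change
# above it (independent of the analytic quadratic-root path)
bisect_contact <- function(P, rP, Q, rQ, u, hi = 60, step = 0.05,
                           tol = 1e-8) {
  gap_grid <- function(ts) {
    out <- rep(Inf, length(ts))
    for (i in seq_len(nrow(P))) {
      for (j in seq_len(nrow(Q))) {
        dx <- P[i, 1] - (Q[j, 1] + ts * u[1])
        dy <- P[i, 2] - (Q[j, 2] + ts * u[2])
        dz <- P[i, 3] - (Q[j, 3] + ts * u[3])
        out <- pmin(out, sqrt(dx^2 + dy^2 + dz^2) - (rP[i] + rQ[j]))
      }
    }
    out
  }
  ts <- seq(hi, -hi, by = -step)
  gs <- gap_grid(ts)
  k <- which(gs < 0)[1]
  if (is.na(k) || k == 1) return(NA_real_)
  lo <- ts[k]
  hi <- ts[k - 1]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (gap_grid(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# a tiny frame: explicit topology + one coordinate set
toy_frame <- function(elements, xyz, roles, mol_ids,
                      is_donor = NULL, is_acceptor = NULL,
                      h_parent = NULL, box = 1e6) {
  n <- length(elements)
  topo <- data.frame(element = elements, role = roles, mol_id = mol_ids,
                     is_donor = is_donor %||% rep(FALSE, n),
                     is_acceptor = is_acceptor %||%
                       (elements %in% c("O", "N", "S")),
                     h_parent = h_parent %||% rep(NA_integer_, n),
                     stringsAsFactors = FALSE)
  list(xyz = matrix(xyz, ncol = 3, byrow = TRUE), topology = topo,
       box = rep(box, 3))
}

# small packed system used by several network tests
toy_system <- function(n_chains = 2, monomers = 5, box = 25,
                       min_sep = 4, seed = 7) {
  pack_chains(n_chains, monomers, box = box, min_sep = min_sep,
              seed = seed)
}
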