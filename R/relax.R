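# harmonic bond force constant, kcal/mol/A^2 (steric-relief heuristic,
# not a calibrated force field)
.K_BOND <- 300

#' Steepest-descent geometry relaxation
#'
#' Relieves steric strain after structural edits: steepest descent on a
#' surrogate potential of harmonic bond-stretch terms (reference lengths
#' from the bond table's \code{r0} column, or the entry geometry) plus
#' Lennard-Jones repulsion/dispersion over non-bonded pairs (1-2 and 1-3
#' excluded, UFF parameters). Periodic systems use minimum-image
#' displacements. The non-bonded pair list is frozen at entry (pairs
#' within \code{cutoff}); energy is non-increasing across accepted steps
#' by backtracking line search.
#'
#' This is a steric-relief heuristic, not a physical model: it removes
#' hard clashes and pulls stretched ester bonds toward their reference
#' length without claiming thermodynamic meaning.
#'
#' @param x a \code{molecule}, \code{polymer_system} or
#'   \code{crosslink_network}
#' @param max_steps maximum descent steps
#' @param force_tol convergence threshold on the maximum atomic force
#'   component norm, kcal/mol/A
#' @param movable integer vector of atom row indices allowed to move
#'   (default: all)
#' @param cutoff non-bonded pair cutoff at entry, Angstrom
#' @param ... passed between methods
#' @return the relaxed object, with attributes \code{energy_trace}
#'   (accepted energies, kcal/mol) and \code{converged}
#' @export
relax <- function(x, max_steps = 200, force_tol = 1.0, ...) {
  UseMethod("relax")
}

#' @rdname relax
#' @export
relax.molecule <- function(x, max_steps = 200, force_tol = 1.0,
                           movable = NULL, cutoff = 8, box = NULL, ...) {
  .relax_core(x, box = box, max_steps = max_steps, force_tol = force_tol,
              movable = movable, cutoff = cutoff)
}

#' @rdname relax
#' @param box periodic box lengths (molecule method only)
#' @export
relax.polymer_system <- function(x, max_steps = 200, force_tol = 1.0,
                                 movable = NULL, cutoff = 8, ...) {
  x$mol <- .relax_core(x$mol, box = x$box, max_steps = max_steps,
                       force_tol = force_tol, movable = movable,
                       cutoff = cutoff)
  attr(x, "energy_trace") <- attr(x$mol, "energy_trace")
  attr(x, "converged") <- attr(x$mol, "converged")
  x
}

#' @rdname relax
#' @export
relax.crosslink_network <- function(x, max_steps = 200, force_tol = 1.0,
                                    movable = NULL, cutoff = 8, ...) {
  x$system <- relax(x$system, max_steps = max_steps,
                    force_tol = force_tol, movable = movable,
                    cutoff = cutoff)
  x
}

.relax_core <- function(mol, box = NULL, max_steps = 200, force_tol = 1.0,
                        movable = NULL, cutoff = 8) {
  n <- natoms(mol)
  xyz <- coords(mol)
  if (is.null(movable)) movable <- seq_len(n)
  idx <- stats::setNames(seq_len(n), as.character(mol$atoms$atom_id))

  # bonds as row-index pairs with reference lengths
  bi <- bj <- integer(0); r0 <- numeric(0)
  if (nrow(mol$bonds)) {
    bi <- unname(idx[as.character(mol$bonds$from)])
    bj <- unname(idx[as.character(mol$bonds$to)])
    r0 <- if (!is.null(mol$bonds$r0)) mol$bonds$r0
          else .bond_lengths(mol, box)
  }

  # frozen non-bonded pair list: pairs involving a movable atom, within
  # cutoff at entry, not 1-2/1-3
  mv <- sort(unique(movable))
  d2 <- if (is.null(box)) {
    .pbc_dist2(xyz[mv, , drop = FALSE], xyz, box = rep(1e9, 3))
  } else {
    .pbc_dist2(xyz[mv, , drop = FALSE], xyz, box)
  }
  hits <- which(d2 <= cutoff^2, arr.ind = TRUE)
  pi_ <- mv[hits[, 1]]; pj_ <- hits[, 2]
  keep <- pi_ < pj_ | (!(pj_ %in% mv) & pi_ != pj_)
  pi_ <- pi_[keep]; pj_ <- pj_[keep]
  excl <- .exclusion_keys(mol, idx, only = unique(c(pi_, pj_)))
  kk <- paste(pmin(pi_, pj_), pmax(pi_, pj_))
  nb <- !(kk %in% excl) & !duplicated(kk)
  pi_ <- pi_[nb]; pj_ <- pj_[nb]
  lj <- lj_params(mol$atoms$element)
  eps_ij <- sqrt(lj$eps[pi_] * lj$eps[pj_])
  sig_ij <- (lj$sigma[pi_] + lj$sigma[pj_]) / 2

  disp <- function(P, Q) {
    d <- P - Q
    if (!is.null(box)) for (k in 1:3) {
      d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    }
    d
  }
  energy_force <- function(X) {
    F <- matrix(0, n, 3)
    E <- 0
    if (length(bi)) {
      dv <- disp(X[bi, , drop = FALSE], X[bj, , drop = FALSE])
      d <- pmax(sqrt(rowSums(dv * dv)), 1e-6)
      E <- E + .K_BOND * sum((d - r0)^2)
      fmag <- -2 * .K_BOND * (d - r0) / d    # along dv acting on atom bi
      fv <- dv * fmag
      for (k in 1:3) {
        F[, k] <- F[, k] + tapply2(bi, fv[, k], n) - tapply2(bj, fv[, k], n)
      }
    }
    if (length(pi_)) {
      dv <- disp(X[pi_, , drop = FALSE], X[pj_, , drop = FALSE])
      d <- pmax(sqrt(rowSums(dv * dv)), 0.5)
      sr6 <- (sig_ij / d)^6
      E <- E + sum(4 * eps_ij * (sr6^2 - sr6))
      dEdd <- 4 * eps_ij * (-12 * sr6^2 + 6 * sr6) / d
      fv <- dv * (-dEdd / d)
      for (k in 1:3) {
        F[, k] <- F[, k] + tapply2(pi_, fv[, k], n) -
          tapply2(pj_, fv[, k], n)
      }
    }
    list(E = E, F = F)
  }

  ef <- energy_force(xyz)
  if (!is.finite(ef$E)) {
    stop("relax: non-finite energy at entry", call. = FALSE)
  }
  trace <- ef$E
  alpha <- 0.02
  converged <- FALSE
  for (step in seq_len(max_steps)) {
    Fm <- ef$F
    Fm[-mv, ] <- 0
    fmax <- sqrt(max(rowSums(Fm * Fm)))
    if (fmax <= force_tol) { converged <- TRUE; break }
    # cap the largest per-atom displacement at 0.2 A
    a <- min(alpha, 0.2 / fmax)
    accepted <- FALSE
    for (bt in 1:20) {
      Xn <- xyz
      Xn[mv, ] <- xyz[mv, ] + a * Fm[mv, , drop = FALSE]
      efn <- energy_force(Xn)
      if (is.finite(efn$E) && efn$E <= ef$E) {
        xyz <- Xn; ef <- efn
        trace <- c(trace, ef$E)
        alpha <- min(a * 1.5, 0.1)
        accepted <- TRUE
        break
      }
      a <- a / 2
    }
    if (!accepted) { converged <- TRUE; break }
  }
  out <- set_coords(mol, if (is.null(box)) xyz else .pbc_wrap(xyz, box))
  attr(out, "energy_trace") <- trace
  attr(out, "converged") <- converged
  out
}

# sum `vals` into bins given by `ind` over 1..n (fast grouped sum)
tapply2 <- function(ind, vals, n) {
  out <- numeric(n)
  agg <- rowsum(vals, ind)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# character keys "i j" (row indices, i<j) of 1-2 and 1-3 pairs; `only`
# restricts the scan to the given atom row indices (keys touching at
# least one of them), which keeps local relaxations cheap
.exclusion_keys <- function(mol, idx, only = NULL) {
  if (!nrow(mol$bonds)) return(character())
  bf <- unname(idx[as.character(mol$bonds$from)])
  bt <- unname(idx[as.character(mol$bonds$to)])
  adj <- split(c(bt, bf), c(bf, bt))
  atoms <- if (is.null(only)) names(adj) else
    intersect(as.character(only), names(adj))
  keys <- vector("list", length(atoms))
  for (ai in seq_along(atoms)) {
    a <- atoms[ai]
    i <- as.integer(a)
    nb1 <- adj[[a]]
    nb2 <- unique(unlist(adj[as.character(nb1)], use.names = FALSE))
    nb <- setdiff(unique(c(nb1, nb2)), i)
    keys[[ai]] <- paste(pmin(i, nb), pmax(i, nb))
  }
  unique(unlist(keys))
}
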