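#' Pack PVA chains into a periodic box
#'
#' Distributes \code{n_chains} idealized PVA chains of
#' \code{chain_length} monomers at random rigid placements (uniform
#' random rotation, uniform random origin) inside an orthorhombic
#' periodic box, rejecting any placement that brings two chains closer
#' than \code{min_sep} under the minimum-image convention. Each chain
#' gets its own atactic hydroxyl pattern derived from the seed. The
#' result is deterministic for a fixed seed.
#'
#' Near the jamming density pure rejection becomes exponentially slow,
#' so chains whose attempt budget runs out are kept at their best
#' attempt and the residual violations are resolved by a deterministic
#' rigid-body refinement that pushes offending chain pairs apart along
#' their closest-contact vector until every pair clears \code{min_sep}
#' (the same final constraint, reached the way practical packers reach
#' it).
#'
#' @param n_chains number of chains
#' @param chain_length monomers per chain
#' @param box box edge lengths, Angstrom (scalar or length-3)
#' @param min_sep minimum inter-chain atom-atom distance, Angstrom
#' @param seed integer seed
#' @param max_attempts placement attempts per chain before the
#'   refinement phase takes over
#' @return a \code{polymer_system}: list with \code{mol} (merged
#'   \code{molecule}; atom table carries a \code{chain} column),
#'   \code{box}, \code{sites} (hydroxyl crosslink-site registry:
#'   \code{chain}, \code{site}, \code{c_id}, \code{o_id}, \code{h_id},
#'   \code{used}), \code{n_monomers}, \code{seed}
#' @export
pack_chains <- function(n_chains, chain_length, box = 70, min_sep = 5,
                        seed = 1, max_attempts = 600) {
  if (length(box) == 1) box <- rep(box, 3)
  stopifnot(n_chains >= 1, chain_length >= 1, all(box > 0), min_sep >= 0)
  # coarse excluded-volume feasibility check: each atom claims a sphere
  # of radius ~min_sep/2
  chain0 <- build_pva_chain(chain_length, tacticity_seed = seed)
  vol_need <- n_chains * natoms(chain0) * (4 / 3) * pi * (min_sep / 2)^3
  if (vol_need > 2 * prod(box)) {
    stop("packing infeasible: requested chains cannot plausibly fit the box",
         call. = FALSE)
  }
  placed <- with_seed(seed, {
    chains <- vector("list", n_chains)
    occ <- list()        # per-chain coordinates (unwrapped, compact)
    occ_c <- list()      # carbon skeletons for the cheap first test
    occ_all <- NULL      # concatenated copies for the vectorized test
    occ_all_c <- NULL
    ms2 <- min_sep^2
    for (i in seq_len(n_chains)) {
      conformer <- 0L
      ch <- build_pva_chain(chain_length,
                            tacticity_seed = seed * 1009L + i,
                            conformation = "coil",
                            name = sprintf("chain%02d", i))
      ch <- translate_mol(ch, -center_of_mass(ch))
      is_c <- ch$atoms$element == "C"
      rad_new <- sqrt(max(rowSums(coords(ch)^2)))
      ok <- FALSE
      best_xyz <- NULL
      best_gap <- -Inf
      for (att in seq_len(max_attempts)) {
        # a stubborn conformer is redrawn periodically, like a flexible
        # packer would
        if (att %% 200L == 0L) {
          conformer <- conformer + 1L
          ch <- build_pva_chain(chain_length,
                                tacticity_seed = seed * 1009L + i +
                                  7919L * conformer,
                                conformation = "coil",
                                name = sprintf("chain%02d", i))
          ch <- translate_mol(ch, -center_of_mass(ch))
          is_c <- ch$atoms$element == "C"
          rad_new <- sqrt(max(rowSums(coords(ch)^2)))
        }
        R <- random_rotation()$R
        origin <- stats::runif(3) * box
        # kept unwrapped (each chain compact); minimum-image distances
        # are unaffected and bounding spheres stay meaningful
        xyz <- sweep(coords(ch) %*% t(R), 2, origin, "+")
        if (length(occ)) {
          # carbon-skeleton test against everything placed, full-atom
          # test only on a near-miss
          d2 <- min(.pbc_dist2(xyz[is_c, , drop = FALSE], occ_all_c,
                               box))
          if (d2 >= ms2) d2 <- min(.pbc_dist2(xyz, occ_all, box))
        } else {
          d2 <- Inf
        }
        if (d2 >= ms2) {
          chains[[i]] <- set_coords(ch, xyz)
          occ[[i]] <- xyz
          occ_c[[i]] <- xyz[is_c, , drop = FALSE]
          occ_all <- rbind(occ_all, xyz)
          occ_all_c <- rbind(occ_all_c, occ_c[[i]])
          ok <- TRUE
          break
        }
        if (d2 > best_gap) {
          best_gap <- d2
          best_xyz <- xyz
        }
      }
      if (!ok) {
        # keep the least-bad attempt; refinement resolves the residue
        chains[[i]] <- set_coords(ch, best_xyz)
        occ[[i]] <- best_xyz
        occ_c[[i]] <- best_xyz[is_c, , drop = FALSE]
        occ_all <- rbind(occ_all, best_xyz)
        occ_all_c <- rbind(occ_all_c, occ_c[[i]])
      }
    }
    chains
  })
  occ <- lapply(placed, coords)
  occ <- .push_apart(occ, box, min_sep,
                     occ_c = lapply(placed, function(m) {
                       coords(m)[m$atoms$element == "C", , drop = FALSE]
                     }))
  placed <- lapply(seq_along(placed), function(i) {
    set_coords(placed[[i]], .pbc_wrap(occ[[i]], box))
  })
  mol <- merge_molecules(lapply(seq_along(placed), function(i) {
    m <- placed[[i]]
    m$atoms$chain <- i
    m
  }), name = sprintf("pva_matrix_%dx%d", n_chains, chain_length))
  # carry an ideal reference length on every bond (used by relaxation)
  mol$bonds$r0 <- .bond_lengths(mol, box)
  offs <- cumsum(c(0L, vapply(placed, natoms, integer(1))))
  sites <- do.call(rbind, lapply(seq_along(placed), function(i) {
    s <- placed[[i]]$sites
    data.frame(chain = i, site = s$site, c_id = s$c_id + offs[i],
               o_id = s$o_id + offs[i], h_id = s$h_id + offs[i],
               used = FALSE)
  }))
  structure(list(mol = mol, box = box, sites = sites,
                 n_monomers = n_chains * chain_length, seed = seed,
                 min_sep = min_sep),
            class = "polymer_system")
}

#' @export
print.polymer_system <- function(x, ...) {
  cat(sprintf(paste0("<polymer_system> %d chains / %d monomers, box ",
                     "%.0fx%.0fx%.0f A, %d sites (%d used)\n"),
              max(x$mol$atoms$chain, na.rm = TRUE), x$n_monomers,
              x$box[1], x$box[2], x$box[3], nrow(x$sites),
              sum(x$sites$used)))
  invisible(x)
}

# Deterministic rigid-body refinement: translate the chains of every
# violating pair apart along their closest-contact vector until all
# inter-chain minimum distances clear min_sep. occ is a list of
# per-chain UNWRAPPED coordinate matrices (each chain compact); a
# centroid-plus-radius bound prunes pairs that cannot possibly violate,
# which keeps the atom-level work confined to actual near-contacts.
.push_apart <- function(occ, box, min_sep, occ_c = NULL,
                        max_iter = 3000) {
  n <- length(occ)
  if (n < 2) return(occ)
  if (is.null(occ_c)) occ_c <- occ
  cent <- t(vapply(occ, colMeans, numeric(3)))
  rad <- vapply(seq_len(n), function(i) {
    sqrt(max(rowSums(sweep(occ[[i]], 2, cent[i, ])^2)))
  }, numeric(1))
  # maximum reach of any atom from its chain's carbon skeleton
  reach <- max(vapply(seq_len(n), function(i) {
    d2 <- .pbc_dist2(occ[[i]], occ_c[[i]], rep(1e9, 3))
    sqrt(max(apply(d2, 1, min)))
  }, numeric(1)))
  pair_exact <- function(i, j) {
    d2 <- .pbc_dist2(occ[[i]], occ[[j]], box)
    k <- arrayInd(which.min(d2), dim(d2))
    a <- occ[[i]][k[1], ]
    dv <- drop(.pbc_disp(a, occ[[j]][k[2], , drop = FALSE], box))
    list(d = sqrt(min(d2)), u = dv / max(sqrt(sum(dv^2)), 1e-9))
  }
  pair_d <- function(i, j) {
    # centroid bound, then skeleton bound, then the exact minimum
    lb <- sqrt(.pbc_dist2(cent[i, , drop = FALSE],
                          cent[j, , drop = FALSE], box)[1, 1]) -
      rad[i] - rad[j]
    if (lb >= min_sep) return(lb)
    lb2 <- sqrt(min(.pbc_dist2(occ_c[[i]], occ_c[[j]], box))) - 2 * reach
    if (lb2 >= min_sep) return(lb2)
    pair_exact(i, j)$d
  }
  dmin <- matrix(Inf, n, n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    dmin[i, j] <- pair_d(i, j)
  }
  for (it in seq_len(max_iter)) {
    viol <- which(dmin < min_sep, arr.ind = TRUE)
    if (nrow(viol) == 0) return(occ)
    # accumulate the push from every violating pair, then apply all
    # displacements at once (Jacobi style), which untangles chains with
    # several simultaneous contacts far faster than pair-at-a-time
    disp <- matrix(0, n, 3)
    moved <- rep(FALSE, n)
    for (v in seq_len(nrow(viol))) {
      i <- viol[v, 1]; j <- viol[v, 2]
      info <- pair_exact(i, j)
      dmin[i, j] <- info$d
      if (info$d >= min_sep) next
      shift <- ((min_sep - info$d) * 0.6 + 0.02) / 2
      disp[i, ] <- disp[i, ] - shift * info$u
      disp[j, ] <- disp[j, ] + shift * info$u
      moved[i] <- moved[j] <- TRUE
    }
    if (!any(moved)) next
    for (i in which(moved)) {
      occ[[i]] <- sweep(occ[[i]], 2, disp[i, ], "+")
      occ_c[[i]] <- sweep(occ_c[[i]], 2, disp[i, ], "+")
      cent[i, ] <- cent[i, ] + disp[i, ]
    }
    for (i in which(moved)) {
      for (j in seq_len(n)) {
        if (j == i) next
        dmin[min(i, j), max(i, j)] <- pair_d(min(i, j), max(i, j))
      }
    }
  }
  stop("packing infeasible: rigid refinement did not converge",
       call. = FALSE)
}

# current lengths of all bonds of a molecule (used as harmonic
# reference); min-image if a box is given, since wrapped chains have
# bonds crossing the boundary
.bond_lengths <- function(mol, box = NULL) {
  if (!nrow(mol$bonds)) return(numeric())
  idx <- stats::setNames(seq_len(natoms(mol)),
                         as.character(mol$atoms$atom_id))
  xyz <- coords(mol)
  d <- xyz[idx[as.character(mol$bonds$from)], , drop = FALSE] -
    xyz[idx[as.character(mol$bonds$to)], , drop = FALSE]
  if (!is.null(box)) {
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  }
  sqrt(rowSums(d * d))
}

#' Brute-force minimum inter-chain distance of a packed system
#'
#' All-pairs minimum-image scan between atoms of different chains; the
#' independent audit for the packing constraint (quadratic cost, meant
#' for verification, not production).
#'
#' @param system a \code{polymer_system}
#' @return numeric, Angstrom (Inf for a single chain)
#' @export
min_interchain_distance <- function(system) {
  at <- system$mol$atoms
  chains <- sort(unique(at$chain[!is.na(at$chain)]))
  if (length(chains) < 2) return(Inf)
  xyz <- coords(system$mol)
  best <- Inf
  for (i in seq_along(chains)[-length(chains)]) {
    A <- xyz[at$chain %in% chains[i], , drop = FALSE]
    B <- xyz[!is.na(at$chain) & at$chain > chains[i], , drop = FALSE]
    best <- min(best, min(.pbc_dist2(A, B, system$box)))
  }
  sqrt(best)
}
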