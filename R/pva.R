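# Evaluate expr under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# idealized bond lengths (Angstrom)
.B_CC <- 1.54
.B_CO <- 1.43
.B_CH <- 1.09
.B_OH <- 0.96
# ester C(carbonyl)-O(ester) bond length used when forming crosslinks
.B_ESTER_CO <- 1.36

# fixed per-group partial charges for PVA chains; each chemical group is
# neutral so a chain's net charge is exactly zero
.Q_PVA <- list(CH2_C = -0.12, CH3_C = -0.18, CHOH_C = 0.205,
               H_C = 0.06, O = -0.683, H_O = 0.418)

#' Build an idealized atactic PVA chain
#'
#' Constructs a poly(vinyl alcohol) chain of \code{n_monomers} vinyl
#' alcohol units on an all-trans zigzag backbone (C-C 1.54 Angstrom,
#' tetrahedral angles) running along the x axis. The backbone carries
#' \code{2 * n_monomers + 1} carbons: methyl caps at both ends, a
#' hydroxyl-bearing carbon at every even position and a methylene between
#' each pair. Which side of the backbone plane each hydroxyl points to is
#' drawn from \code{tacticity_seed} (atactic placement); isotactic
#' variants are available for regular assemblies. Every hydroxyl is
#' registered as a crosslink site in the \code{sites} attribute
#' (\code{site}, \code{c_id}, \code{o_id}, \code{h_id}).
#'
#' Fixed neutral per-group partial charges are assigned, so the chain's
#' net charge is exactly zero. The construction is deterministic for a
#' fixed seed.
#'
#' @param n_monomers number of vinyl alcohol units (>= 1)
#' @param tacticity_seed integer seed controlling hydroxyl side placement
#'   (and, for coils, the backbone dihedral sequence)
#' @param tacticity \code{"atactic"} (seeded random sides),
#'   \code{"iso_up"} (all hydroxyls on +y), \code{"iso_down"}, or a
#'   numeric vector of +1/-1 sides, one per monomer, for explicit
#'   stereochemical idealizations
#' @param conformation \code{"extended"} (all-trans zigzag, the
#'   idealization used for nanopore walls) or \code{"coil"} (a
#'   self-avoiding random coil with backbone dihedrals drawn from the
#'   trans/gauche+/gauche- rotamers, the realistic shape for packing
#'   many long chains into a box)
#' @param name molecule name
#' @return a \code{molecule} with a \code{sites} element listing the
#'   hydroxyl crosslink sites
#' @export
#' @examples
#' ch <- build_pva_chain(5, tacticity_seed = 1)
#' nrow(ch$sites)  # 5 crosslink sites
build_pva_chain <- function(n_monomers, tacticity_seed = 1,
                            tacticity = c("atactic", "iso_up", "iso_down"),
                            conformation = c("extended", "coil"),
                            name = sprintf("pva_%dmer", n_monomers)) {
  conformation <- match.arg(conformation)
  if (!is.numeric(n_monomers) || length(n_monomers) != 1 ||
      is.na(n_monomers) || n_monomers < 1) {
    stop("n_monomers must be a positive integer", call. = FALSE)
  }
  n_monomers <- as.integer(n_monomers)
  nC <- 2L * n_monomers + 1L
  th <- acos(-1 / 3)
  a <- .B_CC * sin(th / 2)
  cz <- .B_CC * cos(th / 2)

  rng <- with_seed(tacticity_seed, list(
    sides = sample(c(-1, 1), n_monomers, replace = TRUE),
    dihedrals = .draw_dihedrals(nC)))
  if (is.numeric(tacticity)) {
    stopifnot(length(tacticity) == n_monomers, all(tacticity %in% c(-1, 1)))
    sides <- tacticity
  } else {
    tacticity <- match.arg(tacticity)
    sides <- switch(tacticity,
                    atactic = rng$sides,
                    iso_up = rep(1, n_monomers),
                    iso_down = rep(-1, n_monomers))
  }

  rows <- list()
  bonds <- list()
  sites <- list()
  oh_jobs <- list()
  nid <- 0L
  add_atom <- function(element, pos, charge, bond_to = NA) {
    nid <<- nid + 1L
    rows[[nid]] <<- data.frame(atom_id = nid, element = element,
                               x = pos[1], y = pos[2], z = pos[3],
                               charge = charge, label = "PVA",
                               stringsAsFactors = FALSE)
    if (!is.na(bond_to)) {
      bonds[[length(bonds) + 1L]] <<- data.frame(from = bond_to, to = nid,
                                                 order = "1",
                                                 stringsAsFactors = FALSE)
    }
    nid
  }

  cpos <- if (conformation == "extended") {
    lapply(seq_len(nC), function(k) {
      c((k - 1) * a, 0, if (k %% 2 == 0) cz else 0)
    })
  } else {
    .coil_backbone(nC, th, rng$dihedrals)
  }
  cid <- integer(nC)
  for (k in seq_len(nC)) {
    q <- if (k == 1 || k == nC) .Q_PVA$CH3_C
         else if (k %% 2 == 0) .Q_PVA$CHOH_C else .Q_PVA$CH2_C
    cid[k] <- add_atom("C", cpos[[k]], q,
                       bond_to = if (k > 1) cid[k - 1] else NA)
  }
  for (k in seq_len(nC)) {
    p <- cpos[[k]]
    if (k == 1 || k == nC) {
      u1 <- .normalize(cpos[[if (k == 1) 2 else nC - 1]] - p)
      for (d in .tetra_directions(u1, ref = c(0, 1, 0))) {
        add_atom("H", p + .B_CH * d, .Q_PVA$H_C, bond_to = cid[k])
      }
    } else {
      u1 <- .normalize(cpos[[k - 1]] - p)
      u2 <- .normalize(cpos[[k + 1]] - p)
      ds <- .tetra_directions(u1, u2)
      if (k %% 2 == 0) {
        m <- k %/% 2L
        s <- sides[m]
        d_o <- if (sign(ds[[1]][2]) == s) ds[[1]] else ds[[2]]
        d_h <- if (sign(ds[[1]][2]) == s) ds[[2]] else ds[[1]]
        opos <- p + .B_CO * d_o
        oid <- add_atom("O", opos, .Q_PVA$O, bond_to = cid[k])
        add_atom("H", p + .B_CH * d_h, .Q_PVA$H_C, bond_to = cid[k])
        sites[[m]] <- data.frame(site = m, c_id = cid[k], o_id = oid,
                                 h_id = NA_integer_)
        oh_jobs[[m]] <- list(m = m, oid = oid, opos = opos, cpos = p)
      } else {
        add_atom("H", p + .B_CH * ds[[1]], .Q_PVA$H_C, bond_to = cid[k])
        add_atom("H", p + .B_CH * ds[[2]], .Q_PVA$H_C, bond_to = cid[k])
      }
    }
  }
  # hydroxyl protons last: each is placed in the ideal tetrahedral
  # direction (about its O-C bond) that stays farthest from every atom
  # already present, which keeps neighbouring same-side hydroxyls from
  # colliding
  pxyz <- t(vapply(rows, function(r) c(r$x, r$y, r$z), numeric(3)))
  oid_rows <- vapply(rows, `[[`, integer(1), "atom_id")
  for (job in oh_jobs) {
    keep <- oid_rows != job$oid
    dirs <- .tetra_directions(.normalize(job$cpos - job$opos),
                              ref = c(1, 0, 0))
    score <- vapply(dirs, function(d) {
      h <- job$opos + .B_OH * d
      min(rowSums(sweep(pxyz[keep, , drop = FALSE], 2, h)^2))
    }, numeric(1))
    hdir <- dirs[[which.max(score)]]
    hpos <- job$opos + .B_OH * hdir
    hid <- add_atom("H", hpos, .Q_PVA$H_O, bond_to = job$oid)
    sites[[job$m]]$h_id <- hid
    pxyz <- rbind(pxyz, hpos)
    oid_rows <- c(oid_rows, hid)
  }
  mol <- molecule(do.call(rbind, rows), do.call(rbind, bonds), name = name)
  mol$sites <- do.call(rbind, sites)
  mol$backbone_c <- cid
  if (conformation == "coil") {
    # folded conformers can leave substituent clashes the backbone
    # check cannot see; a short descent separates them
    mol$bonds$r0 <- .bond_lengths(mol)
    sites_keep <- mol$sites
    bb_keep <- mol$backbone_c
    mol <- relax(mol, max_steps = 60, force_tol = 5)
    attr(mol, "energy_trace") <- NULL
    attr(mol, "converged") <- NULL
    mol$sites <- sites_keep
    mol$backbone_c <- bb_keep
  }
  mol
}

# Random rotamer sequence for a coil backbone: per torsion, a shuffled
# preference order over trans / gauche+ / gauche- (trans listed first
# with higher probability, as in real vinyl chains).
.draw_dihedrals <- function(nC) {
  n_tor <- max(0, nC - 3)
  lapply(seq_len(n_tor), function(i) {
    base <- c(180, 60, -60)
    pick <- sample.int(3, 3, prob = c(0.5, 0.25, 0.25))
    base[pick] * pi / 180
  })
}

# Self-avoiding backbone by natural-extension placement: each carbon is
# placed at bond length 1.54, tetrahedral angle, and the first rotamer
# in its preference list that keeps it at least 2.5 A away from all
# non-adjacent carbons (falling back to the least-bad rotamer).
.coil_backbone <- function(nC, th, dihedrals) {
  b <- .B_CC
  pos <- vector("list", nC)
  pos[[1]] <- c(0, 0, 0)
  if (nC >= 2) pos[[2]] <- c(b, 0, 0)
  if (nC >= 3) {
    pos[[3]] <- pos[[2]] + b * c(cos(pi - th), sin(pi - th), 0)
  }
  if (nC < 4) return(pos[seq_len(nC)])
  prev <- do.call(rbind, pos[1:3])
  for (k in 4:nC) {
    A <- pos[[k - 3]]; B <- pos[[k - 2]]; C <- pos[[k - 1]]
    cand <- lapply(dihedrals[[k - 3]], function(phi) {
      .nerf_place(A, B, C, b, th, phi)
    })
    sep <- vapply(cand, function(p) {
      far <- prev[seq_len(k - 3), , drop = FALSE]   # skip 1-2, 1-3
      if (nrow(far) == 0) return(Inf)
      min(rowSums(sweep(far, 2, p)^2))
    }, numeric(1))
    ok <- which(sep >= 3.2^2)
    pick <- if (length(ok)) ok[1] else which.max(sep)
    pos[[k]] <- cand[[pick]]
    prev <- rbind(prev, pos[[k]])
  }
  pos
}

# place D given A-B-C with |CD| = r, angle(B,C,D) = theta,
# dihedral(A,B,C,D) = phi
.nerf_place <- function(A, B, C, r, theta, phi) {
  bc <- .normalize(C - B)
  n <- .cross3(B - A, bc)
  if (sqrt(sum(n^2)) < 1e-8) n <- .cross3(c(1, 0, 0), bc)
  n <- .normalize(n)
  m <- .cross3(n, bc)
  C + r * (-bc * cos(theta) + m * sin(theta) * cos(phi) +
             n * sin(theta) * sin(phi))
}

#' Functional end-to-end length of a PVA chain
#'
#' Distance between the first and last hydroxyl-bearing backbone carbons,
#' i.e. the span of the crosslinkable segment (the terminal methyl caps
#' are excluded). For a 5-mer this is close to the 10 Angstrom design
#' length of the nanopore walls.
#'
#' @param chain a chain from \code{\link{build_pva_chain}}
#' @return numeric, Angstrom
#' @export
chain_end_to_end <- function(chain) {
  s <- chain$sites
  if (is.null(s) || nrow(s) < 1) stop("chain carries no site registry",
                                      call. = FALSE)
  at <- chain$atoms
  p1 <- unlist(at[at$atom_id == s$c_id[1], c("x", "y", "z")])
  p2 <- unlist(at[at$atom_id == s$c_id[nrow(s)], c("x", "y", "z")])
  sqrt(sum((p1 - p2)^2))
}
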