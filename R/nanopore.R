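#' Canonical nanopore topologies
#'
#' The eight pore forms span the Cartesian product of two linker
#' attachment registers on each wall chain (outer monomers 1 and 5, or
#' inner monomers 2 and 4) and the relative chain orientation (parallel
#' or antiparallel), covering wide/narrow and symmetric/skewed cavities.
#'
#' @return data frame with columns \code{form_id}, \code{register_a},
#'   \code{register_b} (comma-separated monomer indices) and
#'   \code{orientation}
#' @export
nanopore_forms <- function() {
  g <- expand.grid(orientation = c("parallel", "antiparallel"),
                   register_b = c("1,5", "2,4"),
                   register_a = c("1,5", "2,4"),
                   stringsAsFactors = FALSE)
  data.frame(form_id = 1:8,
             register_a = g$register_a,
             register_b = g$register_b,
             orientation = g$orientation,
             stringsAsFactors = FALSE)
}

.parse_register <- function(s) as.integer(strsplit(s, ",")[[1]])

# carboxylate carbons of a (deprotonated) diacid template, ordered by
# mutual distance so [1]..[2] is the bridging axis; errors if not a diacid
.carboxylate_carbons <- function(mol) {
  grp <- .find_ionizable(mol)$carboxyl
  grp <- Filter(function(g) is.na(g$h_id), grp)
  if (length(grp) != 2) {
    stop("molecule '", mol$name,
         "' does not carry exactly two deprotonated carboxylates",
         call. = FALSE)
  }
  list(c1 = grp[[1]], c2 = grp[[2]])
}

.atom_pos <- function(mol, id) {
  unlist(mol$atoms[mol$atoms$atom_id == id, c("x", "y", "z")],
         use.names = FALSE)
}

#' Assemble a PVA nanopore bridged by a dicarboxylic-acid pair
#'
#' Builds the model cavity used in crosslinker screening: two isotactic
#' 5-monomer PVA chains facing each other with their hydroxyls pointing
#' into the cavity, bridged by two molecules of the chosen diacid. Each
#' bridge is attached by two ester bonds; esterification follows the
#' condensation convention used throughout the package (the chain
#' hydroxyl proton and one carboxylate oxygen are eliminated, and the
#' net charge rises by one elementary charge per ester, so a fully
#' esterified pore is neutral). The inter-chain separation is set by the
#' linker's carboxylate span, so longer diacids yield wider pores.
#'
#' The roll orientation of each linker about its bridging axis is chosen
#' deterministically as the clash-minimizing angle on a 10-degree scan.
#'
#' @param acid_id one of the 14 diacid template ids
#'   (\code{\link{diacid_ids}})
#' @param form_id pore topology, 1 to 8 (\code{\link{nanopore_forms}})
#' @return a \code{nanopore} object: list with \code{molecule} (the
#'   assembled complex), \code{acid_id}, \code{form_id},
#'   \code{pore_width} (Angstrom, separation of the chain walls),
#'   \code{ester_bonds} (data frame) and atom-id bookkeeping
#' @export
assemble_nanopore <- function(acid_id, form_id) {
  if (!acid_id %in% diacid_ids()) {
    stop("acid_id must be one of the 14 diacid templates; got '",
         acid_id, "'", call. = FALSE)
  }
  if (!is.numeric(form_id) || length(form_id) != 1 ||
      !(form_id %in% 1:8)) {
    stop("form_id must be an integer in 1..8", call. = FALSE)
  }
  # widen the cavity in small steps if the idealized geometry leaves a
  # hard-sphere clash (tilted linkers in skewed forms need extra room)
  np <- NULL
  for (extra in seq(0, 3, by = 0.3)) {
    np <- .assemble_nanopore_once(acid_id, form_id, extra)
    if (min_overlap_ratio(np$molecule) >= 0.72) break
  }
  np
}

.assemble_nanopore_once <- function(acid_id, form_id, extra_gap = 0) {
  form <- nanopore_forms()[form_id, ]
  regA <- .parse_register(form$register_a)
  regB <- .parse_register(form$register_b)

  linker0 <- load_template(acid_id)
  cc <- .carboxylate_carbons(linker0)
  span <- sqrt(sum((.atom_pos(linker0, cc$c1$c_id) -
                    .atom_pos(linker0, cc$c2$c_id))^2))
  oo_target <- span + 2 * .B_ESTER_CO + extra_gap

  # wall stereochemistry: only the register (linker-bearing) hydroxyls
  # face the cavity; the remaining hydroxyls point outward, keeping the
  # pore interior open for the guest
  sidesA <- ifelse(1:5 %in% regA, 1, -1)
  sidesB <- ifelse(1:5 %in% regB, 1, -1)
  chainA <- build_pva_chain(5, tacticity = sidesA, name = "chainA")
  chainB <- build_pva_chain(5, tacticity = sidesB, name = "chainB")
  # flip B so its hydroxyls face the cavity (-y); antiparallel reverses
  # the chain direction as well
  flip <- if (form$orientation == "parallel") {
    .axis_angle(c(1, 0, 0), pi)
  } else {
    .axis_angle(c(0, 0, 1), pi)
  }
  chainB <- rotate_mol(chainB, flip)

  oA <- lapply(regA, function(m) .atom_pos(chainA, chainA$sites$o_id[m]))
  oBr <- lapply(regB, function(m) .atom_pos(chainB, chainB$sites$o_id[m]))
  # align register midpoints in x/z, then set the vertical gap so that
  # the O..O distance equals the ester-bridged carboxylate span
  midA <- Reduce("+", oA) / 2
  midB <- Reduce("+", oBr) / 2
  shift_xz <- c(midA[1] - midB[1], 0, midA[3] - midB[3])
  chainB <- translate_mol(chainB, shift_xz)
  oBr <- lapply(oBr, function(p) p + shift_xz)
  # linker i bridges A register site i to whichever B register site
  # minimizes the worst lateral skew (matters for antiparallel walls)
  pair_skew <- function(perm) {
    max(vapply(1:2, function(i) {
      d <- oA[[i]] - oBr[[perm[i]]]
      sqrt(d[1]^2 + d[3]^2)
    }, numeric(1)))
  }
  perm <- if (pair_skew(c(1, 2)) <= pair_skew(c(2, 1))) c(1, 2) else c(2, 1)
  regB <- regB[perm]
  oBr <- oBr[perm]
  dxz <- max(vapply(1:2, function(i) {
    d <- oA[[i]] - oBr[[i]]
    sqrt(d[1]^2 + d[3]^2)
  }, numeric(1)))
  dy <- sqrt(max(1.0, oo_target^2 - dxz^2))
  y_shift <- (oA[[1]][2] + dy) - oBr[[1]][2]
  chainB <- translate_mol(chainB, c(0, y_shift, 0))
  oB <- lapply(oBr, function(p) p + c(0, y_shift, 0))

  complex <- merge_molecules(list(chainA, chainB), name =
                               sprintf("PVAnp_%s_form%d", acid_id, form_id))
  nA <- natoms(chainA)
  site_o <- c(chainA$sites$o_id[regA], chainB$sites$o_id[regB] + nA)
  site_h <- c(chainA$sites$h_id[regA], chainB$sites$h_id[regB] + nA)

  # place both linkers, then esterify (placement first keeps atom ids
  # stable through the merges)
  adj2 <- .excluded_pairs(complex, hops = 2)
  junction_of <- function(o_id) {
    complex$atoms$atom_id[adj2[match(o_id, complex$atoms$atom_id), ]]
  }
  linker_info <- list()
  for (i in 1:2) {
    placed <- .place_linker(linker0, cc, oA[[i]], oB[[i]], complex,
                            junction_ids = list(junction_of(site_o[i]),
                                                junction_of(site_o[i + 2])),
                            h_del_ids = site_h)
    off <- max(complex$atoms$atom_id)
    complex <- merge_molecules(list(complex, placed$mol),
                               name = complex$name)
    linker_info[[i]] <- list(
      c_ids = placed$c_ids + off,
      o_del = placed$o_del + off,
      o_chain = c(site_o[i], site_o[i + 2]),
      h_chain = c(site_h[i], site_h[i + 2]))
  }
  esters <- list()
  for (info in linker_info) {
    for (k in 1:2) {
      complex <- .form_ester(complex, info$o_chain[k], info$h_chain[k],
                             info$c_ids[k], info$o_del[k])
      esters[[length(esters) + 1L]] <- data.frame(
        chain_o = info$o_chain[k], carboxyl_c = info$c_ids[k])
    }
  }

  structure(list(molecule = complex, acid_id = acid_id,
                 form_id = as.integer(form_id),
                 orientation = form$orientation,
                 pore_width = dy,
                 ester_bonds = do.call(rbind, esters),
                 chain_a_atoms = seq_len(nA),
                 chain_b_atoms = nA + seq_len(nA)),
            class = "nanopore")
}

#' @export
print.nanopore <- function(x, ...) {
  cat(sprintf("<nanopore> %s form %d (%s): %d atoms, wall gap %.2f A\n",
              x$acid_id, x$form_id, x$orientation, natoms(x$molecule),
              x$pore_width))
  invisible(x)
}

# Rigidly place a diacid so its carboxylate carbons sit on the ester
# geometry between chain oxygens oA (lower wall) and oB (upper wall);
# the roll angle about the bridging axis maximizes the worst steric
# gap against the partially assembled complex.
#
# `junction_ids` lists, per anchor, the context atom ids within two
# bonds of the ester oxygen (they end up 1-2..1-4 of linker atoms once
# the ester bond exists, so they are not scored); the hydroxyl protons
# about to be eliminated are not scored either.
.place_linker <- function(linker, cc, oA, oB, context, junction_ids,
                          h_del_ids) {
  u <- .normalize(oB - oA)
  cA_target <- oA + .B_ESTER_CO * u
  cB_target <- oB - .B_ESTER_CO * u
  p1 <- .atom_pos(linker, cc$c1$c_id)
  p2 <- .atom_pos(linker, cc$c2$c_id)
  lk <- translate_mol(linker, -p1)
  R0 <- .rotation_between(p2 - p1, cB_target - cA_target)
  lk <- rotate_mol(lk, R0)
  ctx_keep <- !(context$atoms$atom_id %in% h_del_ids)
  ctx_xyz <- coords(context)[ctx_keep, , drop = FALSE]
  ctx_vdw <- context$atoms$vdw[ctx_keep]
  ctx_ids <- context$atoms$atom_id[ctx_keep]
  # linker atoms adjacent to each carboxyl carbon (within 2 bonds):
  # masked against that carbon's junction neighbourhood on the chain
  adj2 <- .excluded_pairs(linker, hops = 2)
  lk_rows <- lapply(c(cc$c1$c_id, cc$c2$c_id), function(cid) {
    which(adj2[match(cid, linker$atoms$atom_id), ])
  })
  pick_del <- function(mol, o_ids, target) {
    d <- vapply(o_ids, function(id)
      sqrt(sum((.atom_pos(mol, id) - target)^2)), numeric(1))
    o_ids[which.min(d)]
  }
  best <- NULL
  best_score <- -Inf
  for (ang in seq(0, 350, by = 10) * pi / 180) {
    cand <- rotate_mol(lk, .axis_angle(u, ang))
    cand <- translate_mol(cand, cA_target)
    del <- c(pick_del(cand, cc$c1$o_ids, oA), pick_del(cand, cc$c2$o_ids, oB))
    ratio <- .cdist(coords(cand), ctx_xyz) /
      outer(cand$atoms$vdw, ctx_vdw, "+")
    ratio[match(del, cand$atoms$atom_id), ] <- Inf
    for (k in 1:2) {
      ratio[lk_rows[[k]], ctx_ids %in% junction_ids[[k]]] <- Inf
    }
    score <- min(ratio)
    if (score > best_score) {
      best <- cand
      best_score <- score
      best_del <- del
    }
  }
  list(mol = best,
       c_ids = c(cc$c1$c_id, cc$c2$c_id),
       o_del = best_del)
}

# One esterification on a merged complex: remove the chain hydroxyl
# proton and one carboxylate oxygen, bond the chain oxygen to the
# carboxyl carbon, and restore exact charge bookkeeping (net +1 per
# ester, the hydroxide-equivalent leaving group).
.form_ester <- function(complex, o_chain, h_chain, c_carboxyl, o_del) {
  net_before <- net_charge(complex)
  complex <- .remove_atoms(complex, c(h_chain, o_del))
  newb <- complex$bonds[0, , drop = FALSE]
  newb[1, "from"] <- o_chain
  newb[1, "to"] <- c_carboxyl
  newb[1, "order"] <- "1"
  complex$bonds <- rbind(complex$bonds, newb)
  target <- net_before + 1
  corr <- (target - net_charge(complex)) / 2
  sel <- complex$atoms$atom_id %in% c(o_chain, c_carboxyl)
  complex$atoms$charge[sel] <- complex$atoms$charge[sel] + corr
  complex
}

#' Worst-case steric overlap of a molecule
#'
#' Minimum over non-bonded atom pairs of the ratio distance / (sum of
#' van der Waals radii). Pairs separated by up to three bonds (1-2, 1-3
#' and 1-4) are excluded, mirroring the special treatment of bonded
#' neighbourhoods in standard force fields. Values below 0.7 indicate a
#' hard-sphere clash.
#'
#' @param mol a \code{molecule}
#' @return numeric scalar (Inf for molecules with fewer than 2 atoms)
#' @export
min_overlap_ratio <- function(mol) {
  n <- natoms(mol)
  if (n < 2) return(Inf)
  d <- .cdist(coords(mol), coords(mol))
  ratio <- d / outer(mol$atoms$vdw, mol$atoms$vdw, "+")
  ratio[.excluded_pairs(mol, hops = 3)] <- Inf
  min(ratio)
}
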