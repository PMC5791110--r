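#' Number of crosslinks implied by a monomer:crosslinker ratio
#'
#' For a matrix of \code{n_monomers} PVA monomers and a target
#' composition of \code{p} monomers per \code{q} crosslinker molecules,
#' the number of crosslinker molecules to insert is
#' \code{floor(n_monomers * q / p)}. The study compositions 10:2, 10:4
#' and 10:6 on a 625-monomer matrix give 125, 250 and 375.
#'
#' @param n_monomers total PVA monomers in the matrix
#' @param ratio composition as a string \code{"p:q"} or numeric
#'   \code{c(p, q)}
#' @return integer number of crosslinker molecules
#' @export
#' @examples
#' composition_to_links(625, "10:2")  # 125
composition_to_links <- function(n_monomers, ratio) {
  if (is.character(ratio)) {
    ratio <- as.numeric(strsplit(ratio, ":")[[1]])
  }
  if (length(ratio) != 2 || anyNA(ratio) || any(ratio <= 0) ||
      !is.numeric(n_monomers) || length(n_monomers) != 1 ||
      is.na(n_monomers) || n_monomers <= 0) {
    stop("composition_to_links: n_monomers and both ratio terms must be ",
         "positive", call. = FALSE)
  }
  as.integer(floor(n_monomers * ratio[2] / ratio[1]))
}

#' Composition label of a crosslinked matrix
#'
#' Maps a link count back to the conventional hydrogel designation
#' (crosslinker weight-percent label): 125/625 is the 10:2 composition,
#' labelled 20 wt-%, and so on.
#'
#' @param n_monomers total PVA monomers
#' @param n_links crosslinker molecules inserted
#' @return character label such as \code{"CLPH-MA20"}, or \code{NA} when
#'   the count does not match a p:q composition with q an even integer
#' @export
network_label <- function(n_monomers, n_links) {
  q10 <- 10 * n_links / n_monomers
  if (abs(q10 - round(q10)) > 1e-9) return(NA_character_)
  sprintf("CLPH-MA%d", as.integer(round(q10)) * 10L)
}

#' Randomly select an eligible crosslink site pair
#'
#' Draws uniformly among all eligible pairs of unused hydroxyl sites:
#' the two sites must sit on different chains and their oxygens must be
#' within \code{max_dist} under the minimum-image convention. Consumes
#' one draw from the current RNG stream. Returns \code{NULL} when no
#' eligible pair exists (a valid outcome, signalling saturation).
#'
#' @param system a \code{polymer_system}
#' @param max_dist maximum O-O separation, Angstrom
#' @return list with \code{i}, \code{j} (row indices into
#'   \code{system$sites}) and \code{distance}, or \code{NULL}
#' @export
select_crosslink_pair <- function(system, max_dist = 10) {
  s <- system$sites
  free <- which(!s$used)
  if (length(free) < 2) return(NULL)
  at <- system$mol$atoms
  O <- as.matrix(at[match(s$o_id[free], at$atom_id), c("x", "y", "z")])
  D <- .pbc_cdist(O, O, system$box)
  elig <- which(upper.tri(D) & D <= max_dist &
                  outer(s$chain[free], s$chain[free], "!="),
                arr.ind = TRUE)
  if (nrow(elig) == 0) return(NULL)
  k <- elig[sample.int(nrow(elig), 1), ]
  list(i = free[k[1]], j = free[k[2]], distance = D[k[1], k[2]])
}

#' Form one ester crosslink between two hydroxyl sites
#'
#' Inserts one diacid molecule bridging the two site oxygens and forms
#' two ester bonds. Each esterification eliminates the chain hydroxyl
#' proton and one carboxylate oxygen (a hydroxide-equivalent leaving
#' group under the deprotonated-acid condensation convention used
#' throughout the package) and raises the net charge by one elementary
#' charge, so each fully bonded bridge is charge-neutral. Both sites are
#' marked used. The inserted linker is oriented along the O..O axis
#' with a clash-minimizing roll angle; a short local relaxation
#' afterwards (see \code{\link{build_network}}) settles bond lengths.
#'
#' @param system a \code{polymer_system}
#' @param site_i,site_j row indices into \code{system$sites}
#' @param acid_id diacid template id
#' @return the updated system; the new linker's atoms carry label
#'   \code{"linker"} and \code{chain = NA}
#' @export
form_ester_link <- function(system, site_i, site_j, acid_id) {
  s <- system$sites
  if (s$used[site_i] || s$used[site_j]) {
    stop("crosslink site already used", call. = FALSE)
  }
  if (s$chain[site_i] == s$chain[site_j]) {
    stop("crosslink sites must sit on different chains", call. = FALSE)
  }
  mol <- system$mol
  box <- system$box
  at <- mol$atoms
  pos <- function(id) unlist(at[match(id, at$atom_id), c("x", "y", "z")],
                             use.names = FALSE)
  oi <- pos(s$o_id[site_i])
  oj_raw <- pos(s$o_id[site_j])
  dvec <- drop(.pbc_disp(oi, matrix(oj_raw, 1), box))
  oj <- oi + dvec                       # unwrapped image of site j oxygen

  linker <- load_template(acid_id)
  cc <- .carboxylate_carbons(linker)
  span <- sqrt(sum((.atom_pos(linker, cc$c1$c_id) -
                    .atom_pos(linker, cc$c2$c_id))^2))
  u <- .normalize(dvec)
  mid <- oi + dvec / 2
  p1 <- .atom_pos(linker, cc$c1$c_id)
  p2 <- .atom_pos(linker, cc$c2$c_id)
  lk <- translate_mol(linker, -(p1 + p2) / 2)
  lk <- rotate_mol(lk, .rotation_between(p2 - p1, u))

  # clash-minimizing roll against nearby context (site hydroxyls and
  # their neighbourhood excluded; those pairs become bonded)
  near <- which(.pbc_dist2(coords(mol), matrix(mid, 1), box) < 10^2)
  excl_ids <- c(s$o_id[c(site_i, site_j)], s$h_id[c(site_i, site_j)],
                s$c_id[c(site_i, site_j)])
  near <- setdiff(near, match(excl_ids, at$atom_id))
  best <- NULL; best_score <- -Inf
  ctx <- coords(mol)[near, , drop = FALSE]
  ctx_vdw <- at$vdw[near]
  for (ang in seq(0, 330, by = 30) * pi / 180) {
    cand <- translate_mol(rotate_mol(lk, .axis_angle(u, ang)), mid)
    score <- if (length(near)) {
      min(.pbc_cdist(coords(cand), ctx, box) /
            outer(cand$atoms$vdw, ctx_vdw, "+"))
    } else Inf
    if (score > best_score) { best <- cand; best_score <- score }
  }
  pick_del <- function(o_ids, target) {
    d <- vapply(o_ids, function(id)
      sqrt(sum((.atom_pos(best, id) - target)^2)), numeric(1))
    o_ids[which.min(d)]
  }
  o_del <- c(pick_del(cc$c1$o_ids, oi), pick_del(cc$c2$o_ids, oj))

  best$atoms$chain <- NA_integer_
  best$bonds$r0 <- .bond_lengths(best)
  off <- max(at$atom_id)
  mol <- merge_molecules(list(mol, best), name = mol$name)
  mol <- .form_ester(mol, s$o_id[site_i], s$h_id[site_i],
                     cc$c1$c_id + off, o_del[1] + off)
  mol <- .form_ester(mol, s$o_id[site_j], s$h_id[site_j],
                     cc$c2$c_id + off, o_del[2] + off)
  # reference lengths for the two new ester bonds
  mol$bonds$r0[is.na(mol$bonds$r0)] <- .B_ESTER_CO
  mol <- set_coords(mol, .pbc_wrap(coords(mol), box))

  system$mol <- mol
  system$sites$used[c(site_i, site_j)] <- TRUE
  system
}

#' Build a crosslinked PVA network by cyclic random esterification
#'
#' Repeats the three-step crosslinking cycle until \code{target_links}
#' diacid bridges are formed: (1) uniformly select two unused hydroxyl
#' sites on different chains within \code{max_dist} of each other,
#' (2) insert a diacid and form the two ester bonds, (3) briefly relax
#' the neighbourhood of the new bridge by steepest descent to relieve
#' steric strain. Deterministic for a fixed seed, and incremental: the
#' link list at a smaller target is a prefix of the list at a larger
#' target for the same system and seed.
#'
#' @param system a \code{polymer_system} from \code{\link{pack_chains}}
#' @param acid_id diacid template id (default \code{"malic"})
#' @param target_links number of bridges to form
#' @param seed integer seed
#' @param max_dist site-pair selection cutoff, Angstrom
#' @param relax_steps descent steps after each insertion (0 disables)
#' @param relax_radius radius of the movable region around the new
#'   bridge, Angstrom
#' @return a \code{crosslink_network}: list with \code{system} (updated),
#'   \code{links} (data frame: cycle, chain_i, site_i, chain_j, site_j,
#'   acid, distance_A), \code{n_links}, \code{label}
#' @export
build_network <- function(system, acid_id = "malic", target_links,
                          seed = 1, max_dist = 10, relax_steps = 5,
                          relax_radius = 4) {
  stopifnot(target_links >= 0)
  links <- list()
  if (target_links > 0) {
    system <- with_seed(seed, {
      for (cycle in seq_len(target_links)) {
        pair <- select_crosslink_pair(system, max_dist)
        if (is.null(pair)) {
          stop("network saturated after ", cycle - 1L, " of ",
               target_links, " links: no eligible site pair remains",
               call. = FALSE)
        }
        n_before <- natoms(system$mol)
        system <- form_ester_link(system, pair$i, pair$j, acid_id)
        if (relax_steps > 0) {
          xyz <- coords(system$mol)
          newly <- seq(n_before + 1L, natoms(system$mol))
          d2 <- .pbc_dist2(xyz, xyz[newly, , drop = FALSE], system$box)
          movable <- which(apply(d2 <= relax_radius^2, 1, any))
          system <- relax(system, max_steps = relax_steps,
                          force_tol = 5, movable = movable, cutoff = 6)
        }
        links[[cycle]] <- data.frame(
          cycle = cycle,
          chain_i = system$sites$chain[pair$i],
          site_i = system$sites$site[pair$i],
          chain_j = system$sites$chain[pair$j],
          site_j = system$sites$site[pair$j],
          acid = acid_id, distance_A = pair$distance,
          stringsAsFactors = FALSE)
      }
      system
    })
  }
  links <- if (length(links)) do.call(rbind, links) else
    data.frame(cycle = integer(), chain_i = integer(), site_i = integer(),
               chain_j = integer(), site_j = integer(), acid = character(),
               distance_A = numeric(), stringsAsFactors = FALSE)
  structure(list(system = system, links = links, n_links = nrow(links),
                 label = network_label(system$n_monomers, nrow(links)),
                 acid_id = acid_id, seed = seed),
            class = "crosslink_network")
}

#' @export
print.crosslink_network <- function(x, ...) {
  cat(sprintf("<crosslink_network> %s: %d %s bridges over %d monomers\n",
              ifelse(is.na(x$label), "(unlabelled)", x$label),
              x$n_links, x$acid_id, x$system$n_monomers))
  invisible(x)
}
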