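#' Generate a noisy factorial design from known coefficients
#'
#' Test harness for the factorial regression: responses are generated
#' from the two-factor interaction model
#' \code{y = b0 + b1 A + b2 B + b3 AB} plus Gaussian noise.
#' Deterministic for a fixed seed.
#'
#' @param true_coefficients numeric length-4: b0, b1, b2, b3
#' @param coded_points data frame with columns \code{coded_A},
#'   \code{coded_B} (at least 5 rows so the fit has df >= 1)
#' @param noise_sd Gaussian noise standard deviation (>= 0)
#' @param seed integer seed
#' @return the \code{coded_points} data frame with a \code{response}
#'   column appended
#' @export
make_noisy_design <- function(true_coefficients, coded_points,
                              noise_sd = 0, seed = 1) {
  stopifnot(length(true_coefficients) == 4)
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be non-negative", call. = FALSE)
  }
  if (nrow(coded_points) < 5) {
    stop("need at least 5 design points for a 4-parameter fit",
         call. = FALSE)
  }
  b <- true_coefficients
  A <- coded_points$coded_A
  B <- coded_points$coded_B
  mu <- b[1] + b[2] * A + b[3] * B + b[4] * A * B
  eps <- with_seed(seed, stats::rnorm(length(mu), 0, noise_sd))
  out <- coded_points
  out$response <- mu + if (noise_sd > 0) eps else 0
  out
}

#' Generate a box of rigid three-site waters
#'
#' Places \code{n_waters} water molecules with a rigid TIP3P-like
#' internal geometry (O-H 0.9572 Angstrom, H-O-H 104.52 degrees; no
#' claim about its energetics) at random positions and orientations in
#' a periodic box, by rejection sampling so that no two oxygens come
#' closer than \code{min_oo} under the minimum image. Deterministic for
#' a fixed seed.
#'
#' @param n_waters number of waters (>= 0)
#' @param box box lengths, Angstrom (scalar or length 3)
#' @param seed integer seed
#' @param min_oo minimum O-O distance, Angstrom
#' @param max_attempts attempts per molecule
#' @return list of \code{molecule} objects (possibly empty)
#' @export
make_water_box <- function(n_waters, box, seed = 1, min_oo = 2.4,
                           max_attempts = 10000) {
  if (length(box) == 1) box <- rep(box, 3)
  stopifnot(n_waters >= 0, all(box > 0))
  if (n_waters == 0) return(list())
  if (n_waters * (4 / 3) * pi * (min_oo / 2)^3 > prod(box)) {
    stop("water placement infeasible at the requested density",
         call. = FALSE)
  }
  w0 <- .rigid_water()
  with_seed(seed, {
    out <- vector("list", n_waters)
    o_pos <- matrix(numeric(0), 0, 3)
    for (i in seq_len(n_waters)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        origin <- stats::runif(3) * box
        if (nrow(o_pos) == 0 ||
            min(.pbc_dist2(matrix(origin, 1), o_pos, box)) >= min_oo^2) {
          R <- random_rotation()$R
          w <- set_coords(w0, sweep(coords(w0) %*% t(R), 2, origin, "+"))
          w$name <- sprintf("water%04d", i)
          out[[i]] <- w
          o_pos <- rbind(o_pos, origin)
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("water placement infeasible: molecule ", i, " could not be ",
             "placed in ", max_attempts, " attempts", call. = FALSE)
      }
    }
    out
  })
}

# rigid 3-site water with the oxygen at the origin
.rigid_water <- function() {
  half <- 104.52 / 2 * pi / 180
  r <- 0.9572
  molecule(
    data.frame(atom_id = 1:3, element = c("O", "H", "H"),
               x = c(0, r * sin(half), -r * sin(half)),
               y = c(0, r * cos(half), r * cos(half)),
               z = c(0, 0, 0),
               charge = c(-0.834, 0.417, 0.417),
               label = "water", stringsAsFactors = FALSE),
    data.frame(from = c(1, 1), to = c(2, 3), order = "1"),
    name = "water")
}

#' Generate a trajectory with planted observables
#'
#' Builds a synthetic multi-frame system around a hydrogel in which the
#' pesticide capture fraction, hydration-shell water count and
#' hydrogel-pesticide hydrogen-bond count of every frame are planted by
#' construction, so that the trajectory analyzers can be validated by
#' exact round-trip. Per frame:
#' \itemize{
#'   \item \code{capture_schedule[f]} percent of the \code{n_dmt}
#'     pesticide molecules are placed with their nearest atom
#'     3.6-4.3 Angstrom from the hydrogel (captured at the 4.5 cutoff,
#'     but outside every hydrogen-bond cutoff); the remainder are kept
#'     at least 9 Angstrom away (safely free).
#'   \item \code{hbond_schedule[f]} of the captured molecules are
#'     instead placed to donate exactly one textbook hydrogen bond:
#'     a hydrogel hydroxyl O-H is extended collinearly to a pesticide
#'     acceptor oxygen at 2.8 Angstrom.
#'   \item \code{water_schedule[f]} waters are placed inside the
#'     center-of-mass shell (within \code{0.7 * com_radius}) and
#'     \code{n_far_waters} decoys outside every counting criterion.
#' }
#' Candidate placements that would create unscheduled hydrogen bonds or
#' steric overlap are rejected and redrawn, so the planted counts are
#' exact. Deterministic for a fixed seed.
#'
#' @param network a \code{crosslink_network}, \code{polymer_system} or
#'   hydrogel \code{molecule}
#' @param n_frames number of frames
#' @param n_dmt pesticide molecules per frame (default 50)
#' @param capture_schedule per-frame capture percent (length
#'   \code{n_frames}; values must be multiples of \code{100 / n_dmt})
#' @param water_schedule per-frame in-shell water counts (default 0)
#' @param hbond_schedule per-frame hydrogen-bond counts (default 0;
#'   each must not exceed that frame's captured count)
#' @param n_far_waters far-field decoy waters per frame
#' @param box box lengths, Angstrom
#' @param com_radius shell radius used when planting waters, Angstrom
#' @param dt_ns time step between frames, ns
#' @param seed integer seed
#' @return an \code{hs_trajectory}
#' @export
make_planted_trajectory <- function(network, n_frames,
                                    n_dmt = 50,
                                    capture_schedule = rep(0, n_frames),
                                    water_schedule = rep(0L, n_frames),
                                    hbond_schedule = rep(0L, n_frames),
                                    n_far_waters = 0L,
                                    box = 110, com_radius = 25,
                                    dt_ns = 0.1, seed = 1) {
  if (length(box) == 1) box <- rep(box, 3)
  stopifnot(length(capture_schedule) == n_frames,
            length(water_schedule) == n_frames,
            length(hbond_schedule) == n_frames)
  gel <- if (inherits(network, "crosslink_network")) network$system$mol
         else if (inherits(network, "polymer_system")) network$mol
         else network
  n_capt <- round(capture_schedule / 100 * n_dmt)
  if (max(abs(n_capt / n_dmt * 100 - capture_schedule)) > 1e-9) {
    stop("capture_schedule values must be multiples of 100/n_dmt",
         call. = FALSE)
  }
  if (any(hbond_schedule > n_capt)) {
    stop("hbond_schedule cannot exceed the captured count in any frame",
         call. = FALSE)
  }
  # center the hydrogel in the box
  gel <- translate_mol(gel, box / 2 - center_of_mass(gel))
  dmt0 <- load_template("dimethoate")
  dmt0 <- translate_mol(dmt0, -center_of_mass(dmt0))
  wat0 <- .rigid_water()
  n_wat <- max(c(water_schedule, 0)) + n_far_waters
  mols <- c(list(gel), rep(list(dmt0), n_dmt),
            if (n_wat > 0) rep(list(wat0), n_wat))
  topo <- topology_from_molecules(mols)
  # hydrogel hydroxyl donors (O with attached H) for hbond planting
  donors <- .gel_donor_pairs(gel)
  acc_row <- .dmt_acceptor_o(dmt0)

  frames <- with_seed(seed, {
    lapply(seq_len(n_frames), function(fi) {
      .plant_frame(fi, gel, dmt0, wat0, acc_row, donors,
                   n_dmt, n_capt[fi], hbond_schedule[fi],
                   water_schedule[fi], n_wat, box, com_radius)
    })
  })
  hs_trajectory(topo, frames, times = seq_len(n_frames) * dt_ns, box = box)
}

# (O, H) coordinate pairs of hydrogel hydroxyl donors
.gel_donor_pairs <- function(gel) {
  grp <- .find_ionizable(gel)$hydroxyl
  grp <- Filter(function(g) !is.na(g$h_id), grp)
  if (!length(grp)) stop("hydrogel carries no hydroxyl donors",
                         call. = FALSE)
  lapply(grp, function(g) {
    list(o = .atom_pos(gel, g$o_id), h = .atom_pos(gel, g$h_id))
  })
}

# (heavy, H) row-index pairs for polar hydrogens bonded to O/N/S
.polar_h_pairs <- function(mol) {
  adj <- .bond_adjacency(mol)
  ids <- mol$atoms$atom_id
  out <- list()
  for (r in which(mol$atoms$element == "H")) {
    nb <- adj[[as.character(ids[r])]]
    if (!length(nb)) next
    p <- match(nb[1], ids)
    if (mol$atoms$element[p] %in% c("O", "N", "S")) {
      out[[length(out) + 1L]] <- list(d = p, h = r)
    }
  }
  out
}

# row index of the carbonyl (acceptor) oxygen in the pesticide template:
# the O double-bonded to the amide carbon; falls back to the first oxygen
.dmt_acceptor_o <- function(dmt) {
  o_rows <- which(dmt$atoms$element == "O")
  adj <- .bond_adjacency(dmt)
  for (r in o_rows) {
    id <- dmt$atoms$atom_id[r]
    nb <- adj[[as.character(id)]]
    if (length(nb) == 1) return(r)   # terminal O: the carbonyl
  }
  o_rows[1]
}

.plant_frame <- function(fi, gel, dmt0, wat0, acc_row, donors,
                         n_dmt, n_capt, n_hb, n_wat_in, n_wat_total,
                         box, com_radius) {
  gel_xyz <- coords(gel)
  gel_heavy <- gel_xyz[gel$atoms$element != "H", , drop = FALSE]
  gel_polar <- gel_xyz[gel$atoms$element %in% c("O", "N", "S"), ,
                       drop = FALSE]
  dmt_info <- list(
    elements = dmt0$atoms$element,
    acc_rows = which(dmt0$atoms$element %in% c("O", "N", "S")),
    don_pairs = .polar_h_pairs(dmt0),
    gel_acc = gel_polar)
  gel_m <- atomic_mass(gel$atoms$element)
  gel_com <- drop(crossprod(gel_xyz, gel_m) / sum(gel_m))
  other <- matrix(numeric(0), 0, 3)   # non-hydrogel atoms placed so far
  add <- function(xyz) other <<- rbind(other, xyz)
  dmt_frames <- vector("list", n_dmt)
  # hydrogen-bonded captives first (each consumes one distinct donor);
  # donors that fail on one pass are retried on later passes, since
  # the steric environment changes as molecules are added
  avail <- sample.int(length(donors))
  hb_done <- 0L
  k <- 1L
  for (round in 1:6) {
    if (hb_done >= n_hb || !length(avail)) break
    failed <- integer(0)
    for (di in avail) {
      if (hb_done >= n_hb) break
      don <- donors[[di]]
      xyz <- .plant_hbond_dmt(don, donors, di, dmt0, acc_row, dmt_info,
                              gel_xyz, other, box)
      if (is.null(xyz)) {
        failed <- c(failed, di)
        next
      }
      dmt_frames[[k]] <- xyz
      add(xyz)
      hb_done <- hb_done + 1L
      k <- k + 1L
    }
    avail <- failed
  }
  if (hb_done < n_hb) {
    stop("could not plant ", n_hb, " hydrogen bonds: hydroxyl donors ",
         "exhausted", call. = FALSE)
  }
  # plain captives: nearest heavy-atom approach in the 3.6-4.3 band
  # (inside the 4.5 capture cutoff, outside all hydrogen-bond cutoffs)
  while (k <= n_capt) {
    xyz <- .plant_captured_dmt(dmt0, gel_xyz, gel_heavy, other, box)
    dmt_frames[[k]] <- xyz
    add(xyz)
    k <- k + 1L
  }
  # free pesticides: at least 9 A from every hydrogel atom
  while (k <= n_dmt) {
    xyz <- .plant_far(dmt0, gel_xyz, other, box, min_gel = 9,
                      min_any = 3.0)
    dmt_frames[[k]] <- xyz
    add(xyz)
    k <- k + 1L
  }
  # waters: n_wat_in inside the center-of-mass shell, decoys outside
  # every counting criterion
  wat_frames <- vector("list", n_wat_total)
  for (w in seq_len(n_wat_total)) {
    if (w <= n_wat_in) {
      xyz <- .plant_shell_water(wat0, gel_com, com_radius, gel_xyz,
                                other, box)
    } else {
      xyz <- .plant_far(wat0, gel_xyz, other, box,
                        min_gel = com_radius + 5, min_any = 2.4,
                        center = gel_com)
    }
    wat_frames[[w]] <- xyz
    add(xyz)
  }
  do.call(rbind, c(list(gel_xyz), dmt_frames, wat_frames))
}

# One pesticide donating a textbook hydrogen bond: its acceptor oxygen
# collinear with the chosen donor O-H at 2.8 A. Candidate orientations
# are rejected unless the intended bond is the ONLY donor-H-acceptor
# triple satisfying the geometric rule (checked exactly, with a small
# safety margin, in both directions) and the placement is sterically
# clear.
.plant_hbond_dmt <- function(don, all_donors, don_index, dmt0, acc_row,
                             dmt_info, gel_xyz, other, box) {
  u <- .normalize(don$h - don$o)
  a_target <- don$o + 2.8 * u
  dev_deg <- function(hpos, dpos, apos) {
    v1 <- dpos - hpos; v2 <- apos - hpos
    180 - acos(max(-1, min(1, sum(v1 * v2) /
                             sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
  }
  for (try_ in 1:300) {
    R <- random_rotation()$R
    xyz <- coords(dmt0) %*% t(R)
    xyz <- sweep(xyz, 2, a_target - xyz[acc_row, ], "+")
    bad <- FALSE
    # (a) any DMT acceptor vs any gel donor, except the intended pair
    for (a in dmt_info$acc_rows) {
      lim <- if (dmt_info$elements[a] == "S") 3.55 else 3.05
      for (gi in seq_along(all_donors)) {
        if (a == acc_row && gi == don_index) next
        g <- all_donors[[gi]]
        if (sum((xyz[a, ] - g$o)^2) > lim^2) next
        if (dev_deg(g$h, g$o, xyz[a, ]) <= 32) { bad <- TRUE; break }
      }
      if (bad) break
    }
    if (bad) next
    # (b) any DMT donor hydrogen vs any gel acceptor (all gel O)
    for (dp in dmt_info$don_pairs) {
      d2g <- .pbc_dist2(xyz[dp$d, , drop = FALSE], dmt_info$gel_acc, box)
      for (gi in which(d2g[1, ] <= 3.05^2)) {
        if (dev_deg(xyz[dp$h, ], xyz[dp$d, ],
                    dmt_info$gel_acc[gi, ]) <= 32) { bad <- TRUE; break }
      }
      if (bad) break
    }
    if (bad) next
    rest <- xyz[-acc_row, , drop = FALSE]
    if (min(.pbc_dist2(rest, gel_xyz, box)) < 2.4^2) next
    if (nrow(other) && min(.pbc_dist2(xyz, other, box)) < 2.0^2) next
    return(xyz)
  }
  NULL
}

.plant_captured_dmt <- function(dmt0, gel_xyz, gel_heavy, other, box) {
  repeat {
    anchor <- gel_heavy[sample.int(nrow(gel_heavy), 1), ]
    dir <- random_direction()
    R <- random_rotation()$R
    xyz0 <- coords(dmt0) %*% t(R)
    # offset along dir so the leading atom lands in the capture band
    d_t <- stats::runif(1, 3.7, 4.2)
    proj <- drop(xyz0 %*% dir)
    lead <- which.min(proj)
    xyz <- sweep(xyz0, 2, anchor + (d_t - proj[lead]) * dir, "+")
    dmin <- sqrt(min(.pbc_dist2(xyz, gel_heavy, box)))
    if (dmin < 3.6 || dmin > 4.3) next        # capture band, no hbonds
    if (min(.pbc_dist2(xyz, gel_xyz, box)) < 2.5^2) next
    if (nrow(other) && min(.pbc_dist2(xyz, other, box)) < 2.5^2) next
    return(xyz)
  }
}

.plant_shell_water <- function(wat0, gel_com, com_radius, gel_xyz,
                               other, box) {
  repeat {
    r <- com_radius * 0.7 * stats::runif(1)^(1 / 3)
    origin <- gel_com + r * random_direction()
    R <- random_rotation()$R
    xyz <- sweep(coords(wat0) %*% t(R), 2, origin, "+")
    if (min(.pbc_dist2(xyz, gel_xyz, box)) < 2.4^2) next
    if (nrow(other) && min(.pbc_dist2(xyz, other, box)) < 2.4^2) next
    return(xyz)
  }
}

.plant_far <- function(mol0, gel_xyz, other, box, min_gel, min_any,
                       center = NULL) {
  repeat {
    origin <- stats::runif(3) * box
    if (!is.null(center)) {
      d <- origin - center
      d <- d - box * round(d / box)
      if (sqrt(sum(d^2)) <= min_gel) next
    }
    R <- random_rotation()$R
    xyz <- sweep(coords(mol0) %*% t(R), 2, origin, "+")
    if (min(.pbc_dist2(xyz, gel_xyz, box)) < min_gel^2) next
    if (nrow(other) && min(.pbc_dist2(xyz, other, box)) < min_any^2) next
    return(xyz)
  }
}
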