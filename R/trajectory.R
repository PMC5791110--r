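#' Construct a trajectory object
#'
#' A trajectory couples a fixed topology (who each atom is) with a list
#' of per-frame coordinate matrices. The topology is a data frame with
#' one row per atom: \code{element}, \code{role} (\code{"hydrogel"},
#' \code{"DMT"}, \code{"water"} or \code{"other"}), \code{mol_id}
#' (molecule grouping), \code{is_donor} (heavy atom bearing a polar H),
#' \code{is_acceptor} (O/N/S lone-pair acceptor) and \code{h_parent}
#' (for hydrogens: row index of the bonded heavy atom, else \code{NA}).
#'
#' @param topology topology data frame (see above)
#' @param frames list of n_atoms x 3 coordinate matrices, Angstrom
#' @param times frame times, ns
#' @param box periodic box lengths, Angstrom (length 1 or 3)
#' @return an \code{hs_trajectory}
#' @export
hs_trajectory <- function(topology, frames, times = seq_along(frames),
                          box) {
  if (length(box) == 1) box <- rep(box, 3)
  stopifnot(all(box > 0), length(frames) == length(times))
  for (f in frames) {
    if (nrow(f) != nrow(topology)) {
      stop("frame coordinate count does not match topology", call. = FALSE)
    }
  }
  structure(list(topology = topology, frames = frames,
                 times = as.numeric(times), box = box),
            class = "hs_trajectory")
}

#' @export
print.hs_trajectory <- function(x, ...) {
  cat(sprintf("<hs_trajectory> %d frames x %d atoms (%d hydrogel, %d DMT, %d water)\n",
              length(x$frames), nrow(x$topology),
              sum(x$topology$role == "hydrogel"),
              sum(x$topology$role == "DMT"),
              sum(x$topology$role == "water")))
  invisible(x)
}

# topology row indices by role
.role_idx <- function(topology, role) which(topology$role == role)

#' Build a trajectory topology from labelled molecules
#'
#' Flattens a list of molecules into a single topology table, deriving
#' donor/acceptor flags and hydrogen parents from each molecule's bond
#' graph. Molecule labels map to roles (\code{PVA}/\code{linker} ->
#' \code{hydrogel}).
#'
#' @param mols list of \code{molecule} objects
#' @return topology data frame
#' @export
topology_from_molecules <- function(mols) {
  rows <- list()
  offset <- 0L
  for (mi in seq_along(mols)) {
    m <- mols[[mi]]
    at <- m$atoms
    n <- nrow(at)
    idx <- stats::setNames(seq_len(n), as.character(at$atom_id))
    h_parent <- rep(NA_integer_, n)
    has_h <- rep(FALSE, n)
    if (nrow(m$bonds)) {
      for (k in seq_len(nrow(m$bonds))) {
        i <- idx[[as.character(m$bonds$from[k])]]
        j <- idx[[as.character(m$bonds$to[k])]]
        if (at$element[i] == "H" && at$element[j] != "H") {
          h_parent[i] <- j + offset
          if (at$element[j] %in% c("O", "N", "S")) has_h[j] <- TRUE
        }
        if (at$element[j] == "H" && at$element[i] != "H") {
          h_parent[j] <- i + offset
          if (at$element[i] %in% c("O", "N", "S")) has_h[i] <- TRUE
        }
      }
    }
    role <- vapply(at$label, function(l) switch(l, PVA = "hydrogel",
                                                linker = "hydrogel",
                                                DMT = "DMT",
                                                water = "water", "other"),
                   character(1))
    rows[[mi]] <- data.frame(
      element = at$element, role = unname(role), mol_id = mi,
      is_donor = at$element %in% c("O", "N", "S") & has_h,
      is_acceptor = at$element %in% c("O", "N", "S"),
      h_parent = h_parent, stringsAsFactors = FALSE)
    offset <- offset + n
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a trajectory to a multi-model PDB plus a JSON topology sidecar
#'
#' The PDB carries one MODEL block per frame; the sidecar carries the
#' per-atom roles, molecule ids, donor/acceptor flags and hydrogen
#' parents, plus the box and frame times.
#'
#' @param traj an \code{hs_trajectory}
#' @param pdb_path output PDB path
#' @param topology_path output JSON path
#' @return \code{pdb_path}, invisibly
#' @export
write_trajectory <- function(traj, pdb_path, topology_path) {
  n <- nrow(traj$topology)
  con <- file(pdb_path, "w")
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                     traj$box[1], traj$box[2], traj$box[3]), con)
  close(con)
  for (fi in seq_along(traj$frames)) {
    cat(sprintf("MODEL     %4d\n", fi), file = pdb_path, append = TRUE)
    bio3d::write.pdb(file = pdb_path,
                     xyz = as.numeric(t(traj$frames[[fi]])),
                     resno = traj$topology$mol_id %% 10000L,
                     resid = substr(toupper(traj$topology$role), 1, 3),
                     eleno = seq_len(n),
                     elety = traj$topology$element,
                     elesy = traj$topology$element,
                     o = rep(1, n), b = rep(0, n),
                     end = FALSE, append = TRUE)
    cat("ENDMDL\n", file = pdb_path, append = TRUE)
  }
  cat("END\n", file = pdb_path, append = TRUE)
  jsonlite::write_json(
    list(box = traj$box, times_ns = traj$times,
         atoms = traj$topology),
    topology_path, dataframe = "columns", digits = NA, auto_unbox = FALSE,
    na = "null")
  invisible(pdb_path)
}

#' Read a trajectory written by \code{\link{write_trajectory}}
#'
#' Parses a multi-model PDB (via \pkg{bio3d}) and the JSON topology
#' sidecar back into an \code{hs_trajectory}.
#'
#' @param pdb_path multi-model PDB path
#' @param topology_path JSON sidecar path
#' @return an \code{hs_trajectory}
#' @export
read_trajectory <- function(pdb_path, topology_path) {
  meta <- jsonlite::read_json(topology_path, simplifyVector = TRUE)
  topo <- as.data.frame(meta$atoms, stringsAsFactors = FALSE)
  p <- suppressWarnings(bio3d::read.pdb(pdb_path, multi = TRUE,
                                        verbose = FALSE))
  xyz <- p$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  })
  hs_trajectory(topo, frames, times = meta$times_ns, box = meta$box)
}

#' Evaluate observables over every frame of a trajectory
#'
#' Per-frame evaluation of the requested observables: solvent-accessible
#' surface area and radius of gyration of the hydrogel, water-shell
#' occupancy, pesticide capture percentage, and hydrogel-pesticide
#' hydrogen-bond count. Capture is additionally summarized by the first
#' time the trajectory reaches 100\% (attribute
#' \code{first_full_capture_ns}, \code{NA} if never).
#'
#' @param traj an \code{hs_trajectory}
#' @param observables subset of \code{c("sasa", "rgyr", "capture",
#'   "waters", "hbonds")}
#' @param params named list of observable parameters:
#'   \code{probe_radius}, \code{n_points} (SASA),
#'   \code{backbone_cutoff}, \code{com_radius} (waters),
#'   \code{capture_cutoff}, \code{hbond_dist}, \code{hbond_dist_s},
#'   \code{hbond_angle}
#' @return long data frame: \code{frame}, \code{time_ns},
#'   \code{observable}, \code{value}
#' @export
analyze_trajectory <- function(traj,
                               observables = c("sasa", "rgyr", "capture",
                                               "waters", "hbonds"),
                               params = list()) {
  observables <- match.arg(observables, several.ok = TRUE)
  p <- utils::modifyList(list(probe_radius = 1.4, n_points = 960,
                              backbone_cutoff = 3.0, com_radius = 25,
                              capture_cutoff = 4.5, hbond_dist = 3.0,
                              hbond_dist_s = 3.5, hbond_angle = 30),
                         params)
  out <- list()
  for (fi in seq_along(traj$frames)) {
    fr <- list(xyz = traj$frames[[fi]], topology = traj$topology,
               box = traj$box)
    vals <- c(
      sasa = if ("sasa" %in% observables)
        sasa(fr, selection = .role_idx(traj$topology, "hydrogel"),
             probe_radius = p$probe_radius, n_points = p$n_points)
      else NA,
      rgyr = if ("rgyr" %in% observables)
        rgyr(fr, selection = .role_idx(traj$topology, "hydrogel"))
      else NA,
      capture = if ("capture" %in% observables)
        capture_fraction(fr, cutoff = p$capture_cutoff) else NA,
      waters = if ("waters" %in% observables)
        water_shell_count(fr, backbone_cutoff = p$backbone_cutoff,
                          com_radius = p$com_radius) else NA,
      hbonds = if ("hbonds" %in% observables)
        hbond_count(fr, d_cut = p$hbond_dist, d_cut_s = p$hbond_dist_s,
                    angle_cut = p$hbond_angle) else NA)
    vals <- vals[observables]
    out[[fi]] <- data.frame(frame = fi, time_ns = traj$times[fi],
                            observable = names(vals),
                            value = unname(vals),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if ("capture" %in% observables) {
    cap <- res[res$observable == "capture", ]
    full <- cap$time_ns[cap$value >= 100 - 1e-9]
    attr(res, "first_full_capture_ns") <- if (length(full)) min(full)
                                          else NA_real_
  }
  res
}
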