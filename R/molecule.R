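#' Construct a molecule
#'
#' The molecule is the structural currency of the package: an atom table
#' (element, Cartesian coordinates in Angstrom, fixed partial charge in
#' elementary-charge units, van der Waals radius, role label) plus a bond
#' list. Bonds are topological; no force-field terms are implied beyond
#' what individual operations document.
#'
#' @param atoms data frame with columns \code{atom_id} (unique integer),
#'   \code{element}, \code{x}, \code{y}, \code{z}, \code{charge},
#'   \code{vdw}, \code{label}. Missing \code{vdw} is filled from the Bondi
#'   table, missing \code{label} becomes \code{"other"}, missing
#'   \code{atom_id} becomes the row index.
#' @param bonds data frame with columns \code{from}, \code{to} (atom ids)
#'   and \code{order} (character: \code{"1"}, \code{"2"}, \code{"3"},
#'   \code{"am"}, \code{"ar"}). May be empty.
#' @param name molecule identifier
#' @return object of class \code{molecule}
#' @export
molecule <- function(atoms, bonds = NULL, name = "mol") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  req <- c("element", "x", "y", "z", "charge")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols)) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(atoms$atom_id)) atoms$atom_id <- seq_len(nrow(atoms))
  if (is.null(atoms$vdw)) atoms$vdw <- vdw_radius(atoms$element)
  if (is.null(atoms$label)) atoms$label <- rep("other", nrow(atoms))
  if (anyDuplicated(atoms$atom_id)) {
    stop("atom_id values must be unique within a molecule", call. = FALSE)
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("atom coordinates must be finite", call. = FALSE)
  }
  if (any(atoms$vdw <= 0)) stop("vdw radii must be positive", call. = FALSE)
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0) {
    bonds <- data.frame(from = integer(), to = integer(),
                        order = character(), stringsAsFactors = FALSE)
  } else {
    bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
    bonds$order <- as.character(bonds$order)
    if (!all(c(bonds$from, bonds$to) %in% atoms$atom_id)) {
      stop("bond references an atom id not present in the molecule",
           call. = FALSE)
    }
  }
  structure(list(atoms = atoms, bonds = bonds, name = name),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %d atoms, %d bonds, net charge %+.3f e\n",
              x$name, nrow(x$atoms), nrow(x$bonds), net_charge(x)))
  cat("  formula:", chem_formula(x), "\n")
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a \code{molecule}
#' @return integer
#' @export
natoms <- function(mol) nrow(mol$atoms)

#' Coordinates of a molecule as an n x 3 matrix (Angstrom)
#' @param mol a \code{molecule}
#' @return numeric matrix with columns x, y, z
#' @export
coords <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z"), drop = FALSE])
}

#' Replace the coordinates of a molecule
#' @param mol a \code{molecule}
#' @param xyz n x 3 numeric matrix
#' @return the modified molecule
#' @export
set_coords <- function(mol, xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(nrow(xyz) == natoms(mol), ncol(xyz) == 3)
  mol$atoms$x <- xyz[, 1]
  mol$atoms$y <- xyz[, 2]
  mol$atoms$z <- xyz[, 3]
  mol
}

#' Net charge of a molecule
#'
#' Defined as the sum of the atomic partial charges; the package keeps
#' this bookkeeping exact through every structural edit.
#' @param mol a \code{molecule}
#' @return numeric, elementary charges
#' @export
net_charge <- function(mol) sum(mol$atoms$charge)

#' Hill-order chemical formula of a molecule
#' @param mol a \code{molecule}
#' @return character scalar, e.g. \code{"C5H12NO3PS2"}
#' @export
chem_formula <- function(mol) {
  tab <- table(mol$atoms$element)
  els <- names(tab)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    n <- tab[[e]]
    if (n == 1) e else paste0(e, n)
  }, character(1)), collapse = "")
}

#' Molar mass of a molecule
#' @param mol a \code{molecule}
#' @return numeric, g/mol
#' @export
molar_mass <- function(mol) sum(atomic_mass(mol$atoms$element))

#' Mass-weighted center of a molecule
#'
#' Standard mass-weighted mean position using the shipped standard atomic
#' weights.
#' @param mol a \code{molecule} with at least one atom
#' @return numeric length-3 vector, Angstrom
#' @export
center_of_mass <- function(mol) {
  if (natoms(mol) < 1) stop("center_of_mass: empty molecule", call. = FALSE)
  m <- atomic_mass(mol$atoms$element)
  unname(drop(crossprod(coords(mol), m) / sum(m)))
}

#' Rigidly translate a molecule
#' @param mol a \code{molecule}
#' @param v length-3 translation vector, Angstrom
#' @return the translated molecule
#' @export
translate_mol <- function(mol, v) {
  set_coords(mol, sweep(coords(mol), 2, as.numeric(v), "+"))
}

#' Rigidly rotate a molecule about the origin
#' @param mol a \code{molecule}
#' @param R 3 x 3 rotation matrix
#' @return the rotated molecule
#' @export
rotate_mol <- function(mol, R) {
  set_coords(mol, coords(mol) %*% t(R))
}

#' Merge several molecules into one
#'
#' The first molecule keeps its atom ids (they may contain gaps after
#' structural edits); each subsequent molecule is renumbered to
#' \code{max(id so far) + row index}, so for parts whose ids run 1..n
#' the new id of atom k is the running maximum plus k. Bond tables are
#' remapped accordingly; labels and charges are preserved.
#' @param mols list of \code{molecule} objects
#' @param name name of the merged molecule
#' @return a \code{molecule}
#' @export
merge_molecules <- function(mols, name = "complex") {
  stopifnot(length(mols) >= 1)
  atoms <- list()
  bonds <- list()
  max_id <- 0L
  for (mi in seq_along(mols)) {
    m <- mols[[mi]]
    a <- m$atoms
    b <- m$bonds
    if (mi > 1) {
      idmap <- stats::setNames(max_id + seq_len(nrow(a)), a$atom_id)
      a$atom_id <- unname(idmap[as.character(a$atom_id)])
      if (nrow(b)) {
        b$from <- unname(idmap[as.character(b$from)])
        b$to <- unname(idmap[as.character(b$to)])
      }
    }
    max_id <- max(max_id, a$atom_id)
    atoms[[mi]] <- a
    bonds[[mi]] <- b
  }
  molecule(do.call(rbind, atoms), do.call(rbind, bonds), name = name)
}

# adjacency list: for each atom id, the ids bonded to it
.bond_adjacency <- function(mol) {
  adj <- vector("list", natoms(mol))
  names(adj) <- as.character(mol$atoms$atom_id)
  for (k in seq_len(nrow(mol$bonds))) {
    f <- as.character(mol$bonds$from[k])
    t <- as.character(mol$bonds$to[k])
    adj[[f]] <- c(adj[[f]], mol$bonds$to[k])
    adj[[t]] <- c(adj[[t]], mol$bonds$from[k])
  }
  adj
}

# logical n x n matrix marking pairs separated by up to `hops` bonds
# (and self); hops = 2 excludes 1-2 and 1-3 pairs, hops = 3 adds 1-4
.excluded_pairs <- function(mol, hops = 2) {
  n <- natoms(mol)
  ex <- diag(TRUE, n)
  if (!nrow(mol$bonds)) return(ex)
  idx <- stats::setNames(seq_len(n), as.character(mol$atoms$atom_id))
  bf <- idx[as.character(mol$bonds$from)]
  bt <- idx[as.character(mol$bonds$to)]
  A <- matrix(0, n, n)
  A[cbind(bf, bt)] <- 1
  A[cbind(bt, bf)] <- 1
  reach <- A
  P <- A
  if (hops >= 2) for (h in 2:hops) {
    P <- P %*% A
    reach <- reach + P
  }
  ex | (reach > 0)
}
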