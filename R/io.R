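#' Read a molecular structure file
#'
#' Supported formats: PDB and SYBYL MOL2 (parsed with \pkg{bio3d}) and
#' (extended) XYZ. MOL2 carries bonds and partial charges and is the
#' lossless interchange format of the package. XYZ files may carry a
#' fifth per-atom column holding the partial charge; plain four-column
#' XYZ yields zero charges with a warning. PDB carries coordinates and
#' elements; partial charges are stored in the B-factor column (two
#' decimals) by the matching writer and recovered from there.
#'
#' @param path file path
#' @param format one of \code{"pdb"}, \code{"mol2"}, \code{"xyz"};
#'   inferred from the file extension when missing
#' @param label role label to assign to all atoms
#' @return a \code{molecule}
#' @export
read_structure <- function(path, format = NULL, label = "other") {
  format <- .resolve_format(path, format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
         mol2 = .read_mol2(path, label),
         pdb  = .read_pdb_single(path, label),
         xyz  = .read_xyz(path, label))
}

#' Write a molecular structure file
#'
#' Inverse of \code{\link{read_structure}}. MOL2 round-trips coordinates,
#' elements, bonds and charges; XYZ round-trips coordinates, elements and
#' charges (extended charge column); PDB round-trips coordinates and
#' elements, with charges coarsened to two decimals in the B-factor
#' column and bonds dropped.
#'
#' @param mol a \code{molecule}
#' @param path output file path
#' @param format one of \code{"pdb"}, \code{"mol2"}, \code{"xyz"};
#'   inferred from the extension when missing
#' @return \code{path}, invisibly
#' @export
write_structure <- function(mol, path, format = NULL) {
  format <- .resolve_format(path, format)
  switch(format,
         mol2 = .write_mol2(mol, path),
         pdb  = .write_pdb_single(mol, path),
         xyz  = .write_xyz(mol, path))
  invisible(path)
}

.resolve_format <- function(path, format) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
  }
  format <- tolower(format)
  if (!format %in% c("pdb", "mol2", "xyz")) {
    stop("unsupported structure format: '", format,
         "' (supported: pdb, mol2, xyz)", call. = FALSE)
  }
  format
}

## ---- MOL2 (via bio3d) -----------------------------------------------------

.read_mol2 <- function(path, label = "other") {
  m <- tryCatch(bio3d::read.mol2(path),
                error = function(e) {
                  stop("failed to parse MOL2 file '", path, "': ",
                       conditionMessage(e), call. = FALSE)
                })
  mol2_to_molecule(m, name = m$name, label = label)
}

#' Convert a bio3d mol2 object to a molecule
#' @param m a \code{bio3d} mol2 object
#' @param name molecule name
#' @param label role label
#' @return a \code{molecule}
#' @export
mol2_to_molecule <- function(m, name = "mol", label = "other") {
  a <- m$atom
  element <- sub("\\..*$", "", a$elety)
  atoms <- data.frame(atom_id = as.integer(a$eleno),
                      element = element,
                      x = a$x, y = a$y, z = a$z,
                      charge = if (is.null(a$charge)) 0 else a$charge,
                      label = label,
                      stringsAsFactors = FALSE)
  atoms$vdw <- vdw_radius(atoms$element)
  bonds <- if (!is.null(m$bond) && nrow(m$bond)) {
    data.frame(from = as.integer(m$bond$origin),
               to = as.integer(m$bond$target),
               order = as.character(m$bond$type),
               stringsAsFactors = FALSE)
  } else NULL
  molecule(atoms, bonds, name = name)
}

.sybyl_type <- function(mol) {
  # minimal SYBYL typing: element plus a generic hybridisation suffix;
  # enough for interchange, not for force-field assignment
  el <- mol$atoms$element
  out <- el
  out[el == "C"] <- "C.3"
  out[el == "N"] <- "N.3"
  out[el == "O"] <- "O.3"
  out[el == "S"] <- "S.3"
  out[el == "P"] <- "P.3"
  out
}

.write_mol2 <- function(mol, path) {
  n <- natoms(mol)
  idx <- stats::setNames(seq_len(n), as.character(mol$atoms$atom_id))
  m <- list(
    atom = data.frame(
      eleno = seq_len(n),
      elena = mol$atoms$element,
      x = mol$atoms$x, y = mol$atoms$y, z = mol$atoms$z,
      elety = .sybyl_type(mol),
      resno = 1L, resid = "MOL1",
      charge = mol$atoms$charge,
      stringsAsFactors = FALSE
    ),
    bond = if (nrow(mol$bonds)) data.frame(
      id = seq_len(nrow(mol$bonds)),
      origin = unname(idx[as.character(mol$bonds$from)]),
      target = unname(idx[as.character(mol$bonds$to)]),
      type = mol$bonds$order,
      stringsAsFactors = FALSE
    ) else data.frame(id = integer(), origin = integer(),
                      target = integer(), type = character()),
    substructure = NULL,
    info = c(n, nrow(mol$bonds), 0, 0, 0),
    name = mol$name
  )
  class(m) <- "mol2"
  bio3d::write.mol2(m, file = path)
}

## ---- PDB (via bio3d) ------------------------------------------------------

.read_pdb_single <- function(path, label = "other") {
  p <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
                error = function(e) {
                  stop("failed to parse PDB file '", path, "': ",
                       conditionMessage(e), call. = FALSE)
                })
  if (is.null(p$atom) || nrow(p$atom) == 0) {
    stop("failed to parse PDB file '", path, "': no ATOM/HETATM records",
         call. = FALSE)
  }
  a <- p$atom
  element <- a$elesy
  bad <- is.na(element) | element == ""
  element[bad] <- sub("^[0-9 ]*", "", substr(a$elety[bad], 1, 2))
  element <- paste0(toupper(substr(element, 1, 1)),
                    tolower(substr(element, 2, nchar(element))))
  charge <- a$b
  charge[is.na(charge)] <- 0
  atoms <- data.frame(atom_id = seq_len(nrow(a)),
                      element = trimws(element),
                      x = a$x, y = a$y, z = a$z,
                      charge = charge,
                      label = label,
                      stringsAsFactors = FALSE)
  atoms$vdw <- vdw_radius(atoms$element)
  molecule(atoms, NULL, name = basename(path))
}

.write_pdb_single <- function(mol, path) {
  n <- natoms(mol)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(coords(mol))),
                   resno = rep(1L, n), resid = rep("MOL", n),
                   eleno = seq_len(n),
                   elety = mol$atoms$element,
                   elesy = mol$atoms$element,
                   o = rep(1, n),
                   b = round(mol$atoms$charge, 2))
}

## ---- XYZ (native) ---------------------------------------------------------

.read_xyz <- function(path, label = "other") {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) {
    stop("XYZ parse error in '", path, "' at line 1: file too short",
         call. = FALSE)
  }
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) {
    stop("XYZ parse error in '", path, "' at line 1: invalid atom count",
         call. = FALSE)
  }
  if (length(lines) < n + 2) {
    stop("XYZ parse error in '", path, "' at line ", length(lines) + 1,
         ": expected ", n, " atom records, file truncated", call. = FALSE)
  }
  name <- trimws(lines[2])
  if (name == "") name <- basename(path)
  rows <- vector("list", n)
  has_charge <- TRUE
  for (k in seq_len(n)) {
    ln <- n_line <- k + 2L
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(f) < 4) {
      stop("XYZ parse error in '", path, "' at line ", ln,
           ": expected 'element x y z [charge]'", call. = FALSE)
    }
    xyz <- suppressWarnings(as.numeric(f[2:4]))
    if (anyNA(xyz)) {
      stop("XYZ parse error in '", path, "' at line ", ln,
           ": non-numeric coordinate", call. = FALSE)
    }
    q <- if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else NA_real_
    if (is.na(q)) has_charge <- FALSE
    rows[[k]] <- data.frame(element = f[1], x = xyz[1], y = xyz[2],
                            z = xyz[3], charge = q,
                            stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  if (!has_charge) {
    atoms$charge <- 0
    warning("XYZ file '", path, "' carries no charge column; ",
            "partial charges set to zero", call. = FALSE)
  }
  atoms$atom_id <- seq_len(n)
  atoms$label <- label
  atoms$vdw <- vdw_radius(atoms$element)
  molecule(atoms, NULL, name = name)
}

.write_xyz <- function(mol, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(natoms(mol)), con)
  writeLines(mol$name, con)
  writeLines(sprintf("%-2s %14.8f %14.8f %14.8f %12.8f",
                     mol$atoms$element, mol$atoms$x, mol$atoms$y,
                     mol$atoms$z, mol$atoms$charge), con)
}
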