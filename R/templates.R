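#' Names of the built-in molecule templates
#'
#' Seventeen templates ship with the package: the pesticide dimethoate, a
#' water molecule, a PVA monomer unit, and the fourteen dicarboxylic
#' acids screened as crosslinking agents (oxalic through azelaic). The
#' diacid templates carry both carboxylates deprotonated (net charge -2),
#' the state relevant at the working pH of 5.5.
#'
#' @return character vector of valid template ids
#' @export
template_ids <- function() c("dimethoate", "water", "pva_monomer",
                             diacid_ids())

#' Names of the fourteen dicarboxylic-acid crosslinker templates
#'
#' Ordered by the conventional screening id (roughly increasing size):
#' oxalic, malonic, succinic, malic, fumaric, maleic, citraconic,
#' itaconic, tartaric, glutaric, adipic, pimelic, suberic, azelaic.
#' @return character vector of 14 template ids
#' @export
diacid_ids <- function() {
  c("oxalic", "malonic", "succinic", "malic", "fumaric", "maleic",
    "citraconic", "itaconic", "tartaric", "glutaric", "adipic",
    "pimelic", "suberic", "azelaic")
}

#' Load a built-in molecule template
#'
#' Templates are stored as SYBYL MOL2 files under the package's
#' \code{extdata/templates} directory. Geometries are idealized 3-D
#' structures generated with Open Babel; partial charges are fixed
#' Gasteiger-type values adjusted so that each template's charges sum
#' exactly to its formal net charge (0 for neutral species, -2 for the
#' deprotonated diacids). Bondi van der Waals radii are assigned per
#' element. Users needing different charge models can post-process the
#' returned molecule (the charge column is plain data).
#'
#' @param id a template name; see \code{\link{template_ids}}
#' @return a \code{molecule} with role labels set (\code{"DMT"},
#'   \code{"water"}, \code{"PVA"} or \code{"linker"})
#' @export
#' @examples
#' dmt <- load_template("dimethoate")
#' chem_formula(dmt)
load_template <- function(id) {
  if (!is.character(id) || length(id) != 1 || !(id %in% template_ids())) {
    stop("template not found: '", paste(id, collapse = ","),
         "'; valid ids: ", paste(template_ids(), collapse = ", "),
         call. = FALSE)
  }
  path <- system.file("extdata", "templates", paste0(id, ".mol2"),
                      package = "hydrosieve", mustWork = TRUE)
  label <- switch(id, dimethoate = "DMT", water = "water",
                  pva_monomer = "PVA", "linker")
  mol <- .read_mol2(path, label = label)
  mol$name <- id
  mol
}

## ---- ionizable-group detection -------------------------------------------

# Identify carboxyl(ate) groups and alcohol hydroxyls from the bond graph.
# A carboxyl carbon is a C bonded to exactly two oxygens that have no other
# heavy-atom neighbour; a hydroxyl oxygen is an O with exactly one
# heavy-atom neighbour (a non-carboxyl carbon). Returns a list with
# data frames `carboxyl` (c_id, o_ids, h_id or NA) and `hydroxyl`
# (o_id, h_id or NA).
.find_ionizable <- function(mol) {
  at <- mol$atoms
  adj <- .bond_adjacency(mol)
  elem <- stats::setNames(at$element, as.character(at$atom_id))
  heavy_nb <- function(id) {
    nb <- adj[[as.character(id)]]
    nb[elem[as.character(nb)] != "H"]
  }
  h_nb <- function(id) {
    nb <- adj[[as.character(id)]]
    nb[elem[as.character(nb)] == "H"]
  }
  terminal_o <- function(id) {
    elem[[as.character(id)]] == "O" && length(heavy_nb(id)) == 1
  }
  carboxyl <- list()
  carboxyl_c <- integer()
  for (cid in at$atom_id[at$element == "C"]) {
    onb <- Filter(terminal_o, heavy_nb(cid))
    if (length(onb) == 2) {
      hs <- unlist(lapply(onb, h_nb))
      carboxyl[[length(carboxyl) + 1L]] <- list(
        c_id = cid, o_ids = as.integer(onb),
        h_id = if (length(hs)) as.integer(hs[1]) else NA_integer_)
      carboxyl_c <- c(carboxyl_c, cid)
    }
  }
  hydroxyl <- list()
  for (oid in at$atom_id[at$element == "O"]) {
    hv <- heavy_nb(oid)
    if (length(hv) == 1 && elem[[as.character(hv)]] == "C" &&
        !(hv %in% carboxyl_c)) {
      hs <- h_nb(oid)
      hydroxyl[[length(hydroxyl) + 1L]] <- list(
        o_id = as.integer(oid),
        c_id = as.integer(hv),
        h_id = if (length(hs)) as.integer(hs[1]) else NA_integer_)
    }
  }
  list(carboxyl = carboxyl, hydroxyl = hydroxyl)
}

.remove_atoms <- function(mol, ids) {
  keep <- !(mol$atoms$atom_id %in% ids)
  atoms <- mol$atoms[keep, , drop = FALSE]
  bonds <- mol$bonds[!(mol$bonds$from %in% ids | mol$bonds$to %in% ids),
                     , drop = FALSE]
  molecule(atoms, bonds, name = mol$name)
}

# charge assigned to an acidic proton added on (de)protonation; the
# complement is spread over the group oxygens so the net change is +-1
.PROTON_CHARGE <- 0.4

#' Set protonation states at a given pH
#'
#' Carboxylic-acid groups (pKa 4.7) and alcohol hydroxyls (pKa 10.6) are
#' detected from the bond graph and switched to the state the pH
#' dictates: a group whose pKa lies below the pH loses its acidic proton,
#' one whose pKa lies above it gains one. At the working pH of 5.5 this
#' deprotonates every carboxylate while leaving PVA hydroxyls protonated.
#' Charge bookkeeping is exact: each (de)protonation changes the net
#' charge by exactly one elementary charge, with the proton carrying a
#' fixed partial charge and the remainder spread over the group oxygens.
#' The operation is idempotent; molecules with no ionizable groups are
#' returned unchanged.
#'
#' @param mol a \code{molecule} with bond information
#' @param pH solution pH
#' @param pka_cooh carboxylic-acid pKa (default 4.7)
#' @param pka_oh hydroxyl pKa (default 10.6)
#' @return the adjusted \code{molecule}
#' @export
assign_protonation <- function(mol, pH, pka_cooh = 4.7, pka_oh = 10.6) {
  repeat {
    grp <- .find_ionizable(mol)
    changed <- FALSE
    for (g in grp$carboxyl) {
      if (pH > pka_cooh && !is.na(g$h_id)) {
        mol <- .deprotonate(mol, g$h_id, g$o_ids)
        changed <- TRUE; break
      }
      if (pH <= pka_cooh && is.na(g$h_id)) {
        mol <- .protonate(mol, g$c_id, g$o_ids)
        changed <- TRUE; break
      }
    }
    if (changed) next
    for (g in grp$hydroxyl) {
      if (pH > pka_oh && !is.na(g$h_id)) {
        mol <- .deprotonate(mol, g$h_id, g$o_id)
        changed <- TRUE; break
      }
      if (pH <= pka_oh && is.na(g$h_id)) {
        mol <- .protonate(mol, g$c_id, g$o_id)
        changed <- TRUE; break
      }
    }
    if (!changed) break
  }
  mol
}

.deprotonate <- function(mol, h_id, o_ids) {
  qh <- mol$atoms$charge[mol$atoms$atom_id == h_id]
  mol <- .remove_atoms(mol, h_id)
  sel <- mol$atoms$atom_id %in% o_ids
  mol$atoms$charge[sel] <- mol$atoms$charge[sel] - (1 - qh) / sum(sel)
  mol
}

.protonate <- function(mol, c_id, o_ids) {
  at <- mol$atoms
  # put the proton on the group oxygen carrying the most negative charge
  osel <- at[at$atom_id %in% o_ids, , drop = FALSE]
  o <- osel[which.min(osel$charge), ]
  cpos <- unlist(at[at$atom_id == c_id, c("x", "y", "z")])
  opos <- unlist(o[c("x", "y", "z")])
  dir <- .normalize(opos - cpos)
  hpos <- opos + 0.96 * dir
  new_id <- max(at$atom_id) + 1L
  newrow <- data.frame(atom_id = new_id, element = "H",
                       x = hpos[1], y = hpos[2], z = hpos[3],
                       charge = .PROTON_CHARGE, vdw = vdw_radius("H"),
                       label = o$label, stringsAsFactors = FALSE)
  atoms <- rbind(at[, names(newrow)], newrow)
  bonds <- rbind(mol$bonds,
                 data.frame(from = o$atom_id, to = new_id, order = "1",
                            stringsAsFactors = FALSE))
  out <- molecule(atoms, bonds, name = mol$name)
  sel <- out$atoms$atom_id %in% o_ids
  out$atoms$charge[sel] <- out$atoms$charge[sel] +
    (1 - .PROTON_CHARGE) / sum(sel)
  out
}
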