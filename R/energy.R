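# Conversion factor for Coulomb energies: e^2/Angstrom in kcal/mol
.COULOMB_K <- 332.0637

#' Lennard-Jones + Coulomb surrogate energy backend
#'
#' A desk-scale pairwise energy model used as the default backend of the
#' Monte-Carlo screen. The energy of a multi-molecule geometry is the sum
#' over \emph{intermolecular} atom pairs of
#' \deqn{4 \epsilon_{ij} [(\sigma_{ij}/d)^{12} - (\sigma_{ij}/d)^6] +
#'       332.0637 \, q_i q_j / d}
#' with Lorentz-Berthelot combination (\eqn{\epsilon_{ij} =
#' \sqrt{\epsilon_i \epsilon_j}}, \eqn{\sigma_{ij} = (\sigma_i +
#' \sigma_j)/2}) and UFF per-element parameters. The energy of an
#' isolated molecule is zero by construction, so the supermolecular
#' interaction energy reduces to the intermolecular sum. Absolute
#' energies are not comparable to quantum-chemical backends; rankings and
#' trends are the intended use.
#'
#' @param lj_scale multiplier on the Lennard-Jones term (set 0 to isolate
#'   the Coulomb term)
#' @param coulomb_scale multiplier on the Coulomb term
#' @return an energy backend: list with \code{name} and \code{energy(mols)}
#'   returning kcal/mol for a list of molecules
#' @export
surrogate_energy_backend <- function(lj_scale = 1, coulomb_scale = 1) {
  backend <- list(
    name = "surrogate",
    energy = function(mols) {
      if (length(mols) < 2) return(0)
      e <- 0
      for (i in seq_len(length(mols) - 1)) {
        for (j in seq(i + 1, length(mols))) {
          e <- e + .pair_lj_coulomb(mols[[i]], mols[[j]],
                                    lj_scale, coulomb_scale)
        }
      }
      e
    }
  )
  class(backend) <- "energy_backend"
  backend
}

.pair_lj_coulomb <- function(m1, m2, lj_scale = 1, coulomb_scale = 1) {
  p1 <- lj_params(m1$atoms$element)
  p2 <- lj_params(m2$atoms$element)
  d <- .cdist(coords(m1), coords(m2))
  d[d < 1e-9] <- 1e-9
  sig <- outer(p1$sigma, p2$sigma, "+") / 2
  eps <- sqrt(outer(p1$eps, p2$eps))
  sr6 <- (sig / d)^6
  e_lj <- 4 * eps * (sr6^2 - sr6)
  e_q <- .COULOMB_K * outer(m1$atoms$charge, m2$atoms$charge) / d
  lj_scale * sum(e_lj) + coulomb_scale * sum(e_q)
}

#' Supermolecular interaction energy of a positioned pair
#'
#' Single-point evaluation at frozen geometries: the interaction energy
#' is the energy of the complex minus the sum of the energies of the
#' isolated parts,
#' \deqn{\Delta E = E_{complex} - (E_{mol1} + E_{mol2}).}
#' No relaxation is performed.
#'
#' @param mol1,mol2 positioned \code{molecule} objects
#' @param backend an energy backend (see
#'   \code{\link{surrogate_energy_backend}}, \code{\link{pm7_backend}})
#' @param pose optional pose metadata carried into the sample
#' @return an \code{energy_sample}: list with \code{e_complex},
#'   \code{e_mol1}, \code{e_mol2}, \code{delta_e} (kcal/mol) and
#'   \code{pose}
#' @export
interaction_energy <- function(mol1, mol2, backend, pose = NULL) {
  e_complex <- tryCatch(backend$energy(list(mol1, mol2)),
                        error = function(e) {
                          stop("energy backend '", backend$name,
                               "' failed: ", conditionMessage(e),
                               call. = FALSE)
                        })
  e1 <- backend$energy(list(mol1))
  e2 <- backend$energy(list(mol2))
  structure(list(pose = pose, e_complex = e_complex, e_mol1 = e1,
                 e_mol2 = e2, delta_e = e_complex - (e1 + e2)),
            class = "energy_sample")
}

#' Semi-empirical (PM7) energy backend via an external MOPAC executable
#'
#' Adapter around an externally installed MOPAC-style program: writes a
#' single-point (1SCF) input with the geometry and the molecule's formal
#' net charge, runs the executable, and parses the total energy in
#' kcal/mol. This backend is optional; nothing in the package requires
#' it, and it errors clearly when the executable is absent.
#'
#' @param executable_path path to the MOPAC executable
#' @param keywords extra keyword string appended to the 1SCF header
#' @return an energy backend
#' @export
pm7_backend <- function(executable_path, keywords = "PM7") {
  if (!nzchar(Sys.which(executable_path)) && !file.exists(executable_path)) {
    stop("pm7 backend unavailable: executable not found at '",
         executable_path, "'", call. = FALSE)
  }
  backend <- list(
    name = "pm7",
    energy = function(mols) {
      mol <- if (length(mols) == 1) mols[[1]] else merge_molecules(mols)
      dir <- tempfile("pm7_")
      dir.create(dir)
      on.exit(unlink(dir, recursive = TRUE))
      inp <- file.path(dir, "job.mop")
      chg <- round(net_charge(mol))
      hdr <- sprintf("1SCF %s CHARGE=%d", keywords, chg)
      xyz <- coords(mol)
      writeLines(c(hdr, mol$name, "",
                   sprintf("%-2s %12.6f 1 %12.6f 1 %12.6f 1",
                           mol$atoms$element, xyz[, 1], xyz[, 2],
                           xyz[, 3])), inp)
      status <- system2(executable_path, inp, stdout = TRUE, stderr = TRUE)
      outfile <- file.path(dir, "job.out")
      if (!file.exists(outfile)) {
        stop("pm7 backend: no output produced; captured: ",
             paste(utils::head(status, 5), collapse = " / "),
             call. = FALSE)
      }
      out <- readLines(outfile, warn = FALSE)
      ln <- grep("FINAL HEAT OF FORMATION", out, value = TRUE)
      if (!length(ln)) {
        stop("pm7 backend: could not parse energy from output; tail: ",
             paste(utils::tail(out, 5), collapse = " / "), call. = FALSE)
      }
      m <- regmatches(ln[1],
                      regexpr("-?[0-9]+\\.[0-9]+(?= KCAL/MOL)", ln[1],
                              perl = TRUE))
      if (!length(m)) {
        stop("pm7 backend: unparseable energy line: ", ln[1], call. = FALSE)
      }
      as.numeric(m)
    }
  )
  class(backend) <- "energy_backend"
  backend
}
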