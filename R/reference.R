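#' Reference per-acid average interaction energies
#'
#' The published per-acid averages of the nanopore/dimethoate
#' interaction-energy screen obtained with the full semi-empirical (PM7)
#' protocol, shipped as reference data for ranking and comparison. These
#' values depend on the quantum-chemical backend and the original
#' optimized geometries; the package's surrogate backend reproduces
#' rankings and trends, not these absolute numbers.
#'
#' @return data frame with columns \code{id}, \code{acid},
#'   \code{mean_kcal_mol}
#' @export
reference_interaction_energies <- function() {
  path <- system.file("extdata", "pm7_reference_means.csv",
                      package = "hydrosieve", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
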