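#' Element reference data
#'
#' Per-element reference tables used throughout the package: standard atomic
#' weights (g/mol), Bondi van der Waals radii (Angstrom), and
#' Lennard-Jones well depths / diameters taken from the Universal Force
#' Field (UFF) parameterisation. Only elements that occur in the shipped
#' molecule templates are tabulated.
#'
#' @format A data frame with one row per element and columns
#'   \describe{
#'     \item{element}{chemical symbol}
#'     \item{mass}{standard atomic weight, g/mol}
#'     \item{vdw}{Bondi van der Waals radius, Angstrom}
#'     \item{lj_eps}{UFF well depth, kcal/mol}
#'     \item{lj_sigma}{LJ diameter sigma, Angstrom (UFF minimum distance
#'       x_i divided by 2^(1/6))}
#'   }
#' @export
element_data <- local({
  # UFF: D_i (kcal/mol) and x_i (Angstrom, position of LJ minimum)
  d <- data.frame(
    element = c("H", "C", "N", "O", "P", "S", "F", "Cl", "Br", "Na", "K"),
    mass    = c(1.008, 12.011, 14.007, 15.999, 30.974, 32.06,
                18.998, 35.45, 79.904, 22.990, 39.098),
    vdw     = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80, 1.47, 1.75, 1.85,
                2.27, 2.75),
    uff_d   = c(0.044, 0.105, 0.069, 0.060, 0.305, 0.274, 0.050, 0.227,
                0.251, 0.030, 0.035),
    uff_x   = c(2.886, 3.851, 3.660, 3.500, 4.147, 4.035, 3.364, 3.947,
                4.189, 2.983, 3.812),
    stringsAsFactors = FALSE
  )
  d$lj_eps <- d$uff_d
  d$lj_sigma <- d$uff_x / 2^(1 / 6)
  d$uff_d <- d$uff_x <- NULL
  d
})

.element_lookup <- function(elements, column) {
  i <- match(elements, element_data$element)
  if (anyNA(i)) {
    stop("no parameters tabulated for element(s): ",
         paste(unique(elements[is.na(i)]), collapse = ", "),
         call. = FALSE)
  }
  element_data[[column]][i]
}

#' Standard atomic weights for a vector of element symbols
#' @param elements character vector of element symbols
#' @return numeric vector, g/mol
#' @export
atomic_mass <- function(elements) .element_lookup(elements, "mass")

#' Bondi van der Waals radii for a vector of element symbols
#' @param elements character vector of element symbols
#' @return numeric vector, Angstrom
#' @export
vdw_radius <- function(elements) .element_lookup(elements, "vdw")

#' UFF Lennard-Jones parameters for a vector of element symbols
#' @param elements character vector of element symbols
#' @return data frame with columns \code{eps} (kcal/mol) and \code{sigma}
#'   (Angstrom)
#' @export
lj_params <- function(elements) {
  data.frame(eps   = .element_lookup(elements, "lj_eps"),
             sigma = .element_lookup(elements, "lj_sigma"))
}
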