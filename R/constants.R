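#' Physical constants and element tables
#'
#' Unit system used throughout: energies in kJ/mol, distances in Angstrom,
#' angles in radians internally (degrees at user-facing interfaces), charges
#' in elementary charges, masses in unified atomic mass units, temperatures
#' in Kelvin.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{coulomb}{Coulomb constant, 1389.3546 kJ mol^-1 A e^-2.}
#'   \item{kB}{Boltzmann constant per mole, 8.3144621e-3 kJ mol^-1 K^-1.}
#'   \item{fs_per_time_unit}{Internal MD time unit (sqrt(amu A^2 / (kJ/mol)))
#'     expressed in femtoseconds, ~100 fs; used to convert fs time steps.}
#' }
#' @export
ff_constants <- list(
  coulomb = 1389.3546,
  kB = 8.3144621e-3,
  fs_per_time_unit = 100
)

# atomic masses (amu) and van der Waals radii (A) for the elements the toy
# molecules use
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  S = 32.06, Cl = 35.45
)

.element_vdw <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, S = 1.80, Cl = 1.75
)

#' Atomic masses for a vector of element symbols
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of masses in amu.
#' @export
element_masses <- function(elements) {
  m <- .element_masses[elements]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(elements[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' Van der Waals radii for a vector of element symbols
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of radii in Angstrom.
#' @export
element_vdw_radii <- function(elements) {
  r <- .element_vdw[elements]
  if (anyNA(r)) {
    stop("unknown element symbol(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
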