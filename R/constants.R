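#' Physical constants and unit conversions
#'
#' Internal units follow the GROMACS convention: lengths in nm, times in
#' ps, masses in amu, charges in elementary charge units, energies in
#' kJ/mol.  All unit conversions live here so they can be tested against
#' hand values in one place.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{k_coulomb}{Coulomb constant, kJ mol^-1 nm e^-2 (138.935458).}
#'   \item{kB}{Boltzmann constant times Avogadro, kJ mol^-1 K^-1.}
#'   \item{nm_per_angstrom}{0.1.}
#'   \item{nm2_ps_to_1e10_cm2_s}{Multiplier converting a diffusion
#'     coefficient in nm^2/ps to units of 1e-10 cm^2/s (1 nm^2/ps =
#'     1e-2 cm^2/s = 1e8 x 1e-10 cm^2/s).}
#' }
#' @export
md_constants <- list(
  k_coulomb             = 138.935458,
  kB                    = 0.008314462618,
  nm_per_angstrom       = 0.1,
  nm2_ps_to_1e10_cm2_s  = 1e8
)

# IUPAC 2021 standard atomic weights (abridged, conventional values for
# elements with an interval).  amu.
.atomic_weights <- c(
  H = 1.008,  He = 4.002602,
  Li = 6.94,  Be = 9.0121831, B = 10.81, C = 12.011, N = 14.007,
  O = 15.999, F = 18.998403163, Ne = 20.1797,
  Na = 22.98976928, Mg = 24.305, Al = 26.9815384, Si = 28.085,
  P = 30.973761998, S = 32.06, Cl = 35.45, Ar = 39.95,
  K = 39.0983, Ca = 40.078, Fe = 55.845, Cu = 63.546, Zn = 65.38,
  Br = 79.904, I = 126.90447
)

#' Standard atomic weight lookup
#'
#' @param element character vector of element symbols.
#' @return numeric vector of standard atomic weights in amu.
#' @export
atomic_weight <- function(element) {
  w <- .atomic_weights[element]
  if (anyNA(w)) {
    stop("unknown element(s): ",
         paste(unique(element[is.na(w)]), collapse = ", "))
  }
  unname(w)
}
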