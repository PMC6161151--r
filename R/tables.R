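#' Bundled blend composition table
#'
#' Published molecular content of the sixteen flufenamic acid (FLA) and
#' phenacetin (PAC) blends with four polymers (EEC, PAA, PSA, PVP) plus
#' the six pure systems: polymer chain counts (\code{npol}), monomers
#' per chain (\code{nmon}), API molecule counts (\code{napi}), total
#' masses (amu), API weight percents and average simulation volumes
#' (nm^3).  Pure-polymer rows have an empty \code{api} and
#' \code{napi = 0}; pure-API rows have an empty \code{polymer}.
#'
#' @return data.frame, one row per system.
#' @export
asd_compositions <- function() {
  utils::read.csv(system.file("extdata", "blend_compositions.csv",
                              package = "asdstab"),
                  stringsAsFactors = FALSE)
}

#' Bundled blend descriptor table
#'
#' Published per-blend descriptors for the eight 40 wt% blends:
#' experimental amorphicity indices at 25 and 40 wt% drug load and
#' their six-concentration mean (\code{AI25}, \code{AI40},
#' \code{AI_mean}; dimensionless, 0-100, higher = more stable),
#' intermolecular Coulomb mixing energy \code{dE_coul} (kJ/mol per
#' simulation cell), API translational diffusion coefficient \code{D}
#' (1e-10 cm^2/s) and heavy-atom RMSF after center-of-mass alignment
#' (nm).
#'
#' @return data.frame, one row per API-polymer blend.
#' @export
asd_descriptors <- function() {
  utils::read.csv(system.file("extdata", "blend_descriptors.csv",
                              package = "asdstab"),
                  stringsAsFactors = FALSE)
}
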