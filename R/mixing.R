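#' Frame indices of a late-time averaging window
#'
#' Production averages are taken over the final part of a trajectory
#' where relative energies have settled; the default window is the
#' final 40\% of frames.
#'
#' @param traj an [md_trajectory()].
#' @param window fraction (0, 1] of trailing frames to keep.
#' @return integer frame indices.
#' @export
window_frames <- function(traj, window = 0.4) {
  nf <- n_frames(traj)
  if (window <= 0 || window > 1) stop("window must be in (0, 1]")
  seq.int(max(1L, nf - ceiling(window * nf) + 1L), nf)
}

#' Mixing energy relative to pure amorphous reference phases
#'
#' The reference state is the sum of the energies of the same number
#' of molecules in the pure amorphous phases:
#' \code{dE = E_blend - (Napi * e_api_pure + Npol * e_polymer_pure)},
#' with pure-phase energies stored per API molecule / per polymer
#' chain.  Three normalizations are attached: the raw per-simulation
#' cell value, per volume, and per API molecule.
#'
#' @param e_blend trajectory-averaged blend energy, kJ/mol
#'   (per simulation cell).
#' @param e_api_pure pure-API energy per molecule, kJ/mol.
#' @param e_polymer_pure pure-polymer energy per chain, kJ/mol.
#' @param napi,npol molecule counts in the blend.
#' @param volume blend volume in nm^3 (NA skips the per-volume
#'   normalization).
#' @param term energy term label (\code{"e_tot"}, \code{"e_nb"} or
#'   \code{"e_coul"}); when any energy argument is an
#'   \code{energy_breakdown}, the term is extracted from it and all
#'   such arguments must carry the same components.
#' @return object of class \code{mixing_energy}: list with
#'   \code{term}, \code{delta_raw} (kJ/mol), \code{delta_per_volume}
#'   (kJ/mol/nm^3), \code{delta_per_api} (kJ/mol per API molecule) and
#'   \code{reference}.
#' @export
mixing_energy <- function(e_blend, e_api_pure, e_polymer_pure,
                          napi, npol, volume = NA_real_,
                          term = "e_coul") {
  pick <- function(x) {
    if (inherits(x, "energy_breakdown")) {
      if (is.null(x[[term]])) stop("term '", term,
                                   "' absent from energy breakdown")
      x[[term]]
    } else x
  }
  if (napi <= 0 || npol < 0) stop("invalid molecule counts")
  e_b <- pick(e_blend); e_a <- pick(e_api_pure); e_p <- pick(e_polymer_pure)
  d <- e_b - (napi * e_a + npol * e_p)
  structure(list(
    term = term,
    delta_raw = d,
    delta_per_volume = if (is.na(volume)) NA_real_ else d / volume,
    delta_per_api = d / napi,
    reference = "pure amorphous phases (per-molecule / per-chain averages)"),
    class = "mixing_energy")
}

#' @export
print.mixing_energy <- function(x, ...) {
  cat(sprintf(
    "mixing energy (%s): %.4g kJ/mol  [%.4g kJ/mol/nm^3, %.4g kJ/mol per API]\n",
    x$term, x$delta_raw, x$delta_per_volume, x$delta_per_api))
  invisible(x)
}

#' Polymer ranking by mixing energy
#'
#' Orders polymers by increasing mixing energy (lower = more
#' favourable mixing) and verifies that the ranking is identical
#' across the available normalizations of the same term; ties share a
#' rank rather than being broken arbitrarily.
#'
#' @param deltas either a named numeric vector (names = polymers) or a
#'   data.frame with a \code{polymer} column and one or more of
#'   \code{delta_raw}, \code{delta_per_volume}, \code{delta_per_api};
#'   a list of [mixing_energy()] objects named by polymer also works.
#' @return data.frame with columns \code{polymer}, \code{delta}
#'   (the raw values), \code{rank} (min-ties), ordered by delta; the
#'   attribute \code{normalizations_consistent} records whether every
#'   normalization produced the same ranking.
#' @export
energy_trend <- function(deltas) {
  if (is.list(deltas) && !is.data.frame(deltas) &&
      all(vapply(deltas, inherits, TRUE, "mixing_energy"))) {
    deltas <- data.frame(
      polymer = names(deltas),
      delta_raw = vapply(deltas, `[[`, 0, "delta_raw"),
      delta_per_volume = vapply(deltas, `[[`, 0, "delta_per_volume"),
      delta_per_api = vapply(deltas, `[[`, 0, "delta_per_api"))
  }
  if (is.numeric(deltas)) {
    if (is.null(names(deltas))) stop("deltas must be named by polymer")
    deltas <- data.frame(polymer = names(deltas), delta_raw = deltas)
  }
  if (nrow(deltas) < 2L) stop("need at least 2 blends to rank")
  norm_cols <- intersect(c("delta_raw", "delta_per_volume", "delta_per_api"),
                         names(deltas))
  norm_cols <- norm_cols[vapply(norm_cols,
                                function(c) !anyNA(deltas[[c]]), TRUE)]
  if (!length(norm_cols)) stop("no usable delta column")
  ranks <- lapply(norm_cols, function(c)
    rank(deltas[[c]], ties.method = "min"))
  consistent <- all(vapply(ranks, identical, TRUE, ranks[[1L]]))
  if (!consistent)
    warning("polymer ranking differs across normalizations")
  out <- data.frame(polymer = deltas$polymer,
                    delta = deltas[[norm_cols[1L]]],
                    rank = ranks[[1L]])
  out <- out[order(out$delta), ]
  rownames(out) <- NULL
  attr(out, "normalizations_consistent") <- consistent
  out
}
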