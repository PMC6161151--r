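# Charge-zeroing decomposition of intermolecular Coulomb energies.
#
# The Coulomb energy is a quadratic form in the charge vector, so the
# cross term between one molecule and the rest of the system is exactly
#   E_cross = E(full) - E(charges of the molecule zeroed)
#                     - E(all charges but the molecule's zeroed),
# for any evaluation method that is quadratic in the charges (direct,
# minimum image, Ewald).  This recovers intermolecular energies even
# under long-range electrostatics where a pairwise split is unavailable.

# Resolve frame selection: NULL = all frames.
.frame_sel <- function(traj, frames) frames %||% seq_len(n_frames(traj))

.coul <- function(frame, topology, charges, method, cutoff, ewald) {
  coulomb_energy(frame, topology, method = method, cutoff = cutoff,
                 charges = charges, ewald = ewald)
}

#' Intermolecular Coulomb energy of one molecule by charge zeroing
#'
#' For each selected frame the Coulomb energy is evaluated three times
#' with the same method: for the original charges, with the molecule's
#' charges set to zero, and with all charges but the molecule's set to
#' zero.  The cross term (full minus the two partial evaluations) is
#' the molecule's interaction energy with the rest of the system; it is
#' averaged over the frames.
#'
#' @param traj an [md_trajectory()] or a single [md_frame()].
#' @param topology a [system_topology()].
#' @param mol_id molecule instance id (see the \code{mol_id} column of
#'   \code{topology$atoms}).
#' @param method,cutoff,ewald Coulomb options, see [coulomb_energy()].
#' @param frames optional frame indices (default: every stored frame).
#' @return trajectory-averaged cross energy, kJ/mol.
#' @export
intermolecular_coulomb_by_zeroing <- function(traj, topology, mol_id,
                                              method = "minimum_image",
                                              cutoff = 0.9,
                                              ewald = list(),
                                              frames = NULL) {
  sel <- molecule_atom_indices(topology, mol_id)
  if (!length(sel)) stop("invalid molecule instance id ", mol_id)
  q <- topology$atoms$charge
  q_without <- q; q_without[sel] <- 0
  q_only <- numeric(length(q)); q_only[sel] <- q[sel]
  one <- function(fr) {
    .coul(fr, topology, q, method, cutoff, ewald) -
      .coul(fr, topology, q_without, method, cutoff, ewald) -
      .coul(fr, topology, q_only, method, cutoff, ewald)
  }
  if (inherits(traj, "md_frame")) return(one(traj))
  idx <- .frame_sel(traj, frames)
  mean(vapply(idx, function(i) one(get_frame(traj, i)), 0))
}

#' Species-level intermolecular Coulomb energy
#'
#' Applies the charge-zeroing decomposition to every molecule of a
#' species in turn and aggregates without double counting: the result
#' is the total intermolecular Coulomb energy over molecule pairs in
#' which at least one member belongs to the species (within-species
#' pairs counted once).  With \code{species = "all"} this is the
#' system's total intermolecular Coulomb energy, i.e. the quantity the
#' mixing-energy analysis needs: inter- but no intra-molecular
#' contributions.
#'
#' @param traj an [md_trajectory()] or a single [md_frame()].
#' @param topology a [system_topology()].
#' @param species species name, \code{"role:api"} / \code{"role:polymer"},
#'   or \code{"all"}.
#' @param method,cutoff,ewald Coulomb options, see [coulomb_energy()].
#' @param frames optional frame indices.
#' @return trajectory-averaged energy, kJ/mol.
#' @export
species_intermolecular_coulomb <- function(traj, topology, species,
                                           method = "minimum_image",
                                           cutoff = 0.9, ewald = list(),
                                           frames = NULL) {
  ids <- molecule_ids_of(topology, species)
  q <- topology$atoms$charge
  in_species <- topology$atoms$mol_id %in% ids
  q_sp <- numeric(length(q)); q_sp[in_species] <- q[in_species]
  one <- function(fr) {
    e_full <- .coul(fr, topology, q, method, cutoff, ewald)
    e_sp_full <- .coul(fr, topology, q_sp, method, cutoff, ewald)
    cross_sum <- 0      # sum over species molecules of E_cross vs everything
    cross_sp_sum <- 0   # same but vs other species molecules only
    for (m in ids) {
      sel <- molecule_atom_indices(topology, m)
      q_without <- q; q_without[sel] <- 0
      q_only <- numeric(length(q)); q_only[sel] <- q[sel]
      q_sp_without <- q_sp; q_sp_without[sel] <- 0
      e_only <- .coul(fr, topology, q_only, method, cutoff, ewald)
      cross_sum <- cross_sum + e_full -
        .coul(fr, topology, q_without, method, cutoff, ewald) - e_only
      cross_sp_sum <- cross_sp_sum + e_sp_full -
        .coul(fr, topology, q_sp_without, method, cutoff, ewald) - e_only
    }
    # within-species pairs appear twice in cross_sum and twice in
    # cross_sp_sum; keep them once.
    cross_sum - cross_sp_sum / 2
  }
  if (inherits(traj, "md_frame")) return(one(traj))
  idx <- .frame_sel(traj, frames)
  mean(vapply(idx, function(i) one(get_frame(traj, i)), 0))
}
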