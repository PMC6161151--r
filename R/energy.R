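# Non-bonded and bonded energy evaluation on single configurations.
#
# Conventions (GAFF/Amber style):
#   * 1-2 and 1-3 bonded neighbours never interact non-bonded;
#   * 1-4 pairs are excluded from the "non-bonded" energy e_nb entirely,
#     but enter the total energy with scaled interactions
#     (Coulomb / 1.2, LJ / 2);
#   * unlike LJ pairs combine by Lorentz-Berthelot rules;
#   * periodic systems use the minimum-image convention with an
#     orthorhombic box.

# Logical n x n matrix of pairs excluded from non-bonded evaluation.
# sep_max = 3 excludes 1-2/1-3/1-4; sep_max = 2 leaves 1-4 pairs in.
exclusion_matrix <- function(topology, sep_max = 3L) {
  n <- topology$n_atoms
  ex <- matrix(FALSE, n, n)
  e <- topology$exclusions
  keep <- e$sep <= sep_max
  if (any(keep)) {
    ij <- cbind(e$i[keep], e$j[keep])
    ex[ij] <- TRUE
    ex[ij[, 2:1, drop = FALSE]] <- TRUE
  }
  diag(ex) <- TRUE
  ex
}

# 2-column matrix of 1-4 pairs (i < j).
pairs_14 <- function(topology) {
  e <- topology$exclusions
  as.matrix(e[e$sep == 3L, c("i", "j")])
}

.check_cutoff <- function(cutoff, box) {
  if (!is.null(box) && is.finite(cutoff) && cutoff > min(box) / 2 + 1e-12)
    stop("cutoff (", cutoff, " nm) exceeds half the smallest box edge")
}

#' Lennard-Jones energy of a configuration
#'
#' Sums \code{4 eps [(sigma/r)^12 - (sigma/r)^6]} over non-excluded
#' pairs within the cutoff (minimum image when the frame has a box),
#' with Lorentz-Berthelot combining for unlike pairs.  The optional
#' tail correction adds the standard isotropic long-range dispersion
#' term assuming uniform density beyond the cutoff; it is negative for
#' attractive systems (requires cutoff > sigma).
#'
#' @param frame an [md_frame()].
#' @param topology a [system_topology()].
#' @param cutoff pair cutoff in nm (default 0.9); may be \code{Inf} for
#'   non-periodic systems.
#' @param tail_correction logical.
#' @return energy in kJ/mol.
#' @export
lj_energy <- function(frame, topology, cutoff = 0.9,
                      tail_correction = FALSE) {
  x <- frame$coords
  if (nrow(x) != topology$n_atoms)
    stop("frame atom count does not match topology")
  .check_cutoff(cutoff, frame$box)
  sig <- topology$atoms$sigma
  eps <- topology$atoms$epsilon
  n <- nrow(x)
  d2 <- pair_dist2(x, frame$box)
  sij <- outer(sig, sig, "+") / 2
  eij <- sqrt(outer(eps, eps))
  mask <- upper.tri(d2) & !exclusion_matrix(topology) &
    d2 <= cutoff^2 & eij > 0
  e <- 0
  if (any(mask)) {
    sr6 <- (sij[mask]^2 / d2[mask])^3
    e <- sum(4 * eij[mask] * (sr6 * sr6 - sr6))
  }
  if (tail_correction) {
    if (is.null(frame$box))
      stop("tail correction requires a periodic box")
    if (!is.finite(cutoff)) stop("tail correction requires finite cutoff")
    V <- prod(frame$box)
    off <- upper.tri(sij)
    # ordered-pair sum = 2 * upper triangle (self pairs omitted)
    e_tail <- (16 * pi / V) *
      sum(eij[off] * (sij[off]^12 / (9 * cutoff^9) -
                      sij[off]^6 / (3 * cutoff^3)))
    e <- e + e_tail
  }
  e
}

#' Coulomb energy of a configuration
#'
#' @param frame an [md_frame()].
#' @param topology a [system_topology()].
#' @param method \code{"direct"} (non-periodic all-pairs),
#'   \code{"minimum_image"} (periodic nearest image within cutoff) or
#'   \code{"ewald"} (classic Ewald summation, see [ewald_energy()]).
#' @param cutoff real-space cutoff in nm (minimum_image and ewald).
#' @param charges optional charge vector overriding the topology
#'   charges (used by the charge-zeroing decomposition).
#' @param ewald list of Ewald parameters passed to [ewald_params()]
#'   (\code{accuracy}, optionally \code{alpha}, \code{kmax}).
#' @return energy in kJ/mol; excluded (1-2/1-3/1-4) pairs contribute
#'   nothing.
#' @export
coulomb_energy <- function(frame, topology,
                           method = c("minimum_image", "direct", "ewald"),
                           cutoff = 0.9, charges = NULL,
                           ewald = list()) {
  method <- match.arg(method)
  x <- frame$coords
  if (nrow(x) != topology$n_atoms)
    stop("frame atom count does not match topology")
  q <- charges %||% topology$atoms$charge
  if (length(q) != nrow(x)) stop("charge vector length mismatch")
  if (all(q == 0)) return(0)
  if (method == "ewald") {
    if (is.null(frame$box)) stop("ewald requires a periodic box")
    par <- do.call(ewald_params,
                   c(list(box = frame$box, cutoff = cutoff), ewald))
    return(ewald_energy(x, q, frame$box, topology$exclusions, par))
  }
  box <- if (method == "minimum_image") {
    if (is.null(frame$box)) stop("minimum_image requires a periodic box")
    frame$box
  } else NULL
  .check_cutoff(cutoff, box)
  d2 <- pair_dist2(x, box)
  mask <- upper.tri(d2) & !exclusion_matrix(topology)
  qq <- outer(q, q)
  live <- mask & qq != 0
  if (method == "minimum_image") live <- live & d2 <= cutoff^2
  if (any(live & d2 < 1e-12))
    stop("overlapping charged atoms (r < 1e-6 nm)")
  if (!any(live)) return(0)
  md_constants$k_coulomb * sum(qq[live] / sqrt(d2[live]))
}

#' Bonded energies of a configuration
#'
#' Harmonic bonds \code{0.5 k (r - r0)^2}, harmonic angles
#' \code{0.5 ka (theta - theta0)^2} and periodic dihedrals
#' \code{kd (1 + cos(n phi - phi0))}.  Displacements use the minimum
#' image so molecules may be stored wrapped.
#'
#' @param frame an [md_frame()].
#' @param topology a [system_topology()].
#' @return list with \code{e_bond}, \code{e_angle}, \code{e_dih}
#'   (kJ/mol).
#' @export
bonded_energy <- function(frame, topology) {
  x <- frame$coords
  box <- frame$box
  e_bond <- e_angle <- e_dih <- 0
  offset <- 0L
  disp <- function(i, j) {
    d <- x[j, , drop = FALSE] - x[i, , drop = FALSE]
    min_image(d, box)
  }
  for (sp in topology$species) {
    mol <- sp$molecule
    na <- nrow(mol$atoms)
    for (inst in seq_len(as.integer(sp$count %||% 1L))) {
      o <- offset
      if (!is.null(mol$bonds)) for (r in seq_len(nrow(mol$bonds))) {
        b <- mol$bonds[r, ]
        d <- disp(o + b$i, o + b$j)
        rij <- sqrt(sum(d * d))
        e_bond <- e_bond + 0.5 * b$k * (rij - b$r0)^2
      }
      if (!is.null(mol$angles)) for (r in seq_len(nrow(mol$angles))) {
        a <- mol$angles[r, ]
        u <- disp(o + a$j, o + a$i)
        v <- disp(o + a$j, o + a$k)
        if (sum(u * u) < 1e-24 || sum(v * v) < 1e-24)
          stop("zero-length bond vector in angle evaluation")
        cosang <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
        theta <- acos(pmin(1, pmax(-1, cosang)))
        e_angle <- e_angle + 0.5 * a$ka * (theta - a$theta0)^2
      }
      if (!is.null(mol$dihedrals)) for (r in seq_len(nrow(mol$dihedrals))) {
        dh <- mol$dihedrals[r, ]
        b1 <- disp(o + dh$i, o + dh$j)
        b2 <- disp(o + dh$j, o + dh$k)
        b3 <- disp(o + dh$k, o + dh$l)
        n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
                b1[3] * b2[1] - b1[1] * b2[3],
                b1[1] * b2[2] - b1[2] * b2[1])
        n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
                b2[3] * b3[1] - b2[1] * b3[3],
                b2[1] * b3[2] - b2[2] * b3[1])
        if (sum(n1 * n1) < 1e-24 || sum(n2 * n2) < 1e-24)
          stop("zero-length bond vector in dihedral evaluation")
        m1 <- sqrt(sum(b2 * b2))
        phi <- atan2(sum(b1 * n2) * m1, sum(n1 * n2))
        e_dih <- e_dih + dh$kd * (1 + cos(dh$n * phi - dh$phi0))
      }
      offset <- offset + na
    }
  }
  list(e_bond = e_bond, e_angle = e_angle, e_dih = e_dih)
}

# Scaled 1-4 contributions (Amber convention: Coulomb / 1.2, LJ / 2),
# evaluated with plain pair formulas under minimum image.
scaled_14_energy <- function(frame, topology) {
  p14 <- pairs_14(topology)
  if (!nrow(p14)) return(list(lj = 0, coul = 0))
  x <- frame$coords
  d <- min_image(x[p14[, 2], , drop = FALSE] - x[p14[, 1], , drop = FALSE],
                 frame$box)
  r2 <- rowSums(d * d)
  at <- topology$atoms
  sij <- (at$sigma[p14[, 1]] + at$sigma[p14[, 2]]) / 2
  eij <- sqrt(at$epsilon[p14[, 1]] * at$epsilon[p14[, 2]])
  sr6 <- ifelse(eij > 0, (sij^2 / r2)^3, 0)
  lj <- sum(4 * eij * (sr6 * sr6 - sr6)) / 2
  qq <- at$charge[p14[, 1]] * at$charge[p14[, 2]]
  coul <- md_constants$k_coulomb * sum(qq / sqrt(r2)) / 1.2
  list(lj = lj, coul = coul)
}

#' Full energy breakdown of a configuration
#'
#' Assembles the classical force-field decomposition
#' \code{e_tot = e_bond + e_angle + e_dih + e_lj + e_coul}.  In the
#' breakdown, \code{e_lj} and \code{e_coul} include the scaled 1-4
#' contributions so that the total is additive, whereas \code{e_nb}
#' is the sum of LJ and Coulomb over non-excluded pairs only, with 1-4
#' interactions excluded entirely.
#'
#' @param frame an [md_frame()].
#' @param topology a [system_topology()].
#' @param method Coulomb method, see [coulomb_energy()].
#' @param cutoff non-bonded cutoff, nm.
#' @param tail_correction logical, see [lj_energy()].
#' @param ewald Ewald parameter list, see [coulomb_energy()].
#' @return an object of class \code{energy_breakdown}: list with
#'   \code{e_bond}, \code{e_angle}, \code{e_dih}, \code{e_lj},
#'   \code{e_coul}, \code{e_nb}, \code{e_tot} (kJ/mol) and
#'   \code{method}.
#' @export
total_energy <- function(frame, topology,
                         method = c("minimum_image", "direct", "ewald"),
                         cutoff = 0.9, tail_correction = FALSE,
                         ewald = list()) {
  method <- match.arg(method)
  bonded <- bonded_energy(frame, topology)
  e_lj_nb <- lj_energy(frame, topology, cutoff = cutoff,
                       tail_correction = tail_correction)
  e_coul_nb <- coulomb_energy(frame, topology, method = method,
                              cutoff = cutoff, ewald = ewald)
  s14 <- scaled_14_energy(frame, topology)
  e_lj <- e_lj_nb + s14$lj
  e_coul <- e_coul_nb + s14$coul
  structure(list(
    e_bond = bonded$e_bond, e_angle = bonded$e_angle,
    e_dih = bonded$e_dih, e_lj = e_lj, e_coul = e_coul,
    e_nb = e_lj_nb + e_coul_nb,
    e_tot = bonded$e_bond + bonded$e_angle + bonded$e_dih + e_lj + e_coul,
    method = method), class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(paste0("energy breakdown (%s Coulomb), kJ/mol:\n",
                     "  bond %12.4f  angle %12.4f  dihedral %12.4f\n",
                     "  LJ   %12.4f  Coul  %12.4f\n",
                     "  e_nb %12.4f  e_tot %12.4f\n"),
              x$method, x$e_bond, x$e_angle, x$e_dih, x$e_lj, x$e_coul,
              x$e_nb, x$e_tot))
  invisible(x)
}
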