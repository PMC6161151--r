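# Synthetic-trajectory generators.  They stand in for MD production
# runs: statistically exact samples (independent Gaussian draws rather
# than integrated dynamics) with known ground truth, so parameter
# recovery tests carry no integrator error.  All generators are
# deterministic under a fixed seed and leave the caller's RNG state
# untouched.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

# Single-atom "molecule" used by the Brownian generator.
point_molecule <- function(name = "PT", element = "C", mass = 1) {
  molecule_topology(name, data.frame(
    name = element, element = element, mass = mass, charge = 0,
    sigma = 0, epsilon = 0))
}

#' Brownian point-molecule trajectory with known diffusion coefficient
#'
#' Independent Gaussian steps with per-axis variance \code{2 D_in dt},
#' sampled exactly (no integrator).  Coordinates are stored unwrapped;
#' the box is attached for I/O plumbing only.  Defaults mirror a
#' typical blend: 95 API-like molecules, frames every 2 ps and a
#' diffusion coefficient of 1e-10 cm^2/s (1e-8 nm^2/ps).
#'
#' @param n_mol number of molecules.
#' @param D_in input diffusion coefficient, nm^2/ps (>= 0; 0 gives a
#'   static trajectory).
#' @param dt frame spacing, ps.
#' @param n_frames number of frames (>= 2).
#' @param box box edges, nm.
#' @param seed RNG seed.
#' @return list with \code{topology} and \code{traj}, plus the input
#'   \code{D_in} converted to 1e-10 cm^2/s in \code{D_in_1e10}.
#' @export
gen_brownian <- function(n_mol = 95L, D_in = 1e-8, dt = 2, n_frames = 1e4L,
                         box = c(6, 6, 6), seed = 1L) {
  if (D_in < 0) stop("D_in must be >= 0")
  stopifnot_scalar_number(dt, "dt", positive = TRUE)
  if (n_frames < 2L) stop("n_frames must be >= 2")
  top <- system_topology(list(list(molecule = point_molecule(),
                                   count = n_mol, role = "api")))
  coords <- with_seed(seed, {
    x0 <- matrix(stats::runif(n_mol * 3), n_mol, 3L) %*% diag(box)
    steps <- array(stats::rnorm((n_frames - 1L) * n_mol * 3L,
                                sd = sqrt(2 * D_in * dt)),
                   c(n_frames - 1L, n_mol, 3L))
    out <- array(0, c(n_frames, n_mol, 3L))
    for (k in 1:3) {
      sk <- matrix(steps[, , k], nrow = n_frames - 1L)
      cs <- apply(sk, 2L, cumsum)
      if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1L)
      out[, , k] <- rbind(x0[, k], sweep(cs, 2L, x0[, k], "+"))
    }
    out
  })
  list(topology = top,
       traj = md_trajectory(coords, dt = dt, box = box, wrapped = FALSE),
       D_in_1e10 = D_in * md_constants$nm2_ps_to_1e10_cm2_s)
}

#' Harmonic-well trajectory with known fluctuation amplitude
#'
#' Atoms sampled independently Gaussian around fixed sites so that the
#' fluctuation about each atom's mean position in the molecule's
#' center-of-mass frame has per-axis variance \code{kT / k}
#' (equipartition in an isotropic harmonic well): the expected
#' per-atom RMSF after COM removal is exactly \code{sqrt(3 kT / k)}.
#' Because subtracting the COM of \code{n} equal-mass i.i.d. atoms
#' shrinks the per-atom variance by \code{(1 - 1/n)}, the raw draws
#' use variance \code{kT / k / (1 - 1/n)} (for \code{n = 1} the COM
#' frame is degenerate and the RMSF is 0 by construction).  An
#' optional uniform drift translates every frame to verify that
#' per-molecule center-of-mass removal kills translation.
#'
#' @param n_atoms_per_mol atoms per molecule.
#' @param n_mol number of molecules.
#' @param k isotropic spring constant, kJ/mol/nm^2 (> 0).
#' @param kT thermal energy, kJ/mol.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param drift constant drift velocity, nm/frame (length 1 or 3).
#' @return list with \code{topology}, \code{traj} and the expected
#'   per-atom fluctuation \code{rmsf_expected} (nm).
#' @export
gen_harmonic <- function(n_atoms_per_mol = 5L, n_mol = 10L, k = 2500,
                         kT = 2.494, n_frames = 1e4L, seed = 1L,
                         drift = 0) {
  if (k <= 0) stop("spring constant k must be > 0")
  if (kT < 0) stop("kT must be >= 0")
  mol <- molecule_topology("HRM", data.frame(
    name = paste0("C", seq_len(n_atoms_per_mol)),
    element = "C", mass = 12.011, charge = 0, sigma = 0, epsilon = 0))
  top <- system_topology(list(list(molecule = mol, count = n_mol,
                                   role = "api")))
  n <- top$n_atoms
  drift <- rep(drift, length.out = 3L)
  coords <- with_seed(seed, {
    # fixed sites: molecules 2 nm apart, atoms 0.3 nm apart in a row
    sites <- matrix(0, n, 3L)
    idx <- 1L
    for (m in seq_len(n_mol)) for (a in seq_len(n_atoms_per_mol)) {
      sites[idx, ] <- c(2 * (m - 1L), 0.3 * (a - 1L), 0)
      idx <- idx + 1L
    }
    sd <- if (n_atoms_per_mol > 1L)
      sqrt(kT / k / (1 - 1 / n_atoms_per_mol)) else sqrt(kT / k)
    out <- array(stats::rnorm(n_frames * n * 3L, sd = sd),
                 c(n_frames, n, 3L))
    for (kk in 1:3)
      out[, , kk] <- out[, , kk] +
        matrix(sites[, kk], n_frames, n, byrow = TRUE) +
        (seq_len(n_frames) - 1L) * drift[kk]
    out
  })
  list(topology = top,
       traj = md_trajectory(coords, dt = 1, wrapped = FALSE),
       rmsf_expected = sqrt(3 * kT / k))
}

#' Hydrogen-bond geometry fixture
#'
#' Places one O-H donor / O acceptor triple per requested geometry at
#' exactly the stated donor-acceptor distance and H-donor-acceptor
#' angle, with successive triples 3 nm apart so they cannot
#' cross-react.  Donor molecules carry role \code{"api"}, acceptors
#' role \code{"polymer"}.
#'
#' @param geometries data.frame with columns \code{distance} (nm) and
#'   \code{angle} (degrees).
#' @return list with \code{topology} and \code{frame}.
#' @export
gen_hbond_fixture <- function(geometries) {
  geometries <- as.data.frame(geometries)
  if (!nrow(geometries)) stop("no geometries given")
  if (any(geometries$distance < 0.1))
    stop("donor-acceptor distance below the covalent O-H length")
  donor <- molecule_topology("DON", data.frame(
    name = c("OD", "HD"), element = c("O", "H"),
    mass = c(15.999, 1.008), charge = 0, sigma = 0, epsilon = 0),
    bonds = data.frame(i = 1L, j = 2L, r0 = 0.1, k = 3e5))
  accep <- molecule_topology("ACC", data.frame(
    name = "OA", element = "O", mass = 15.999, charge = 0,
    sigma = 0, epsilon = 0))
  n <- nrow(geometries)
  top <- system_topology(list(
    list(molecule = donor, count = n, role = "api"),
    list(molecule = accep, count = n, role = "polymer")))
  coords <- matrix(0, 2L * n + n, 3L)
  for (e in seq_len(n)) {
    origin <- c(0, 0, 3 * (e - 1L))
    a <- geometries$angle[e] * pi / 180
    d <- geometries$distance[e]
    coords[2L * e - 1L, ] <- origin                       # donor O
    coords[2L * e, ] <- origin + c(0.1, 0, 0)             # H along +x
    coords[2L * n + e, ] <- origin + d * c(cos(a), sin(a), 0)
  }
  list(topology = top, frame = md_frame(coords, wrapped = FALSE))
}

# Toy API: C-O-H with a strong hydroxyl donor.  charge_scale 0 gives a
# nonpolar variant.
toy_api_molecule <- function(charge_scale = 1) {
  molecule_topology("API", data.frame(
    name = c("C1", "O1", "H1"), element = c("C", "O", "H"),
    mass = c(12.011, 15.999, 1.008),
    charge = charge_scale * c(0, -0.45, 0.45),
    sigma = c(0.34, 0.30, 0.10), epsilon = c(0.36, 0.65, 0.06)),
    bonds = data.frame(i = c(1L, 2L), j = c(2L, 3L),
                       r0 = c(0.14, 0.10), k = 2.5e5))
}

# Toy acceptor-only polymer: a chain of C=O monomers (no donor H).
toy_polymer_molecule <- function(monomers = 6L, charge_scale = 1) {
  atoms <- do.call(rbind, lapply(seq_len(monomers), function(m)
    data.frame(name = c(paste0("C", m), paste0("O", m)),
               element = c("C", "O"), mass = c(12.011, 15.999),
               charge = charge_scale * c(0.45, -0.45),
               sigma = c(0.34, 0.30), epsilon = c(0.36, 0.65))))
  bonds <- data.frame(i = 2L * seq_len(monomers) - 1L,
                      j = 2L * seq_len(monomers), r0 = 0.122, k = 4e5)
  if (monomers > 1L)
    bonds <- rbind(bonds, data.frame(
      i = 2L * seq_len(monomers - 1L) - 1L,
      j = 2L * seq_len(monomers - 1L) + 1L, r0 = 0.15, k = 2.5e5))
  molecule_topology("POL", atoms, bonds = bonds)
}

#' Toy blend with replicates
#'
#' A small periodic blend of donor-bearing "API" molecules and an
#' acceptor-only "polymer", hand-packed so that every API donor points
#' at a polymer carbonyl oxygen at hydrogen-bond geometry (0.28 nm,
#' collinear).  Four replicate trajectories jitter the packed
#' configuration with independent Gaussian noise, mimicking the
#' replicate structure of production simulations, so every descriptor
#' (energies, H-bonds, mobility, replicate spread) is computable end
#' to end.
#'
#' @param n_api number of API molecules (placed one per polymer
#'   carbonyl; at most \code{n_chains * monomers_per_chain}).
#' @param n_chains number of polymer chains.
#' @param monomers_per_chain monomers per chain.
#' @param charge_pattern \code{"hbonding"} (donor API + acceptor-only
#'   polymer) or \code{"zero"} (all charges zero).
#' @param n_frames frames per replicate.
#' @param n_replicates number of replicate trajectories.
#' @param jitter per-frame Gaussian jitter sd, nm.
#' @param box box edges, nm; must accommodate the packed layout.
#' @param seed base RNG seed (replicate r uses seed + r - 1).
#' @return list with \code{topology}, \code{replicates} (list of
#'   [md_trajectory()]) and \code{base_frame}.
#' @export
gen_toy_blend <- function(n_api = 6L, n_chains = 2L,
                          monomers_per_chain = 6L,
                          charge_pattern = c("hbonding", "zero"),
                          n_frames = 20L, n_replicates = 4L,
                          jitter = 0.004, box = NULL, seed = 1L) {
  charge_pattern <- match.arg(charge_pattern)
  cs <- if (charge_pattern == "zero") 0 else 1
  if (n_api > n_chains * monomers_per_chain)
    stop("more API molecules than polymer carbonyl sites")
  api <- toy_api_molecule(cs)
  pol <- toy_polymer_molecule(monomers_per_chain, cs)
  top <- system_topology(list(
    list(molecule = api, count = n_api, role = "api"),
    list(molecule = pol, count = n_chains, role = "polymer")))
  need <- c(0.3 * monomers_per_chain + 1.2, 1.4 * n_chains + 1.2, 2.0)
  box <- box %||% pmax(need, 2.0)
  if (any(box < need))
    stop("box too small for the packed blend layout")
  coords <- matrix(0, top$n_atoms, 3L)
  # APIs first (atom order follows topology: all APIs, then chains)
  site_of <- function(i) {   # carbonyl site i -> (chain, monomer)
    c(chain = (i - 1L) %/% monomers_per_chain + 1L,
      mon = (i - 1L) %% monomers_per_chain + 1L)
  }
  chain_y <- function(c) 1.4 * (c - 1L) + 0.6
  z0 <- 1.0
  idx <- 1L
  for (i in seq_len(n_api)) {
    s <- site_of(i)
    xm <- 0.3 * (s["mon"] - 1L) + 0.6
    yO <- chain_y(s["chain"]) + 0.122          # polymer O height
    # donor O 0.28 nm above the acceptor O, H collinear in between
    coords[idx, ]      <- c(xm, yO + 0.28 + 0.14, z0)   # C1
    coords[idx + 1L, ] <- c(xm, yO + 0.28, z0)          # O1 (donor)
    coords[idx + 2L, ] <- c(xm, yO + 0.18, z0)          # H1
    idx <- idx + 3L
  }
  for (c in seq_len(n_chains)) {
    yc <- chain_y(c)
    for (m in seq_len(monomers_per_chain)) {
      xm <- 0.3 * (m - 1L) + 0.6
      coords[idx, ]      <- c(xm, yc, z0)               # C
      coords[idx + 1L, ] <- c(xm, yc + 0.122, z0)       # O
      idx <- idx + 2L
    }
  }
  base <- md_frame(coords, box = box, wrapped = FALSE)
  replicates <- lapply(seq_len(n_replicates), function(r) {
    arr <- with_seed(seed + r - 1L, {
      array(stats::rnorm(n_frames * top$n_atoms * 3L, sd = jitter),
            c(n_frames, top$n_atoms, 3L))
    })
    for (k in 1:3) arr[, , k] <- arr[, , k] +
        matrix(coords[, k], n_frames, top$n_atoms, byrow = TRUE)
    md_trajectory(arr, dt = 2, box = box, wrapped = FALSE)
  })
  list(topology = top, replicates = replicates, base_frame = base)
}

#' Pure-phase toy system
#'
#' Molecules of one toy species placed far apart (sparse grid), so the
#' pure phase has no intermolecular hydrogen bonds; used as the pure
#' amorphous reference for mixing and dNHB tests.
#'
#' @param kind \code{"api"} or \code{"polymer"}.
#' @param n number of molecules.
#' @param monomers_per_chain monomers per chain (polymer kind).
#' @param charge_pattern as in [gen_toy_blend()].
#' @param n_frames,n_replicates,jitter,seed as in [gen_toy_blend()].
#' @return list with \code{topology}, \code{replicates},
#'   \code{base_frame}.
#' @export
gen_toy_pure <- function(kind = c("api", "polymer"), n = 6L,
                         monomers_per_chain = 6L,
                         charge_pattern = c("hbonding", "zero"),
                         n_frames = 20L, n_replicates = 4L,
                         jitter = 0.004, seed = 1L) {
  kind <- match.arg(kind)
  charge_pattern <- match.arg(charge_pattern)
  cs <- if (charge_pattern == "zero") 0 else 1
  mol <- if (kind == "api") toy_api_molecule(cs)
         else toy_polymer_molecule(monomers_per_chain, cs)
  top <- system_topology(list(list(molecule = mol, count = n,
                                   role = kind)))
  span <- if (kind == "api") 0.5 else 0.3 * monomers_per_chain
  spacing <- span + 2.0
  box <- c(spacing * n, spacing, spacing) + 2.0
  coords <- matrix(0, top$n_atoms, 3L)
  na <- nrow(mol$atoms)
  for (m in seq_len(n)) {
    o <- c(spacing * (m - 1L) + 1.0, 1.0, 1.0)
    if (kind == "api") {
      coords[(m - 1L) * na + 1L, ] <- o + c(0.26, 0, 0)
      coords[(m - 1L) * na + 2L, ] <- o + c(0.12, 0, 0)
      coords[(m - 1L) * na + 3L, ] <- o + c(0.02, 0, 0)
    } else {
      for (mm in seq_len(monomers_per_chain)) {
        coords[(m - 1L) * na + 2L * mm - 1L, ] <- o + c(0.3 * (mm - 1L), 0, 0)
        coords[(m - 1L) * na + 2L * mm, ] <- o + c(0.3 * (mm - 1L), 0.122, 0)
      }
    }
  }
  base <- md_frame(coords, box = box, wrapped = FALSE)
  replicates <- lapply(seq_len(n_replicates), function(r) {
    arr <- with_seed(seed + 100L + r - 1L, {
      array(stats::rnorm(n_frames * top$n_atoms * 3L, sd = jitter),
            c(n_frames, top$n_atoms, 3L))
    })
    for (k in 1:3) arr[, , k] <- arr[, , k] +
        matrix(coords[, k], n_frames, top$n_atoms, byrow = TRUE)
    md_trajectory(arr, dt = 2, box = box, wrapped = FALSE)
  })
  list(topology = top, replicates = replicates, base_frame = base)
}

#' Rock-salt ionic lattice fixture
#'
#' A cubic lattice of alternating +1/-1 point charges (each ion its
#' own molecule), the classic Madelung benchmark for Ewald summation:
#' the exact energy per ion pair is \code{-alpha_M k_e / r_nn} with
#' Madelung constant \code{alpha_M = 1.747565} and nearest-neighbour
#' distance \code{r_nn}.
#'
#' @param n sites per axis (even, so the lattice is neutral).
#' @param spacing nearest-neighbour distance, nm.
#' @return list with \code{topology}, \code{frame}, \code{n_ions}.
#' @export
gen_rocksalt <- function(n = 4L, spacing = 0.28) {
  if (n %% 2L != 0L) stop("n must be even for a neutral lattice")
  grid <- as.matrix(expand.grid(0:(n - 1L), 0:(n - 1L), 0:(n - 1L)))
  sgn <- (-1)^rowSums(grid)
  plus <- molecule_topology("ION+", data.frame(
    name = "NA", element = "Na", mass = 22.99, charge = 1,
    sigma = 0, epsilon = 0))
  minus <- molecule_topology("ION-", data.frame(
    name = "CL", element = "Cl", mass = 35.45, charge = -1,
    sigma = 0, epsilon = 0))
  ord <- order(-sgn)   # all +1 ions first, then -1
  top <- system_topology(list(
    list(molecule = plus, count = sum(sgn > 0), role = "other"),
    list(molecule = minus, count = sum(sgn < 0), role = "other")))
  coords <- grid[ord, , drop = FALSE] * spacing
  list(topology = top,
       frame = md_frame(coords, box = rep(n * spacing, 3L),
                        wrapped = TRUE),
       n_ions = n^3)
}

#' Random charged multi-molecule configuration
#'
#' Molecules with random internal geometry and zero-sum random partial
#' charges placed on a jittered grid; used to exercise the
#' charge-zeroing decomposition against brute-force cross-molecule
#' pair summation.
#'
#' @param n_mol number of molecules.
#' @param atoms_per_mol atoms per molecule.
#' @param seed RNG seed.
#' @param lj logical: also draw LJ parameters (otherwise 0).
#' @return list with \code{topology} and \code{frame} (periodic box).
#' @export
gen_random_charged <- function(n_mol = 10L, atoms_per_mol = 5L,
                               seed = 1L, lj = FALSE) {
  per_side <- ceiling(n_mol^(1 / 3))
  spacing <- 0.8
  box <- rep(per_side * spacing + 1.9, 3L)
  with_seed(seed, {
    species <- lapply(seq_len(n_mol), function(m) {
      q <- stats::rnorm(atoms_per_mol, sd = 0.3)
      q <- q - mean(q)
      mol <- molecule_topology(paste0("RND", m), data.frame(
        name = paste0("A", seq_len(atoms_per_mol)), element = "C",
        mass = 12.011, charge = q,
        sigma = if (lj) stats::runif(atoms_per_mol, 0.25, 0.35) else 0,
        epsilon = if (lj) stats::runif(atoms_per_mol, 0.2, 0.8) else 0),
        bonds = if (atoms_per_mol > 1L)
          data.frame(i = seq_len(atoms_per_mol - 1L),
                     j = seq_len(atoms_per_mol - 1L) + 1L,
                     r0 = 0.15, k = 2.5e5) else NULL)
      list(molecule = mol, count = 1L,
           role = if (m %% 2L) "api" else "polymer")
    })
    top <- system_topology(species)
    coords <- matrix(0, top$n_atoms, 3L)
    idx <- 1L
    for (m in seq_len(n_mol)) {
      cell <- c((m - 1L) %% per_side,
                ((m - 1L) %/% per_side) %% per_side,
                (m - 1L) %/% per_side^2)
      center <- cell * spacing + 0.5 + stats::runif(3, -0.05, 0.05)
      for (a in seq_len(atoms_per_mol)) {
        coords[idx, ] <- center + 0.15 * (a - (atoms_per_mol + 1) / 2) *
          c(1, 0, 0) + stats::rnorm(3, sd = 0.02)
        idx <- idx + 1L
      }
    }
    list(topology = top, frame = md_frame(coords, box = box,
                                          wrapped = FALSE))
  })
}
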