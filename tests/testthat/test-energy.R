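test_that("LJ pair energy has the textbook zero crossing and minimum", {
  p <- pair_system(r = 0.3, sigma = 0.3, epsilon = 0.5)
  expect_equal(lj_energy(p$frame, p$topology, cutoff = Inf), 0,
               tolerance = 1e-12)
  p <- pair_system(r = 2^(1 / 6) * 0.3, sigma = 0.3, epsilon = 0.5)
  expect_equal(lj_energy(p$frame, p$topology, cutoff = Inf), -0.5,
               tolerance = 1e-12)
})

test_that("periodic LJ lattice energy equals the brute-force all-image sum", {
  # 4x4x4 cubic lattice of identical LJ atoms
  a <- 0.4
  grid <- as.matrix(expand.grid(0:3, 0:3, 0:3)) * a
  box <- rep(4 * a, 3)
  mol <- molecule_topology("LJ", data.frame(
    name = "A", element = "Ar", mass = 40, charge = 0,
    sigma = 0.34, epsilon = 0.997))
  top <- system_topology(list(list(molecule = mol, count = 64,
                                   role = "other")))
  fr <- md_frame(grid, box = box, wrapped = TRUE)
  e_pkg <- lj_energy(fr, top, cutoff = 0.79)
  e_bf <- bf_lj(grid, box, rep(0.34, 64), rep(0.997, 64), cutoff = 0.79)
  expect_equal(e_pkg, e_bf, tolerance = 1e-10)
})

test_that("LJ cutoff validation and dispersion tail correction behave", {
  p <- pair_system(r = 0.3, box = c(2, 2, 2))
  expect_error(lj_energy(p$frame, p$topology, cutoff = 1.5),
               "half the smallest box edge")
  e0 <- lj_energy(p$frame, p$topology, cutoff = 0.9)
  et <- lj_energy(p$frame, p$topology, cutoff = 0.9,
                  tail_correction = TRUE)
  expect_lt(et, e0)  # tail strictly negative for attractive systems
})

test_that("direct Coulomb reproduces the Coulomb constant and zero-charge limit", {
  p <- pair_system(r = 1.0, q = c(1, -1))
  expect_equal(coulomb_energy(p$frame, p$topology, method = "direct"),
               -138.935458, tolerance = 1e-9)
  p0 <- pair_system(r = 1.0, q = c(0, 0))
  for (m in c("direct", "minimum_image"))
    expect_identical(coulomb_energy(p0$frame, p0$topology, method = m,
                                    cutoff = Inf), 0)
  # overlap guard
  bad <- pair_system(r = 1e-8, q = c(1, -1))
  expect_error(coulomb_energy(bad$frame, bad$topology, method = "direct"),
               "overlapping")
})

test_that("bonded terms evaluate their closed forms", {
  mol <- molecule_topology("B", data.frame(
    name = c("A", "B"), element = "C", mass = 12, charge = 0,
    sigma = 0, epsilon = 0),
    bonds = data.frame(i = 1, j = 2, r0 = 0.15, k = 1000))
  top <- system_topology(list(list(molecule = mol, count = 1,
                                   role = "other")))
  at_r0 <- md_frame(rbind(c(0, 0, 0), c(0.15, 0, 0)))
  expect_equal(bonded_energy(at_r0, top)$e_bond, 0, tolerance = 1e-12)
  displaced <- md_frame(rbind(c(0, 0, 0), c(0.17, 0, 0)))
  expect_equal(bonded_energy(displaced, top)$e_bond,
               0.5 * 1000 * 0.02^2, tolerance = 1e-10)

  # angle at theta0 and displaced
  mol3 <- molecule_topology("A3", data.frame(
    name = c("A", "B", "C"), element = "C", mass = 12, charge = 0,
    sigma = 0, epsilon = 0),
    bonds = data.frame(i = 1:2, j = 2:3, r0 = 0.15, k = 1000),
    angles = data.frame(i = 1, j = 2, k = 3, theta0 = pi / 2, ka = 500))
  top3 <- system_topology(list(list(molecule = mol3, count = 1,
                                    role = "other")))
  right <- md_frame(rbind(c(0.15, 0, 0), c(0, 0, 0), c(0, 0.15, 0)))
  expect_equal(bonded_energy(right, top3)$e_angle, 0, tolerance = 1e-12)
  straight <- md_frame(rbind(c(-0.15, 0, 0), c(0, 0, 0), c(0.15, 0, 0)))
  expect_equal(bonded_energy(straight, top3)$e_angle,
               0.5 * 500 * (pi / 2)^2, tolerance = 1e-10)

  # dihedral at phi = phi0 with n = 1 gives 2 kd (cosine term = 1)
  mol4 <- molecule_topology("D4", data.frame(
    name = LETTERS[1:4], element = "C", mass = 12, charge = 0,
    sigma = 0, epsilon = 0),
    bonds = data.frame(i = 1:3, j = 2:4, r0 = 0.15, k = 1000),
    dihedrals = data.frame(i = 1, j = 2, k = 3, l = 4, n = 1,
                           phi0 = 0, kd = 3))
  top4 <- system_topology(list(list(molecule = mol4, count = 1,
                                    role = "other")))
  cis <- md_frame(rbind(c(0.15, 0.15, 0), c(0.15, 0, 0),
                        c(0.3, 0, 0), c(0.3, 0.15, 0)))
  expect_equal(bonded_energy(cis, top4)$e_dih, 2 * 3, tolerance = 1e-9)
  trans <- md_frame(rbind(c(0.15, 0.15, 0), c(0.15, 0, 0),
                          c(0.3, 0, 0), c(0.3, -0.15, 0)))
  expect_equal(bonded_energy(trans, top4)$e_dih, 0, tolerance = 1e-9)
})

test_that("total energy is additive and matches a naive double-loop oracle", {
  g <- gen_random_charged(8, 4, seed = 21, lj = TRUE)
  br <- total_energy(g$frame, g$topology, method = "direct", cutoff = Inf)
  expect_equal(br$e_tot,
               br$e_bond + br$e_angle + br$e_dih + br$e_lj + br$e_coul,
               tolerance = 1e-9)
  # naive non-bonded oracle: all non-excluded pairs, no cutoff, plus
  # scaled 1-4 terms; compare to e_lj + e_coul of the breakdown
  at <- g$topology$atoms
  x <- g$frame$coords
  ex <- g$topology$exclusions
  excl_level <- matrix(0L, nrow(x), nrow(x))
  excl_level[as.matrix(ex[c("i", "j")])] <- ex$sep
  excl_level[as.matrix(ex[c("j", "i")])] <- ex$sep
  ke <- md_constants$k_coulomb
  e_lj <- e_coul <- 0
  for (i in 1:(nrow(x) - 1)) for (j in (i + 1):nrow(x)) {
    lev <- excl_level[i, j]
    if (lev %in% c(1L, 2L)) next
    r <- sqrt(sum((x[i, ] - x[j, ])^2))
    sij <- (at$sigma[i] + at$sigma[j]) / 2
    eij <- sqrt(at$epsilon[i] * at$epsilon[j])
    sr6 <- (sij / r)^6
    lj <- 4 * eij * (sr6^2 - sr6)
    cl <- ke * at$charge[i] * at$charge[j] / r
    if (lev == 3L) { lj <- lj / 2; cl <- cl / 1.2 }
    e_lj <- e_lj + lj
    e_coul <- e_coul + cl
  }
  expect_equal(br$e_lj, e_lj, tolerance = 1e-8)
  expect_equal(br$e_coul, e_coul, tolerance = 1e-8)
  # e_nb excludes the 1-4 terms entirely
  expect_equal(br$e_nb,
               lj_energy(g$frame, g$topology, cutoff = Inf) +
                 coulomb_energy(g$frame, g$topology, method = "direct"),
               tolerance = 1e-9)
})

test_that("energies are invariant under rotation and atom-order permutation", {
  g <- gen_random_charged(6, 4, seed = 31, lj = TRUE)
  fr <- g$frame
  fr$box <- NULL  # non-periodic for free rotation
  e0 <- lj_energy(fr, g$topology, cutoff = Inf) +
    coulomb_energy(fr, g$topology, method = "direct")
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  fr_rot <- md_frame(fr$coords %*% R, wrapped = FALSE)
  e_rot <- lj_energy(fr_rot, g$topology, cutoff = Inf) +
    coulomb_energy(fr_rot, g$topology, method = "direct")
  expect_equal(e_rot, e0, tolerance = 1e-9)

  # permute whole molecules (atom order within the flat table changes
  # consistently with the topology by swapping species order)
  sp <- g$topology$species
  perm <- rev(seq_along(sp))
  top_p <- system_topology(sp[perm])
  n_per <- vapply(sp, function(s) nrow(s$molecule$atoms), 0L)
  starts <- cumsum(c(1L, n_per))[seq_along(sp)]
  idx <- unlist(lapply(perm, function(m) starts[m] + 0:(n_per[m] - 1L)))
  fr_p <- md_frame(fr$coords[idx, ], wrapped = FALSE)
  e_p <- lj_energy(fr_p, top_p, cutoff = Inf) +
    coulomb_energy(fr_p, top_p, method = "direct")
  expect_equal(e_p, e0, tolerance = 1e-9)
})
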