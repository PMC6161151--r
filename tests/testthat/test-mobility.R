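test_that("unwrapping inverts wrapping and is idempotent", {
  b <- gen_brownian(n_mol = 20, D_in = 1e-3, dt = 2, n_frames = 400,
                    box = c(2, 2, 2), seed = 11)
  wrapped <- wrap_trajectory(b$traj)
  unwrapped <- unwrap_trajectory(wrapped)
  # recovery up to a constant per-molecule image offset: first frames
  # must agree after the initial wrap, displacements exactly
  d_orig <- b$traj$coords[400, , ] - b$traj$coords[1, , ]
  d_back <- unwrapped$coords[400, , ] - unwrapped$coords[1, , ]
  expect_lt(max(abs(d_orig - d_back)), 1e-9)
  expect_false(unwrapped$wrapped)
  # idempotence on already-unwrapped input
  again <- unwrap_trajectory(unwrapped)
  expect_identical(again$coords, unwrapped$coords)
})

test_that("a particle crossing the boundary continues monotonically after unwrap", {
  coords <- array(0, c(5, 1, 3))
  coords[, 1, 1] <- c(1.7, 1.9, 0.1, 0.3, 0.5)  # +x crossing in a 2-box
  tr <- md_trajectory(coords, dt = 1, box = c(2, 2, 2), wrapped = TRUE)
  un <- unwrap_trajectory(tr)
  expect_equal(un$coords[, 1, 1], c(1.7, 1.9, 2.1, 2.3, 2.5))
  # too-sparse sampling is refused
  jump <- array(0, c(2, 1, 3))
  jump[, 1, 1] <- c(0, 1)  # half the box in one step
  expect_error(unwrap_trajectory(md_trajectory(jump, dt = 1,
                                               box = c(2, 2, 2),
                                               wrapped = TRUE)),
               "sparse")
})

test_that("MSD vanishes for static input, is quadratic for drift, and requires unwrapped coordinates", {
  coords <- array(0.5, c(50, 4, 3))
  tr <- md_trajectory(coords, dt = 2, wrapped = FALSE)
  top <- system_topology(list(list(molecule = asdstab:::point_molecule(),
                                   count = 4, role = "api")))
  curve <- msd(tr, top, species = "all", n_lags = 20)
  expect_true(all(curve$msd == 0))
  expect_equal(curve$msd[curve$lag == 0], 0)

  # uniform drift v: msd(tau) = (v tau)^2 * 3 for drift on all axes
  v <- 0.01
  drift <- array(rep((0:49) * v * 2, 4 * 3), c(50, 4, 3))
  tr2 <- md_trajectory(drift, dt = 2, wrapped = FALSE)
  curve2 <- msd(tr2, top, species = "all", n_lags = 25,
                origin_stride = 1)
  expect_equal(curve2$msd, 3 * (v * curve2$lag)^2, tolerance = 1e-9)

  wrapped <- md_trajectory(coords, dt = 2, box = c(1, 1, 1),
                           wrapped = TRUE)
  expect_error(msd(wrapped, top, species = "all"), "unwrapped")
  expect_error(msd(md_trajectory(coords[1, , , drop = FALSE], dt = 2,
                                 wrapped = FALSE), top, species = "all"),
               "2 frames")
})

test_that("MSD of Brownian motion recovers the input diffusion coefficient", {
  b <- gen_brownian(n_mol = 80, D_in = 1e-8, dt = 2, n_frames = 3000,
                    seed = 123)
  curve <- msd(b$traj, b$topology, origin_stride = 5, n_lags = 80)
  # diffusive regime: msd ~ 6 D tau throughout
  res <- diffusion_coefficient(curve)
  expect_equal(res$D, b$D_in_1e10, tolerance = 0.15)
  expect_gt(res$r2, 0.99)
})

test_that("diffusion fitting handles exact lines and degenerate input", {
  lag <- seq(0, 100, by = 2)
  exact <- structure(data.frame(lag = lag, msd = 6 * lag,
                                n_origins = 100),
                     class = c("msd_curve", "data.frame"))
  res <- diffusion_coefficient(exact)
  expect_equal(res$D, 1e8, tolerance = 1e-9)  # 1 nm^2/ps in 1e-10 cm^2/s
  expect_equal(res$r2, 1, tolerance = 1e-12)
  flat <- structure(data.frame(lag = lag, msd = 0, n_origins = 100),
                    class = c("msd_curve", "data.frame"))
  expect_equal(diffusion_coefficient(flat)$D, 0)
  down <- structure(data.frame(lag = lag, msd = -0.01 * lag,
                               n_origins = 100),
                    class = c("msd_curve", "data.frame"))
  expect_warning(resd <- diffusion_coefficient(down), "clamping")
  expect_equal(resd$D, 0)
})

test_that("RMSF matches the equipartition value and hand-computed two-frame case", {
  h <- gen_harmonic(n_atoms_per_mol = 5, n_mol = 10, k = 2500,
                    kT = 2.494, n_frames = 5000, seed = 77)
  r <- rmsf(h$traj, h$topology, species = "all")
  expect_equal(r$value, h$rmsf_expected, tolerance = 0.02)

  # two-frame toy: one heavy atom at +-0.1 from its mean after the
  # two-atom COM centering -> fluctuation 0.1 nm
  mol <- molecule_topology("T", data.frame(
    name = c("C1", "C2"), element = "C", mass = 12, charge = 0,
    sigma = 0, epsilon = 0))
  top <- system_topology(list(list(molecule = mol, count = 1,
                                   role = "api")))
  arr <- array(0, c(2, 2, 3))
  arr[1, 1, 1] <- 0.0; arr[1, 2, 1] <- 1.0
  arr[2, 1, 1] <- 0.4; arr[2, 2, 1] <- 1.0   # atom 1 moves +0.4 raw
  tr <- md_trajectory(arr, dt = 1, wrapped = FALSE)
  r2 <- rmsf(tr, top, species = "all")
  # COM moves +0.2, so centered positions change by +-0.1 per atom
  expect_equal(unname(r2$per_atom), c(0.1, 0.1), tolerance = 1e-12)
})

test_that("RMSF ignores translation and drops hydrogen-only molecules", {
  h <- gen_harmonic(n_atoms_per_mol = 4, n_mol = 5, k = 2500,
                    kT = 2.494, n_frames = 2000, seed = 5)
  hd <- gen_harmonic(n_atoms_per_mol = 4, n_mol = 5, k = 2500,
                     kT = 2.494, n_frames = 2000, seed = 5,
                     drift = 0.05)
  r0 <- rmsf(h$traj, h$topology, species = "all")
  r1 <- rmsf(hd$traj, hd$topology, species = "all")
  expect_equal(r1$value, r0$value, tolerance = 1e-9)

  # rigid translating molecule -> zero fluctuation
  mol <- molecule_topology("R", data.frame(
    name = c("C1", "C2"), element = "C", mass = 12, charge = 0,
    sigma = 0, epsilon = 0))
  top <- system_topology(list(list(molecule = mol, count = 1,
                                   role = "api")))
  arr <- array(0, c(10, 2, 3))
  for (f in 1:10) arr[f, , 1] <- c(0, 0.3) + 0.1 * f
  r2 <- rmsf(md_trajectory(arr, dt = 1, wrapped = FALSE), top,
             species = "all")
  expect_equal(r2$value, 0, tolerance = 1e-12)

  hmol <- molecule_topology("H2", data.frame(
    name = c("H1", "H2"), element = "H", mass = 1, charge = 0,
    sigma = 0, epsilon = 0))
  top2 <- system_topology(list(list(molecule = hmol, count = 1,
                                    role = "api")))
  expect_error(expect_warning(
    rmsf(md_trajectory(arr, dt = 1, wrapped = FALSE), top2,
         species = "all"), "no heavy atoms"))
})

test_that("replicate statistics follow the sample-sd convention and ignore order", {
  expect_equal(replicate_stats(c(1, 1, 1, 1)), list(mean = 1, sd = 0,
                                                    n = 4L))
  r <- replicate_stats(c(0, 2, 0, 2))
  expect_equal(r$mean, 1)
  expect_equal(r$sd, sqrt(4 / 3))  # sample sd with n-1 = 3
  expect_equal(replicate_stats(c(2, 0, 2, 0))[c("mean", "sd")],
               r[c("mean", "sd")])
  expect_warning(s1 <- replicate_stats(5), "single replicate")
  expect_true(is.na(s1$sd))
})
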