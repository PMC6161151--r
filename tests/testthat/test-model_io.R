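test_that("GRO read is an identity on a simple file and PDB converts Angstrom to nm", {
  tmp <- tempfile(fileext = ".gro")
  writeLines(c("single atom t= 5.0",
               "    1",
               "    1MOL     C1    1   1.000   2.000   3.000",
               "   4.00000   5.00000   6.00000"), tmp)
  s <- read_structure(tmp)
  expect_equal(unname(s$frame$coords[1, ]), c(1, 2, 3))
  expect_equal(s$frame$box, c(4, 5, 6))
  expect_equal(s$frame$time, 5)

  tmp2 <- tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   40.000   40.000   40.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  C1  MOL A   1      10.000   0.000   5.000  1.00  0.00           C",
    "END"), tmp2)
  p <- read_structure(tmp2)
  expect_equal(unname(p$frame$coords[1, ]), c(1.0, 0.0, 0.5))
  expect_equal(p$frame$box, c(4, 4, 4))
})

test_that("structure round-trips hold at declared precision for all formats", {
  set.seed(42)
  coords <- matrix(runif(30, 0, 3), 10, 3)
  fr <- md_frame(coords, box = c(3, 3, 3), wrapped = FALSE)
  prec <- c(gro = 5e-4, pdb = 5e-5, xyz = 5e-8)
  for (fmt in names(prec)) {
    tmp <- tempfile(fileext = paste0(".", fmt))
    write_structure(fr, tmp, atoms = data.frame(element = rep("C", 10)))
    back <- read_structure(tmp)
    expect_lt(max(abs(back$frame$coords - coords)), prec[[fmt]])
    expect_equal(back$frame$box, c(3, 3, 3), tolerance = 1e-6)
  }
})

test_that("malformed structure files raise parse errors naming the problem", {
  tmp <- tempfile(fileext = ".gro")
  writeLines(c("bad", "    2",
               "    1MOL     C1    1   1.000   xxx     3.000",
               "    1MOL     C2    2   1.000   2.000   3.000",
               "   4.0 4.0 4.0"), tmp)
  expect_error(read_structure(tmp), "line 3")
  tmp2 <- tempfile(fileext = ".gro")
  writeLines(c("truncated", "    3",
               "    1MOL     C1    1   1.000   1.000   3.000"), tmp2)
  expect_error(read_structure(tmp2), "truncated")
  expect_error(read_trajectory(tempfile(fileext = ".xyz")))
})

test_that("trajectory round-trip is lossless within format precision", {
  b <- gen_brownian(n_mol = 5, D_in = 1e-4, dt = 2, n_frames = 50,
                    box = c(3, 3, 3), seed = 9)
  tmp <- tempfile(fileext = ".xyz")
  write_trajectory(b$traj, tmp)
  back <- read_trajectory(tmp)
  expect_equal(n_frames(back), 50)
  expect_lt(max(abs(back$coords - b$traj$coords)), 5e-8)
  expect_equal(back$times, b$traj$times)
  expect_equal(back$box, b$traj$box, tolerance = 1e-6)

  # constant 3-frame trajectory, GRO dialect
  fr <- md_frame(matrix(1, 4, 3), box = c(3, 3, 3))
  tr <- trajectory_from_frames(list(
    md_frame(fr$coords, time = 0, box = fr$box),
    md_frame(fr$coords, time = 2, box = fr$box),
    md_frame(fr$coords, time = 4, box = fr$box)))
  tmp2 <- tempfile(fileext = ".gro")
  write_trajectory(tr, tmp2)
  back2 <- read_trajectory(tmp2)
  expect_equal(back2$coords, tr$coords, tolerance = 1e-9)
})

test_that("inconsistent atom counts across frames are rejected", {
  tmp <- tempfile(fileext = ".xyz")
  writeLines(c("2", "t= 0", "C 0 0 0", "C 1 0 0",
               "1", "t= 2", "C 0 0 0"), tmp)
  expect_error(read_trajectory(tmp), "inconsistent atom count")
  expect_error(trajectory_from_frames(list(
    md_frame(matrix(0, 2, 3)), md_frame(matrix(0, 3, 3)))),
    "inconsistent atom count")
})

test_that("exclusion derivation classifies bonded paths like a BFS oracle", {
  # linear chain A-B-C-D
  chain <- molecule_topology("CH", data.frame(
    name = LETTERS[1:4], element = "C", mass = 12, charge = 0,
    sigma = 0.3, epsilon = 0.3),
    bonds = data.frame(i = 1:3, j = 2:4, r0 = 0.15, k = 1e5))
  e <- chain$exclusions
  expect_equal(e$sep[e$i == 1 & e$j == 2], 1L)
  expect_equal(e$sep[e$i == 1 & e$j == 3], 2L)
  expect_equal(e$sep[e$i == 1 & e$j == 4], 3L)

  # 5-ring: shortest path wins; no pair classified at two separations
  ring <- molecule_topology("RG", data.frame(
    name = LETTERS[1:5], element = "C", mass = 12, charge = 0,
    sigma = 0.3, epsilon = 0.3),
    bonds = data.frame(i = c(1:4, 5), j = c(2:5, 1), r0 = 0.15, k = 1e5))
  expect_false(any(duplicated(ring$exclusions[c("i", "j")])))
  expect_true(all(ring$exclusions$sep <= 2))  # max path in a 5-ring is 2

  set.seed(7)
  for (rep in 1:5) {
    n <- sample(5:9, 1)
    bonds <- data.frame(i = seq_len(n - 1L), j = seq_len(n - 1L) + 1L)
    extra <- sample(n, 2)
    if (abs(diff(extra)) > 1)
      bonds <- rbind(bonds, data.frame(i = min(extra), j = max(extra)))
    bonds$r0 <- 0.15; bonds$k <- 1e5
    mol <- molecule_topology("R", data.frame(
      name = paste0("A", 1:n), element = "C", mass = 12, charge = 0,
      sigma = 0.3, epsilon = 0.3), bonds = bonds)
    expect_same_pairs(mol$exclusions, igraph_path_pairs(n, bonds))
  }
})

test_that("no exclusions cross molecule boundaries and counts are validated", {
  mol <- molecule_topology("M", data.frame(
    name = c("A", "B"), element = "C", mass = 12, charge = 0,
    sigma = 0.3, epsilon = 0.3),
    bonds = data.frame(i = 1, j = 2, r0 = 0.15, k = 1e5))
  top <- system_topology(list(list(molecule = mol, count = 2,
                                   role = "api")))
  ex <- top$exclusions
  m_of <- top$atoms$mol_id
  expect_true(all(m_of[ex$i] == m_of[ex$j]))
  expect_error(molecule_topology("M", data.frame(
    name = "A", element = "C", mass = 12, charge = 0, sigma = 0.3,
    epsilon = 0.3), bonds = data.frame(i = 1, j = 5, r0 = 0.1, k = 1)),
    "dangling")
  expect_error(system_topology(list(list(molecule = mol, count = -1,
                                         role = "api"))), "negative")
})

test_that("topology YAML round-trips including derived donor/acceptor flags", {
  tb <- gen_toy_blend(n_api = 2, n_chains = 1, monomers_per_chain = 3,
                      seed = 1)
  tmp <- tempfile(fileext = ".yaml")
  write_topology(tb$topology, tmp)
  back <- load_topology(tmp)
  expect_equal(back$n_atoms, tb$topology$n_atoms)
  expect_equal(back$atoms$charge, tb$topology$atoms$charge)
  expect_equal(back$atoms$is_donor_h, tb$topology$atoms$is_donor_h)
  expect_same_pairs(back$exclusions, tb$topology$exclusions)
})
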