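# Shared fixtures and independent oracles.

# Two identical single-atom molecules at separation r.
pair_system <- function(r, sigma = 0.3, epsilon = 0.5, q = c(0, 0),
                        box = NULL, element = c("Ar", "Ar")) {
  mols <- lapply(1:2, function(i)
    list(molecule = molecule_topology(paste0("M", i), data.frame(
      name = "A", element = element[i], mass = 1, charge = q[i],
      sigma = sigma, epsilon = epsilon)), count = 1L,
      role = if (i == 1L) "api" else "polymer"))
  list(topology = system_topology(mols),
       frame = md_frame(rbind(c(0, 0, 0), c(r, 0, 0)), box = box,
                        wrapped = FALSE))
}

# Brute-force periodic LJ sum: every pair through every image shift in
# -1..1 within the cutoff.  Independent of the package's minimum-image
# path.
bf_lj <- function(coords, box, sigma, epsilon, cutoff) {
  n <- nrow(coords)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  e <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sij <- (sigma[i] + sigma[j]) / 2
    eij <- sqrt(epsilon[i] * epsilon[j])
    if (eij == 0) next
    for (s in seq_len(nrow(shifts))) {
      d <- coords[j, ] + shifts[s, ] * box - coords[i, ]
      r2 <- sum(d * d)
      if (r2 <= cutoff^2) {
        sr6 <- (sij^2 / r2)^3
        e <- e + 4 * eij * (sr6^2 - sr6)
      }
    }
  }
  e
}

# Brute-force cross-molecule Coulomb pair sum (direct, non-periodic)
# over pairs with at least one member among mol ids `ids`.
bf_cross_coulomb <- function(frame, topology, ids) {
  at <- topology$atoms
  x <- frame$coords
  q <- at$charge
  ke <- md_constants$k_coulomb
  n <- nrow(x)
  e <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    mi <- at$mol_id[i]; mj <- at$mol_id[j]
    if (mi == mj) next
    if (!(mi %in% ids) && !(mj %in% ids)) next
    if (q[i] == 0 || q[j] == 0) next
    e <- e + ke * q[i] * q[j] / sqrt(sum((x[i, ] - x[j, ])^2))
  }
  e
}

# Evjen shell summation of the rock-salt Madelung constant: sum of
# (-1)^(i+j+k+1)/r over the cube [-n, n]^3 with fractional weights
# (1/2 per face coordinate) for boundary sites.
evjen_madelung <- function(n = 6L) {
  g <- as.matrix(expand.grid(-n:n, -n:n, -n:n))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  w <- apply(g, 1L, function(p) prod(ifelse(abs(p) == n, 0.5, 1)))
  r <- sqrt(rowSums(g^2))
  sum(w * (-1)^(rowSums(g) + 1) / r)
}

# Shortest bonded path lengths via igraph (independent BFS oracle).
igraph_path_pairs <- function(n_atoms, bonds) {
  gr <- igraph::graph_from_edgelist(as.matrix(bonds[, c("i", "j")]),
                                    directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0, n_atoms - igraph::vcount(gr)))
  dm <- igraph::distances(gr)
  out <- list()
  for (i in seq_len(n_atoms - 1L)) for (j in (i + 1L):n_atoms) {
    d <- dm[i, j]
    if (is.finite(d) && d >= 1 && d <= 3)
      out[[length(out) + 1L]] <- data.frame(i = i, j = j, sep = as.integer(d))
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer(),
                                      sep = integer()))
  do.call(rbind, out)
}

expect_same_pairs <- function(a, b) {
  key <- function(d) sort(paste(d$i, d$j, d$sep))
  expect_identical(key(a), key(b))
}
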