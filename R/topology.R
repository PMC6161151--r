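#' Molecule topology
#'
#' Bundles the per-molecule force-field description: atoms (with partial
#' charges and Lennard-Jones parameters), harmonic bonds and angles,
#' periodic dihedrals, and the bonded-path exclusion sets derived from
#' the bond graph (1-2, 1-3 and 1-4 neighbours by shortest bonded path).
#'
#' @param name molecule species name.
#' @param atoms data.frame with columns \code{name}, \code{element},
#'   \code{mass} (amu), \code{charge} (e), \code{sigma} (nm),
#'   \code{epsilon} (kJ/mol) and optionally logical \code{is_donor_h}
#'   (an H covalently bound to N or O) and \code{is_acceptor} (N or O).
#'   Missing flags are derived from the elements and the bond list.
#' @param bonds data.frame with columns \code{i}, \code{j} (1-based atom
#'   indices), \code{r0} (nm), \code{k} (kJ/mol/nm^2); may be NULL.
#' @param angles data.frame with \code{i}, \code{j}, \code{k} (vertex is
#'   \code{j}), \code{theta0} (rad), \code{ka} (kJ/mol/rad^2); may be NULL.
#' @param dihedrals data.frame with \code{i}, \code{j}, \code{k},
#'   \code{l}, \code{n} (periodicity), \code{phi0} (rad), \code{kd}
#'   (kJ/mol); may be NULL.
#' @return an object of class \code{molecule_topology}.
#' @export
molecule_topology <- function(name, atoms, bonds = NULL, angles = NULL,
                              dihedrals = NULL) {
  atoms <- as.data.frame(atoms)
  req <- c("name", "element", "mass", "charge", "sigma", "epsilon")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(atoms$mass <= 0)) stop("atom masses must be > 0")
  if (any(atoms$sigma < 0) || any(atoms$epsilon < 0))
    stop("LJ sigma and epsilon must be >= 0")
  na <- nrow(atoms)

  norm_idx <- function(tab, cols, what) {
    if (is.null(tab) || nrow(as.data.frame(tab)) == 0L) return(NULL)
    tab <- as.data.frame(tab)
    idx <- as.matrix(tab[cols])
    if (any(idx < 1L) || any(idx > na))
      stop("dangling atom index in ", what, " table")
    tab
  }
  bonds     <- norm_idx(bonds, c("i", "j"), "bond")
  angles    <- norm_idx(angles, c("i", "j", "k"), "angle")
  dihedrals <- norm_idx(dihedrals, c("i", "j", "k", "l"), "dihedral")

  # H-bond role flags: derivable from elements + bonds, overridable.
  if (is.null(atoms$is_acceptor))
    atoms$is_acceptor <- atoms$element %in% c("N", "O")
  if (is.null(atoms$is_donor_h)) {
    flag <- rep(FALSE, na)
    if (!is.null(bonds)) {
      for (r in seq_len(nrow(bonds))) {
        i <- bonds$i[r]; j <- bonds$j[r]
        ei <- atoms$element[i]; ej <- atoms$element[j]
        if (ei == "H" && ej %in% c("N", "O")) flag[i] <- TRUE
        if (ej == "H" && ei %in% c("N", "O")) flag[j] <- TRUE
      }
    }
    atoms$is_donor_h <- flag
  }

  excl <- derive_exclusions(na, bonds)
  structure(list(name = name, atoms = atoms, bonds = bonds,
                 angles = angles, dihedrals = dihedrals,
                 exclusions = excl),
            class = "molecule_topology")
}

# Shortest bonded path classification within one molecule.
# Returns a data.frame (i, j, sep) with i < j and sep in 1:3
# (1 = 1-2 pair, 2 = 1-3 pair, 3 = 1-4 pair).  Shortest-path semantics
# guarantee a pair appears at exactly one separation.
derive_exclusions <- function(n_atoms, bonds) {
  empty <- data.frame(i = integer(), j = integer(), sep = integer())
  if (is.null(bonds) || nrow(bonds) == 0L) return(empty)
  adj <- vector("list", n_atoms)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds$i[r]; j <- bonds$j[r]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  out <- list()
  for (s in seq_len(n_atoms)) {
    dist <- rep(NA_integer_, n_atoms)
    dist[s] <- 0L
    frontier <- s
    for (d in 1:3) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.na(dist[nxt])]
      if (!length(nxt)) break
      dist[nxt] <- d
      frontier <- nxt
    }
    hit <- which(!is.na(dist) & dist > 0L & seq_len(n_atoms) > s)
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(i = s, j = hit, sep = dist[hit])
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' System topology
#'
#' Assembles molecule species into a full system: each species appears
#' \code{count} times, with a role of \code{"api"} or \code{"polymer"}
#' (or \code{"other"}).  A flat per-atom table with global indices,
#' molecule-instance ids and species labels is derived, together with
#' the global exclusion pair list.
#'
#' @param species list of entries, each a list with elements
#'   \code{molecule} (a [molecule_topology()]), \code{count} (positive
#'   integer) and \code{role} (\code{"api"}, \code{"polymer"} or
#'   \code{"other"}).
#' @return an object of class \code{system_topology} with elements
#'   \code{species}, \code{atoms} (flat table with columns
#'   \code{species}, \code{role}, \code{mol_id}, \code{local},
#'   \code{name}, \code{element}, \code{mass}, \code{charge},
#'   \code{sigma}, \code{epsilon}, \code{is_donor_h},
#'   \code{is_acceptor}), \code{exclusions} (global \code{i < j} pairs
#'   with column \code{sep}), \code{n_atoms}, \code{n_molecules}.
#' @export
system_topology <- function(species) {
  stopifnot(length(species) >= 1L)
  atoms <- list(); excl <- list()
  mol_id <- 0L; offset <- 0L
  for (sp in species) {
    mol <- sp$molecule
    if (!inherits(mol, "molecule_topology"))
      stop("each species needs a molecule_topology in $molecule")
    count <- as.integer(sp$count %||% 1L)
    if (count < 0L) stop("negative molecule count for species ", mol$name)
    role <- sp$role %||% "other"
    if (!role %in% c("api", "polymer", "other"))
      stop("role must be api, polymer or other")
    na <- nrow(mol$atoms)
    for (c in seq_len(count)) {
      mol_id <- mol_id + 1L
      at <- mol$atoms
      at$species <- mol$name
      at$role <- role
      at$mol_id <- mol_id
      at$local <- seq_len(na)
      atoms[[length(atoms) + 1L]] <- at
      if (nrow(mol$exclusions)) {
        e <- mol$exclusions
        e$i <- e$i + offset
        e$j <- e$j + offset
        excl[[length(excl) + 1L]] <- e
      }
      offset <- offset + na
    }
  }
  atoms <- do.call(rbind, atoms)
  rownames(atoms) <- NULL
  excl <- if (length(excl)) do.call(rbind, excl) else
    data.frame(i = integer(), j = integer(), sep = integer())
  rownames(excl) <- NULL
  structure(list(species = species, atoms = atoms, exclusions = excl,
                 n_atoms = nrow(atoms), n_molecules = mol_id),
            class = "system_topology")
}

#' @export
print.system_topology <- function(x, ...) {
  cat("system_topology:", x$n_atoms, "atoms in", x$n_molecules,
      "molecules\n")
  for (sp in x$species)
    cat(sprintf("  %s (%s): %d x %d atoms\n", sp$molecule$name,
                sp$role %||% "other", as.integer(sp$count %||% 1L),
                nrow(sp$molecule$atoms)))
  invisible(x)
}

# Global atom indices of one molecule instance.
molecule_atom_indices <- function(topology, mol_id) {
  which(topology$atoms$mol_id == mol_id)
}

# Molecule ids belonging to a species name, or to a role if prefixed
# "role:" ("role:api"), or all molecules for "all".
molecule_ids_of <- function(topology, species) {
  a <- topology$atoms
  if (identical(species, "all")) return(unique(a$mol_id))
  if (startsWith(species, "role:")) {
    role <- sub("^role:", "", species)
    ids <- unique(a$mol_id[a$role == role])
  } else {
    ids <- unique(a$mol_id[a$species == species])
  }
  if (!length(ids)) stop("no molecules match species '", species, "'")
  ids
}

#' Load a system topology from a YAML file
#'
#' The topology format is structured text: a top-level \code{species}
#' list, each entry carrying \code{name}, \code{role}, \code{count}, an
#' \code{atoms} list (name, element, mass, charge, sigma, epsilon,
#' optional donor/acceptor flags) and optional \code{bonds},
#' \code{angles}, \code{dihedrals} lists using 1-based atom indices.
#' Exclusion sets are always re-derived from the bond graph.
#'
#' @param path YAML file path.
#' @return a [system_topology()].
#' @export
load_topology <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$species)) stop("topology file has no 'species' list")
  species <- lapply(doc$species, function(sp) {
    atoms <- do.call(rbind, lapply(sp$atoms, function(a)
      data.frame(name = a$name, element = a$element, mass = a$mass,
                 charge = a$charge %||% 0, sigma = a$sigma %||% 0,
                 epsilon = a$epsilon %||% 0,
                 is_donor_h = a$is_donor_h %||% NA,
                 is_acceptor = a$is_acceptor %||% NA)))
    if (all(is.na(atoms$is_donor_h))) atoms$is_donor_h <- NULL
    if (all(is.na(atoms$is_acceptor))) atoms$is_acceptor <- NULL
    tab <- function(x) if (is.null(x)) NULL else
      do.call(rbind, lapply(x, as.data.frame))
    count <- as.integer(sp$count %||% 1L)
    if (count < 0L) stop("negative count for species ", sp$name)
    mol <- molecule_topology(sp$name, atoms, tab(sp$bonds),
                             tab(sp$angles), tab(sp$dihedrals))
    list(molecule = mol, count = count, role = sp$role %||% "other")
  })
  system_topology(species)
}

#' Write a system topology to a YAML file
#'
#' Inverse of [load_topology()]; exclusion sets are not written (they
#' are derived from the bond graph on load).
#'
#' @param topology a [system_topology()].
#' @param path output file path.
#' @export
write_topology <- function(topology, path) {
  species <- lapply(topology$species, function(sp) {
    mol <- sp$molecule
    list(
      name = mol$name, role = sp$role %||% "other",
      count = as.integer(sp$count %||% 1L),
      atoms = lapply(seq_len(nrow(mol$atoms)), function(i)
        as.list(mol$atoms[i, c("name", "element", "mass", "charge",
                               "sigma", "epsilon", "is_donor_h",
                               "is_acceptor")])),
      bonds = if (is.null(mol$bonds)) NULL else
        lapply(seq_len(nrow(mol$bonds)), function(i) as.list(mol$bonds[i, ])),
      angles = if (is.null(mol$angles)) NULL else
        lapply(seq_len(nrow(mol$angles)), function(i) as.list(mol$angles[i, ])),
      dihedrals = if (is.null(mol$dihedrals)) NULL else
        lapply(seq_len(nrow(mol$dihedrals)), function(i)
          as.list(mol$dihedrals[i, ]))
    )
  })
  yaml::write_yaml(list(species = species), path)
  invisible(path)
}
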