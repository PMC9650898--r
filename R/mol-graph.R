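#' Molecular graph objects
#'
#' A `mol_graph` is the light-weight molecule representation used throughout
#' the package: a heavy-atom graph with implicit hydrogens tracked as counts.
#' It consists of an atom table (element symbol, formal charge, implicit
#' hydrogen count, aromatic flag, isotope), a bond table (endpoint indices,
#' integer order 1--3, aromatic flag) and a list of tetrahedral stereo
#' descriptors. Bond orders always carry a definite Kekule assignment;
#' aromatic flags are an overlay set by aromaticity perception.
#'
#' @param atoms data.frame with columns `element` (character), `charge`
#'   (integer), `nh` (integer implicit hydrogen count), `aromatic` (logical),
#'   `isotope` (integer, `NA` for natural abundance).
#' @param bonds data.frame with columns `a1`, `a2` (atom indices), `order`
#'   (integer in 1..3) and `aromatic` (logical).
#' @param stereo list of tetrahedral descriptors as returned by
#'   [stereo_center()].
#' @return An object of class `mol_graph`.
#' @examples
#' benzene <- parse_smiles("c1ccccc1")
#' n_atoms(benzene)
#' @export
mol_graph <- function(atoms = empty_atom_table(), bonds = empty_bond_table(),
                      stereo = list()) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  if (nrow(bonds)) {
    # normalise endpoint order so duplicate detection is index-order free
    swap <- bonds$a1 > bonds$a2
    tmp <- bonds$a1[swap]
    bonds$a1[swap] <- bonds$a2[swap]
    bonds$a2[swap] <- tmp
  }
  m <- structure(list(atoms = atoms, bonds = bonds, stereo = stereo),
                 class = "mol_graph")
  validate_mol_graph(m)
  m
}

empty_atom_table <- function() {
  data.frame(element = character(), charge = integer(), nh = integer(),
             aromatic = logical(), isotope = integer(),
             stringsAsFactors = FALSE)
}

empty_bond_table <- function() {
  data.frame(a1 = integer(), a2 = integer(), order = integer(),
             aromatic = logical(), stringsAsFactors = FALSE)
}

#' Tetrahedral stereo descriptor
#'
#' Describes the configuration at a tetrahedral centre. `neighbors` lists the
#' substituent atom indices in a fixed reference order; the value `0` stands
#' for an implicit hydrogen. `parity` is 1 when, looking from the first
#' neighbor, the remaining ones appear clockwise (SMILES `@@`), and 2 for
#' anticlockwise (SMILES `@`). This matches the MDL ctab parity convention
#' when neighbors are in increasing index order with the implicit H last.
#'
#' @param atom index of the stereo centre.
#' @param neighbors integer vector of 4 neighbor indices (0 = implicit H).
#' @param parity 1 (`@@`) or 2 (`@`).
#' @return A list of class `stereo_center`.
#' @export
stereo_center <- function(atom, neighbors, parity) {
  stopifnot(length(neighbors) == 4L, parity %in% c(1L, 2L))
  structure(list(atom = as.integer(atom),
                 neighbors = as.integer(neighbors),
                 parity = as.integer(parity)),
            class = "stereo_center")
}

validate_mol_graph <- function(m) {
  na <- nrow(m$atoms)
  b <- m$bonds
  if (nrow(b)) {
    if (any(b$a1 < 1L | b$a2 < 1L | b$a1 > na | b$a2 > na))
      stop("mol_graph: bond endpoint out of range", call. = FALSE)
    if (any(b$a1 == b$a2))
      stop("mol_graph: self-bond", call. = FALSE)
    if (anyDuplicated(b[, c("a1", "a2")]))
      stop("mol_graph: duplicate bond", call. = FALSE)
    if (!all(b$order %in% 1:3))
      stop("mol_graph: bond order must be 1, 2 or 3", call. = FALSE)
  }
  for (s in m$stereo) {
    refs <- s$neighbors[s$neighbors > 0L]
    if (s$atom < 1L || s$atom > na || any(refs > na))
      stop("mol_graph: stereo descriptor references a missing atom",
           call. = FALSE)
  }
  invisible(m)
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %d atoms, %d bonds, %d stereo centres\n",
              nrow(x$atoms), nrow(x$bonds), length(x$stereo)))
  invisible(x)
}

#' Number of atoms / bonds of a molecular graph
#' @param m a `mol_graph` (or `scaffold`).
#' @return integer count.
#' @export
n_atoms <- function(m) nrow(as_mol_graph(m)$atoms)

#' @rdname n_atoms
#' @export
n_bonds <- function(m) nrow(as_mol_graph(m)$bonds)

# Coerce scaffold-like wrappers down to the raw graph.
as_mol_graph <- function(m) {
  if (inherits(m, "scaffold")) m$graph else m
}

is_empty_mol <- function(m) n_atoms(m) == 0L

# igraph view of the heavy-atom skeleton (edge order == bond table order)
mol_igraph <- function(m) {
  m <- as_mol_graph(m)
  igraph::graph_from_edgelist(
    cbind(m$bonds$a1, m$bonds$a2), directed = FALSE) |>
    (\(g) if (igraph::vcount(g) < nrow(m$atoms))
       igraph::add_vertices(g, nrow(m$atoms) - igraph::vcount(g)) else g)()
}

# indices of bonds incident to each atom; returns list of integer vectors
incident_bonds <- function(m) {
  m <- as_mol_graph(m)
  res <- vector("list", nrow(m$atoms))
  if (nrow(m$bonds)) {
    for (i in seq_len(nrow(m$bonds))) {
      res[[m$bonds$a1[i]]] <- c(res[[m$bonds$a1[i]]], i)
      res[[m$bonds$a2[i]]] <- c(res[[m$bonds$a2[i]]], i)
    }
  }
  res
}

mol_degree <- function(m) {
  m <- as_mol_graph(m)
  deg <- integer(nrow(m$atoms))
  if (nrow(m$bonds)) {
    t1 <- tabulate(m$bonds$a1, nbins = nrow(m$atoms))
    t2 <- tabulate(m$bonds$a2, nbins = nrow(m$atoms))
    deg <- t1 + t2
  }
  deg
}

# connected component membership (integer vector, 1-based labels)
mol_components <- function(m) {
  m <- as_mol_graph(m)
  if (nrow(m$atoms) == 0L) return(integer())
  igraph::components(mol_igraph(m))$membership
}

# Atoms that belong to at least one cycle: endpoints of non-bridge bonds.
cyclic_atoms <- function(m) {
  m <- as_mol_graph(m)
  if (!nrow(m$bonds)) return(integer())
  g <- mol_igraph(m)
  br <- igraph::bridges(g)
  cyc <- setdiff(seq_len(nrow(m$bonds)), as.integer(br))
  sort(unique(c(m$bonds$a1[cyc], m$bonds$a2[cyc])))
}

# Bonds that lie on a cycle (non-bridges).
cyclic_bonds <- function(m) {
  m <- as_mol_graph(m)
  if (!nrow(m$bonds)) return(integer())
  g <- mol_igraph(m)
  setdiff(seq_len(nrow(m$bonds)), as.integer(igraph::bridges(g)))
}

# Delete atoms (and incident bonds). Freed valence at surviving neighbors is
# converted into implicit hydrogens. Stereo descriptors whose defining atoms
# do not all survive are dropped; surviving ones are re-indexed.
delete_atoms <- function(m, idx) {
  m <- as_mol_graph(m)
  idx <- unique(as.integer(idx))
  if (!length(idx)) return(m)
  keep <- setdiff(seq_len(nrow(m$atoms)), idx)
  map <- integer(nrow(m$atoms))
  map[keep] <- seq_along(keep)
  atoms <- m$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- m$bonds
  if (nrow(bonds)) {
    gone <- bonds$a1 %in% idx | bonds$a2 %in% idx
    # hydrogen bookkeeping for cut bonds
    for (i in which(gone)) {
      for (a in c(bonds$a1[i], bonds$a2[i])) {
        if (!(a %in% idx)) atoms$nh[map[a]] <- atoms$nh[map[a]] + bonds$order[i]
      }
    }
    bonds <- bonds[!gone, , drop = FALSE]
    bonds$a1 <- map[bonds$a1]
    bonds$a2 <- map[bonds$a2]
    rownames(bonds) <- NULL
  }
  stereo <- list()
  for (s in m$stereo) {
    refs <- c(s$atom, s$neighbors[s$neighbors > 0L])
    if (all(!(refs %in% idx))) {
      nb <- s$neighbors
      nb[nb > 0L] <- map[nb[nb > 0L]]
      stereo[[length(stereo) + 1L]] <- stereo_center(map[s$atom], nb, s$parity)
    }
  }
  mol_graph(atoms, bonds, stereo)
}

# Delete bonds by index, adding hydrogens for the freed valence.
delete_bonds <- function(m, idx) {
  m <- as_mol_graph(m)
  idx <- unique(as.integer(idx))
  if (!length(idx)) return(m)
  atoms <- m$atoms
  for (i in idx) {
    atoms$nh[m$bonds$a1[i]] <- atoms$nh[m$bonds$a1[i]] + m$bonds$order[i]
    atoms$nh[m$bonds$a2[i]] <- atoms$nh[m$bonds$a2[i]] + m$bonds$order[i]
  }
  bonds <- m$bonds[-idx, , drop = FALSE]
  rownames(bonds) <- NULL
  # stereo centres that lost a neighbor bond are no longer defined
  stereo <- Filter(function(s) {
    nb <- s$neighbors[s$neighbors > 0L]
    all(vapply(nb, function(b) bond_index(bonds, s$atom, b), integer(1)) > 0L)
  }, m$stereo)
  mol_graph(atoms, bonds, stereo)
}

# index of bond a-b in a bond table, 0 if absent
bond_index <- function(bonds, a, b) {
  lo <- min(a, b); hi <- max(a, b)
  w <- which(bonds$a1 == lo & bonds$a2 == hi)
  if (length(w)) w[1] else 0L
}

# induced subgraph on a set of atoms, keeping only the listed bonds
# (bond_idx defaults to all bonds within the atom set)
subgraph_atoms <- function(m, atom_idx, bond_idx = NULL) {
  m <- as_mol_graph(m)
  atom_idx <- sort(unique(as.integer(atom_idx)))
  map <- integer(nrow(m$atoms))
  map[atom_idx] <- seq_along(atom_idx)
  if (is.null(bond_idx)) {
    bond_idx <- which(m$bonds$a1 %in% atom_idx & m$bonds$a2 %in% atom_idx)
  }
  atoms <- m$atoms[atom_idx, , drop = FALSE]
  rownames(atoms) <- NULL
  # hydrogens for valence freed at the cut
  if (nrow(m$bonds)) {
    for (i in setdiff(seq_len(nrow(m$bonds)), bond_idx)) {
      for (a in c(m$bonds$a1[i], m$bonds$a2[i])) {
        if (a %in% atom_idx) atoms$nh[map[a]] <- atoms$nh[map[a]] + m$bonds$order[i]
      }
    }
  }
  bonds <- m$bonds[bond_idx, , drop = FALSE]
  if (nrow(bonds)) {
    bonds$a1 <- map[bonds$a1]
    bonds$a2 <- map[bonds$a2]
    rownames(bonds) <- NULL
  }
  stereo <- list()
  for (s in m$stereo) {
    refs <- c(s$atom, s$neighbors[s$neighbors > 0L])
    if (all(refs %in% atom_idx)) {
      nb <- s$neighbors
      nb[nb > 0L] <- map[nb[nb > 0L]]
      ok <- all(vapply(nb[nb > 0L], function(b)
        bond_index(bonds, map[s$atom], b) > 0L, logical(1)))
      if (ok) stereo[[length(stereo) + 1L]] <- stereo_center(map[s$atom], nb, s$parity)
    }
  }
  mol_graph(atoms, bonds, stereo)
}

#' Strip all stereo descriptors from a molecule
#' @param m a `mol_graph`.
#' @return the graph without stereo information.
#' @export
drop_stereo <- function(m) {
  g <- as_mol_graph(m)
  g$stereo <- list()
  g
}
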