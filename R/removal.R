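#' Terminality and removability of rings, and ring removal
#'
#' `is_terminal()` checks that deleting the ring's exclusive atoms and bonds
#' (those not shared with any other ring), after discarding fragments that
#' are pure side chains, leaves at most one connected ring-bearing
#' component; turning former ring atoms into linker atoms does not count as
#' staying connected. `is_removable()` additionally requires that the ring
#' owns at least one exclusive atom, that its removal does not create a
#' spiro junction absent from the child scaffold, and that an aromatic ring
#' does not share an atom with two or more other rings (the double-bond
#' repair would violate valence there). `remove_ring()` performs the
#' removal with bond repair:
#'
#' 1. if the removed ring was aromatic and shared exactly one bond with one
#'    remaining ring, that bond becomes a double bond (also when the
#'    remaining ring is aromatic);
#' 2. if the removed ring is three-membered with exactly one heteroatom and
#'    the shared bond lies opposite the heteroatom, the shared bond becomes
#'    a double bond;
#' 3. unless `settings$retain_only_hybridisations_at_aromatic_bonds` is
#'    `TRUE`, any formerly ring-shared single bond whose two atoms would
#'    both lose sp2 character becomes a double bond when valence permits.
#'
#' Stereo descriptors are transferred when all their defining atoms
#' survive; side chains orphaned by the removal are deleted; aromaticity is
#' re-perceived on the product when `settings$determine_aromaticity` is
#' `TRUE`.
#'
#' @param scaffold a `scaffold`.
#' @param ring a ring from `detect_rings(scaffold)`.
#' @param settings a [scaffold_settings()].
#' @return `is_terminal`/`is_removable`: a logical flag. `remove_ring`: the
#'   parent `scaffold` with exactly one ring fewer.
#' @examples
#' s <- extract_scaffold(parse_smiles("c1ccc2ccccc2c1"))
#' r <- detect_rings(s)$rings[[1]]
#' remove_ring(s, r)$smiles_key  # "c1ccccc1"
#' @export
is_terminal <- function(scaffold, ring) {
  g <- as_mol_graph(scaffold)
  rings <- require_member_ring(g, ring)
  terminal_idx(g, rings$all, rings$index)
}

terminal_idx <- function(g, all_rings, index) {
  rings <- list(all = all_rings, index = index)
  excl <- exclusive_parts(g, rings$all, rings$index)
  n <- nrow(g$atoms)
  keep_atoms <- setdiff(seq_len(n), excl$atoms)
  other_ring_atoms <- unique(unlist(lapply(rings$all[-rings$index],
                                           function(r) r$atom_indices)))
  if (!length(keep_atoms) || !length(other_ring_atoms)) return(TRUE)
  dead_bonds <- unique(c(excl$bonds,
                         which(g$bonds$a1 %in% excl$atoms |
                                 g$bonds$a2 %in% excl$atoms)))
  live <- setdiff(seq_len(nrow(g$bonds)), dead_bonds)
  map <- match(seq_len(n), keep_atoms)
  ig <- igraph::make_empty_graph(n = length(keep_atoms), directed = FALSE)
  if (length(live)) {
    ig <- igraph::add_edges(ig, rbind(map[g$bonds$a1[live]],
                                      map[g$bonds$a2[live]]))
  }
  memb <- igraph::components(ig)$membership
  ring_comps <- unique(memb[map[other_ring_atoms]])
  length(ring_comps) <= 1L
}

#' @rdname is_terminal
#' @export
is_removable <- function(scaffold, ring, settings = scaffold_settings()) {
  g <- as_mol_graph(scaffold)
  rings <- require_member_ring(g, ring)
  removable_idx(g, rings$all, rings$index, settings)
}

removable_idx <- function(g, all_rings, index, settings) {
  excl <- exclusive_parts(g, all_rings, index)
  if (!length(excl$atoms)) return(FALSE)                       # (b)
  if (!terminal_idx(g, all_rings, index)) return(FALSE)        # (a)
  r <- all_rings[[index]]
  if (r$aromatic) {                                            # (d)
    others <- all_rings[-index]
    for (a in r$atom_indices) {
      sharing <- sum(vapply(others, function(o) a %in% o$atom_indices,
                            logical(1)))
      if (sharing >= 2L) return(FALSE)
    }
  }
  # (c) no artificially created spiro junction
  parent <- remove_ring_core(g, all_rings, index, settings,
                             perceive = FALSE)
  sp_parent <- spiro_atoms(parent$graph)
  if (length(sp_parent)) {
    sp_child <- spiro_atoms(g)
    if (any(!(parent$orig_atoms[sp_parent] %in% sp_child))) return(FALSE)
  }
  TRUE
}

#' @rdname is_terminal
#' @export
remove_ring <- function(scaffold, ring, settings = scaffold_settings()) {
  if (!is_removable(scaffold, ring, settings)) {
    stop("ring is not removable from this scaffold", call. = FALSE)
  }
  g <- as_mol_graph(scaffold)
  rings <- require_member_ring(g, ring)
  res <- remove_ring_core(g, rings$all, rings$index, settings,
                          perceive = settings$determine_aromaticity)
  new_scaffold(res$graph, settings)
}

# ---- internals -------------------------------------------------------------

require_member_ring <- function(g, ring) {
  rs <- detect_rings_graph(g)
  key <- paste(sort(ring$bond_indices), collapse = ",")
  idx <- which(vapply(rs$rings, function(r)
    paste(sort(r$bond_indices), collapse = ","), character(1)) == key)
  if (!length(idx)) {
    stop("ring does not belong to this scaffold", call. = FALSE)
  }
  list(all = rs$rings, index = idx[1])
}

# atoms/bonds of ring i not shared with any other detected ring
exclusive_parts <- function(g, rings, i) {
  r <- rings[[i]]
  others <- rings[-i]
  oa <- unique(unlist(lapply(others, function(o) o$atom_indices)))
  ob <- unique(unlist(lapply(others, function(o) o$bond_indices)))
  list(atoms = setdiff(r$atom_indices, oa),
       bonds = setdiff(r$bond_indices, ob))
}

# articulation points lying in >= 2 cyclic blocks (spiro junctions)
spiro_atoms <- function(g) {
  if (!nrow(g$bonds)) return(integer())
  ig <- mol_igraph(g)
  arts <- as.integer(igraph::articulation_points(ig))
  if (!length(arts)) return(integer())
  blocks <- cyclic_blocks(g)
  out <- integer()
  for (a in arts) {
    k <- sum(vapply(blocks, function(b) a %in% b$atoms, logical(1)))
    if (k >= 2L) out <- c(out, a)
  }
  sort(out)
}

# Remove ring `i` from graph `g` (rings = detected ring list), returning
# list(graph, orig_atoms): orig_atoms maps result atoms to input indices.
remove_ring_core <- function(g, rings, i, settings, perceive = TRUE) {
  r <- rings[[i]]
  excl <- exclusive_parts(g, rings, i)
  shared_bonds <- setdiff(r$bond_indices, excl$bonds)

  # plan the double-bond repairs on the pre-removal graph
  repairs <- integer()    # global bond indices to promote to order 2
  repair_kind <- integer()  # 1/2 mandatory, 3 opportunistic
  if (length(shared_bonds) == 1L) {
    sb <- shared_bonds
    sharing_rings <- sum(vapply(rings[-i], function(o) sb %in% o$bond_indices,
                                logical(1)))
    if (r$aromatic && sharing_rings == 1L && g$bonds$order[sb] == 1L) {
      repairs <- sb; repair_kind <- 1L                    # repair (1)
    } else if (r$size == 3L && sum(r$heteroatom_counts) == 1L &&
               g$bonds$order[sb] == 1L) {
      het <- r$atom_indices[!(g$atoms$element[r$atom_indices] %in% "C")]
      opposite <- !(g$bonds$a1[sb] %in% het) && !(g$bonds$a2[sb] %in% het)
      if (opposite) { repairs <- sb; repair_kind <- 2L }  # repair (2)
    }
  }
  if (!length(repairs) &&
      !settings$retain_only_hybridisations_at_aromatic_bonds) {
    for (sb in sort(shared_bonds)) {                      # repair (3)
      if (g$bonds$order[sb] != 1L) next
      ends <- c(g$bonds$a1[sb], g$bonds$a2[sb])
      loses <- vapply(ends, function(a) loses_sp2(g, a, excl$bonds),
                      logical(1))
      if (all(loses)) { repairs <- c(repairs, sb); repair_kind <- c(repair_kind, 3L) }
    }
  }
  repair_pairs <- lapply(repairs, function(bi) c(g$bonds$a1[bi],
                                                 g$bonds$a2[bi]))

  # delete exclusive bonds between surviving atoms, then exclusive atoms
  orig <- seq_len(nrow(g$atoms))
  excl_bond_only <- excl$bonds[!(g$bonds$a1[excl$bonds] %in% excl$atoms |
                                   g$bonds$a2[excl$bonds] %in% excl$atoms)]
  out <- delete_bonds(g, excl_bond_only)
  keep <- setdiff(orig, excl$atoms)
  out <- delete_atoms(out, excl$atoms)
  orig <- keep

  # prune side chains orphaned by the removal (framework semantics of the
  # current mode)
  fw <- framework_atom_set(out, settings$scaffold_mode)
  if (length(fw$keep) < nrow(out$atoms)) {
    out <- subgraph_atoms(out, fw$keep)
    orig <- orig[sort(fw$keep)]
  }

  # execute repairs on the surviving graph
  for (k in seq_along(repair_pairs)) {
    pp <- repair_pairs[[k]]
    a <- match(pp[1], orig); b <- match(pp[2], orig)
    if (is.na(a) || is.na(b)) next
    bi <- bond_index(out$bonds, a, b)
    if (bi == 0L) next
    if (out$atoms$nh[a] < 1L || out$atoms$nh[b] < 1L) {
      if (repair_kind[k] == 3L) next       # opportunistic: valence decides
      stop("double-bond repair impossible without violating valence",
           call. = FALSE)
    }
    out$bonds$order[bi] <- 2L
    out$atoms$nh[a] <- out$atoms$nh[a] - 1L
    out$atoms$nh[b] <- out$atoms$nh[b] - 1L
  }

  if (perceive) {
    out <- perceive_aromaticity(out, settings$aromaticity_model)
  } else {
    # flags on deleted-adjacent bonds may be stale only if perception is
    # off; they reflect the input as given
  }
  list(graph = out, orig_atoms = orig)
}

# would atom `a` lose its sp2 character if `gone_bonds` were deleted?
loses_sp2 <- function(g, a, gone_bonds) {
  inc <- which(g$bonds$a1 == a | g$bonds$a2 == a)
  sp2 <- inc[g$bonds$order[inc] >= 2L | g$bonds$aromatic[inc]]
  length(sp2) > 0L && all(sp2 %in% gone_bonds)
}
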