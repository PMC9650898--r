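#' Parent scaffold generation
#'
#' `enumerate_parent_scaffolds()` computes the breadth-first closure of all
#' possible parent scaffolds: from every scaffold each removable ring is
#' removed separately, repeatedly, until only single-ring scaffolds remain
#' or no ring is removable; duplicates (by SMILES key) are returned once.
#' `schuffenhauer_chain()` instead selects exactly one removable ring at
#' every step with the 13 prioritisation rules, producing a linear chain
#' from the original scaffold down to its root scaffold.
#'
#' @param mol a `mol_graph` (or a ready-made `scaffold`).
#' @param settings a [scaffold_settings()].
#' @return A `dissection_result`: list with `scaffolds` (list of
#'   `scaffold`, original first) and `edges` (data.frame with columns
#'   `child`, `parent` of SMILES keys, each parent having exactly one ring
#'   fewer than its child).
#' @examples
#' res <- enumerate_parent_scaffolds(parse_smiles("C1CCC2CCCCC2C1"))
#' vapply(res$scaffolds, function(s) s$smiles_key, character(1))
#' @export
enumerate_parent_scaffolds <- function(mol, settings = scaffold_settings()) {
  orig <- as_scaffold(mol, settings)
  scaffolds <- list()
  scaffolds[[map_key(orig$smiles_key)]] <- orig
  edges <- list()
  queue <- list(orig)
  while (length(queue)) {
    s <- queue[[1]]
    queue <- queue[-1]
    cand <- candidate_parents(s, settings)
    for (cp in cand) {
      key <- cp$parent$smiles_key
      edge_id <- paste(s$smiles_key, key, sep = "\r")
      edges[[edge_id]] <- c(child = s$smiles_key, parent = key)
      if (is.null(scaffolds[[map_key(key)]])) {
        scaffolds[[map_key(key)]] <- cp$parent
        queue[[length(queue) + 1L]] <- cp$parent
      }
    }
  }
  dissection_result(unname(scaffolds), edges)
}

#' @rdname enumerate_parent_scaffolds
#' @export
schuffenhauer_chain <- function(mol, settings = scaffold_settings()) {
  s <- as_scaffold(mol, settings)
  chain <- list(s)
  edges <- list()
  repeat {
    cand <- candidate_parents(s, settings)
    if (!length(cand)) break
    pick <- if (length(cand) == 1L) cand[[1]] else
      apply_schuffenhauer_rules(s, cand, settings)
    edges[[length(edges) + 1L]] <- c(child = s$smiles_key,
                                     parent = pick$parent$smiles_key)
    s <- pick$parent
    chain[[length(chain) + 1L]] <- s
  }
  dissection_result(chain, edges)
}

#' Select the ring to remove according to the Schuffenhauer rules
#'
#' Applies the 13 prioritisation rules as ordered filters over the set of
#' removable rings; a rule narrows the candidate set only when its
#' selection is non-empty, and the process stops as soon as a single
#' candidate remains. The final tie-break picks the candidate whose parent
#' has the lexicographically smallest unique SMILES (byte order).
#'
#' @param scaffold a `scaffold` with at least one removable ring.
#' @param settings a [scaffold_settings()].
#' @return the selected ring (class `mol_ring`).
#' @export
select_ring_schuffenhauer <- function(scaffold,
                                      settings = scaffold_settings()) {
  cand <- candidate_parents(scaffold, settings)
  if (!length(cand)) {
    stop("scaffold has no removable ring", call. = FALSE)
  }
  pick <- if (length(cand) == 1L) cand[[1]] else
    apply_schuffenhauer_rules(scaffold, cand, settings)
  pick$ring
}

dissection_result <- function(scaffolds, edges) {
  ed <- if (length(edges)) {
    df <- as.data.frame(do.call(rbind, unname(edges)),
                        stringsAsFactors = FALSE)
    rownames(df) <- NULL
    df
  } else data.frame(child = character(), parent = character(),
                    stringsAsFactors = FALSE)
  structure(list(scaffolds = scaffolds, edges = ed),
            class = "dissection_result")
}

#' @export
print.dissection_result <- function(x, ...) {
  cat(sprintf("<dissection_result> %d scaffolds, %d edges\n",
              length(x$scaffolds), nrow(x$edges)))
  for (s in x$scaffolds) {
    cat("  ", if (nzchar(s$smiles_key)) s$smiles_key else "<empty>", "\n")
  }
  invisible(x)
}

# names in key->value maps are prefixed so the empty scaffold key is legal
map_key <- function(key) paste0("k:", key)

as_scaffold <- function(mol, settings) {
  if (inherits(mol, "scaffold")) mol else extract_scaffold(mol, settings)
}

# all removable rings of a scaffold with their parent scaffolds:
# list of list(ring, parent (scaffold), parent_rings (ring_set))
candidate_parents <- function(scaffold, settings) {
  g <- as_mol_graph(scaffold)
  rs <- detect_rings_graph(g)
  if (length(rs$rings) <= 1L) return(list())
  out <- list()
  for (i in seq_along(rs$rings)) {
    if (!removable_idx(g, rs$rings, i, settings)) next
    core <- remove_ring_core(g, rs$rings, i, settings,
                             perceive = settings$determine_aromaticity)
    parent <- new_scaffold(core$graph, settings)
    out[[length(out) + 1L]] <- list(ring = rs$rings[[i]], parent = parent,
                                    parent_rings =
                                      detect_rings_graph(core$graph))
  }
  out
}

# ---- the 13 prioritisation rules as ordered filters ------------------------

apply_schuffenhauer_rules <- function(scaffold, cand, settings) {
  g <- as_mol_graph(scaffold)
  child_rings <- detect_rings_graph(g)$rings
  ring_size <- vapply(cand, function(c) c$ring$size, integer(1))
  ring_het <- vapply(cand, function(c) sum(c$ring$heteroatom_counts),
                     integer(1))
  het_el <- function(el) vapply(cand, function(c) {
    n <- c$ring$heteroatom_counts[el]
    if (is.na(n)) 0L else as.integer(n)
  }, integer(1))
  delta <- vapply(cand, function(c) ring_assembly_delta(c$parent_rings),
                  integer(1))
  parent_key <- vapply(cand, function(c) c$parent$smiles_key, character(1))

  narrow <- function(keep) {
    if (any(keep) && !all(keep)) {
      cand <<- cand[keep]
      ring_size <<- ring_size[keep]
      ring_het <<- ring_het[keep]
      delta <<- delta[keep]
      parent_key <<- parent_key[keep]
    }
    length(cand) == 1L
  }

  # rule 1: remove three-membered heterocycles first
  if (narrow(ring_size == 3L & ring_het >= 1L)) return(cand[[1]])
  # rule 2: do not remove rings of >= 12 atoms if smaller ones exist
  if (narrow(ring_size < 12L)) return(cand[[1]])
  # rule 3: parent with the fewest acyclic linker bonds
  linker_bonds <- vapply(cand, function(c)
    acyclic_linker_bond_count(as_mol_graph(c$parent)), integer(1))
  if (narrow(linker_bonds == min(linker_bonds))) return(cand[[1]])
  # rule 4: retain bridged/spiro/nonlinear fusion with preference (max |delta|)
  if (narrow(abs(delta) == max(abs(delta)))) return(cand[[1]])
  # rule 5: bridged systems over spiro systems
  if (narrow(delta > 0L)) return(cand[[1]])
  # rule 6: remove rings of size 3, 5 or 6 first
  if (narrow(ring_size %in% c(3L, 5L, 6L))) return(cand[[1]])
  # rule 7: a fully aromatic ring system must stay aromatic
  if (rule7_effective(settings) &&
      length(child_rings) > 1L &&
      all(vapply(child_rings, function(r) r$aromatic, logical(1)))) {
    keeps_arom <- vapply(cand, function(c) {
      all(vapply(c$parent_rings$rings, function(r) r$aromatic, logical(1)))
    }, logical(1))
    if (narrow(keeps_arom)) return(cand[[1]])
  }
  # rule 8: remove the ring with the fewest heteroatoms first
  if (narrow(ring_het == min(ring_het))) return(cand[[1]])
  # rule 9: element priority N, then O, then S
  for (el in c("N", "O", "S")) {
    cnt <- het_el(el)
    if (narrow(cnt == min(cnt))) return(cand[[1]])
  }
  # rule 10: remove smaller rings first
  if (narrow(ring_size == min(ring_size))) return(cand[[1]])
  # rule 11: mixed aromatic/nonaromatic systems retain nonaromatic rings
  if (settings$determine_aromaticity) {
    arom <- vapply(child_rings, function(r) r$aromatic, logical(1))
    if (any(arom) && !all(arom)) {
      cand_arom <- vapply(cand, function(c) c$ring$aromatic, logical(1))
      if (narrow(cand_arom)) return(cand[[1]])
    }
  }
  # rule 12: rings attached to a linker touching a ring heteroatom first
  if (narrow(vapply(cand, function(c)
    linker_hetero_attachment(g, c$ring), logical(1)))) return(cand[[1]])
  # rule 13: tie-break on the unique SMILES of the parent (byte order)
  cand[[order(parent_key, method = "radix")[1]]]
}

# delta = nrrb - (nR - 1): bonds shared by >= 2 rings minus (ring count - 1);
# 0 for linear/branched fusion, > 0 bridged, < 0 spiro
ring_assembly_delta <- function(ring_set) {
  rings <- ring_set$rings
  n_r <- length(rings)
  if (!n_r) return(0L)
  all_bonds <- unlist(lapply(rings, function(r) r$bond_indices))
  nrrb <- sum(table(all_bonds) >= 2L)
  as.integer(nrrb - (n_r - 1L))
}

# number of acyclic linker bonds of a scaffold graph (bonds outside all
# rings whose endpoints are ring or linker atoms, i.e. not appended atoms)
acyclic_linker_bond_count <- function(g) {
  if (!nrow(g$bonds)) return(0L)
  cyc_b <- cyclic_bonds(g)
  roles <- atom_roles(g)
  acyc <- setdiff(seq_len(nrow(g$bonds)), cyc_b)
  sum(vapply(acyc, function(i) {
    roles[g$bonds$a1[i]] != "appended" && roles[g$bonds$a2[i]] != "appended"
  }, logical(1)))
}

# rule 12 predicate: some linker bond incident to the candidate ring
# touches a heteroatom that is itself a ring atom (provisional reading)
linker_hetero_attachment <- function(g, ring) {
  if (!nrow(g$bonds)) return(FALSE)
  cyc_a <- cyclic_atoms(g)
  cyc_b <- cyclic_bonds(g)
  roles <- atom_roles(g)
  for (i in setdiff(seq_len(nrow(g$bonds)), cyc_b)) {
    ends <- c(g$bonds$a1[i], g$bonds$a2[i])
    if (any(roles[ends] == "appended")) next
    if (!any(ends %in% ring$atom_indices)) next
    for (e in ends) {
      if (e %in% cyc_a && !(g$atoms$element[e] %in% c("C", "H"))) {
        return(TRUE)
      }
    }
  }
  FALSE
}
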