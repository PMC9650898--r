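#' Ring detection with relevant cycles and MCB fallback
#'
#' Detects the rings of a scaffold as the set of relevant cycles, i.e. the
#' union of all minimum cycle bases (all SSSR) of the molecular graph. When
#' this union contains more rings than the scaffold has atoms, a single
#' minimum cycle basis (MCB) is used instead and the result is marked
#' `mcb_fallback`; the MCB ring count then equals the circuit rank
#' (bonds - atoms + components of the cyclic part).
#'
#' Relevant cycles are computed exactly per biconnected component by
#' enumerating the GF(2) cycle space spanned by a fundamental basis; a
#' cycle is relevant when it is not a sum of strictly shorter cycles.
#' Components of circuit rank above 15 (far beyond drug-like ring systems)
#' skip the enumeration and fall back to an MCB directly.
#'
#' @param scaffold a `scaffold` or `mol_graph`.
#' @param method `"auto"` (relevant cycles with the fallback rule) or
#'   `"mcb"` to force a single minimum cycle basis.
#' @return An object of class `ring_set`: a list with `rings` (each ring a
#'   list with `atom_indices`, `bond_indices`, `size`, `aromatic`,
#'   `heteroatom_counts`) and `method` (`"relevant_union"` or
#'   `"mcb_fallback"`).
#' @examples
#' adam <- parse_smiles("C1C2CC3CC1CC(C2)C3")
#' length(detect_rings(adam)$rings)  # 4 relevant rings
#' length(detect_rings(adam, method = "mcb")$rings)  # 3 = circuit rank
#' @export
detect_rings <- function(scaffold, method = c("auto", "mcb")) {
  method <- match.arg(method)
  detect_rings_graph(as_mol_graph(scaffold), force_mcb = method == "mcb")
}

#' @export
print.ring_set <- function(x, ...) {
  cat(sprintf("<ring_set> %d rings (%s)\n", length(x$rings), x$method))
  invisible(x)
}

.rank_cap <- 15L

detect_rings_graph <- function(m, force_mcb = FALSE) {
  if (!nrow(m$bonds)) {
    return(structure(list(rings = list(), method = "relevant_union"),
                     class = "ring_set"))
  }
  comps <- cyclic_blocks(m)
  relevant <- list()
  mcb <- list()
  forced_fallback <- FALSE
  for (cp in comps) {
    res <- component_cycles(m, cp)
    relevant <- c(relevant, res$relevant)
    mcb <- c(mcb, res$mcb)
    if (res$forced_fallback) forced_fallback <- TRUE
  }
  use_fallback <- force_mcb || forced_fallback ||
    length(relevant) > nrow(m$atoms)
  bondsets <- if (use_fallback) mcb else relevant
  rings <- lapply(bondsets, function(bs) make_ring(m, bs))
  rings <- rings[order(vapply(rings, function(r) r$size, integer(1)),
                       vapply(rings, function(r) paste(r$bond_indices,
                                                       collapse = ","),
                              character(1)))]
  structure(list(rings = rings,
                 method = if (use_fallback) "mcb_fallback" else
                   "relevant_union"),
            class = "ring_set")
}

make_ring <- function(m, bond_idx) {
  bond_idx <- sort(unique(as.integer(bond_idx)))
  atoms <- sort(unique(c(m$bonds$a1[bond_idx], m$bonds$a2[bond_idx])))
  het <- m$atoms$element[atoms]
  het <- het[!(het %in% c("C", "H"))]
  aromatic <- length(bond_idx) > 0L &&
    all(m$bonds$aromatic[bond_idx]) && all(m$atoms$aromatic[atoms])
  structure(list(atom_indices = atoms,
                 bond_indices = bond_idx,
                 size = length(atoms),
                 aromatic = aromatic,
                 heteroatom_counts = if (length(het)) table(het) else
                   table(character())),
            class = "mol_ring")
}

#' @export
print.mol_ring <- function(x, ...) {
  cat(sprintf("<ring> size %d%s atoms {%s}\n", x$size,
              if (x$aromatic) " aromatic" else "",
              paste(x$atom_indices, collapse = ",")))
  invisible(x)
}

# biconnected components of the cyclic part: list of list(atoms, bonds)
cyclic_blocks <- function(m) {
  g <- mol_igraph(m)
  bc <- igraph::biconnected_components(g)
  out <- list()
  for (vs in bc$components) {
    v <- sort(as.integer(vs))
    if (length(v) < 3L) next
    b <- which(m$bonds$a1 %in% v & m$bonds$a2 %in% v)
    if (length(b) >= length(v)) {       # contains a cycle
      out[[length(out) + 1L]] <- list(atoms = v, bonds = b)
    }
  }
  out
}

# relevant cycles + MCB of one biconnected component, as global bond sets
component_cycles <- function(m, cp) {
  nb <- length(cp$bonds)
  nv <- length(cp$atoms)
  rank <- nb - nv + 1L
  if (rank == 1L) {
    return(list(relevant = list(cp$bonds), mcb = list(cp$bonds),
                forced_fallback = FALSE))
  }
  if (rank > .rank_cap) {
    basis <- horton_mcb(m, cp)
    return(list(relevant = basis, mcb = basis, forced_fallback = TRUE))
  }
  # local edge indexing
  a1 <- match(m$bonds$a1[cp$bonds], cp$atoms)
  a2 <- match(m$bonds$a2[cp$bonds], cp$atoms)
  fund <- fundamental_cycles(nv, a1, a2)
  stopifnot(length(fund) == rank)
  # enumerate the cycle space by Gray code
  cur <- rep(FALSE, nb)
  cycles <- list()
  lens <- integer()
  total <- bitwShiftL(1L, rank) - 1L
  prev_code <- 0L
  for (i in seq_len(total)) {
    code <- bitwXor(i, bitwShiftR(i, 1L))
    flip <- bitwXor(code, prev_code)
    j <- 1L + as.integer(round(log2(flip)))
    cur <- xor(cur, fund[[j]])
    prev_code <- code
    if (is_simple_cycle(cur, a1, a2, nv)) {
      cycles[[length(cycles) + 1L]] <- cur
      lens[length(lens) + 1L] <- sum(cur)
    }
  }
  ord <- order(lens)
  cycles <- cycles[ord]
  lens <- lens[ord]
  # relevant: not a sum of strictly shorter cycles; MCB: greedy independent
  basis <- list()        # reduced rows for "shorter" span
  relevant_idx <- integer()
  mcb_idx <- integer()
  mcb_basis <- list()
  i <- 1L
  nc <- length(cycles)
  while (i <= nc) {
    j <- i
    while (j <= nc && lens[j] == lens[i]) j <- j + 1L
    for (k in i:(j - 1L)) {
      if (!gf2_in_span(cycles[[k]], basis)) {
        relevant_idx <- c(relevant_idx, k)
      }
      if (length(mcb_idx) < rank) {
        red <- gf2_reduce(cycles[[k]], mcb_basis)
        if (any(red)) {
          mcb_basis[[length(mcb_basis) + 1L]] <- red
          mcb_idx <- c(mcb_idx, k)
        }
      }
    }
    for (k in i:(j - 1L)) {             # now add this length class to span
      red <- gf2_reduce(cycles[[k]], basis)
      if (any(red)) basis[[length(basis) + 1L]] <- red
    }
    i <- j
  }
  to_global <- function(v) cp$bonds[which(v)]
  list(relevant = lapply(cycles[relevant_idx], to_global),
       mcb = lapply(cycles[mcb_idx], to_global),
       forced_fallback = FALSE)
}

# fundamental cycles of a connected local graph (vertices 1..nv, edges
# a1/a2), as logical vectors over the local edges
fundamental_cycles <- function(nv, a1, a2) {
  ne <- length(a1)
  adj <- vector("list", nv)
  for (i in seq_len(ne)) {
    adj[[a1[i]]] <- rbind(adj[[a1[i]]], c(a2[i], i))
    adj[[a2[i]]] <- rbind(adj[[a2[i]]], c(a1[i], i))
  }
  parent <- integer(nv)
  parent_edge <- integer(nv)
  depth <- rep(-1L, nv)
  depth[1] <- 0L
  queue <- 1L
  tree_edge <- logical(ne)
  order_visited <- 1L
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    for (r in seq_len(nrow(adj[[v]]))) {
      w <- adj[[v]][r, 1]
      e <- adj[[v]][r, 2]
      if (depth[w] < 0L) {
        depth[w] <- depth[v] + 1L
        parent[w] <- v
        parent_edge[w] <- e
        tree_edge[e] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  fund <- list()
  for (e in which(!tree_edge)) {
    v <- a1[e]; w <- a2[e]
    vec <- logical(ne)
    vec[e] <- TRUE
    while (v != w) {
      if (depth[v] < depth[w]) { t <- v; v <- w; w <- t }
      vec[parent_edge[v]] <- xor(vec[parent_edge[v]], TRUE)
      v <- parent[v]
    }
    fund[[length(fund) + 1L]] <- vec
  }
  fund
}

# does this edge subset form one simple cycle?
is_simple_cycle <- function(vec, a1, a2, nv) {
  e <- which(vec)
  deg <- tabulate(c(a1[e], a2[e]), nbins = nv)
  touched <- which(deg > 0L)
  if (any(deg[touched] != 2L)) return(FALSE)
  if (length(e) != length(touched)) return(FALSE)
  # connectivity walk along the cycle
  adj <- vector("list", nv)
  for (i in e) {
    adj[[a1[i]]] <- c(adj[[a1[i]]], a2[i])
    adj[[a2[i]]] <- c(adj[[a2[i]]], a1[i])
  }
  start <- touched[1]
  prev <- 0L
  cur <- start
  steps <- 0L
  repeat {
    nxt <- adj[[cur]]
    nxt <- nxt[nxt != prev]
    if (!length(nxt)) return(FALSE)
    prev <- cur
    cur <- nxt[1]
    steps <- steps + 1L
    if (cur == start) break
    if (steps > length(e)) return(FALSE)
  }
  steps == length(e)
}

gf2_reduce <- function(vec, basis) {
  for (b in basis) {
    p <- which(b)[1]
    if (vec[p]) vec <- xor(vec, b)
  }
  vec
}

gf2_in_span <- function(vec, basis) {
  !any(gf2_reduce(vec, basis))
}

# Horton-style MCB for components of high circuit rank: shortest-path
# candidate cycles, greedy GF(2)-independent selection.
horton_mcb <- function(m, cp) {
  nv <- length(cp$atoms)
  a1 <- match(m$bonds$a1[cp$bonds], cp$atoms)
  a2 <- match(m$bonds$a2[cp$bonds], cp$atoms)
  ne <- length(a1)
  rank <- ne - nv + 1L
  adj <- vector("list", nv)
  for (i in seq_len(ne)) {
    adj[[a1[i]]] <- rbind(adj[[a1[i]]], c(a2[i], i))
    adj[[a2[i]]] <- rbind(adj[[a2[i]]], c(a1[i], i))
  }
  cand <- list()
  seen <- character()
  for (v in seq_len(nv)) {
    # BFS tree from v
    par <- integer(nv); par_e <- integer(nv); d <- rep(-1L, nv)
    d[v] <- 0L; queue <- v
    while (length(queue)) {
      x <- queue[1]; queue <- queue[-1]
      for (r in seq_len(nrow(adj[[x]]))) {
        w <- adj[[x]][r, 1]
        if (d[w] < 0L) {
          d[w] <- d[x] + 1L; par[w] <- x; par_e[w] <- adj[[x]][r, 2]
          queue <- c(queue, w)
        }
      }
    }
    path_edges <- function(x) {
      out <- integer()
      while (x != v) { out <- c(out, par_e[x]); x <- par[x] }
      out
    }
    path_vertices <- function(x) {
      out <- x
      while (x != v) { x <- par[x]; out <- c(out, x) }
      out
    }
    for (i in seq_len(ne)) {
      x <- a1[i]; y <- a2[i]
      px <- path_vertices(x); py <- path_vertices(y)
      if (length(intersect(px, py)) != 1L) next
      vec <- logical(ne)
      vec[c(path_edges(x), path_edges(y), i)] <- TRUE
      if (!is_simple_cycle(vec, a1, a2, nv)) next
      key <- paste(which(vec), collapse = ",")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        cand[[length(cand) + 1L]] <- vec
      }
    }
  }
  lens <- vapply(cand, sum, numeric(1))
  cand <- cand[order(lens)]
  basis <- list()
  chosen <- list()
  for (vec in cand) {
    if (length(chosen) >= rank) break
    red <- gf2_reduce(vec, basis)
    if (any(red)) {
      basis[[length(basis) + 1L]] <- red
      chosen[[length(chosen) + 1L]] <- cp$bonds[which(vec)]
    }
  }
  chosen
}
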