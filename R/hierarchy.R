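#' Scaffold trees, forests and networks
#'
#' `build_network()` unites the enumerative dissection results of a
#' molecule collection into one scaffold network (a directed acyclic
#' multi-parent hierarchy, possibly with several disconnected components).
#' `build_forest()` merges each molecule's Schuffenhauer chain into the
#' scaffold tree sharing its root scaffold, creating new trees as needed;
#' the list of trees is the scaffold forest.
#'
#' Every node records its origin molecules as SMILES strings (generated
#' with `settings$smiles_flavor`): a molecule is a *non-virtual* origin of
#' its original scaffold's node and a *virtual* origin of every proper
#' parent node. A node with only virtual origins is a virtual scaffold.
#' Ring-free molecules map to the empty-scaffold node.
#'
#' @param mols list of `mol_graph` objects (or a single one).
#' @param settings a [scaffold_settings()].
#' @return `build_network()`: a `scaffold_network`; `build_forest()`: a
#'   `scaffold_forest` (list of `scaffold_tree`s with pairwise distinct
#'   roots).
#' @examples
#' net <- build_network(parse_smiles(c("Cc1ccccc1", "c1ccccc1")))
#' node_frequencies(net)
#' @export
build_network <- function(mols, settings = scaffold_settings()) {
  if (inherits(mols, "mol_graph")) mols <- list(mols)
  net <- scaffold_network()
  for (m in mols) {
    res <- enumerate_parent_scaffolds(m, settings)
    mol_smi <- to_smiles(m, settings$smiles_flavor)
    net <- absorb_dissection(net, res, mol_smi)
  }
  net
}

#' @rdname build_network
#' @export
build_forest <- function(mols, settings = scaffold_settings()) {
  if (inherits(mols, "mol_graph")) mols <- list(mols)
  trees <- list()
  for (m in mols) {
    res <- schuffenhauer_chain(m, settings)
    mol_smi <- to_smiles(m, settings$smiles_flavor)
    root_key <- res$scaffolds[[length(res$scaffolds)]]$smiles_key
    hit <- which(vapply(trees, function(t) t$root_key == root_key,
                        logical(1)))
    tr <- if (length(hit)) trees[[hit[1]]] else scaffold_tree(root_key)
    tr <- absorb_dissection(tr, res, mol_smi)
    if (length(hit)) trees[[hit[1]]] <- tr else
      trees[[length(trees) + 1L]] <- tr
  }
  structure(list(trees = trees), class = "scaffold_forest")
}

#' Empty hierarchy constructors
#' @param root_key SMILES key of the tree root (for `scaffold_tree`).
#' @return an empty `scaffold_network` / `scaffold_tree`.
#' @export
scaffold_network <- function() {
  structure(list(nodes = list()), class = "scaffold_network")
}

#' @rdname scaffold_network
#' @export
scaffold_tree <- function(root_key = NULL) {
  structure(list(nodes = list(), root_key = root_key),
            class = "scaffold_tree")
}

new_node <- function(scaffold) {
  list(smiles_key = scaffold$smiles_key, scaffold = scaffold,
       parent_keys = character(), child_keys = character(),
       origins_nonvirtual = character(), origins_virtual = character())
}

# fold one dissection result (chain or closure) into a hierarchy; the
# first scaffold is the molecule's original scaffold (non-virtual origin)
absorb_dissection <- function(x, res, mol_smi) {
  for (i in seq_along(res$scaffolds)) {
    s <- res$scaffolds[[i]]
    k <- map_key(s$smiles_key)
    if (is.null(x$nodes[[k]])) x$nodes[[k]] <- new_node(s)
    if (i == 1L) {
      x$nodes[[k]]$origins_nonvirtual <-
        union(x$nodes[[k]]$origins_nonvirtual, mol_smi)
    } else {
      x$nodes[[k]]$origins_virtual <-
        union(x$nodes[[k]]$origins_virtual, mol_smi)
    }
  }
  if (nrow(res$edges)) {
    for (j in seq_len(nrow(res$edges))) {
      ck <- map_key(res$edges$child[j])
      pk <- map_key(res$edges$parent[j])
      x$nodes[[ck]]$parent_keys <- union(x$nodes[[ck]]$parent_keys,
                                         res$edges$parent[j])
      x$nodes[[pk]]$child_keys <- union(x$nodes[[pk]]$child_keys,
                                        res$edges$child[j])
    }
  }
  x
}

#' @export
print.scaffold_network <- function(x, ...) {
  cat(sprintf("<scaffold_network> %d nodes, %d virtual\n",
              length(x$nodes), sum(vapply(x$nodes, is_virtual_node,
                                          logical(1)))))
  invisible(x)
}

#' @export
print.scaffold_tree <- function(x, ...) {
  cat(sprintf("<scaffold_tree root=%s> %d nodes\n",
              if (is.null(x$root_key)) "<unset>" else
                if (nzchar(x$root_key)) x$root_key else "<empty>",
              length(x$nodes)))
  invisible(x)
}

#' @export
print.scaffold_forest <- function(x, ...) {
  cat(sprintf("<scaffold_forest> %d trees\n", length(x$trees)))
  for (t in x$trees) print(t)
  invisible(x)
}

is_virtual_node <- function(node) length(node$origins_nonvirtual) == 0L

#' Node keys of a hierarchy
#' @param x a `scaffold_tree`, `scaffold_network` or `scaffold_forest`.
#' @return character vector of SMILES keys (sorted, byte order).
#' @export
node_keys <- function(x) {
  if (inherits(x, "scaffold_forest")) {
    keys <- unlist(lapply(x$trees, node_keys))
    return(sort(unique(keys), method = "radix"))
  }
  keys <- vapply(x$nodes, function(n) n$smiles_key, character(1))
  sort(unname(keys), method = "radix")
}

#' Merge two scaffold hierarchies of the same type
#'
#' Node sets are united by SMILES key; parent/child links and origin sets
#' are united; levels are recomputed on demand. Trees can only be merged
#' when they share the same root key.
#'
#' @param x,y two `scaffold_network`s or two `scaffold_tree`s.
#' @param ... unused.
#' @return the merged hierarchy.
#' @export
merge.scaffold_network <- function(x, y, ...) {
  stopifnot(inherits(y, "scaffold_network"))
  merge_nodes(x, y)
}

#' @rdname merge.scaffold_network
#' @export
merge.scaffold_tree <- function(x, y, ...) {
  stopifnot(inherits(y, "scaffold_tree"))
  if (!is.null(x$root_key) && !is.null(y$root_key) &&
      !identical(x$root_key, y$root_key)) {
    stop("cannot merge scaffold trees with different roots", call. = FALSE)
  }
  out <- merge_nodes(x, y)
  out$root_key <- if (is.null(x$root_key)) y$root_key else x$root_key
  out
}

merge_nodes <- function(x, y) {
  for (k in names(y$nodes)) {
    if (is.null(x$nodes[[k]])) {
      x$nodes[[k]] <- y$nodes[[k]]
    } else {
      a <- x$nodes[[k]]; b <- y$nodes[[k]]
      a$parent_keys <- union(a$parent_keys, b$parent_keys)
      a$child_keys <- union(a$child_keys, b$child_keys)
      a$origins_nonvirtual <- union(a$origins_nonvirtual,
                                    b$origins_nonvirtual)
      a$origins_virtual <- union(a$origins_virtual, b$origins_virtual)
      x$nodes[[k]] <- a
    }
  }
  x
}

#' Validity of a scaffold tree
#'
#' A tree is valid when it has exactly one root (a node without parent),
#' every other node has exactly one parent, and the parent links form a
#' connected acyclic graph.
#'
#' @param t a `scaffold_tree`.
#' @return logical flag.
#' @export
is_valid_tree <- function(t) {
  if (!length(t$nodes)) return(FALSE)
  parents <- lapply(t$nodes, function(n) n$parent_keys)
  n_par <- vapply(parents, length, integer(1))
  roots <- names(t$nodes)[n_par == 0L]
  if (length(roots) != 1L) return(FALSE)
  if (any(n_par > 1L)) return(FALSE)
  # all parent links must resolve, and every node must reach the root
  for (k in names(t$nodes)) {
    seen <- character()
    cur <- k
    repeat {
      if (cur %in% seen) return(FALSE)     # cycle
      seen <- c(seen, cur)
      pk <- t$nodes[[cur]]$parent_keys
      if (!length(pk)) break
      cur <- map_key(pk[1])
      if (is.null(t$nodes[[cur]])) return(FALSE)   # orphan link
    }
    if (seen[length(seen)] != roots) return(FALSE)
  }
  TRUE
}

#' Node levels of a hierarchy
#'
#' Root scaffolds sit on level 0. In a tree, a child is one level below
#' its parent. In a network, a node's level is the longest parent-path
#' length from any root, which respects every parent-child edge even when
#' roots of different ring counts coexist.
#'
#' @param x a `scaffold_tree` or `scaffold_network`.
#' @return named integer vector (names are SMILES keys).
#' @export
node_levels <- function(x) {
  keys <- names(x$nodes)
  lev <- rep(NA_integer_, length(keys))
  names(lev) <- keys
  resolve <- function(k) {
    if (!is.na(lev[[k]])) return(lev[[k]])
    pk <- x$nodes[[k]]$parent_keys
    pk <- pk[vapply(pk, function(p) !is.null(x$nodes[[map_key(p)]]),
                    logical(1))]
    val <- if (!length(pk)) 0L else
      max(vapply(pk, function(p) resolve(map_key(p)), integer(1))) + 1L
    lev[[k]] <<- val
    val
  }
  for (k in keys) resolve(k)
  out <- unname(lev)
  names(out) <- vapply(x$nodes, function(n) n$smiles_key, character(1))
  out
}

#' Adjacency matrix of a hierarchy
#'
#' @param x a `scaffold_tree` or `scaffold_network`.
#' @return list with `keys` (sorted SMILES keys) and `matrix` (0/1 matrix;
#'   entry (i, j) is 1 when node i is a parent of node j).
#' @export
to_adjacency <- function(x) {
  keys <- node_keys(x)
  n <- length(keys)
  mat <- matrix(0L, n, n, dimnames = list(keys, keys))
  for (node in x$nodes) {
    j <- match(node$smiles_key, keys)
    for (p in node$parent_keys) {
      i <- match(p, keys)
      if (!is.na(i)) mat[i, j] <- 1L
    }
  }
  list(keys = keys, matrix = mat)
}

#' Scaffold frequencies
#'
#' The frequency of a node is its number of origin molecules, virtual and
#' non-virtual combined.
#'
#' @param x a `scaffold_tree` or `scaffold_network`.
#' @return named integer vector (names are SMILES keys, sorted).
#' @export
node_frequencies <- function(x) {
  keys <- node_keys(x)
  out <- vapply(keys, function(k) {
    n <- x$nodes[[map_key(k)]]
    length(union(n$origins_nonvirtual, n$origins_virtual))
  }, integer(1))
  names(out) <- keys
  out
}
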