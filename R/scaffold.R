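#' Extract a molecular scaffold
#'
#' Computes the scaffold of a molecule according to the mode in `settings`:
#'
#' * `MURCKO_FRAMEWORK` - all rings plus the acyclic linkers connecting
#'   them; terminal side chains removed.
#' * `SCAFFOLD` - the Murcko framework plus every atom attached to a ring
#'   or linker atom by a bond of order 2 or higher (exocyclic/exolinker
#'   multi-bonds shape hybridisation and synthetic accessibility).
#' * `ELEMENTAL_WIREFRAME` - Murcko framework with all bond orders set to
#'   1, elements kept.
#' * `BASIC_FRAMEWORK` - Murcko framework with all atoms carbon, bond
#'   orders kept.
#' * `BASIC_WIREFRAME` - all atoms carbon and all bonds single.
#'
#' A ring-free molecule yields the empty scaffold. When
#' `settings$determine_aromaticity` is `TRUE`, aromaticity is perceived on
#' the input and again on the extracted scaffold.
#'
#' @param mol a `mol_graph`.
#' @param settings a [scaffold_settings()].
#' @return An object of class `scaffold` with fields `graph`, `mode` and
#'   `smiles_key`.
#' @examples
#' sc <- extract_scaffold(parse_smiles("Cc1ccccc1"), scaffold_settings())
#' sc$smiles_key
#' @export
extract_scaffold <- function(mol, settings = scaffold_settings()) {
  g <- as_mol_graph(mol)
  g <- maybe_perceive(g, settings)
  fw <- framework_atom_set(g, settings$scaffold_mode)
  if (!length(fw$keep)) {
    return(new_scaffold(mol_graph(), settings, origin_atoms = integer()))
  }
  sub <- subgraph_atoms(g, fw$keep)
  sub <- apply_mode(sub, settings$scaffold_mode)
  sub <- maybe_perceive(sub, settings)
  new_scaffold(sub, settings, origin_atoms = sort(fw$keep))
}

new_scaffold <- function(graph, settings, origin_atoms = NULL) {
  key <- to_smiles(graph, settings$smiles_flavor)
  structure(list(graph = graph, mode = settings$scaffold_mode,
                 smiles_key = key, origin_atoms = origin_atoms),
            class = "scaffold")
}

#' @export
print.scaffold <- function(x, ...) {
  cat(sprintf("<scaffold mode=%s> %s (%d atoms)\n", x$mode,
              if (nzchar(x$smiles_key)) x$smiles_key else "<empty>",
              n_atoms(x)))
  invisible(x)
}

# atoms of the framework for the given mode: list(keep, framework, appended)
framework_atom_set <- function(g, mode) {
  cyc <- cyclic_atoms(g)
  if (!length(cyc)) {
    return(list(keep = integer(), framework = integer(),
                appended = integer()))
  }
  # iteratively strip terminal non-ring atoms; what remains is rings+linkers
  keep <- rep(TRUE, nrow(g$atoms))
  is_cyc <- seq_len(nrow(g$atoms)) %in% cyc
  repeat {
    deg <- integer(nrow(g$atoms))
    if (nrow(g$bonds)) {
      live <- keep[g$bonds$a1] & keep[g$bonds$a2]
      deg <- tabulate(c(g$bonds$a1[live], g$bonds$a2[live]),
                      nbins = nrow(g$atoms))
    }
    drop <- which(keep & !is_cyc & deg <= 1L)
    if (!length(drop)) break
    keep[drop] <- FALSE
  }
  framework <- which(keep)
  appended <- integer()
  if (mode == "SCAFFOLD" && nrow(g$bonds)) {
    for (i in seq_len(nrow(g$bonds))) {
      if (g$bonds$order[i] < 2L) next
      a <- g$bonds$a1[i]; b <- g$bonds$a2[i]
      if (keep[a] && !keep[b]) appended <- c(appended, b)
      if (keep[b] && !keep[a]) appended <- c(appended, a)
    }
    appended <- unique(appended)
  }
  list(keep = sort(c(framework, appended)), framework = framework,
       appended = appended)
}

# mode-specific post-processing of an extracted framework
apply_mode <- function(m, mode) {
  if (mode %in% c("SCAFFOLD", "MURCKO_FRAMEWORK")) return(m)
  if (mode %in% c("BASIC_FRAMEWORK", "BASIC_WIREFRAME")) {
    m$atoms$element <- "C"
    m$atoms$charge <- 0L
    m$atoms$isotope <- NA_integer_
  }
  if (mode %in% c("ELEMENTAL_WIREFRAME", "BASIC_WIREFRAME")) {
    if (nrow(m$bonds)) m$bonds$order <- 1L
  }
  if (nrow(m$bonds)) m$bonds$aromatic <- FALSE
  m$atoms$aromatic <- FALSE
  m$stereo <- list()      # abstracted representations carry no stereo
  recompute_hydrogens(m)
}

#' Scaffold building blocks: rings, linkers, terminal side chains
#'
#' `get_rings()` returns one fragment per detected ring (fused systems are
#' split; shared atoms and bonds appear in every ring they belong to).
#' `get_linkers()` returns the maximal acyclic connectors between rings; a
#' direct ring-ring bond is reported as a zero-atom fragment carrying the
#' bond in its `bond` attribute. `get_side_chains()` returns the maximal
#' fragments of the molecule outside its scaffold; a ring-free molecule is
#' returned whole as side chain.
#'
#' @param scaffold a `scaffold` (for `get_side_chains`: the input molecule).
#' @param settings a [scaffold_settings()].
#' @return list of objects of class `fragment` (fields `graph`, `kind`).
#' @examples
#' s <- extract_scaffold(parse_smiles("c1ccc2ccccc2c1"))
#' length(get_rings(s))  # 2
#' @export
get_rings <- function(scaffold, settings = scaffold_settings()) {
  g <- as_mol_graph(scaffold)
  if (!nrow(g$atoms)) return(list())
  rs <- detect_rings_graph(g)
  lapply(rs$rings, function(r) {
    fragment(subgraph_atoms(g, r$atom_indices, r$bond_indices), "ring")
  })
}

fragment <- function(graph, kind, bond = NULL) {
  structure(list(graph = graph, kind = kind, bond = bond),
            class = "fragment")
}

#' @export
print.fragment <- function(x, ...) {
  cat(sprintf("<fragment %s> %d atoms%s\n", x$kind, n_atoms(x$graph),
              if (!is.null(x$bond)) " (bond-only)" else ""))
  invisible(x)
}

#' @rdname get_rings
#' @export
get_linkers <- function(scaffold) {
  g <- as_mol_graph(scaffold)
  if (!nrow(g$atoms)) return(list())
  cyc <- cyclic_atoms(g)
  roles <- atom_roles(g)
  linker_atoms <- which(roles == "linker")
  out <- list()
  if (length(linker_atoms)) {
    sub_membership <- local_components(g, linker_atoms)
    for (k in seq_len(max(sub_membership))) {
      comp <- linker_atoms[sub_membership == k]
      out[[length(out) + 1L]] <-
        fragment(subgraph_atoms(g, comp), "linker")
    }
  }
  # zero-atom linkers: acyclic bonds directly joining two ring atoms
  cb <- cyclic_bonds(g)
  if (nrow(g$bonds)) {
    for (i in setdiff(seq_len(nrow(g$bonds)), cb)) {
      if (g$bonds$a1[i] %in% cyc && g$bonds$a2[i] %in% cyc) {
        out[[length(out) + 1L]] <-
          fragment(mol_graph(), "linker", bond = c(g$bonds$a1[i],
                                                   g$bonds$a2[i]))
      }
    }
  }
  out
}

# role of each scaffold atom: ring, linker, or appended (SCAFFOLD mode
# atoms attached by a non-single bond)
atom_roles <- function(g) {
  n <- nrow(g$atoms)
  roles <- rep("linker", n)
  cyc <- cyclic_atoms(g)
  roles[cyc] <- "ring"
  deg <- mol_degree(g)
  inc <- incident_bonds(g)
  for (a in which(roles == "linker")) {
    if (deg[a] == 1L && g$bonds$order[inc[[a]]] >= 2L) roles[a] <- "appended"
  }
  roles
}

# component membership restricted to a subset of atoms
local_components <- function(g, atoms) {
  if (!length(atoms)) return(integer())
  map <- match(seq_len(nrow(g$atoms)), atoms)
  el <- g$bonds[g$bonds$a1 %in% atoms & g$bonds$a2 %in% atoms, , drop = FALSE]
  ig <- igraph::make_empty_graph(n = length(atoms), directed = FALSE)
  if (nrow(el)) {
    ig <- igraph::add_edges(ig, rbind(map[el$a1], map[el$a2]))
  }
  igraph::components(ig)$membership
}

#' @rdname get_rings
#' @param mol the input molecule (for `get_side_chains`).
#' @export
get_side_chains <- function(mol, settings = scaffold_settings()) {
  g <- as_mol_graph(mol)
  if (!nrow(g$atoms)) return(list())
  sc <- extract_scaffold(g, settings)
  outside <- setdiff(seq_len(nrow(g$atoms)), sc$origin_atoms)
  if (!length(outside)) return(list())
  memb <- local_components(g, outside)
  lapply(seq_len(max(memb)), function(k) {
    fragment(subgraph_atoms(g, outside[memb == k]), "side_chain")
  })
}
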