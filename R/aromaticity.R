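#' Aromaticity models
#'
#' Aromaticity perception is pluggable: a model is a named function contract
#' that takes a `mol_graph` and returns it with aromatic flags set on atoms
#' and bonds, leaving the topology and Kekule bond orders untouched.
#' Perception must be deterministic and idempotent.
#'
#' The default model, `"hueckel"`, is a ring-based Hueckel heuristic: a
#' detected ring is aromatic when every ring atom can participate in the pi
#' system and the pi-electron count over the ring is 4n+2. Electron
#' contributions: an atom whose double bond lies in the ring contributes 1;
#' an atom whose double bond is exocyclic contributes 1 if the partner atom
#' is itself cyclic (fused-ring Kekule forms) and 0 otherwise (carbonyl-type
#' sinks); a neutral N/O/S/P/Se/As ring atom without any double bond
#' contributes its lone pair (2); a carbanion contributes 2 and a
#' carbocation 0; a saturated uncharged carbon blocks aromaticity.
#' Perimeter-only aromaticity (azulene-type systems) is not perceived by
#' this model; the model slot accepts any user function with the same
#' contract.
#'
#' @param perceive function `mol_graph -> mol_graph` setting aromatic flags.
#' @param name label used in outputs.
#' @return An object of class `aromaticity_model`.
#' @examples
#' m <- perceive_aromaticity(parse_smiles("C1=CC=CC=C1"))
#' all(m$atoms$aromatic)
#' @export
aromaticity_model <- function(perceive, name) {
  stopifnot(is.function(perceive), is.character(name))
  structure(list(perceive = perceive, name = name),
            class = "aromaticity_model")
}

#' @rdname aromaticity_model
#' @export
hueckel_model <- function() {
  aromaticity_model(hueckel_perceive, "hueckel")
}

#' Perceive aromaticity on a molecular graph
#'
#' Clears all aromatic flags and re-derives them with the given model.
#' Topology and bond orders are unchanged.
#'
#' @param mol a `mol_graph`.
#' @param model an [aromaticity_model()].
#' @return the graph with aromatic flags set.
#' @export
perceive_aromaticity <- function(mol, model = hueckel_model()) {
  g <- as_mol_graph(mol)
  out <- model$perceive(g)
  if (!identical(dim(out$atoms)[1], dim(g$atoms)[1]) ||
      !identical(dim(out$bonds)[1], dim(g$bonds)[1])) {
    stop("aromaticity model changed the molecule topology", call. = FALSE)
  }
  if (inherits(mol, "scaffold")) {
    mol$graph <- out
    mol
  } else {
    keep <- attributes(mol)
    for (a in setdiff(names(keep), c("names", "class"))) attr(out, a) <- keep[[a]]
    out
  }
}

hueckel_perceive <- function(m) {
  m$atoms$aromatic <- FALSE
  if (nrow(m$bonds)) m$bonds$aromatic <- FALSE
  if (!nrow(m$bonds)) return(m)
  rings <- ring_atom_bond_sets(m)
  if (!length(rings)) return(m)
  cyc_atoms <- cyclic_atoms(m)
  inc <- incident_bonds(m)

  contribution <- function(a, ring_bonds) {
    at <- m$atoms[a, ]
    dbl <- inc[[a]][m$bonds$order[inc[[a]]] >= 2L]
    if (length(dbl) && any(m$bonds$order[dbl] == 3L)) return(NA_integer_)
    if (length(dbl)) {
      in_ring <- dbl[dbl %in% ring_bonds]
      if (length(in_ring)) return(1L)
      partner <- vapply(dbl, function(bi)
        if (m$bonds$a1[bi] == a) m$bonds$a2[bi] else m$bonds$a1[bi],
        integer(1))
      if (any(partner %in% cyc_atoms)) return(1L)
      return(0L)
    }
    # no double bond anywhere: lone-pair donors or charged carbon
    if (at$element %in% c("N", "O", "S", "P", "Se", "As")) {
      if (at$charge <= 0L) return(2L)
      return(NA_integer_)
    }
    if (at$element %in% c("C", "Si", "B")) {
      if (at$charge < 0L) return(2L)
      if (at$charge > 0L) return(0L)
      return(NA_integer_)   # saturated carbon: not part of a pi system
    }
    NA_integer_
  }

  for (r in rings) {
    pe <- vapply(r$atoms, contribution, integer(1), ring_bonds = r$bonds)
    if (anyNA(pe)) next
    total <- sum(pe)
    if (total >= 2L && (total - 2L) %% 4L == 0L) {
      m$atoms$aromatic[r$atoms] <- TRUE
      m$bonds$aromatic[r$bonds] <- TRUE
    }
  }
  m
}

# Rings used for aromaticity perception: the relevant-cycle set (with MCB
# fallback), as atom/bond index lists.
ring_atom_bond_sets <- function(m) {
  rs <- detect_rings_graph(m)
  lapply(rs$rings, function(r) list(atoms = r$atom_indices,
                                    bonds = r$bond_indices))
}
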