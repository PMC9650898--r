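#' SMILES output flavor
#'
#' Controls how scaffold and molecule SMILES strings are generated. The
#' default matches the package-wide matching convention: unique (canonical)
#' SMILES with aromatic symbols, without stereochemistry and without
#' isotopes. Scaffold identity everywhere in this package is string equality
#' of these keys.
#'
#' @param unique canonicalise the output (identical graphs give identical
#'   strings regardless of atom numbering).
#' @param aromatic_symbols write aromatic atoms in lower case; if `FALSE`, a
#'   Kekule structure is written.
#' @param include_stereo encode tetrahedral stereo centres.
#' @param include_isotopes encode isotope labels.
#' @return A list of class `smiles_flavor`.
#' @examples
#' smiles_flavor(include_stereo = TRUE)
#' @export
smiles_flavor <- function(unique = TRUE, aromatic_symbols = TRUE,
                          include_stereo = FALSE, include_isotopes = FALSE) {
  structure(list(unique = isTRUE(unique),
                 aromatic_symbols = isTRUE(aromatic_symbols),
                 include_stereo = isTRUE(include_stereo),
                 include_isotopes = isTRUE(include_isotopes)),
            class = "smiles_flavor")
}

#' Generate a SMILES string for a molecular graph
#'
#' Serialises the graph to SMILES. With `flavor$unique = TRUE` (the default)
#' the string is canonicalised by Open Babel, so identical graphs yield
#' identical strings irrespective of atom order. The empty graph gives `""`.
#'
#' @param mol a `mol_graph` or `scaffold`.
#' @param flavor a [smiles_flavor()].
#' @return character scalar.
#' @examples
#' to_smiles(parse_smiles("C1=CC=CC=C1"))  # "c1ccccc1"
#' @export
to_smiles <- function(mol, flavor = smiles_flavor()) {
  raw <- write_smiles_raw(as_mol_graph(mol),
                          include_stereo = flavor$include_stereo,
                          include_isotopes = flavor$include_isotopes)
  if (!nzchar(raw)) return("")
  if (!flavor$unique) return(raw)
  canonicalize_smiles(raw, kekule = !flavor$aromatic_symbols)
}

# default flavor, callable from default arguments without name shadowing
default_smiles_flavor <- function() smiles_flavor()

# Canonicalise one or more (internally generated, hence valid) SMILES
# strings in a single Open Babel call. Empty strings pass through.
canonicalize_smiles <- function(smiles, kekule = FALSE) {
  out <- character(length(smiles))
  todo <- which(nzchar(smiles))
  if (!length(todo)) return(out)
  src <- paste0(paste(smiles[todo], collapse = "\n"), "\n")
  res <- if (kekule) {
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "CAN", src, options = data.frame(names = "k", args = "")))
  } else {
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", src))
  }
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- sub("[ \t]+$", "", lines)
  if (length(lines) != length(todo)) {
    stop("canonicalisation failed for ", length(todo) - length(lines),
         " structure(s)", call. = FALSE)
  }
  out[todo] <- lines
  out
}

# ---- raw (non-canonical) SMILES writer -------------------------------------
# DFS writer with ring-closure digits. Atoms are always written in brackets,
# which sidesteps implicit-valence ambiguity; Open Babel normalises the
# presentation during canonicalisation. Bond orders are written as a Kekule
# structure; aromatic lower-case output is produced by the canonicaliser.

.organic_lower <- c("B", "C", "N", "O", "P", "S", "Se", "As")

write_smiles_raw <- function(m, include_stereo = FALSE,
                             include_isotopes = FALSE) {
  if (!nrow(m$atoms)) return("")
  comp <- mol_components(m)
  parts <- vapply(seq_len(max(comp)), function(k) {
    write_component(m, which(comp == k), include_stereo, include_isotopes)
  }, character(1))
  paste(parts, collapse = ".")
}

write_component <- function(m, atoms_in_comp, include_stereo,
                            include_isotopes) {
  inc <- incident_bonds(m)
  n <- nrow(m$atoms)
  visited <- logical(n)
  bond_used <- logical(nrow(m$bonds))
  ring_digit <- list()   # per atom: list of (digit, partner) in writing order
  written_order <- list()  # neighbor order per atom, for stereo
  next_digit <- 0L
  open_digits <- list()  # digit -> c(a, b) pending closure

  stereo_by_atom <- list()
  if (include_stereo) {
    for (s in m$stereo) stereo_by_atom[[as.character(s$atom)]] <- s
  }

  other_end <- function(bi, a) {
    if (m$bonds$a1[bi] == a) m$bonds$a2[bi] else m$bonds$a1[bi]
  }
  bond_sym <- function(bi) {
    switch(m$bonds$order[bi], "", "=", "#")
  }

  # first pass: DFS to assign ring-closure bonds
  start <- min(atoms_in_comp)
  ring_bonds <- integer()
  stack <- list(list(atom = start, from_bond = 0L))
  visited_dfs <- logical(n)
  tree_children <- vector("list", n)  # bond indices, in visit order
  visit_dfs <- function(a) {
    visited_dfs[a] <<- TRUE
    for (bi in inc[[a]]) {
      if (bond_used[bi]) next
      b <- other_end(bi, a)
      if (visited_dfs[b]) {
        bond_used[bi] <<- TRUE
        ring_bonds <<- c(ring_bonds, bi)
      } else {
        bond_used[bi] <<- TRUE
        tree_children[[a]] <<- c(tree_children[[a]], bi)
        visit_dfs(b)
      }
    }
  }
  visit_dfs(start)

  # digits per atom: ring bond bi gets a digit, opened at the atom visited
  # first, closed at the other
  digit_of_bond <- integer(nrow(m$bonds))
  visit_seq <- integer(n)
  order_counter <- 0L
  number_visit <- function(a) {
    order_counter <<- order_counter + 1L
    visit_seq[a] <<- order_counter
    for (bi in tree_children[[a]]) number_visit(other_end(bi, a))
  }
  number_visit(start)
  if (length(ring_bonds)) {
    digit_of_bond[ring_bonds] <- seq_along(ring_bonds)
  }

  emit_atom <- function(a, prev) {
    at <- m$atoms[a, ]
    ring_here <- integer()
    for (bi in inc[[a]]) {
      if (digit_of_bond[bi] > 0L) ring_here <- c(ring_here, bi)
    }
    # neighbor order as written: prev, implicit H (inside bracket),
    # ring closures, then branches
    nbrs <- integer()
    if (prev > 0L) nbrs <- prev
    has_h_slot <- at$nh == 1L
    if (has_h_slot) nbrs <- c(nbrs, 0L)
    for (bi in ring_here) nbrs <- c(nbrs, other_end(bi, a))
    for (bi in tree_children[[a]]) nbrs <- c(nbrs, other_end(bi, a))

    stereo_tag <- ""
    key <- as.character(a)
    if (include_stereo && !is.null(stereo_by_atom[[key]])) {
      s <- stereo_by_atom[[key]]
      if (length(nbrs) == 4L && setequal(nbrs, s$neighbors)) {
        perm <- match(nbrs, s$neighbors)
        par <- s$parity
        if (permutation_sign(perm) < 0) par <- 3L - par
        stereo_tag <- if (par == 2L) "@" else "@@"
      }
    }

    sym <- at$element
    iso <- ""
    if (include_isotopes && !is.na(at$isotope)) iso <- as.character(at$isotope)
    hstr <- if (at$nh == 0L) "" else if (at$nh == 1L) "H" else paste0("H", at$nh)
    cstr <- if (at$charge == 0L) "" else if (at$charge > 0L)
      paste0(strrep("+", 1L), if (at$charge > 1L) at$charge else "")
    else paste0("-", if (at$charge < -1L) -at$charge else "")
    token <- paste0("[", iso, sym, stereo_tag, hstr, cstr, "]")
    ring_str <- ""
    for (bi in ring_here) {
      d <- digit_of_bond[bi]
      dsym <- if (visit_seq[other_end(bi, a)] > visit_seq[a]) bond_sym(bi) else ""
      # write the bond symbol on the opening side only
      opening <- visit_seq[a] < visit_seq[other_end(bi, a)]
      dsym <- if (opening) bond_sym(bi) else ""
      dtxt <- if (d > 9L) paste0("%", d) else as.character(d)
      ring_str <- paste0(ring_str, dsym, dtxt)
    }
    paste0(token, ring_str)
  }

  emit <- function(a, prev, via_bond) {
    pre <- if (via_bond > 0L) bond_sym(via_bond) else ""
    out <- paste0(pre, emit_atom(a, prev))
    kids <- tree_children[[a]]
    if (length(kids)) {
      for (i in seq_along(kids)) {
        bi <- kids[i]
        b <- other_end(bi, a)
        child <- emit(b, a, bi)
        if (i < length(kids)) child <- paste0("(", child, ")")
        out <- paste0(out, child)
      }
    }
    out
  }

  emit(start, 0L, 0L)
}

# sign of a permutation given as an integer vector
permutation_sign <- function(p) {
  n <- length(p)
  visited <- logical(n)
  sign <- 1L
  for (i in seq_len(n)) {
    if (!visited[i]) {
      len <- 0L
      j <- i
      while (!visited[j]) {
        visited[j] <- TRUE
        j <- p[j]
        len <- len + 1L
      }
      if (len %% 2L == 0L) sign <- -sign
    }
  }
  sign
}
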