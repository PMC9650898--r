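#' Random small drug-like molecules for property testing
#'
#' Assembles random molecules from a pool of ring systems (aromatic and
#' saturated, including fused, bridged and spiro blocks) joined by short
#' alkyl linkers or direct bonds, then decorated with common substituents
#' (methyl, hydroxyl, amino, halogen, carbonyl). Sizes are drug-like: one
#' to three ring blocks and up to three decorations per molecule. The
#' generator is deterministic for a fixed seed and only produces
#' valence-correct graphs; it emulates the connectivity statistics of
#' small-molecule libraries, not their full functional-group diversity.
#'
#' @param n number of molecules.
#' @param seed integer seed.
#' @return list of `mol_graph` objects.
#' @examples
#' mols <- random_molecules(5, seed = 1)
#' vapply(mols, to_smiles, character(1))
#' @export
random_molecules <- function(n, seed = 1L) {
  pool <- c(
    "c1ccccc1", "c1ccncc1", "c1cc[nH]c1", "c1ccoc1", "c1ccsc1",
    "c1cnc[nH]1", "C1CCCCC1", "C1CCCC1", "C1CC1", "C1CCNCC1", "C1CCOC1",
    "c1ccc2ccccc2c1", "C1CCC2CCCCC2C1", "C1Cc2ccccc2C1", "C1CC2CCC1C2",
    "C1CCC2(CC1)CCCC2", "O=C1CCCCC1", "C1CCC2OC2C1", "O=C1CCCN1"
  )
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  parsed <- lapply(pool, parse_smiles)   # value semantics: safe to reuse
  lapply(seq_len(n), function(i) random_molecule_once(parsed))
}

random_molecule_once <- function(pool) {
  k <- sample(1:3, 1, prob = c(0.35, 0.45, 0.2))
  blocks <- pool[sample.int(length(pool), k, replace = TRUE)]
  m <- blocks[[1]]
  if (k > 1L) {
    for (b in blocks[-1]) {
      m <- join_blocks(m, b, linker_len = sample(0:2, 1))
    }
  }
  for (d in seq_len(sample(0:3, 1))) {
    m <- decorate(m)
  }
  m
}

# attach graph b to m through `linker_len` CH2 atoms (0 = direct bond)
join_blocks <- function(m, b, linker_len = 0L) {
  a1 <- pick_open_atom(m)
  a2 <- pick_open_atom(b)
  if (is.na(a1) || is.na(a2)) return(m)
  off <- nrow(m$atoms)
  atoms <- rbind(m$atoms, b$atoms)
  bonds2 <- b$bonds
  bonds2$a1 <- bonds2$a1 + off
  bonds2$a2 <- bonds2$a2 + off
  bonds <- rbind(m$bonds, bonds2)
  out <- mol_graph(atoms, bonds, c(m$stereo, lapply(b$stereo, function(s) {
    nb <- s$neighbors
    nb[nb > 0L] <- nb[nb > 0L] + off
    stereo_center(s$atom + off, nb, s$parity)
  })))
  ends <- c(a1, a2 + off)
  if (linker_len > 0L) {
    for (j in seq_len(linker_len)) {
      out$atoms <- rbind(out$atoms,
                         data.frame(element = "C", charge = 0L, nh = 4L,
                                    aromatic = FALSE,
                                    isotope = NA_integer_))
    }
    chain <- nrow(out$atoms) - linker_len + seq_len(linker_len)
    path <- c(ends[1], chain, ends[2])
    for (j in seq_len(length(path) - 1L)) {
      out <- add_single_bond(out, path[j], path[j + 1L])
    }
  } else {
    out <- add_single_bond(out, ends[1], ends[2])
  }
  out
}

# an atom with a free hydrogen to substitute
pick_open_atom <- function(m, need = 1L) {
  open <- which(m$atoms$nh >= need)
  if (!length(open)) return(NA_integer_)
  open[sample.int(length(open), 1)]
}

add_single_bond <- function(m, a, b) {
  if (m$atoms$nh[a] < 1L || m$atoms$nh[b] < 1L) return(m)
  m$bonds <- rbind(m$bonds, data.frame(a1 = min(a, b), a2 = max(a, b),
                                       order = 1L, aromatic = FALSE))
  m$atoms$nh[a] <- m$atoms$nh[a] - 1L
  m$atoms$nh[b] <- m$atoms$nh[b] - 1L
  # substitution breaks any stereo bookkeeping at these atoms
  m$stereo <- Filter(function(s) !(s$atom %in% c(a, b)) &&
                       !any(s$neighbors %in% c(a, b)), m$stereo)
  m
}

decorate <- function(m) {
  kind <- sample(c("CH3", "OH", "NH2", "Cl", "F", "carbonyl"), 1)
  if (kind == "carbonyl") {
    host <- which(m$atoms$element == "C" & !m$atoms$aromatic &
                    m$atoms$nh >= 2L)
    if (!length(host)) return(m)
    a <- host[sample.int(length(host), 1)]
    m$atoms <- rbind(m$atoms, data.frame(element = "O", charge = 0L,
                                         nh = 0L, aromatic = FALSE,
                                         isotope = NA_integer_))
    o <- nrow(m$atoms)
    m$bonds <- rbind(m$bonds, data.frame(a1 = a, a2 = o, order = 2L,
                                         aromatic = FALSE))
    m$atoms$nh[a] <- m$atoms$nh[a] - 2L
    m$stereo <- Filter(function(s) s$atom != a, m$stereo)
    return(m)
  }
  el <- switch(kind, CH3 = c("C", 4L), OH = c("O", 2L), NH2 = c("N", 3L),
               Cl = c("Cl", 1L), F = c("F", 1L))
  a <- pick_open_atom(m)
  if (is.na(a)) return(m)
  m$atoms <- rbind(m$atoms, data.frame(element = el[1],
                                       charge = 0L,
                                       nh = as.integer(el[2]),
                                       aromatic = FALSE,
                                       isotope = NA_integer_))
  add_single_bond(m, a, nrow(m$atoms))
}
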