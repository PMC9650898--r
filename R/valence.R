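# Implicit-hydrogen model: MDL-style default valences with charge adjustment.
# Used when molecules are read from Kekule ctabs and when scaffold operations
# recompute hydrogen counts after bond-order changes.

.default_valences <- list(
  H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L,
  Si = 4L, P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L,
  As = c(3L, 5L), Se = c(2L, 4L, 6L), Br = 1L, I = 1L
)

# effective valence options for an element with a formal charge
element_valences <- function(element, charge = 0L) {
  v <- .default_valences[[element]]
  if (is.null(v)) return(integer())   # metals etc.: no implicit hydrogens
  if (charge != 0L) {
    shift <- if (element %in% c("N", "P", "O", "S", "As", "Se")) {
      charge            # cations gain a bond, anions lose one
    } else if (element %in% c("C", "Si", "B")) {
      -abs(charge)      # carbanion/carbocation and borate all drop valence
    } else {
      -abs(charge)
    }
    v <- v + shift
    v <- v[v >= 0L]
  }
  v
}

# implicit hydrogen count given the sum of bond orders at the atom
implicit_h_count <- function(element, charge, bond_order_sum) {
  v <- element_valences(element, charge)
  v <- v[v >= bond_order_sum]
  if (!length(v)) return(0L)
  as.integer(min(v) - bond_order_sum)
}

# recompute nh for every atom from the current bond table
recompute_hydrogens <- function(m) {
  m <- as_mol_graph(m)
  if (!nrow(m$atoms)) return(m)
  bsum <- integer(nrow(m$atoms))
  if (nrow(m$bonds)) {
    for (i in seq_len(nrow(m$bonds))) {
      bsum[m$bonds$a1[i]] <- bsum[m$bonds$a1[i]] + m$bonds$order[i]
      bsum[m$bonds$a2[i]] <- bsum[m$bonds$a2[i]] + m$bonds$order[i]
    }
  }
  m$atoms$nh <- mapply(implicit_h_count, m$atoms$element, m$atoms$charge,
                       bsum, USE.NAMES = FALSE)
  m
}
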