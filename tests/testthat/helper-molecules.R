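# shared shortcuts for the test suite

default_settings <- scaffold_settings()
murcko_settings <- scaffold_settings(scaffold_mode = "MURCKO_FRAMEWORK")

# canonical key of a SMILES under the default flavor
canon <- function(smiles, flavor = smiles_flavor()) {
  to_smiles(parse_smiles(smiles), flavor)
}

scaffold_keys <- function(res) {
  vapply(res$scaffolds, function(s) s$smiles_key, character(1))
}

ring_count <- function(x) length(detect_rings(x)$rings)

# circuit rank of the cyclic part: bonds - atoms + components, summed over
# the cyclic blocks (independent oracle for MCB ring counts)
circuit_rank <- function(m) {
  g <- if (inherits(m, "scaffold")) m$graph else m
  if (!n_bonds(g)) return(0L)
  ig <- igraph::graph_from_edgelist(cbind(g$bonds$a1, g$bonds$a2),
                                    directed = FALSE)
  if (igraph::vcount(ig) < n_atoms(g)) {
    ig <- igraph::add_vertices(ig, n_atoms(g) - igraph::vcount(ig))
  }
  # drop isolated/acyclic parts: rank is invariant, compute globally
  as.integer(n_bonds(g) - n_atoms(g) + igraph::components(ig)$no)
}

# molecules used by several property suites (fixed seed, modest n)
property_molecules <- function(n = 60, seed = 421L) {
  random_molecules(n, seed = seed)
}
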