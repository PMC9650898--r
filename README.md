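# scaffoldTrees

Molecular scaffold extraction, dissection and scaffold tree/network
construction in R.

Medicinal chemists and cheminformaticians analyse compound collections
through their *scaffolds* — the ring systems of a molecule plus the
linkers connecting them, with terminal side chains removed. This package
implements the full scaffold-hierarchy workflow:

* **Five scaffold representations**: the scaffold (Murcko framework plus
  all atoms attached to rings/linkers by non-single bonds), the Murcko
  framework itself, and three abstractions — elemental wireframe (all
  bonds single), basic framework (all atoms carbon) and basic wireframe
  (both).
* **Building blocks**: rings (fused systems split into their constituent
  relevant cycles), linkers (including zero-atom direct ring–ring bonds)
  and terminal side chains.
* **Ring perception**: relevant cycles — the union of all minimum cycle
  bases (SSSR) — with automatic fallback to a single minimum cycle basis
  when more rings are detected than the structure has atoms.
* **Parent scaffold generation**: either the enumerative closure of all
  admissible single-ring removals, or a deterministic chain selected by
  the 13 Schuffenhauer prioritisation rules. Ring removal honours
  terminality, exclusive-atom, anti-spiro and aromatic-sharing guards,
  and repairs bond orders (aromatic fusion bonds and opened
  three-membered heterocycles become double bonds; sp2 centres are
  preserved, optionally for aromatic systems only).
* **Hierarchies**: scaffold networks (multi-parent DAGs), scaffold trees
  (single-parent, one per root scaffold) and forests, with merging,
  validity checking, level assignment, virtual/non-virtual origin
  tracking, frequency counts, and adjacency/TSV/DOT/GraphML export.
* **A snapshot protocol** over SD files (import, >10-ring filter, both
  dissections, forest/network builds over growing fractions, frequency
  export) plus a thin command-line front end.

Molecule I/O (SDF, SMILES) and canonical SMILES generation are built on
ChemmineR/ChemmineOB (Open Babel); graph algorithms use igraph. Scaffold
identity everywhere is string equality of unique SMILES keys under a
configurable flavor (aromatic symbols on, stereo and isotopes off by
default).

## Worked example

```r
library(scaffoldTrees)

st <- scaffold_settings()           # defaults: SCAFFOLD mode, Hueckel
                                    # aromaticity, rule 7 on
dia <- fixture("diazepam")

# deterministic dissection chain down to the root scaffold
vapply(schuffenhauer_chain(dia, st)$scaffolds,
       function(s) s$smiles_key, character(1))
#> [1] "O=C1CN=C(c2c(N1)cccc2)c1ccccc1" "O=C1CN=Cc2c(N1)cccc2"
#> [3] "O=C1CN=CC=CN1"
```

The three lines are the original scaffold of diazepam (three rings), the
two-ring parent after the pendant phenyl is removed (rule 3: fewest
acyclic linker bonds), and the root scaffold: the seven-membered
diazepinenone ring, with a double bond inserted where the fused benzene
ring was cleaved so the nitrogen-bearing ring keeps its hybridisation.

```r
trio <- list(fixture("diazepam"), fixture("bromazepam"),
             fixture("zolazepam"))
forest <- build_forest(trio, st)
length(forest$trees)                       # 1  — all share one root
network <- build_network(trio, st)
node_frequencies(network)[["c1ccccc1"]]    # 3  — benzene in all three
```

All three anxiolytics collapse into a single scaffold tree rooted at the
diazepinenone ring, while the network additionally reveals the shared
two-ring parents and the benzene ring common to all three compounds.

```r
export_frequencies(network, "network_frequencies.tsv")
rep <- run_snapshot("molecules.sdf", n_fractions = 2, out_dir = "out")
```

A command-line front end wrapping these functions is installed at
`system.file("scripts", "scaffold-cli", package = "scaffoldTrees")`, with
`snapshot`, `dissect` and `build` subcommands.

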