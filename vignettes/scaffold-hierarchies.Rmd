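---
title: "Molecular scaffold hierarchies: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular scaffold hierarchies: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffoldTrees)
```

## The scaffold concept

Medicinal chemists organise compound collections by their *scaffolds*: the
ring systems of a molecule together with the acyclic linkers that connect
them, with terminal side chains stripped away. Hierarchies over scaffolds
-- scaffold trees and scaffold networks -- make large collections
navigable: a multi-ring scaffold is dissected ring by ring into ever
smaller *parent scaffolds*, down to single-ring *root scaffolds*, and
molecules sharing parents end up close to each other in the hierarchy.
This package implements that whole pipeline: scaffold extraction in five
representations, ring perception, rule-guided and exhaustive ring removal,
and tree/forest/network containers with origin tracking and export.

## Scaffold representations

`extract_scaffold()` supports five modes. The *Murcko framework* keeps
rings and linkers only. The default *scaffold* mode additionally keeps
every atom attached to a ring or linker atom through a bond of order two
or higher: exocyclic and exolinker multi-bonds change hybridisation and
synthetic accessibility, so discarding them merges chemically distinct
scaffolds. Triple bonds are treated like double bonds here -- they are
rare in such positions but just as consequential. Three abstractions
complete the set: *elemental wireframe* (all bonds single), *basic
framework* (all atoms carbon) and *basic wireframe* (both). The
abstractions operate on the bare Murcko framework: in an all-single-bond
representation a pendant atom that was appended for its double bond would
be meaningless, so appended atoms are only ever part of the default
scaffold mode. The three abstractions commute (the basic wireframe of an
elemental wireframe equals the basic wireframe of the molecule), which
the test suite checks as an invariant. Abstracted modes also drop charges
only where the element is rewritten (basic modes); the elemental
wireframe keeps charges so that valences stay interpretable.

```{r modes}
st <- scaffold_settings()
flx <- fixture("flucloxacillin")
for (mode in c("SCAFFOLD", "MURCKO_FRAMEWORK", "BASIC_WIREFRAME")) {
  s <- extract_scaffold(flx, scaffold_settings(scaffold_mode = mode))
  cat(sprintf("%-18s %s\n", mode, s$smiles_key))
}
```

A molecule without rings has no scaffold; the empty scaffold (empty graph,
empty SMILES key) is a legal value and a legal hierarchy node, so that
ring-free molecules remain countable in frequency analyses.

## Ring perception

Rings are detected as *relevant cycles*: the union of all minimum cycle
bases (all SSSR) of the graph. This splits fused systems into their
constituent rings without the arbitrariness of a single SSSR. Relevant
cycles are computed exactly per biconnected component by enumerating the
GF(2) cycle space over a fundamental basis and keeping every simple cycle
that is not a sum of strictly shorter cycles. Molecular graphs keep this
cheap: the circuit rank of one ring system rarely exceeds a handful. A
component whose rank exceeds 15 skips the enumeration and uses a minimum
cycle basis directly; with at most 2^15 combinations below that cap, the
bound was chosen comfortably above anything drug-like that survives the
snapshot protocol's >10-ring filter.

In rare topologies -- interlocking macrocycles, cages -- the relevant set
explodes. Whenever more rings are detected than the structure has atoms,
the detector falls back to a single minimum cycle basis, whose size equals
the circuit rank (bonds − atoms + components). The synthetic octahedral C6
cage fixture shows the behaviour:

```{r rings}
cage <- fixture("octahedral_cage_synthetic")
detect_rings(cage)          # falls back: 8 relevant triangles > 6 atoms
length(detect_rings(fixture("adamantane"))$rings)  # 4 relevant rings
```

## Ring removal

Only rings passing four guards are removed during dissection:

1. **Terminal**: deleting the ring's exclusive atoms and bonds (those not
   shared with any other ring), after discarding fragments that are pure
   side chains, must leave one connected ring-bearing component. Turning
   former ring atoms into linker atoms does not count -- the central ring
   of dodecahydro-s-indacene is therefore not terminal.
2. **Owns an atom**: at least one atom must belong to this ring alone.
   In adamantane every atom lies in two relevant rings, so adamantane is
   never dissected.
3. **No artificial spiro junction**: a removal must not leave a spiro
   junction that was absent before. Spiro junctions are detected as
   articulation points contained in two or more cyclic blocks; exactly
   one removal path of tricyclo[7.2.1.0(1,6)]dodecane is blocked by this
   guard.
4. **Aromatic sharing**: an aromatic ring sharing an atom with two or
   more other rings is not removable, because the double-bond repair
   below would violate valence. This is why most fused aromatics
   (pyrene) are never dissected -- partial dissection would not give
   meaningful parents. Whether the two other rings must share the *same*
   atom is not fully determined; the implementation reads it as "some
   atom of the ring lies in two or more other rings" and documents the
   choice as provisional.

Removal deletes the exclusive atoms/bonds, prunes side chains orphaned by
the removal, and then repairs bond orders: (1) if the removed ring was
aromatic and shared exactly one bond with one remaining ring, that bond
becomes a double bond -- also when the remaining ring is aromatic, so
dissected aromatic systems always remain representable as a valid
contributing structure rather than a resonance hybrid; (2) a removed
three-membered ring with exactly one heteroatom whose shared bond lies
opposite that heteroatom leaves a double bond behind (the likely
precursor of an epoxidation/aziridination); (3) unless
`retain_only_hybridisations_at_aromatic_bonds` is set, any formerly
shared single bond whose two atoms would both lose sp2 character gains a
double bond when valence permits. Since the graph stores bond orders, not
hybridisations, "losing sp2" is inferred: an atom loses sp2 when its only
non-single or aromatic bonds belonged to the removed ring. When several
shared bonds qualify for repair (3) they are processed in canonical bond
order, and each repair is applied only if both atoms still have a
hydrogen to give -- determinism and valence safety decide ties.

```{r removal}
hhq <- fixture("hexahydroisoquinoline")
for (retain in c(FALSE, TRUE)) {
  s <- scaffold_settings(retain_only_hybridisations_at_aromatic_bonds = retain)
  sc <- extract_scaffold(hhq, s)
  rings <- detect_rings(sc)$rings
  carbo <- rings[[which(vapply(rings, function(r)
    sum(r$heteroatom_counts), integer(1)) == 0)]]
  cat(sprintf("retain=%-5s -> %s\n", retain,
              remove_ring(sc, carbo, s)$smiles_key))
}
```

## The prioritisation rules

`schuffenhauer_chain()` selects exactly one removable ring per step with
13 ordered rules, applied as filters: a rule replaces the candidate set by
its selection only when that selection is non-empty, and filtering stops
as soon as one candidate remains. In brief: (1) three-membered
heterocycles go first; (2) rings of twelve or more atoms are kept while
smaller ones exist; (3) prefer the parent with the fewest acyclic linker
bonds; (4) retain bridged, spiro and nonlinearly fused assemblies, via
the descriptor delta = nrrb − (nR − 1) computed on the candidate *parent*
(nrrb = bonds shared by two or more rings, nR = ring count; 0 means
linear fusion, positive bridged, negative spiro) -- candidates maximising
|delta| survive; (5) bridged beats spiro (delta > 0 preferred); (6) rings
of size 3, 5 or 6 are removed first; (7) a fully aromatic ring system
must not lose aromaticity in any remaining ring (this requires perceiving
every candidate parent, so it is toggleable and skipped automatically
when aromaticity perception is off); (8) fewest heteroatoms first;
(9) ties resolved by minimising N, then O, then S; (10) smaller rings
first; (11) in mixed aromatic/nonaromatic systems the nonaromatic rings
are retained, i.e. aromatic candidates are removed first; (12) rings
whose linker touches a ring heteroatom go first -- operationalised as "a
linker bond incident to the candidate ring touches a heteroatom that is a
ring atom", a provisional reading documented in the code; (13) the final
tie-break takes the candidate whose parent has the byte-wise smallest
unique SMILES. Byte order over canonical SMILES is an arbitrary but total
order; any fixed direction gives the determinism the chain needs, which
the property tests assert by re-running every chain.

Delta is computed on the remaining scaffold rather than the removed ring
because the rules' intent is to *retain* characteristic assemblies:
what matters is the shape of what is left.

```{r chain}
vapply(schuffenhauer_chain(fixture("diazepam"))$scaffolds,
       function(s) s$smiles_key, character(1))
```

`enumerate_parent_scaffolds()` instead performs every admissible removal
breadth-first until single-ring scaffolds remain, de-duplicating globally
by SMILES key: a scaffold reachable at two depths is a single node.

## Aromaticity

Aromaticity enters in four places: the removability guard, repair (1),
and rules 7 and 11. Perception runs on the input molecule, on the primary
scaffold, and again on every generated parent, so stored flags always
match the returned structure. The model is pluggable
(`aromaticity_model()`): any deterministic, idempotent function setting
aromatic flags can be injected, and the default is a ring-based Hückel
heuristic (`"hueckel"`): a ring is aromatic when every atom contributes
to the pi system (in-ring double bond: 1 electron; exocyclic double bond
to a cyclic atom: 1; to a terminal atom such as carbonyl oxygen: 0;
lone-pair heteroatom: 2; carbanion 2, carbocation 0; saturated carbon
blocks) and the total is 4n+2. The heuristic perceives benzene, pyridine,
pyrrole, thiophene, isoxazole and fused polycyclics correctly; it does
not perceive perimeter-only aromaticity (azulene-type), which is the
documented price of a per-ring model. Aromaticity is not uniquely defined
and every toolkit's model differs; results that depend on it should be
read with the model name in mind, which is why the model is named in the
settings and injectable.

With `determine_aromaticity = FALSE` no perception ever runs (the test
suite verifies this with a counting model), input flags are preserved,
and rule 7 is automatically excluded.

## SMILES keys and matching

Scaffold identity is *string equality of unique SMILES keys* under the
configured `smiles_flavor()` -- never graph isomorphism at merge time.
The default flavor encodes aromaticity but neither stereochemistry nor
isotopes; stereo-aware keys can be requested, in which case enantiomeric
scaffolds become distinct hierarchy nodes. Canonicalisation is delegated
to Open Babel (via ChemmineOB) from a Kekulé serialisation written by the
package; canonical strings are stable within a run and across runs of the
same toolkit version, but equality with other toolkits' canonical SMILES
is not promised. Tetrahedral stereo centres are transferred through
extraction and removal whenever all defining atoms survive;
double-bond (cis/trans) descriptors are not modelled -- a known
limitation.

## Hierarchies

Scaffold networks unite the enumerative closures of all molecules;
scaffold trees unite Schuffenhauer chains sharing a root, and a molecule
set with several roots yields a forest. Origins are stored as SMILES
strings rather than molecule objects (memory-friendly, and sufficient for
joining external annotations). A node whose non-virtual origin set is
empty is a *virtual scaffold* -- never an input molecule's own scaffold,
only generated; such nodes are promising hypotheses in screening
analysis. Tree levels count down from the root (level 0); network levels
are defined as the longest parent-path from any root, a deterministic
layering that respects every edge even when roots with different ring
counts coexist (the alternative, ring-count layering, is not decidable
from first principles and breaks when a multi-ring root such as
adamantane meets single-ring roots). Merging unites node sets by key;
tree merges require equal roots. The containers are not thread-safe.

## The snapshot protocol and exports

`run_snapshot()` imports an SD file, discards molecules with more than
ten rings (using the same ring detector as dissection, so the filter is
consistent with downstream behaviour), dissects everything both ways,
builds forest and network over growing fraction unions with timing logged
to stderr, and exports scaffold frequencies as TSV. Timing numbers are
logged but never asserted anywhere -- they are hardware facts, not
chemistry. Exports are sorted (frequency descending, SMILES ascending)
and byte-identical across runs.

## Synthetic test data

`random_molecules()` assembles molecules from a pool of ring systems
(aromatic heterocycles, carbocycles, fused/bridged/spiro blocks) joined
by short alkyl linkers and decorated with common substituents, all
valence-checked, deterministic under a seed. It emulates the ring-count
and connectivity statistics of small drug-like compounds -- one to three
ring blocks, up to three decorations -- but not tautomerism, charge
states, macrocycles or stereo-rich natural products; property tests
passing on this population demonstrate the algebraic invariants
(ring-count decrements, connectivity, chain-within-closure, merge
order-independence), not coverage of every chemistry corner case. The
test suite and the acceptance script run these suites at 40-200 molecules,
sizes chosen so the whole battery completes in minutes on one core while
still exercising several hundred distinct removals.

## Known limitations

* Cis/trans double-bond stereo is not represented.
* The default aromaticity model misses perimeter-only aromatic systems.
* Canonical SMILES equality across different toolkits is not guaranteed.
* Dissection of fused aromatic systems into partial aromatics is
  deliberately not attempted (no meaningful parents); a future extension
  could extract e.g. benzene from pyrene.
* Input structures are used as given: no tautomer or protonation
  standardisation is applied, by design -- curation belongs upstream.
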