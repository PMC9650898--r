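# Bundled reference structures used in examples and tests. SMILES are
# pinned for well-known compounds; the octahedral C6 cage is a synthetic
# graph (not a real compound) exercising the MCB fallback, built directly
# from its bond list.

.fixture_smiles <- c(
  flucloxacillin =
    "CC1=C(C(=NO1)C2=CC=CC=C2Cl)C(=O)NC3C(=O)N4C3SC(C)(C)C4C(=O)O",
  adamantane = "C1C2CC3CC1CC(C2)C3",
  pyrene = "c1cc2ccc3cccc4ccc(c1)c2c34",
  anthracene = "c1ccc2cc3ccccc3cc2c1",
  dodecahydro_s_indacene = "C1CC2CC3CCCC3CC2C1",
  tricyclododecane = "C1CCC23C(C1)CCC(C3)CC2",
  diazepam = "CN1C(=O)CN=C(c2ccccc2)c2cc(Cl)ccc21",
  bromazepam = "O=C1CN=C(c2ccccn2)c2cc(Br)ccc2N1",
  zolazepam = "CC1=NN(C)C2=C1C(=NCC(=O)N2C)C1=CC=CC=C1F",
  thalidomide_plus = "O=C1CC[C@@H](N2C(=O)c3ccccc3C2=O)C(=O)N1",
  thalidomide_minus = "O=C1CC[C@H](N2C(=O)c3ccccc3C2=O)C(=O)N1",
  hexahydroisoquinoline = "C1NCCC2=CCCC=C12",
  naphthalene = "c1ccc2ccccc2c1",
  decalin = "C1CCC2CCCCC2C1",
  benzene = "c1ccccc1",
  toluene = "Cc1ccccc1",
  cyclohexane = "C1CCCCC1",
  cyclohexanone = "O=C1CCCCC1",
  biphenyl = "c1ccc(-c2ccccc2)cc1",
  diphenylmethane = "C(c1ccccc1)c1ccccc1",
  oxabicycloheptane = "C1CCC2OC2C1",
  pyridine = "c1ccncc1",
  hexane = "CCCCCC"
)

#' Bundled fixture molecules
#'
#' Returns one of the reference structures used throughout the package's
#' examples and tests, parsed into a `mol_graph`. `fixture_names()` lists
#' the registry. The `octahedral_cage_synthetic` entry is not a chemical
#' compound but a 4-regular C6 graph whose relevant-cycle count (8
#' triangles) exceeds its atom count, exercising the MCB fallback.
#'
#' @param name registry name, e.g. `"adamantane"`.
#' @return a `mol_graph`.
#' @examples
#' n_atoms(fixture("adamantane"))  # 10
#' @export
fixture <- function(name) {
  if (identical(name, "octahedral_cage_synthetic")) {
    atoms <- data.frame(element = rep("C", 6), charge = 0L, nh = 0L,
                        aromatic = FALSE, isotope = NA_integer_)
    bonds <- data.frame(a1 = c(1, 1, 1, 1, 2, 2, 2, 3, 3, 4, 4, 5),
                        a2 = c(2, 3, 4, 5, 3, 4, 6, 5, 6, 5, 6, 6),
                        order = 1L, aromatic = FALSE)
    return(mol_graph(atoms, bonds))
  }
  if (!(name %in% names(.fixture_smiles))) {
    stop("unknown fixture: ", name, call. = FALSE)
  }
  parse_smiles(.fixture_smiles[[name]])
}

#' @rdname fixture
#' @export
fixture_names <- function() {
  c(names(.fixture_smiles), "octahedral_cage_synthetic")
}
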