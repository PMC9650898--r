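test_that("ring-free molecules yield the empty scaffold", {
  s <- extract_scaffold(fixture("hexane"), default_settings)
  expect_identical(n_atoms(s), 0L)
  expect_identical(s$smiles_key, "")
})

test_that("exocyclic double bonds are kept only in SCAFFOLD mode", {
  keto <- fixture("cyclohexanone")
  expect_identical(extract_scaffold(keto, murcko_settings)$smiles_key,
                   canon("C1CCCCC1"))
  expect_identical(extract_scaffold(keto, default_settings)$smiles_key,
                   canon("O=C1CCCCC1"))
})

test_that("abstracting modes follow their definitions on pyridine", {
  p <- fixture("pyridine")
  expect_identical(
    extract_scaffold(p, scaffold_settings("ELEMENTAL_WIREFRAME"))$smiles_key,
    canon("C1CCNCC1"))
  expect_identical(
    extract_scaffold(p, scaffold_settings("BASIC_WIREFRAME"))$smiles_key,
    canon("C1CCCCC1"))
  expect_identical(
    extract_scaffold(p, scaffold_settings("BASIC_FRAMEWORK"))$smiles_key,
    canon("c1ccccc1"))
})

test_that("flucloxacillin scaffolds match hand-constructed expectations", {
  flx <- fixture("flucloxacillin")
  # Murcko framework: four rings, the amide linker carbon without its O
  expect_identical(
    extract_scaffold(flx, murcko_settings)$smiles_key,
    canon("C1=C(C(=NO1)C2=CC=CC=C2)CNC3CN4C3SCC4"))
  # scaffold: additionally both carbonyl O (amide and beta-lactam)
  expect_identical(
    extract_scaffold(flx, default_settings)$smiles_key,
    canon("C1=C(C(=NO1)C2=CC=CC=C2)C(=O)NC3C(=O)N4C3SCC4"))
})

test_that("extraction is idempotent for every mode", {
  modes <- c("SCAFFOLD", "MURCKO_FRAMEWORK", "ELEMENTAL_WIREFRAME",
             "BASIC_FRAMEWORK", "BASIC_WIREFRAME")
  for (nm in c("flucloxacillin", "diazepam", "naphthalene",
               "cyclohexanone", "toluene")) {
    for (md in modes) {
      st <- scaffold_settings(scaffold_mode = md)
      s1 <- extract_scaffold(fixture(nm), st)
      s2 <- extract_scaffold(s1$graph, st)
      expect_identical(s2$smiles_key, s1$smiles_key,
                       info = paste(nm, md))
    }
  }
})

test_that("scaffold and side chains partition the molecule's atoms", {
  for (nm in c("flucloxacillin", "diazepam", "toluene", "cyclohexanone",
               "zolazepam")) {
    for (st in list(default_settings, murcko_settings)) {
      m <- fixture(nm)
      s <- extract_scaffold(m, st)
      chains <- get_side_chains(m, st)
      n_chain <- sum(vapply(chains, function(f) n_atoms(f$graph),
                            integer(1)))
      expect_identical(n_atoms(s) + n_chain, n_atoms(m),
                       info = paste(nm, st$scaffold_mode))
    }
  }
})

test_that("the abstraction lattice commutes down to the basic wireframe", {
  bw <- scaffold_settings("BASIC_WIREFRAME")
  for (nm in c("flucloxacillin", "diazepam", "naphthalene", "biphenyl")) {
    m <- fixture(nm)
    direct <- extract_scaffold(m, bw)$smiles_key
    via_ew <- extract_scaffold(
      extract_scaffold(m, scaffold_settings("ELEMENTAL_WIREFRAME"))$graph,
      bw)$smiles_key
    via_bf <- extract_scaffold(
      extract_scaffold(m, scaffold_settings("BASIC_FRAMEWORK"))$graph,
      bw)$smiles_key
    expect_identical(via_ew, direct, info = nm)
    expect_identical(via_bf, direct, info = nm)
  }
})

test_that("ring fragments split fused systems and duplicate shared atoms", {
  nap <- extract_scaffold(fixture("naphthalene"), default_settings)
  rings <- get_rings(nap)
  expect_length(rings, 2L)
  expect_identical(vapply(rings, function(f) n_atoms(f$graph), integer(1)),
                   c(6L, 6L))
  flx <- extract_scaffold(fixture("flucloxacillin"), default_settings)
  frags <- get_rings(flx)
  expect_length(frags, 4L)
  expect_setequal(vapply(frags, function(f) n_atoms(f$graph), integer(1)),
                  c(5L, 6L, 4L, 5L))
  benz <- extract_scaffold(fixture("benzene"), default_settings)
  rb <- get_rings(benz)
  expect_length(rb, 1L)
  expect_identical(to_smiles(rb[[1]]$graph), benz$smiles_key)
})

test_that("linkers are reported, including zero-atom ring-ring bonds", {
  dpm <- extract_scaffold(fixture("diphenylmethane"), default_settings)
  lk <- get_linkers(dpm)
  expect_length(lk, 1L)
  expect_identical(n_atoms(lk[[1]]$graph), 1L)
  bip <- extract_scaffold(fixture("biphenyl"), default_settings)
  lk2 <- get_linkers(bip)
  expect_length(lk2, 1L)
  expect_identical(n_atoms(lk2[[1]]$graph), 0L)
  expect_length(lk2[[1]]$bond, 2L)
  nap <- extract_scaffold(fixture("naphthalene"), default_settings)
  expect_length(get_linkers(nap), 0L)
})

test_that("side chains respect the scaffold mode", {
  tol <- fixture("toluene")
  sc <- get_side_chains(tol, default_settings)
  expect_length(sc, 1L)
  expect_identical(n_atoms(sc[[1]]$graph), 1L)
  expect_length(get_side_chains(fixture("benzene"), default_settings), 0L)
  keto <- fixture("cyclohexanone")
  expect_length(get_side_chains(keto, default_settings), 0L)
  sc2 <- get_side_chains(keto, murcko_settings)
  expect_length(sc2, 1L)
  expect_identical(sc2[[1]]$graph$atoms$element, "O")
  # a ring-free molecule is one whole side chain
  sc3 <- get_side_chains(fixture("hexane"), default_settings)
  expect_length(sc3, 1L)
  expect_identical(n_atoms(sc3[[1]]$graph), 6L)
})
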