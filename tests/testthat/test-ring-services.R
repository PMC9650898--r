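test_that("adamantane has four relevant rings but a three-ring MCB", {
  adam <- fixture("adamantane")
  expect_identical(n_atoms(adam), 10L)
  expect_identical(n_bonds(adam), 12L)
  rs <- detect_rings(adam)
  expect_identical(length(rs$rings), 4L)
  expect_identical(rs$method, "relevant_union")
  mcb <- detect_rings(adam, method = "mcb")
  expect_identical(length(mcb$rings), 3L)
  expect_identical(length(mcb$rings), circuit_rank(adam))
})

test_that("oversized relevant-cycle sets fall back to a single MCB", {
  cage <- fixture("octahedral_cage_synthetic")
  rs <- detect_rings(cage)
  expect_identical(rs$method, "mcb_fallback")
  expect_identical(length(rs$rings), circuit_rank(cage))  # 7
  # without the fallback rule the cage has 8 relevant triangles (> 6 atoms)
  blocks <- scaffoldTrees:::cyclic_blocks(cage)
  rel <- scaffoldTrees:::component_cycles(cage, blocks[[1]])$relevant
  expect_identical(length(rel), 8L)
  expect_true(all(vapply(rel, length, integer(1)) == 3L))
})

test_that("MCB ring count equals the circuit rank on random molecules", {
  for (m in property_molecules(40, seed = 91L)) {
    mcb <- detect_rings(m, method = "mcb")
    expect_identical(length(mcb$rings), circuit_rank(m),
                     info = to_smiles(m))
    expect_gte(length(detect_rings(m)$rings), length(mcb$rings))
  }
})

test_that("terminality matches the worked fused-ring examples", {
  ant <- extract_scaffold(fixture("anthracene"), default_settings)
  rings <- detect_rings(ant)$rings
  term <- vapply(rings, function(r) is_terminal(ant, r), logical(1))
  expect_identical(sum(term), 2L)   # both outer rings, not the middle one
  middle <- rings[[which(!term)]]
  # the middle ring contains both fusion bonds
  expect_identical(length(setdiff(middle$atom_indices,
                                  unlist(lapply(rings[term],
                                                function(r) r$atom_indices)))),
                   2L)

  ind <- extract_scaffold(fixture("dodecahydro_s_indacene"),
                          default_settings)
  rind <- detect_rings(ind)$rings
  central <- rind[[which(vapply(rind, function(r) r$size, integer(1)) == 6L)]]
  expect_false(is_terminal(ind, central))

  benz <- extract_scaffold(fixture("benzene"), default_settings)
  expect_true(is_terminal(benz, detect_rings(benz)$rings[[1]]))
})

test_that("removability honours exclusive-atom, spiro and aromatic guards", {
  st <- default_settings
  adam <- extract_scaffold(fixture("adamantane"), st)
  expect_false(any(vapply(detect_rings(adam)$rings,
                          function(r) is_removable(adam, r, st),
                          logical(1))))
  pyr <- extract_scaffold(fixture("pyrene"), st)
  expect_false(any(vapply(detect_rings(pyr)$rings,
                          function(r) is_removable(pyr, r, st),
                          logical(1))))
  nap <- extract_scaffold(fixture("naphthalene"), st)
  expect_true(all(vapply(detect_rings(nap)$rings,
                         function(r) is_removable(nap, r, st),
                         logical(1))))
  # bridged tricyclododecane: exactly the removal path that would leave a
  # spiro junction is forbidden
  tcd <- extract_scaffold(fixture("tricyclododecane"), st)
  rings <- detect_rings(tcd)$rings
  rem <- vapply(rings, function(r) is_removable(tcd, r, st), logical(1))
  expect_identical(sum(rem), 2L)
  blocked <- rings[[which(!rem)]]
  expect_identical(blocked$size, 6L)
  expect_true(is_terminal(tcd, blocked))   # blocked by the spiro guard only
})

test_that("ring membership is checked", {
  nap <- extract_scaffold(fixture("naphthalene"), default_settings)
  benz <- extract_scaffold(fixture("benzene"), default_settings)
  foreign <- detect_rings(benz)$rings[[1]]
  foreign$bond_indices <- foreign$bond_indices + 20L
  expect_error(is_terminal(nap, foreign), "does not belong")
  mid <- detect_rings(extract_scaffold(fixture("anthracene"),
                                       default_settings))$rings
  ant <- extract_scaffold(fixture("anthracene"), default_settings)
  not_rem <- mid[[which(!vapply(mid, function(r)
    is_removable(ant, r, default_settings), logical(1)))[1]]]
  expect_error(remove_ring(ant, not_rem, default_settings),
               "not removable")
})

test_that("removing a naphthalene ring yields benzene via double-bond repair", {
  nap <- extract_scaffold(fixture("naphthalene"), default_settings)
  r <- detect_rings(nap)$rings[[1]]
  parent <- remove_ring(nap, r, default_settings)
  expect_identical(parent$smiles_key, canon("c1ccccc1"))
  expect_true(all(parent$graph$atoms$aromatic))
})

test_that("three-membered heterocycle removal restores the precursor double bond", {
  oxa <- extract_scaffold(fixture("oxabicycloheptane"), default_settings)
  rings <- detect_rings(oxa)$rings
  oxirane <- rings[[which(vapply(rings, function(r) r$size,
                                 integer(1)) == 3L)]]
  parent <- remove_ring(oxa, oxirane, default_settings)
  expect_identical(parent$smiles_key, canon("C1=CCCCC1"))
})

test_that("the hybridisation-retention setting toggles the inserted double bond", {
  hhq <- fixture("hexahydroisoquinoline")
  for (retain in c(FALSE, TRUE)) {
    st <- scaffold_settings(
      retain_only_hybridisations_at_aromatic_bonds = retain)
    sc <- extract_scaffold(hhq, st)
    rings <- detect_rings(sc)$rings
    carbo <- rings[[which(vapply(rings, function(r)
      sum(r$heteroatom_counts), integer(1)) == 0L)]]
    parent <- remove_ring(sc, carbo, st)
    expected <- if (retain) canon("C1CCNCC1") else canon("C1=CCNCC1")
    expect_identical(parent$smiles_key, expected, info = retain)
  }
})

test_that("every removal drops the ring count by one and keeps connectivity", {
  st <- default_settings
  checked <- 0L
  for (m in property_molecules(40, seed = 1371L)) {
    s <- extract_scaffold(m, st)
    if (n_atoms(s) == 0L) next
    rings <- detect_rings(s)$rings
    if (length(rings) <= 1L) next
    for (r in rings) {
      if (!is_removable(s, r, st)) next
      p <- remove_ring(s, r, st)
      checked <- checked + 1L
      expect_identical(ring_count(p), length(rings) - 1L,
                       info = s$smiles_key)
      expect_identical(as.integer(max(scaffoldTrees:::mol_components(p$graph))), 1L)
      expect_lt(n_atoms(p), n_atoms(s))
    }
  }
  expect_gte(checked, 20L)
})
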