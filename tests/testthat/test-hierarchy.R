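trio <- function() list(fixture("diazepam"), fixture("bromazepam"),
                        fixture("zolazepam"))

test_that("the diazepinenone trio shares one tree and a benzene node", {
  st <- default_settings
  fo <- build_forest(trio(), st)
  expect_length(fo$trees, 1L)
  tree <- fo$trees[[1]]
  expect_true(is_valid_tree(tree))
  root <- tree$nodes[[scaffoldTrees:::map_key(tree$root_key)]]
  expect_length(root$parent_keys, 0L)
  rr <- detect_rings(root$scaffold)$rings
  expect_identical(rr[[1]]$size, 7L)

  net <- build_network(trio(), st)
  fr <- node_frequencies(net)
  benz <- canon("c1ccccc1")
  expect_identical(unname(fr[names(fr) == benz]), 3L)
  bn <- net$nodes[[scaffoldTrees:::map_key(benz)]]
  expect_length(union(bn$origins_nonvirtual, bn$origins_virtual), 3L)
  expect_true(scaffoldTrees:::is_virtual_node(bn))
  # diazepam shares two-ring parent nodes with each of the others
  two_ring <- Filter(function(n) ring_count(n$scaffold) == 2L, net$nodes)
  dia_smi <- to_smiles(fixture("diazepam"))
  shared <- Filter(function(n) {
    org <- union(n$origins_nonvirtual, n$origins_virtual)
    dia_smi %in% org && length(org) >= 2L
  }, two_ring)
  expect_gte(length(shared), 2L)
  # forest nodes are a subset of network nodes
  expect_true(all(node_keys(fo) %in% node_keys(net)))
})

test_that("stereo-aware keys split the thalidomide leaves", {
  pair <- list(fixture("thalidomide_plus"), fixture("thalidomide_minus"))
  fo <- build_forest(pair, default_settings)
  expect_length(fo$trees, 1L)
  n_default <- length(node_keys(fo$trees[[1]]))
  st_stereo <- scaffold_settings(
    smiles_flavor = smiles_flavor(include_stereo = TRUE))
  fo2 <- build_forest(pair, st_stereo)
  expect_length(fo2$trees, 1L)
  expect_identical(length(node_keys(fo2$trees[[1]])), n_default + 1L)
  leaves <- Filter(function(n) length(n$child_keys) == 0L,
                   fo2$trees[[1]]$nodes)
  expect_length(leaves, 2L)
})

test_that("molecules with different roots give separate trees", {
  fo <- build_forest(list(fixture("benzene"), fixture("cyclohexane")),
                     default_settings)
  expect_length(fo$trees, 2L)
  expect_identical(anyDuplicated(vapply(fo$trees, function(t) t$root_key,
                                        character(1))), 0L)
})

test_that("network construction is order independent and merge well behaved", {
  st <- default_settings
  mols <- trio()
  whole <- build_network(mols, st)
  a <- build_network(mols[1], st)
  b <- build_network(mols[2:3], st)
  merged <- merge(a, b)
  expect_identical(node_keys(merged), node_keys(whole))
  expect_identical(node_frequencies(merged), node_frequencies(whole))
  # identity and idempotence
  expect_identical(node_keys(merge(whole, scaffold_network())),
                   node_keys(whole))
  expect_identical(node_frequencies(merge(whole, whole)),
                   node_frequencies(whole))
  # associativity at the node-set level
  c3 <- build_network(mols[3], st)
  ab_c <- merge(merge(a, build_network(mols[2], st)), c3)
  a_bc <- merge(a, merge(build_network(mols[2], st), c3))
  expect_identical(node_keys(ab_c), node_keys(a_bc))
  # trees with different roots refuse to merge
  t1 <- build_forest(list(fixture("benzene")), st)$trees[[1]]
  t2 <- build_forest(list(fixture("pyridine")), st)$trees[[1]]
  expect_error(merge(t1, t2), "different roots")
})

test_that("tree validity detects orphans and multi-parent corruption", {
  st <- default_settings
  tree <- build_forest(list(fixture("diazepam")), st)$trees[[1]]
  expect_true(is_valid_tree(tree))
  broken <- tree
  orphan <- extract_scaffold(fixture("cyclohexane"), st)
  broken$nodes[[scaffoldTrees:::map_key(orphan$smiles_key)]] <-
    scaffoldTrees:::new_node(orphan)
  expect_false(is_valid_tree(broken))    # two parentless nodes
  single <- build_forest(list(fixture("benzene")), st)$trees[[1]]
  expect_true(is_valid_tree(single))
})

test_that("levels, adjacency and frequencies are consistent", {
  st <- default_settings
  net <- build_network(trio(), st)
  lev <- node_levels(net)
  for (node in net$nodes) {
    if (length(node$parent_keys)) {
      pl <- lev[match(node$parent_keys, names(lev))]
      expect_identical(unname(lev[match(node$smiles_key, names(lev))]),
                       max(pl) + 1L)
    } else {
      expect_identical(unname(lev[match(node$smiles_key, names(lev))]), 0L)
    }
  }
  tree <- build_forest(trio(), st)$trees[[1]]
  tlev <- node_levels(tree)
  for (node in tree$nodes) {
    if (length(node$parent_keys)) {
      expect_identical(unname(tlev[match(node$smiles_key, names(tlev))]),
                       unname(tlev[match(node$parent_keys,
                                         names(tlev))]) + 1L)
    }
  }
  adj <- to_adjacency(tree)
  expect_identical(dim(adj$matrix), c(length(tree$nodes),
                                      length(tree$nodes)))
  expect_true(all(colSums(adj$matrix) <= 1L))
  root_col <- match(tree$root_key, adj$keys)
  expect_identical(sum(adj$matrix[, root_col]), 0L)
  expect_identical(sum(adj$matrix),
                   sum(vapply(tree$nodes, function(n)
                     length(n$parent_keys), integer(1))))
  # single node: 1x1 zero matrix
  single <- build_network(list(fixture("benzene")), st)
  adj1 <- to_adjacency(single)
  expect_identical(adj1$matrix, matrix(0L, 1, 1, dimnames =
                                         list(canon("c1ccccc1"),
                                              canon("c1ccccc1"))))
  expect_identical(unname(node_frequencies(single)), 1L)
})

test_that("ring-free molecules occupy the empty-scaffold node", {
  st <- default_settings
  net <- build_network(list(fixture("hexane"), fixture("benzene")), st)
  expect_true("" %in% node_keys(net))
  empty_node <- net$nodes[[scaffoldTrees:::map_key("")]]
  expect_length(empty_node$parent_keys, 0L)
  expect_length(empty_node$child_keys, 0L)
  expect_false(scaffoldTrees:::is_virtual_node(empty_node))
})

test_that("every ring-bearing molecule is a non-virtual origin exactly once", {
  st <- default_settings
  mols <- property_molecules(15, seed = 5L)
  net <- build_network(mols, st)
  for (m in mols) {
    smi <- to_smiles(m, st$smiles_flavor)
    hits <- sum(vapply(net$nodes, function(n)
      smi %in% n$origins_nonvirtual, logical(1)))
    expect_identical(hits, 1L, info = smi)
  }
  fo <- build_forest(mols, st)
  expect_true(all(node_keys(fo) %in% node_keys(net)))
})
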