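test_that("enumeration closures of undissectable scaffolds are singletons", {
  st <- default_settings
  for (nm in c("benzene", "pyrene", "adamantane")) {
    res <- enumerate_parent_scaffolds(fixture(nm), st)
    expect_length(res$scaffolds, 1L)
    expect_identical(nrow(res$edges), 0L)
  }
  dec <- enumerate_parent_scaffolds(fixture("decalin"), st)
  expect_identical(scaffold_keys(dec),
                   c(canon("C1CCC2CCCCC2C1"), canon("C1CCCCC1")))
  hexane <- enumerate_parent_scaffolds(fixture("hexane"), st)
  expect_identical(scaffold_keys(hexane), "")
})

test_that("the flucloxacillin closure is closed, distinct and rooted", {
  st <- default_settings
  res <- enumerate_parent_scaffolds(fixture("flucloxacillin"), st)
  keys <- scaffold_keys(res)
  expect_identical(anyDuplicated(keys), 0L)
  expect_identical(keys[1],
                   extract_scaffold(fixture("flucloxacillin"),
                                    st)$smiles_key)
  # closure: every removable ring of every member leads back into the set
  for (s in res$scaffolds) {
    for (r in detect_rings(s)$rings) {
      if (length(detect_rings(s)$rings) > 1L && is_removable(s, r, st)) {
        expect_true(remove_ring(s, r, st)$smiles_key %in% keys)
      }
    }
  }
  # every edge connects a child to a parent with exactly one ring fewer
  by_key <- setNames(res$scaffolds, vapply(res$scaffolds, function(s)
    s$smiles_key, character(1)))
  for (j in seq_len(nrow(res$edges))) {
    child <- by_key[[res$edges$child[j]]]
    parent <- by_key[[res$edges$parent[j]]]
    expect_identical(ring_count(parent), ring_count(child) - 1L)
  }
})

test_that("individual prioritisation rules pick the documented ring", {
  st <- default_settings
  sel_size <- function(smiles) {
    s <- extract_scaffold(parse_smiles(smiles), st)
    select_ring_schuffenhauer(s, st)$size
  }
  # rule 2: a six-ring beats a fourteen-ring
  expect_identical(sel_size("C1CCCCC1CC1CCCCCCCCCCCC1"), 6L)
  # rule 6: sizes {5, 7} resolve to the five-ring
  expect_identical(sel_size("C1CCCC1CC1CCCCCC1"), 5L)
  # rule 1: a fused three-membered heterocycle goes first
  expect_identical(sel_size("c1ccccc1CC1CCC2OC2C1"), 3L)
  # rule 8: fewest heteroatoms ({0, 2}) wins
  s <- extract_scaffold(parse_smiles("C1CCCCC1CC1COCCO1"), st)
  picked <- select_ring_schuffenhauer(s, st)
  expect_identical(sum(picked$heteroatom_counts), 0L)
  # no removable ring is a contract violation
  expect_error(select_ring_schuffenhauer(
    extract_scaffold(fixture("benzene"), st), st), "no removable")
})

test_that("the fusion descriptor delta separates linear, bridged and spiro", {
  delta_of <- function(smiles) {
    scaffoldTrees:::ring_assembly_delta(detect_rings(parse_smiles(smiles)))
  }
  expect_identical(delta_of("C1CCC2CCCCC2C1"), 0L)        # decalin
  expect_gt(delta_of("C1CC2CCC1C2"), 0L)                  # norbornane
  expect_identical(delta_of("C1CCC2(CC1)CCCC2"), -1L)     # spiro[4.5]decane
})

test_that("the Schuffenhauer chain reaches the documented roots", {
  st <- default_settings
  expect_length(schuffenhauer_chain(fixture("benzene"), st)$scaffolds, 1L)
  expect_length(schuffenhauer_chain(fixture("adamantane"), st)$scaffolds, 1L)
  ch <- schuffenhauer_chain(fixture("diazepam"), st)
  expect_length(ch$scaffolds, 3L)
  root <- ch$scaffolds[[length(ch$scaffolds)]]
  rr <- detect_rings(root)$rings
  expect_length(rr, 1L)
  expect_identical(rr[[1]]$size, 7L)      # the diazepinenone ring
  expect_identical(sum(root$graph$atoms$element == "N"), 2L)
  expect_identical(sum(vapply(seq_len(n_bonds(root)), function(i)
    root$graph$bonds$order[i] == 2L &&
      "O" %in% root$graph$atoms$element[c(root$graph$bonds$a1[i],
                                          root$graph$bonds$a2[i])],
    logical(1))), 1L)                     # keeps its lactam carbonyl
  # ring count decreases by exactly one per step
  counts <- vapply(ch$scaffolds, ring_count, integer(1))
  expect_identical(counts, seq(counts[1], counts[length(counts)]))
})

test_that("chains are contained in closures and fully deterministic", {
  st <- default_settings
  for (m in property_molecules(30, seed = 77L)) {
    ch <- schuffenhauer_chain(m, st)
    cl <- enumerate_parent_scaffolds(m, st)
    expect_true(all(scaffold_keys(ch) %in% scaffold_keys(cl)),
                info = to_smiles(m))
    expect_lte(length(ch$scaffolds), max(1L, ring_count(ch$scaffolds[[1]])))
    ch2 <- schuffenhauer_chain(m, st)
    expect_identical(scaffold_keys(ch2), scaffold_keys(ch))
  }
})

test_that("rule 7 only affects fully aromatic multi-ring systems", {
  on <- scaffold_settings(rule_seven_applied = TRUE)
  off <- scaffold_settings(rule_seven_applied = FALSE)
  for (nm in c("diazepam", "flucloxacillin", "zolazepam", "decalin",
               "cyclohexanone")) {
    expect_identical(scaffold_keys(schuffenhauer_chain(fixture(nm), on)),
                     scaffold_keys(schuffenhauer_chain(fixture(nm), off)),
                     info = nm)
  }
  # a fully aromatic fused pair stays aromatic through dissection
  ch <- schuffenhauer_chain(fixture("naphthalene"), on)
  expect_identical(scaffold_keys(ch)[2], canon("c1ccccc1"))
})

test_that("disabling aromaticity perception suppresses every perception call", {
  calls <- 0L
  counting <- aromaticity_model(function(m) {
    calls <<- calls + 1L
    m
  }, "counting")
  st_off <- scaffold_settings(determine_aromaticity = FALSE,
                              aromaticity_model = counting)
  invisible(schuffenhauer_chain(fixture("flucloxacillin"), st_off))
  invisible(enumerate_parent_scaffolds(fixture("diazepam"), st_off))
  expect_identical(calls, 0L)
  st_on <- scaffold_settings(aromaticity_model = counting)
  invisible(extract_scaffold(fixture("benzene"), st_on))
  expect_gt(calls, 0L)
})
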