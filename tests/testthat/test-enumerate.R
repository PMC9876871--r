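test_that("bicyclic seeds are six all-carbon 5/6-ring systems", {
  seeds <- bicyclic_seeds()
  expect_length(seeds, 6L)
  for (s in seeds) {
    expect_true(all(s$elements == "C"))
    expect_true(all(s$bonds$order == 1L))
    expect_equal(nrow(s$bonds) - n_atoms(s) + 1L, 2L)  # cyclomatic 2
    expect_true(all(ring_info(s)$sizes %in% c(5L, 6L)))
  }
  expect_equal(n_atoms(seeds[[1]]), 8L)
})

test_that("fragment-size combinations respect the carbon window", {
  expect_setequal(
    apply(mn_combinations(8, enum_config(carbon_min = 10,
                                         carbon_max = 10)), 1, paste,
          collapse = ","),
    c("2,0", "1,1"))
  expect_setequal(
    apply(mn_combinations(8, enum_config(carbon_min = 9, carbon_max = 9)),
          1, paste, collapse = ","),
    "1,0")
  expect_equal(nrow(mn_combinations(8, enum_config(carbon_min = 8,
                                                   carbon_max = 8))), 0L)
})

test_that("bridge extension matches brute-force enumeration with VF2 dedup", {
  chx <- parse_smiles("C1CCCCC1")
  got <- bridge_extend(chx, 1L)
  oracle <- dedup_by_vf2(brute_bridge_products(chx, 1L))
  expect_equal(length(got), length(oracle))
  # every product has one extra atom and one extra independent cycle
  for (g in got) {
    expect_equal(n_atoms(g), 7L)
    expect_equal(nrow(g$bonds) - n_atoms(g) + 1L, 2L)
  }
  # norbornane and bicyclo[2.1.1]hexane-style products present
  expect_true(any(vapply(got, mol_isomorphic, logical(1),
                         g2 = parse_smiles("C1CC2CCC1C2"))))

  cp <- parse_smiles("C1CC1")
  got3 <- bridge_extend(cp, 1L)
  expect_length(got3, 1L)  # all atom pairs symmetric
  expect_true(mol_isomorphic(got3[[1]], parse_smiles("C1C2CC12")))

  expect_error(bridge_extend(chx, -1L))
  expect_length(bridge_extend(chx, 0L, allow_zero = FALSE), 0L)
})

test_that("bridge extension brute-force agreement holds on varied cores", {
  cores <- list(parse_smiles("C1CCCC1"), parse_smiles("C1CC2CCC1C2"),
                parse_smiles("C1CCC2CCCC12"))
  for (core in cores) {
    for (k in 1:2) {
      got <- bridge_extend(core, k)
      oracle <- dedup_by_vf2(brute_bridge_products(core, k))
      expect_equal(length(got), length(oracle),
                   info = paste(canonical_smiles(core), k))
    }
  }
})

test_that("toy enumeration matches an independent brute-force count", {
  cfg <- enum_config(seed_smiles = c(toy = "C1CCCCC1"), carbon_min = 7L,
                     carbon_max = 7L, ring_size_whitelist = NULL,
                     require_bridged = FALSE)
  recs <- enumerate_ring_systems(cfg)
  # only m = 1 applies (7 carbons); oracle = brute force on the seed
  oracle <- dedup_by_vf2(brute_bridge_products(parse_smiles("C1CCCCC1"), 1L))
  expect_equal(length(recs), length(oracle))
  keys <- vapply(recs, `[[`, "", "key")
  expect_false(anyDuplicated(keys) > 0)
})

test_that("enumeration is order-independent and key-deduplicated", {
  cfg1 <- enum_config(seed_smiles = scaffmime:::.DEFAULT_SEEDS[c(1, 4, 5)],
                      carbon_min = 10L, carbon_max = 10L)
  recs1 <- enumerate_ring_systems(cfg1)
  cfg2 <- cfg1
  cfg2$seed_smiles <- rev(cfg1$seed_smiles)
  recs2 <- enumerate_ring_systems(cfg2)
  k1 <- sort(vapply(recs1, `[[`, "", "key"))
  k2 <- sort(vapply(recs2, `[[`, "", "key"))
  expect_identical(k1, k2)
  expect_false(anyDuplicated(k1) > 0)
  # invariants of every record under the default convention
  for (r in recs1) {
    expect_true(all(r$graph$elements == "C"))
    expect_true(all(r$graph$bonds$order == 1L))
    expect_true(r$cyclomatic %in% c(3L, 4L))
    expect_true(r$carbons >= 10L && r$carbons <= 14L)
    expect_true(is_connected_mol(r$graph))
  }
  # dedup completeness against pairwise VF2 on a sample
  smp <- recs1[seq_len(min(40, length(recs1)))]
  gs <- lapply(smp, `[[`, "graph")
  expect_equal(length(dedup_by_vf2(gs)), length(gs))
})

test_that("methyl placement matches brute-force orbit enumeration", {
  chx <- parse_smiles("C1CCCCC1")
  got <- place_substituents(chx, enum_config())
  expect_length(got, 6L)
  oracle <- brute_substituted(chx)
  expect_equal(length(got), length(oracle))

  for (core_smi in c("C1CC2CCC1C2", "C1CCC2CCCC12", "C1CC2CCC1CC2",
                     "C1CCCC1")) {
    core <- parse_smiles(core_smi)
    got <- place_substituents(core, enum_config())
    oracle <- brute_substituted(core)
    expect_equal(length(got), length(oracle), info = core_smi)
    for (sk in got) {
      deg <- heavy_degree(sk$graph)
      expect_lte(sum(deg == 4L), 1L)
      expect_true(all(deg <= 4L))
    }
  }
})

test_that("bridged-arrangement test separates fused from bridged systems", {
  expect_true(is_bridged(parse_smiles("C1CC2CCC1C2")))      # norbornane
  expect_true(is_bridged(parse_smiles("C1CC2CCC1CC2")))     # bicyclo[2.2.2]
  expect_false(is_bridged(parse_smiles("C1CCC2CCCCC2C1")))  # decalin
  expect_false(is_bridged(parse_smiles("C1CCC2CCCC12")))    # fused 5-5
  expect_false(is_bridged(parse_smiles("C1CCC2(CC1)CCCCC2")))  # spiro
  expect_true(is_bridged(parse_smiles("C1C2CC3CC1CC(C2)C3")))  # adamantane
})
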