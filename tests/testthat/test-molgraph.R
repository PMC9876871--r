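test_that("SMILES parsing handles molecules and failures as values", {
  g <- parse_smiles("C")
  expect_s3_class(g, "molgraph")
  expect_equal(n_atoms(g), 1L)
  expect_equal(implicit_hydrogens(g), 4L)

  ring <- parse_smiles("C1CCCCC1")
  expect_equal(n_atoms(ring), 6L)
  expect_equal(nrow(ring$bonds), 6L)
  expect_equal(ring_info(ring)$sizes, 6L)

  bad <- parse_smiles("C1CC")
  expect_true(is_parse_failure(bad))
  hyper <- parse_smiles("C(C)(C)(C)(C)C")
  expect_true(is_parse_failure(hyper))
  expect_equal(hyper$reason, "valence")
  expect_true(is_parse_failure(parse_smiles("")))

  batch <- parse_smiles_batch(c("CCO", "xx]", "c1ccncc1"))
  expect_false(is_parse_failure(batch[[1]]))
  expect_true(is_parse_failure(batch[[2]]))
  expect_false(is_parse_failure(batch[[3]]))
})

test_that("carbonization follows the stated reduction rule", {
  pyr <- carbonize(parse_smiles("c1ccncc1"))
  expect_true(mol_isomorphic(pyr, parse_smiles("C1CCCCC1")))

  lactam <- carbonize(parse_smiles("O=C1CCCN1"))
  expect_true(mol_isomorphic(lactam, parse_smiles("CC1CCCC1")))

  chx <- parse_smiles("C1CCCCC1")
  expect_true(mol_isomorphic(carbonize(chx), chx))
})

test_that("carbonization is idempotent and preserves heavy-atom topology", {
  fixtures <- c("c1ccncc1", "O=C1CCCN1", "CC(=O)Oc1ccccc1C(=O)O",
                "c1cc2[nH]ccc2cc1", "CC(C)(Cl)C1CCS(=O)(=O)C1",
                "O=S(=O)(N)c1ccc(N)cc1", "FC(F)(F)c1ccc(Br)cc1",
                "C1CC2CCC1C2", "O=C1NC(=O)C2(CCCC2)N1")
  for (s in fixtures) {
    g <- parse_smiles(s)
    expect_false(is_parse_failure(g), info = s)
    cg <- carbonize(g)
    expect_equal(n_atoms(cg), n_atoms(g), info = s)
    expect_true(all(cg$elements == "C"), info = s)
    expect_true(all(cg$bonds$order == 1L), info = s)
    # adjacency unchanged
    expect_equal(cbind(cg$bonds$from, cg$bonds$to),
                 cbind(g$bonds$from, g$bonds$to), info = s)
    expect_true(mol_isomorphic(carbonize(cg), cg), info = s)
  }
})

test_that("carbonization preserves topology on randomized corpus graphs", {
  pairs <- synthetic_corpus(30, seed = 42, skeleton_pool = test_pool())
  for (p in pairs) {
    cg <- carbonize(p$target)
    expect_true(mol_isomorphic(cg, p$source))
  }
})

test_that("canonical SMILES is isomorphism-invariant and deterministic", {
  a <- parse_smiles("C1CCCCC1")
  b <- parse_smiles("C(C1)CCCC1")
  expect_identical(canonical_smiles(a), canonical_smiles(b))
  # idempotent under re-parsing
  expect_identical(canonical_smiles(parse_smiles(canonical_smiles(a))),
                   canonical_smiles(a))
  # distinct molecules get distinct strings
  decalin <- parse_smiles("C1CCC2CCCCC2C1")
  bco <- parse_smiles("C1CC2CCC1CC2")
  expect_false(canonical_smiles(decalin) == canonical_smiles(bco))
})

test_that("randomized SMILES round-trip and canonical invariance", {
  tol <- parse_smiles("Cc1ccccc1")
  canon <- canonical_smiles(tol)
  strs <- character(0)
  for (i in seq_len(n_atoms(tol))) {
    s <- randomized_smiles(tol, i, seed = i)
    g2 <- parse_smiles(as.character(s))
    expect_false(is_parse_failure(g2))
    expect_true(mol_isomorphic(g2, tol))
    expect_identical(canonical_smiles(g2), canon)
    strs <- c(strs, as.character(s))
  }
  expect_gte(length(unique(strs)), 2L)
  expect_error(randomized_smiles(tol, 99L))
  # single atom
  expect_identical(as.character(randomized_smiles(parse_smiles("C"), 1L)),
                   "C")
  # reproducible under seed
  expect_identical(as.character(randomized_smiles(tol, 2L, seed = 7)),
                   as.character(randomized_smiles(tol, 2L, seed = 7)))
})

test_that("ring perception reports SSSR sizes and exocyclic atoms", {
  expect_equal(ring_info(parse_smiles("C1CCCCC1"))$sizes, 6L)
  nor <- ring_info(parse_smiles("C1CC2CCC1C2"))
  expect_equal(nor$sizes, c(5L, 5L))
  tol <- parse_smiles("Cc1ccccc1")
  ri <- ring_info(tol)
  expect_equal(ri$sizes, 6L)
  methyl <- which(heavy_degree(tol) == 1L)
  expect_false(ri$ring_atoms[methyl])
  expect_equal(sum(ri$ring_atoms), 6L)
})

test_that("graph keys agree with VF2 isomorphism on decorated graphs", {
  pairs <- synthetic_corpus(12, seed = 9, skeleton_pool = test_pool())
  gs <- lapply(pairs, `[[`, "target")
  keys <- vapply(gs, graph_key, "")
  for (i in seq_along(gs)[-1]) {
    for (j in seq_len(i - 1)) {
      expect_equal(keys[i] == keys[j], mol_isomorphic(gs[[i]], gs[[j]]),
                   info = paste(i, j))
    }
  }
})
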