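test_that("target extraction keeps framework plus first shell", {
  aspirin <- parse_smiles("CC(=O)Oc1ccccc1C(=O)O")
  tgt <- extract_target(aspirin)
  expect_false(is_extract_reject(tgt))
  expect_true(mol_isomorphic(tgt, parse_smiles("Cc1ccccc1O")))

  tol <- parse_smiles("Cc1ccccc1")
  expect_true(mol_isomorphic(extract_target(tol), tol))

  se <- extract_target(parse_smiles("CCc1cc[se]1"))
  expect_true(is_extract_reject(se))
  expect_equal(se$reason, "element")

  acyc <- extract_target(parse_smiles("CCCCO"))
  expect_true(is_extract_reject(acyc))
  expect_equal(acyc$reason, "acyclic")

  big <- extract_target(parse_smiles("C1CCCCCCCCC1"))  # 10-ring
  expect_true(is_extract_reject(big))
  expect_equal(big$reason, "ring_size")
})

test_that("target extraction is idempotent and keeps exocyclic bond orders", {
  fixtures <- c("CC(=O)Oc1ccccc1C(=O)O", "O=C1CCCN1CCC",
                "O=S(=O)(NC)c1ccc(OCC)cc1", "ClCC1CC2(CCN2C(=O)C)C1")
  for (s in fixtures) {
    t1 <- extract_target(parse_smiles(s))
    expect_false(is_extract_reject(t1), info = s)
    t2 <- extract_target(t1)
    expect_true(mol_isomorphic(t1, t2), info = s)
    expect_true(all(ring_info(t1)$sizes <= 8L), info = s)
    expect_true(all(t1$elements %in% c("C", "N", "O", "S", "F", "Cl",
                                       "Br", "I")), info = s)
  }
  # exocyclic carbonyl on a ring atom survives with its double bond
  lactam <- extract_target(parse_smiles("O=C1CCCN1CC(C)C"))
  expect_true(any(lactam$elements == "O"))
  expect_true(any(lactam$bonds$order == 2L))
})

test_that("pairs satisfy the carbonization invariant and deduplicate", {
  t1 <- parse_smiles("Cc1ccccc1O")
  p <- make_pair(t1)
  expect_true(mol_isomorphic(p$source, carbonize(p$target)))
  expect_true(mol_isomorphic(p$source, parse_smiles("CC1CCCCC1C")))

  sat <- parse_smiles("CC1CCCC1")
  expect_true(mol_isomorphic(make_pair(sat)$source, sat))

  pairs <- list(p, p, make_pair(sat))
  dd <- dedup_corpus(pairs)
  expect_length(dd, 2L)
  expect_length(dedup_corpus(list()), 0L)
  # distinct targets sharing a source are both kept
  ring <- parse_smiles("C1=CCCCC1")
  ring2 <- parse_smiles("C1=CC=CCC1")
  expect_length(dedup_corpus(list(make_pair(ring), make_pair(ring2))), 2L)
})

test_that("synthetic corpus is reproducible and satisfies pair invariants", {
  pool <- test_pool()
  pairs <- synthetic_corpus(60, seed = 17, skeleton_pool = pool)
  expect_length(pairs, 60L)
  for (p in pairs) {
    expect_true(mol_isomorphic(carbonize(p$target), p$source))
    expect_true(all(ring_info(p$target)$sizes <= 8L))
  }
  pairs2 <- synthetic_corpus(60, seed = 17, skeleton_pool = pool)
  expect_identical(
    vapply(pairs, function(p) canonical_smiles(p$target), ""),
    vapply(pairs2, function(p) canonical_smiles(p$target), ""))

  ident <- synthetic_corpus(10, seed = 3, skeleton_pool = pool,
                            p_het = 0, p_unsat = 0)
  for (p in ident) {
    expect_true(mol_isomorphic(p$target, p$source))
  }
  expect_error(synthetic_corpus(0))
})

test_that("corpus TSV round-trips", {
  tf <- tempfile(fileext = ".tsv")
  pairs <- synthetic_corpus(5, seed = 2, skeleton_pool = test_pool())
  write_corpus_tsv(pairs, tf)
  back <- read_corpus_tsv(tf)
  expect_length(back, 5L)
  for (i in seq_along(back)) {
    expect_true(mol_isomorphic(back[[i]]$target, pairs[[i]]$target))
  }
})
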