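test_that("retention requires exact skeleton and substituent topology", {
  sk <- test_pool()[[1]]
  # the skeleton itself is retained
  expect_true(retention_check(sk$graph, sk))
  # heteroatom-substituted copy at identical topology is retained
  dec <- with_local_seed(3, scaffmime:::decorate_skeleton(sk$graph, 0.3,
                                                          0.2))
  expect_true(retention_check(dec, sk))
  # ring expanded by one atom is not
  g <- sk$graph
  n <- n_atoms(g)
  b <- g$bonds
  b$to[1] <- n + 1L
  b <- rbind(b, data.frame(from = n + 1L, to = g$bonds$to[1], order = 1L))
  bigger <- molgraph(c(g$elements, "C"), b, validate = FALSE)
  expect_false(retention_check(bigger, sk))
  # parse failures count as not retained
  expect_false(retention_check(parse_failure("syntax"), sk))
})

test_that("retention agrees with a direct VF2 oracle on decorated cases", {
  pool <- test_pool()
  set.seed(60)
  for (i in 1:25) {
    sk <- pool[[sample(length(pool), 1)]]
    other <- pool[[sample(length(pool), 1)]]
    dec <- scaffmime:::decorate_skeleton(other$graph, 0.25, 0.15)
    expect_equal(retention_check(dec, sk),
                 mol_isomorphic(carbonize(dec), sk$graph))
  }
})

test_that("generation reports follow the documented conventions", {
  sk <- test_pool()[[1]]
  smi <- canonical_smiles(sk$graph)
  # perfect copier: retention 1, novelty 0 iff input among training targets
  rep1 <- evaluate_generation(rep(smi, 5), list(sk$graph), sk,
                              training_targets = smi, sa = FALSE)
  expect_equal(rep1$validity, 1)
  expect_equal(rep1$retention, 1)
  expect_equal(rep1$novelty, 0)
  rep1b <- evaluate_generation(rep(smi, 5), list(sk$graph), sk,
                               training_targets = character(0), sa = FALSE)
  expect_equal(rep1b$novelty, 1)
  # all-garbage sampler: validity 0, retention 0 by convention
  rep2 <- evaluate_generation(c("xx]", "C1CC", "((", ")("), list(), sk,
                              sa = FALSE)
  expect_equal(rep2$validity, 0)
  expect_equal(rep2$retention, 0)
  expect_equal(rep2$n_unique, 0L)
})

test_that("synthetic accessibility scores are bounded and ordered", {
  benzene <- parse_smiles("c1ccccc1")
  cage <- test_pool()[[1]]$graph
  sb <- sa_score(benzene)
  sc <- sa_score(cage)
  expect_gte(sb, 1); expect_lte(sb, 10)
  expect_gte(sc, 1); expect_lte(sc, 10)
  expect_lt(sb, 4)           # familiar planar aromatic scores as easy
  expect_gt(sc, sb)          # caged polycyclic is harder than benzene
  expect_identical(sa_score(benzene), sa_score(parse_smiles("C1=CC=CC=C1")))
  pairs <- synthetic_corpus(15, seed = 77, skeleton_pool = test_pool())
  for (p in pairs) {
    s <- sa_score(p$target)
    expect_gte(s, 1); expect_lte(s, 10)
  }
})
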