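test_that("edit distance is the unit-cost Levenshtein metric", {
  expect_equal(edit_distance("C1CCCCC1", "C1CCCCC1"), 0L)
  expect_equal(edit_distance("C1CCCCC1", "C1CCNCC1"), 1L)
  expect_equal(edit_distance("", "CC"), 2L)

  # metric axioms on random string triples
  set.seed(5)
  alph <- c("C", "N", "O", "1", "2", "(", ")", "=")
  rnd <- function() paste(sample(alph, sample(1:12, 1), TRUE), collapse = "")
  for (i in 1:200) {
    a <- rnd(); b <- rnd(); c <- rnd()
    dab <- edit_distance(a, b)
    expect_equal(dab, edit_distance(b, a))
    expect_equal(dab == 0L, a == b)
    expect_lte(edit_distance(a, c), dab + edit_distance(b, c))
  }
})

test_that("global alignment maximises matches with deterministic gaps", {
  al <- global_align("CCC", "CCC")
  expect_equal(al$match_score, 3L)
  expect_identical(al$aligned_source, "CCC")

  al2 <- global_align("CC", "CCO")
  expect_identical(al2$aligned_source, "CC-")
  expect_equal(al2$match_score, 2L)

  # alignment invariants on corpus strings
  pairs <- synthetic_corpus(25, seed = 4, skeleton_pool = test_pool())
  aligned <- augment_corpus(pairs, 2L, seed = 8)
  for (a in aligned) {
    expect_equal(nchar(a$aligned_source), nchar(a$aligned_target))
    expect_identical(gsub("-", "", a$aligned_source, fixed = FALSE),
                     a$source_str)
    expect_identical(gsub("-", "", a$aligned_target, fixed = FALSE),
                     a$target_str)
    chars_s <- strsplit(a$aligned_source, "")[[1]]
    chars_t <- strsplit(a$aligned_target, "")[[1]]
    expect_equal(a$match_score,
                 sum(chars_s == chars_t & chars_s != "-"))
  }
  # self-alignment score equals string length
  for (a in aligned[1:20]) {
    expect_equal(global_align(a$target_str, a$target_str)$match_score,
                 nchar(a$target_str))
  }
})

test_that("gaps are confined to the source for corpus-built pairs", {
  pairs <- synthetic_corpus(60, seed = 21, skeleton_pool = test_pool())
  aligned <- augment_corpus(pairs, 3L, seed = 22)
  target_gap <- vapply(aligned, function(a) {
    grepl("-", a$aligned_target, fixed = TRUE)
  }, logical(1))
  expect_gte(mean(!target_gap), 0.99)
})

test_that("best pairing attains the exhaustive rooted-SMILES minimum", {
  pairs <- c(
    lapply(c("O=C1CCCN1", "Cc1ccncc1", "OC1CCOCC1F", "O=C1NC2CCC1CC2",
             "S1C=CC=C1Br"),
           function(s) structure_pair(parse_smiles(s))),
    synthetic_corpus(5, seed = 33, skeleton_pool = test_pool())
  )
  for (p in pairs) {
    bp <- best_pairing(p, n_augment = 2L, seed = 1)
    # oracle: all roots of source x all roots of target, default traversal
    ct <- vapply(seq_len(n_atoms(p$target)), function(i) {
      as.character(write_smiles(p$target, root = i))
    }, "")
    cs <- vapply(seq_len(n_atoms(p$source)), function(i) {
      as.character(write_smiles(p$source, root = i))
    }, "")
    oracle <- min(utils::adist(cs, ct))
    expect_equal(bp$edit_distance, oracle,
                 info = canonical_smiles(p$target))
    # never worse than the canonical pairing
    canon_d <- edit_distance(canonical_smiles(p$source),
                             canonical_smiles(p$target))
    expect_lte(bp$edit_distance, canon_d)
  }
  # identity pair reaches distance zero
  allc <- structure_pair(parse_smiles("CC1CCCC1"))
  expect_equal(best_pairing(allc, seed = 2)$edit_distance, 0L)
})

test_that("augmentation lowers mean edit distance versus canonical pairs", {
  pairs <- synthetic_corpus(40, seed = 13, skeleton_pool = test_pool())
  aug <- augment_corpus(pairs, 3L, seed = 14)
  can <- canonical_corpus(pairs)
  expect_lte(mean(vapply(aug, `[[`, 1L, "edit_distance")),
             mean(vapply(can, `[[`, 1L, "edit_distance")))
  # reproducibility
  aug2 <- augment_corpus(pairs, 3L, seed = 14)
  expect_identical(vapply(aug, `[[`, "", "aligned_source"),
                   vapply(aug2, `[[`, "", "aligned_source"))
  expect_gte(length(aug), length(pairs))
})
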