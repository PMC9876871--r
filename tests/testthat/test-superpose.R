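test_that("Kabsch recovers planted rigid transforms exactly", {
  set.seed(31)
  for (i in 1:20) {
    P <- matrix(rnorm(18, sd = 2), 6, 3)
    R <- random_rotation()
    t <- rnorm(3)
    Q <- P %*% t(R) + matrix(t, 6, 3, byrow = TRUE)
    k <- kabsch(P, Q)
    expect_lt(k$ssd, 1e-10)
    expect_lt(max(abs(k$rotation %*% t(k$rotation) - diag(3))), 1e-8)
    expect_equal(det(k$rotation), 1, tolerance = 1e-8)
  }
})

test_that("Kabsch SSD matches the rotation-grid oracle", {
  set.seed(77)
  for (i in 1:3) {
    P <- matrix(rnorm(18, sd = 2), 6, 3)
    Q <- matrix(rnorm(18, sd = 2), 6, 3)
    k <- kabsch(P, Q)
    oracle <- grid_ssd_oracle(P, Q)
    expect_lt(abs(k$ssd - oracle), 1e-3)
    expect_lte(k$ssd, oracle + 1e-9)  # closed form never worse than grid
  }
})

test_that("superposition optimises over residue assignments", {
  set.seed(12)
  # skeleton-side points: 3 core/methyl pairs
  vectors <- lapply(1:3, function(i) {
    core <- rnorm(3, sd = 2)
    list(core = core, methyl = core + rnorm(3, sd = 0.5))
  })
  # query = same geometry under rigid motion, with residues permuted
  R <- random_rotation(); tr <- rnorm(3)
  perm <- c(3, 1, 2)
  ca <- matrix(0, 3, 3); cb <- matrix(0, 3, 3)
  for (j in 1:3) {
    ca[perm[j], ] <- as.numeric(R %*% vectors[[j]]$core + tr)
    cb[perm[j], ] <- as.numeric(R %*% vectors[[j]]$methyl + tr)
  }
  q <- peptide_query(ca, cb)
  sp <- superpose(vectors, q)
  expect_lt(sp$ssd, 1e-10)
  expect_equal(sp$assignment, perm)
  # optimised SSD never exceeds the identity assignment
  ident_Q <- do.call(rbind, lapply(1:3, function(ri) rbind(ca[ri, ],
                                                           cb[ri, ])))
  ident_P <- do.call(rbind, lapply(vectors, function(v) rbind(v$core,
                                                              v$methyl)))
  expect_lte(sp$ssd, kabsch(ident_P, ident_Q)$ssd + 1e-12)
  # a 1 angstrom displacement yields the grid-oracle SSD
  cb2 <- cb; cb2[1, ] <- cb2[1, ] + c(1, 0, 0)
  sp2 <- superpose(vectors, peptide_query(ca, cb2))
  best_oracle <- min(vapply(seq_len(6), function(pi) {
    perm2 <- scaffmime:::.PERMS3[pi, ]
    Q <- do.call(rbind, lapply(perm2, function(ri) rbind(ca[ri, ],
                                                         cb2[ri, ])))
    grid_ssd_oracle(ident_P, Q)
  }, numeric(1)))
  expect_lt(abs(sp2$ssd - best_oracle), 1e-3)
})

test_that("SSD is invariant under rigid motion of the query", {
  set.seed(55)
  vectors <- lapply(1:3, function(i) {
    core <- rnorm(3, sd = 2)
    list(core = core, methyl = core + rnorm(3, sd = 0.5))
  })
  ca <- matrix(rnorm(9, sd = 3), 3, 3)
  cb <- ca + matrix(rnorm(9, sd = 0.6), 3, 3)
  base <- superpose(vectors, peptide_query(ca, cb))$ssd
  for (i in 1:20) {
    R <- random_rotation(); tr <- rnorm(3, sd = 5)
    q2 <- peptide_query(ca %*% t(R) + matrix(tr, 3, 3, byrow = TRUE),
                        cb %*% t(R) + matrix(tr, 3, 3, byrow = TRUE))
    expect_equal(superpose(vectors, q2)$ssd, base, tolerance = 1e-6)
  }
})

test_that("peptide loading validates residues and atoms", {
  ca <- matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0), 3, byrow = TRUE)
  cb <- ca + matrix(c(0, 1.5, 0), 3, 3, byrow = TRUE)
  pdb <- tempfile(fileext = ".pdb")
  write_test_pdb(pdb, ca, cb)
  q <- load_peptide(pdb, chain = "A", residues = 1:3)
  expect_equal(q$ca, ca, ignore_attr = TRUE)
  expect_equal(q$cb, cb, ignore_attr = TRUE)

  gly <- tempfile(fileext = ".pdb")
  write_test_pdb(gly, ca, cb, resid = c("ALA", "GLY", "SER"))
  expect_error(load_peptide(gly, "A", 1:3), "glycine")
  expect_error(load_peptide(pdb, "A", 1:2), "3 residues")
  expect_error(load_peptide(pdb, "A", c(1, 2, 9)), "not found")
})

test_that("a planted skeleton is ranked first in library search", {
  pool <- test_pool()[1:6]
  confs <- embed_skeleton(pool[[3]], n_conformers = 1L)
  expect_false(is.null(confs))
  vecs <- confs[[1]]$vectors
  R <- random_rotation(); tr <- rnorm(3, sd = 4)
  mv <- function(x) as.numeric(R %*% x + tr)
  ca <- do.call(rbind, lapply(vecs, function(v) mv(v$core)))
  cb <- do.call(rbind, lapply(vecs, function(v) mv(v$methyl)))
  q <- peptide_query(ca, cb)
  rk <- rank_library(q, pool, n_conformers = 1L)
  expect_equal(rk$skeleton[1], names(pool)[3])
  expect_lt(rk$ssd_A2[1], 1e-8)
  # top_k larger than the library returns everything embedded
  expect_lte(nrow(rank_library(q, pool, top_k = 50L)), length(pool))
})
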