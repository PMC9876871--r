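test_that("analytic gradients match numerical differentiation", {
  set.seed(42)
  hp <- hyperparams("test", d_model = 16L, n_heads = 2L,
                    n_encoder_layers = 1L, n_decoder_layers = 1L,
                    ff_dim = 16L, dropout = 0)
  V <- 9L
  params <- scaffmime:::.init_params(hp, V)
  pos <- scaffmime:::.posenc(32L, hp$d_model)
  B <- 2L; S <- 4L; Tt <- 5L
  src <- matrix(sample(2:V, B * S, TRUE), B, S); src[1, 4] <- 1L
  tgt <- matrix(sample(2:V, B * Tt, TRUE), B, Tt); tgt[2, 5] <- 1L
  labels <- as.vector(t(matrix(sample(5:V, B * Tt, TRUE), B, Tt)))
  lossf <- function(p) {
    fw <- scaffmime:::.model_fwd(p, hp, pos, src, tgt, train = FALSE)
    scaffmime:::.ce_loss(fw$logits, labels)$loss
  }
  fw <- scaffmime:::.model_fwd(params, hp, pos, src, tgt, train = FALSE)
  ce <- scaffmime:::.ce_loss(fw$logits, labels)
  gr <- scaffmime:::.model_bwd(fw, ce$dlogits, params, hp)
  paths <- scaffmime:::.leaf_paths(params)
  eps <- 1e-6
  for (pn in sample(names(paths), 12)) {
    p <- paths[[pn]]
    arr <- scaffmime:::.get_path(params, p)
    k <- sample(length(arr), 1)
    a2 <- arr; a2[k] <- a2[k] + eps
    l1 <- lossf(scaffmime:::.set_path(params, p, a2))
    a2[k] <- a2[k] - 2 * eps
    l0 <- lossf(scaffmime:::.set_path(params, p, a2))
    num <- (l1 - l0) / (2 * eps)
    ana <- scaffmime:::.get_path(gr, p)[k]
    expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-4,
              label = paste("grad", pn))
  }
})

test_that("training is deterministic under a fixed seed", {
  df <- data.frame(source = c("CC1CCC1", "CCC1CC1", "C1CCCC1", "CC(C)C1CC1"),
                   target = c("CN1CCC1", "CCC1CO1", "C1CCNC1", "CC(C)C1CS1"))
  hp <- hyperparams("test", d_model = 32L, epochs = 3L, batch_size = 2L)
  m1 <- seq2seq_train(df, hp, seed = 5)
  m2 <- seq2seq_train(df, hp, seed = 5)
  expect_identical(m1$history, m2$history)
  s1 <- seq2seq_sample(m1, "CC1CCC1", n_unique = 3L, seed = 9,
                       attempt_budget = 30L)
  s2 <- seq2seq_sample(m2, "CC1CCC1", n_unique = 3L, seed = 9,
                       attempt_budget = 30L)
  expect_identical(s1$raw, s2$raw)
  expect_error(seq2seq_train(df[0, ], hp))
})

test_that("a tiny model memorises a small corpus and decodes it greedily", {
  pool <- test_pool()
  pairs <- lapply(1:8, function(i) {
    with_local_seed(200 + i, {
      tgt <- scaffmime:::decorate_skeleton(pool[[i]]$graph, 0.2, 0.15)
      structure_pair(tgt, carbonize(tgt), "synthetic")
    })
  })
  df <- pairs_to_df(pairs)
  expect_false(anyDuplicated(df$source) > 0)
  hp <- hyperparams("test", epochs = 180L, batch_size = 4L,
                    learning_rate = 3e-3)
  m <- seq2seq_train(df, hp, seed = 11)
  expect_lt(tail(m$history$train_loss, 1), 0.1)
  # loss history running minimum is non-increasing
  expect_true(all(diff(cummin(m$history$train_loss)) <= 0))
  hits <- vapply(seq_len(nrow(df)), function(i) {
    identical(greedy_decode(m, df$source[i]), df$target[i])
  }, logical(1))
  expect_gte(sum(hits), 7L)
  # greedy limit: temperature 0 sampling returns the memorised target
  s <- seq2seq_sample(m, df$source[1], n_unique = 1L, temperature = 0,
                      seed = 1)
  expect_identical(s$raw[1], df$target[1])
})
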