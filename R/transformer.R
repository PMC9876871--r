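# Transformer encoder--decoder over SMILES tokens (post-layer-norm variant
# with sinusoidal positional encodings, trained with Adam and teacher
# forcing). Activations are (B*T) x d matrices with row (b-1)*T + t;
# attention runs over per-(batch,head) slices in C++ (src/attention.cpp).

#' Model hyperparameters
#'
#' The default (`"paper"`) profile uses 512-dimensional token embeddings,
#' 8 attention heads, 3 encoder and 3 decoder sub-layers and a 512-unit
#' feed-forward block, trained for 30 epochs. The `"test"` profile is a
#' desk-scale configuration (64 dimensions, 4 heads, 2 sub-layers) small
#' enough for CPU-only continuous testing.
#'
#' @param profile `"paper"` or `"test"`.
#' @param ... Named overrides of any field.
#' @return A list of class `hyperparams`.
#' @export
hyperparams <- function(profile = c("paper", "test"), ...) {
  profile <- match.arg(profile)
  hp <- if (profile == "paper") {
    list(d_model = 512L, n_heads = 8L, n_encoder_layers = 3L,
         n_decoder_layers = 3L, ff_dim = 512L, dropout = 0.1,
         learning_rate = 5e-4, warmup_steps = 400L, lr_schedule = "cosine",
         batch_size = 64L, epochs = 30L, temperature = 1.0,
         max_decode_len = 120L, seed = 1L)
  } else {
    list(d_model = 64L, n_heads = 4L, n_encoder_layers = 2L,
         n_decoder_layers = 2L, ff_dim = 256L, dropout = 0,
         learning_rate = 3e-3, warmup_steps = 100L, lr_schedule = "cosine",
         batch_size = 64L, epochs = 10L, temperature = 1.0,
         max_decode_len = 70L, seed = 1L)
  }
  ov <- list(...)
  hp[names(ov)] <- ov
  if (hp$d_model %% hp$n_heads != 0) {
    stop("d_model must be divisible by n_heads")
  }
  structure(hp, class = "hyperparams")
}

# ---- parameter initialisation ----------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

.xavier <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -r, r), nin, nout)
}

.init_attn <- function(d) {
  list(Wq = .xavier(d, d), bq = numeric(d), Wk = .xavier(d, d),
       bk = numeric(d), Wv = .xavier(d, d), bv = numeric(d),
       Wo = .xavier(d, d), bo = numeric(d))
}

.init_ln <- function(d) list(g = rep(1, d), b = numeric(d))

.init_ff <- function(d, f) {
  list(W1 = .xavier(d, f), b1 = numeric(f), W2 = .xavier(f, d),
       b2 = numeric(d))
}

.init_params <- function(hp, V) {
  d <- hp$d_model; f <- hp$ff_dim
  enc <- lapply(seq_len(hp$n_encoder_layers), function(i) {
    list(attn = .init_attn(d), ln1 = .init_ln(d), ff = .init_ff(d, f),
         ln2 = .init_ln(d))
  })
  dec <- lapply(seq_len(hp$n_decoder_layers), function(i) {
    list(self = .init_attn(d), ln1 = .init_ln(d), cross = .init_attn(d),
         ln2 = .init_ln(d), ff = .init_ff(d, f), ln3 = .init_ln(d))
  })
  list(emb = .xavier(V, d) * sqrt(V / d),  # keep embedding scale modest
       enc = enc, dec = dec,
       out = list(W = .xavier(d, V), b = numeric(V)))
}

.posenc <- function(Tlen, d) {
  pos <- matrix(0, Tlen, d)
  t <- seq_len(Tlen) - 1
  for (i in seq_len(d %/% 2)) {
    w <- 1 / 10000^((2 * (i - 1)) / d)
    pos[, 2 * i - 1] <- sin(t * w)
    pos[, 2 * i] <- cos(t * w)
  }
  pos
}

# ---- primitive layers ------------------------------------------------------

.lin_fwd <- function(X, W, b) .add_bias(X %*% W, b)
.lin_bwd <- function(dY, X, W) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

.ln_fwd <- function(X, p, eps = 1e-5) .ln_fwd_cpp(X, p$g, p$b, eps)
.ln_bwd <- function(dY, cache, p) {
  r <- .ln_bwd_cpp(dY, cache$xhat, cache$inv, p$g)
  list(dX = r$dX, dg = as.numeric(r$dg), db = as.numeric(r$db))
}

.mha_fwd <- function(Xq, Xkv, p, Tq, Tk, B, H, mask) {
  dk <- ncol(Xq) / H
  Q <- .lin_fwd(Xq, p$Wq, p$bq)
  K <- .lin_fwd(Xkv, p$Wk, p$bk)
  V <- .lin_fwd(Xkv, p$Wv, p$bv)
  Qc <- .to_heads(Q, Tq, B, H)
  Kc <- .to_heads(K, Tk, B, H)
  Vc <- .to_heads(V, Tk, B, H)
  a <- .attn_fwd(Qc, Kc, Vc, mask, 1 / sqrt(dk), H)
  O <- .from_heads(a$out, Tq, B, H)
  Y <- .lin_fwd(O, p$Wo, p$bo)
  list(Y = Y, Xq = Xq, Xkv = Xkv, Qc = Qc, Kc = Kc, Vc = Vc, P = a$P, O = O)
}
.mha_bwd <- function(dY, cache, p, Tq, Tk, B, H) {
  dk <- ncol(dY) / H
  lo <- .lin_bwd(dY, cache$O, p$Wo)
  dOc <- .to_heads(lo$dX, Tq, B, H)
  ab <- .attn_bwd(dOc, cache$Qc, cache$Kc, cache$Vc, cache$P, 1 / sqrt(dk))
  dQ <- .from_heads(ab$dQ, Tq, B, H)
  dK <- .from_heads(ab$dK, Tk, B, H)
  dV <- .from_heads(ab$dV, Tk, B, H)
  lq <- .lin_bwd(dQ, cache$Xq, p$Wq)
  lk <- .lin_bwd(dK, cache$Xkv, p$Wk)
  lv <- .lin_bwd(dV, cache$Xkv, p$Wv)
  list(dXq = lq$dX, dXkv = lk$dX + lv$dX,
       g = list(Wq = lq$dW, bq = lq$db, Wk = lk$dW, bk = lk$db,
                Wv = lv$dW, bv = lv$db, Wo = lo$dW, bo = lo$db))
}

.ff_fwd <- function(X, p) {
  H1 <- .lin_fwd(X, p$W1, p$b1)
  A <- pmax(H1, 0)
  list(Y = .lin_fwd(A, p$W2, p$b2), X = X, A = A)
}
.ff_bwd <- function(dY, cache, p) {
  l2 <- .lin_bwd(dY, cache$A, p$W2)
  dA <- l2$dX * (cache$A > 0)
  l1 <- .lin_bwd(dA, cache$X, p$W1)
  list(dX = l1$dX, g = list(W1 = l1$dW, b1 = l1$db, W2 = l2$dW, b2 = l2$db))
}

.dropmask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix(stats::rbinom(nr * nc, 1, 1 - p) / (1 - p), nr, nc)
}
.apply_drop <- function(X, mask) if (is.null(mask)) X else X * mask

# additive masks, one slice per batch element
.pad_mask_cube <- function(Tq, keep, B) {
  # keep: B x Tk logical (TRUE = real token)
  Tk <- ncol(keep)
  m <- array(0, c(Tq, Tk, B))
  for (b in seq_len(B)) m[, !keep[b, ], b] <- -Inf
  m
}
.causal_mask_cube <- function(Tq, keep, B) {
  m <- .pad_mask_cube(Tq, keep, B)
  up <- upper.tri(matrix(0, Tq, Tq))
  for (b in seq_len(B)) m[, , b][up] <- -Inf
  m
}

# ---- full forward / backward ----------------------------------------------

.embed_fwd <- function(ids, params, hp, pos) {
  # ids: B x T; returns (B*T) x d
  Tlen <- ncol(ids); B <- nrow(ids)
  idvec <- as.vector(t(ids))
  params$emb[idvec, , drop = FALSE] * sqrt(hp$d_model) +
    pos[rep(seq_len(Tlen), B), , drop = FALSE]
}

.encoder_fwd <- function(params, hp, pos, src, train = FALSE) {
  B <- nrow(src); S <- ncol(src); H <- hp$n_heads
  skeep <- src != .PAD
  enc_mask <- .pad_mask_cube(S, skeep, B)
  dp <- if (train) hp$dropout else 0
  X <- .embed_fwd(src, params, hp, pos)
  enc_caches <- vector("list", hp$n_encoder_layers)
  for (l in seq_along(params$enc)) {
    p <- params$enc[[l]]
    a <- .mha_fwd(X, X, p$attn, S, S, B, H, enc_mask)
    m1 <- .dropmask(nrow(X), ncol(X), dp)
    l1 <- .ln_fwd(X + .apply_drop(a$Y, m1), p$ln1)
    f <- .ff_fwd(l1$Y, p$ff)
    m2 <- .dropmask(nrow(X), ncol(X), dp)
    l2 <- .ln_fwd(l1$Y + .apply_drop(f$Y, m2), p$ln2)
    enc_caches[[l]] <- list(a = a, l1 = l1, f = f, l2 = l2, m1 = m1, m2 = m2)
    X <- l2$Y
  }
  list(enc_out = X, enc_caches = enc_caches, skeep = skeep)
}

.model_fwd <- function(params, hp, pos, src, tgt_in, train = FALSE,
                       enc = NULL) {
  B <- nrow(src); S <- ncol(src); Tt <- ncol(tgt_in)
  H <- hp$n_heads
  if (is.null(enc)) enc <- .encoder_fwd(params, hp, pos, src, train)
  tkeep <- tgt_in != .PAD
  self_mask <- .causal_mask_cube(Tt, tkeep, B)
  cross_mask <- .pad_mask_cube(Tt, enc$skeep, B)
  dp <- if (train) hp$dropout else 0
  enc_out <- enc$enc_out
  enc_caches <- enc$enc_caches

  Y <- .embed_fwd(tgt_in, params, hp, pos)
  dec_caches <- vector("list", hp$n_decoder_layers)
  for (l in seq_along(params$dec)) {
    p <- params$dec[[l]]
    a <- .mha_fwd(Y, Y, p$self, Tt, Tt, B, H, self_mask)
    m1 <- .dropmask(nrow(Y), ncol(Y), dp)
    l1 <- .ln_fwd(Y + .apply_drop(a$Y, m1), p$ln1)
    cr <- .mha_fwd(l1$Y, enc_out, p$cross, Tt, S, B, H, cross_mask)
    m2 <- .dropmask(nrow(Y), ncol(Y), dp)
    l2 <- .ln_fwd(l1$Y + .apply_drop(cr$Y, m2), p$ln2)
    f <- .ff_fwd(l2$Y, p$ff)
    m3 <- .dropmask(nrow(Y), ncol(Y), dp)
    l3 <- .ln_fwd(l2$Y + .apply_drop(f$Y, m3), p$ln3)
    dec_caches[[l]] <- list(a = a, l1 = l1, cr = cr, l2 = l2, f = f, l3 = l3,
                            m1 = m1, m2 = m2, m3 = m3)
    Y <- l3$Y
  }
  logits <- .lin_fwd(Y, params$out$W, params$out$b)
  list(logits = logits, enc_out = enc_out, enc_caches = enc_caches,
       dec_caches = dec_caches, dec_out = Y, src = src, tgt_in = tgt_in,
       B = B, S = S, Tt = Tt)
}

.rowmax <- function(x) {
  m <- x[, 1]
  for (j in 2:ncol(x)) m <- pmax(m, x[, j])
  m
}

.ce_loss <- function(logits, labels) {
  # labels: integer vector length nrow(logits); PAD rows excluded
  nonpad <- labels != .PAD
  m <- .rowmax(logits)
  ex <- exp(logits - m)
  z <- rowSums(ex)
  p <- ex / z
  idx <- cbind(seq_along(labels), labels)
  ll <- log(p[idx])
  ntok <- sum(nonpad)
  loss <- -sum(ll[nonpad]) / ntok
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  dlogits[!nonpad, ] <- 0
  dlogits <- dlogits / ntok
  list(loss = loss, dlogits = dlogits)
}

.model_bwd <- function(fw, dlogits, params, hp) {
  B <- fw$B; S <- fw$S; Tt <- fw$Tt; H <- hp$n_heads
  g <- list(enc = vector("list", length(params$enc)),
            dec = vector("list", length(params$dec)))
  lo <- .lin_bwd(dlogits, fw$dec_out, params$out$W)
  g$out <- list(W = lo$dW, b = lo$db)
  dY <- lo$dX
  dEnc <- matrix(0, B * S, hp$d_model)
  for (l in rev(seq_along(params$dec))) {
    p <- params$dec[[l]]; ch <- fw$dec_caches[[l]]
    b3 <- .ln_bwd(dY, ch$l3, p$ln3)
    dff_out <- .apply_drop(b3$dX, ch$m3)
    fb <- .ff_bwd(dff_out, ch$f, p$ff)
    d2 <- b3$dX + fb$dX
    b2 <- .ln_bwd(d2, ch$l2, p$ln2)
    dcr_out <- .apply_drop(b2$dX, ch$m2)
    cb <- .mha_bwd(dcr_out, ch$cr, p$cross, Tt, S, B, H)
    dEnc <- dEnc + cb$dXkv
    d1 <- b2$dX + cb$dXq
    b1 <- .ln_bwd(d1, ch$l1, p$ln1)
    dself_out <- .apply_drop(b1$dX, ch$m1)
    sb <- .mha_bwd(dself_out, ch$a, p$self, Tt, Tt, B, H)
    dY <- b1$dX + sb$dXq + sb$dXkv
    g$dec[[l]] <- list(self = sb$g, ln1 = list(g = b1$dg, b = b1$db),
                       cross = cb$g, ln2 = list(g = b2$dg, b = b2$db),
                       ff = fb$g, ln3 = list(g = b3$dg, b = b3$db))
  }
  dtgt_emb <- dY
  dX <- dEnc
  for (l in rev(seq_along(params$enc))) {
    p <- params$enc[[l]]; ch <- fw$enc_caches[[l]]
    b2 <- .ln_bwd(dX, ch$l2, p$ln2)
    dff_out <- .apply_drop(b2$dX, ch$m2)
    fb <- .ff_bwd(dff_out, ch$f, p$ff)
    d1 <- b2$dX + fb$dX
    b1 <- .ln_bwd(d1, ch$l1, p$ln1)
    da_out <- .apply_drop(b1$dX, ch$m1)
    ab <- .mha_bwd(da_out, ch$a, p$attn, S, S, B, H)
    dX <- b1$dX + ab$dXq + ab$dXkv
    g$enc[[l]] <- list(attn = ab$g, ln1 = list(g = b1$dg, b = b1$db),
                       ff = fb$g, ln2 = list(g = b2$dg, b = b2$db))
  }
  dsrc_emb <- dX
  demb <- matrix(0, nrow(params$emb), ncol(params$emb))
  sc <- sqrt(hp$d_model)
  for (pair in list(list(ids = fw$src, d = dsrc_emb),
                    list(ids = fw$tgt_in, d = dtgt_emb))) {
    idvec <- as.vector(t(pair$ids))
    agg <- rowsum(pair$d, group = idvec)
    rows <- as.integer(rownames(agg))
    demb[rows, ] <- demb[rows, ] + agg * sc
  }
  g$emb <- demb
  g
}

# ---- flat parameter utilities (Adam) ---------------------------------------

.leaf_paths <- function(x, prefix = character(0)) {
  if (is.list(x)) {
    nms <- if (is.null(names(x))) as.character(seq_along(x)) else names(x)
    unlist(lapply(seq_along(x), function(i) {
      .leaf_paths(x[[i]], c(prefix, nms[i]))
    }), recursive = FALSE)
  } else {
    stats::setNames(list(prefix), paste(prefix, collapse = "/"))
  }
}

.path_idx <- function(p) if (grepl("^[0-9]+$", p)) as.integer(p) else p
.get_path <- function(x, path) {
  for (p in path) x <- x[[.path_idx(p)]]
  x
}
.set_path <- function(x, path, value) {
  i <- .path_idx(path[1])
  if (length(path) == 1) {
    x[[i]] <- value
  } else {
    x[[i]] <- .set_path(x[[i]], path[-1], value)
  }
  x
}

.adam_init <- function(params) {
  paths <- .leaf_paths(params)
  zeros <- lapply(paths, function(p) {
    v <- .get_path(params, p)
    if (is.matrix(v)) matrix(0, nrow(v), ncol(v)) else numeric(length(v))
  })
  list(paths = paths, m = zeros, v = zeros, t = 0)
}

.adam_step <- function(params, grads, st, lr, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  st$t <- st$t + 1
  for (i in seq_along(st$paths)) {
    p <- st$paths[[i]]
    gr <- .get_path(grads, p)
    if (is.null(gr)) next
    st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * gr
    st$v[[i]] <- b2 * st$v[[i]] + (1 - b2) * gr^2
    mh <- st$m[[i]] / (1 - b1^st$t)
    vh <- st$v[[i]] / (1 - b2^st$t)
    cur <- .get_path(params, p)
    params <- .set_path(params, p, cur - lr * mh / (sqrt(vh) + eps))
  }
  list(params = params, st = st)
}

# ---- batching --------------------------------------------------------------

# pairs_df: data.frame(source, target); returns list of batches with padded
# id matrices src (B x S) and tgt_in/tgt_lab (B x T)
.make_batches <- function(pairs_df, vocab, batch_size) {
  src_ids <- lapply(pairs_df$source, encode_smiles, vocab = vocab)
  tgt_ids <- lapply(pairs_df$target, encode_smiles, vocab = vocab)
  len <- vapply(src_ids, length, 1L) + vapply(tgt_ids, length, 1L)
  ord <- order(len)
  chunks <- split(ord, ceiling(seq_along(ord) / batch_size))
  lapply(chunks, function(ix) {
    S <- max(vapply(src_ids[ix], length, 1L))
    Tt <- max(vapply(tgt_ids[ix], length, 1L)) + 1L  # BOS in / EOS out
    B <- length(ix)
    src <- matrix(.PAD, B, S)
    tin <- matrix(.PAD, B, Tt)
    lab <- matrix(.PAD, B, Tt)
    for (b in seq_len(B)) {
      si <- src_ids[[ix[b]]]
      ti <- tgt_ids[[ix[b]]]
      src[b, seq_along(si)] <- si
      tin[b, seq_len(length(ti) + 1L)] <- c(.BOS, ti)
      lab[b, seq_len(length(ti) + 1L)] <- c(ti, .EOS)
    }
    list(src = src, tgt_in = tin, labels = as.vector(t(lab)))
  })
}

# ---- training --------------------------------------------------------------

#' Train the SMILES sequence-to-sequence transformer
#'
#' Teacher-forced token-level cross-entropy training with Adam. Aligned
#' pairs must be supplied with gaps already removed (alignment is a pairing
#' device, not model input); [pairs_to_df()] does this. Training is
#' reproducible: identical seeds give identical loss histories.
#'
#' @param train_df Data frame with `source` and `target` SMILES columns.
#' @param hp A [hyperparams()] object.
#' @param seed Integer seed controlling initialisation, shuffling and
#'   dropout.
#' @param val_df Optional validation data frame (same columns).
#' @param verbose Print per-epoch losses.
#' @return A `seq2seq_model`: list with `params`, `hp`, `vocab`, `history`
#'   (per-epoch train/validation loss).
#' @export
seq2seq_train <- function(train_df, hp = hyperparams("test"), seed = 1L,
                          val_df = NULL, verbose = FALSE) {
  if (nrow(train_df) < 2) stop("need at least 2 training pairs")
  vocab <- build_vocab(c(train_df$source, train_df$target))
  pos <- .posenc(512L, hp$d_model)
  with_local_seed(seed, {
    params <- .init_params(hp, length(vocab))
    st <- .adam_init(params)
    batches <- .make_batches(train_df, vocab, hp$batch_size)
    total_steps <- length(batches) * hp$epochs
    val_batches <- if (!is.null(val_df) && nrow(val_df) > 0) {
      .make_batches(val_df, vocab, hp$batch_size)
    }
    history <- NULL
    for (ep in seq_len(hp$epochs)) {
      ord <- sample(length(batches))
      tot <- 0; ntok <- 0
      for (bi in ord) {
        ba <- batches[[bi]]
        fw <- .model_fwd(params, hp, pos, ba$src, ba$tgt_in, train = TRUE)
        ce <- .ce_loss(fw$logits, ba$labels)
        nt <- sum(ba$labels != .PAD)
        tot <- tot + ce$loss * nt; ntok <- ntok + nt
        gr <- .model_bwd(fw, ce$dlogits, params, hp)
        wu <- max(1L, hp$warmup_steps %||% 0L)
        lr_t <- hp$learning_rate * min(1, (st$t + 1) / wu)
        if (identical(hp$lr_schedule %||% "cosine", "cosine")) {
          prog <- min(1, st$t / max(1, total_steps))
          lr_t <- lr_t * (0.25 + 0.375 * (1 + cos(pi * prog)))
        }
        up <- .adam_step(params, gr, st, lr_t)
        params <- up$params; st <- up$st
      }
      tl <- tot / ntok
      vl <- NA_real_
      if (!is.null(val_batches)) {
        vt <- 0; vn <- 0
        for (ba in val_batches) {
          fw <- .model_fwd(params, hp, pos, ba$src, ba$tgt_in, train = FALSE)
          ce <- .ce_loss(fw$logits, ba$labels)
          nt <- sum(ba$labels != .PAD)
          vt <- vt + ce$loss * nt; vn <- vn + nt
        }
        vl <- vt / vn
      }
      history <- rbind(history, data.frame(epoch = ep, train_loss = tl,
                                           val_loss = vl))
      if (verbose) {
        message(sprintf("epoch %d: train %.4f val %s", ep, tl,
                        ifelse(is.na(vl), "-", sprintf("%.4f", vl))))
      }
    }
    structure(list(params = params, hp = hp, vocab = vocab, pos = pos,
                   history = history),
              class = "seq2seq_model")
  })
}

#' @export
print.seq2seq_model <- function(x, ...) {
  cat(sprintf(
    "<seq2seq transformer: d=%d heads=%d enc=%d dec=%d vocab=%d epochs=%d>\n",
    x$hp$d_model, x$hp$n_heads, x$hp$n_encoder_layers, x$hp$n_decoder_layers,
    length(x$vocab), nrow(x$history)))
  invisible(x)
}

#' Aligned pairs to model input
#'
#' Strips alignment gaps and returns the `source`/`target` data frame the
#' trainer consumes.
#'
#' @param aligned List of `aligned_pair` objects (or a list of
#'   [structure_pair()]s, in which case canonical strings are used).
#' @return Data frame with `source` and `target` character columns.
#' @export
pairs_to_df <- function(aligned) {
  data.frame(
    source = vapply(aligned, function(p) {
      if (inherits(p, "aligned_pair")) p$source_str else
        canonical_smiles(p$source)
    }, ""),
    target = vapply(aligned, function(p) {
      if (inherits(p, "aligned_pair")) p$target_str else
        canonical_smiles(p$target)
    }, "")
  )
}

# ---- sampling --------------------------------------------------------------

.decode_wave <- function(model, src_row, nwave, temperature, max_len) {
  hp <- model$hp; pos <- model$pos
  src <- matrix(rep(src_row, each = nwave), nrow = nwave)
  enc <- .encoder_fwd(model$params, hp, pos, src, train = FALSE)
  cur <- matrix(.BOS, nwave, 1)
  finished <- rep(FALSE, nwave)
  for (step in seq_len(max_len)) {
    fw <- .model_fwd(model$params, hp, pos, src, cur, train = FALSE,
                     enc = enc)
    Tt <- ncol(cur)
    rows <- (seq_len(nwave) - 1L) * Tt + Tt   # last position of each row
    logits <- fw$logits[rows, , drop = FALSE]
    logits[, .PAD] <- -Inf
    nxt <- integer(nwave)
    if (temperature <= 0) {
      nxt <- max.col(logits, ties.method = "first")
    } else {
      sc <- logits / temperature
      sc <- sc - .rowmax(sc)
      pr <- exp(sc); pr <- pr / rowSums(pr)
      for (b in seq_len(nwave)) {
        nxt[b] <- sample.int(ncol(pr), 1, prob = pr[b, ])
      }
    }
    nxt[finished] <- .PAD
    finished <- finished | nxt == .EOS
    cur <- cbind(cur, nxt)
    if (all(finished)) break
  }
  apply(cur, 1, function(ids) {
    ids <- ids[-1]
    stop_at <- which(ids == .EOS)
    if (length(stop_at) > 0) ids <- ids[seq_len(stop_at[1] - 1L)]
    decode_ids(ids, model$vocab)
  })
}

#' Sample structures from a trained model
#'
#' Multinomial per-token sampling at the given temperature (argmax when
#' `temperature <= 0`), repeated in waves until `n_unique` unique valid
#' canonical structures are collected or the attempt budget is exhausted.
#' Invalid strings stay in the raw list so validity can be scored.
#'
#' @param model A `seq2seq_model`.
#' @param source_smiles Input skeleton SMILES.
#' @param n_unique Unique valid structures requested.
#' @param temperature Softmax temperature.
#' @param max_len Decode length cap.
#' @param seed Integer seed.
#' @param attempt_budget Maximum raw samples drawn.
#' @return List with `raw` (all sampled strings), `unique` (canonical
#'   SMILES of unique valid structures), `graphs` (their `molgraph`s) and
#'   `n_attempts`.
#' @export
seq2seq_sample <- function(model, source_smiles, n_unique = 100L,
                           temperature = 1.0, max_len = NULL, seed = 1L,
                           attempt_budget = 20L * n_unique) {
  if (is.null(max_len)) max_len <- model$hp$max_decode_len
  src_row <- c(encode_smiles(source_smiles, model$vocab), .EOS)
  raw <- character(0)
  uniq <- character(0)
  graphs <- list()
  with_local_seed(seed, {
    while (length(uniq) < n_unique && length(raw) < attempt_budget) {
      nwave <- min(max(n_unique, 32L), attempt_budget - length(raw))
      out <- .decode_wave(model, src_row, nwave, temperature, max_len)
      raw <- c(raw, out)
      gs <- parse_smiles_batch(out)
      for (g in gs) {
        if (is_parse_failure(g) || !is_connected_mol(g)) next
        cs <- canonical_smiles(g)
        if (!(cs %in% uniq)) {
          uniq <- c(uniq, cs)
          graphs[[length(graphs) + 1]] <- g
        }
        if (length(uniq) >= n_unique) break
      }
      if (temperature <= 0) break  # deterministic decode cannot diversify
    }
  })
  if (length(uniq) > n_unique) {
    graphs <- graphs[seq_len(n_unique)]
    uniq <- uniq[seq_len(n_unique)]
  }
  if (length(uniq) < n_unique && temperature > 0) {
    warning("attempt budget exhausted: ", length(uniq), " of ", n_unique,
            " unique structures")
  }
  list(raw = raw, unique = uniq, graphs = graphs, n_attempts = length(raw))
}

#' Greedy decode
#'
#' @param model A `seq2seq_model`.
#' @param source_smiles Input SMILES.
#' @param max_len Decode length cap.
#' @return The argmax-decoded output string.
#' @export
greedy_decode <- function(model, source_smiles, max_len = NULL) {
  seq2seq_sample(model, source_smiles, n_unique = 1L, temperature = 0,
                 max_len = max_len, seed = 1L, attempt_budget = 1L)$raw[1]
}
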