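# Small neural text classifiers over token-id sequences with jointly
# trained word embeddings: a 1-D convolutional network (32 kernels of
# width 3, ReLU, max pooling over time, two dense layers ending in
# softmax) and a bidirectional LSTM with a softmax head. Forward and
# backward passes are vectorized over the mini-batch; right-padding is
# masked so state carries through padded steps.

#' Encode token documents as padded id sequences
#'
#' Sequence length is capped at the given quantile of document lengths
#' (at least 3, the convolution width); shorter documents are
#' right-padded with id 0.
#'
#' @param docs List of [token_doc()]s.
#' @param cap_quantile Length-cap quantile (default 0.95).
#' @return List with `ids` (n x L integer matrix), `vocab`,
#'   `vocab_size`, `seq_len`.
#' @export
encode_sequences <- function(docs, cap_quantile = 0.95) {
  toks <- lapply(docs, `[[`, "tokens")
  vocab <- sort(unique(unlist(toks)))
  lens <- lengths(toks)
  L <- max(3L, as.integer(ceiling(stats::quantile(lens, cap_quantile))))
  ids <- matrix(0L, length(toks), L)
  for (i in seq_along(toks)) {
    tk <- head(toks[[i]], L)
    if (length(tk)) ids[i, seq_along(tk)] <- match(tk, vocab)
  }
  list(ids = ids, vocab = vocab, vocab_size = length(vocab), seq_len = L)
}

#' Build an untrained neural classifier
#'
#' @param spec A [classifier_spec()] with name `"cnn_embed"` or
#'   `"rnn_embed"`.
#' @param vocab_size Vocabulary size (ids `1..vocab_size`; 0 = padding).
#' @param n_classes Number of output classes.
#' @return A `neural_model`: parameter list, architecture metadata and
#'   `n_params` (total trainable parameter count).
#' @export
build_neural <- function(spec, vocab_size, n_classes) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (!spec$name %in% c("cnn_embed", "rnn_embed")) {
    stop("build_neural expects a cnn_embed or rnn_embed spec")
  }
  hp <- spec$hyperparams
  d <- hp$emb_dim %||% 32L
  h <- hp$hidden %||% 32L
  K <- as.integer(n_classes)
  V <- as.integer(vocab_size)
  init <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
  params <- with_local_seed(spec$seed, {
    if (spec$name == "cnn_embed") {
      nf <- 32L # convolution kernels, width 3 (fixed architecture)
      list(
        E = init(V, d, 0.1),
        Wc = init(3L * d, nf, sqrt(2 / (3 * d))), bc = numeric(nf),
        W1 = init(nf, h, sqrt(2 / nf)), b1 = numeric(h),
        W2 = init(h, K, sqrt(2 / h)), b2 = numeric(K)
      )
    } else {
      list(
        E = init(V, d, 0.1),
        Wx_f = init(d, 4L * h, 0.1), Wh_f = init(h, 4L * h, 0.1),
        bg_f = numeric(4L * h),
        Wx_b = init(d, 4L * h, 0.1), Wh_b = init(h, 4L * h, 0.1),
        bg_b = numeric(4L * h),
        Wo = init(2L * h, K, sqrt(2 / (2 * h))), bo = numeric(K)
      )
    }
  })
  structure(
    list(
      name = spec$name, params = params, emb_dim = d, hidden = h,
      n_classes = K, vocab_size = V,
      n_params = sum(vapply(params, length, integer(1))),
      classes = NULL
    ),
    class = "neural_model"
  )
}

# Embedding lookup helper: E0 has a fixed zero row for padding id 0.
emb_table <- function(E) rbind(0, E)

sigm <- function(x) 1 / (1 + exp(-x))

# --- CNN forward/backward ---------------------------------------------------

cnn_forward <- function(model, ids, keep_cache = FALSE) {
  p <- model$params
  B <- nrow(ids); L <- ncol(ids)
  L2 <- L - 2L
  stopifnot(L2 >= 1)
  E0 <- emb_table(p$E)
  d <- model$emb_dim
  # rows of Z are (t, b) pairs in column-major order: row (t-1)*B + b
  Z <- cbind(
    E0[as.vector(ids[, 1:L2, drop = FALSE]) + 1L, , drop = FALSE],
    E0[as.vector(ids[, 2:(L2 + 1), drop = FALSE]) + 1L, , drop = FALSE],
    E0[as.vector(ids[, 3:L, drop = FALSE]) + 1L, , drop = FALSE]
  )
  Hpre <- Z %*% p$Wc + rep(p$bc, each = nrow(Z))
  H <- pmax(Hpre, 0)
  nf <- ncol(H)
  M <- matrix(-Inf, B, nf)
  amax <- matrix(1L, B, nf)
  for (t in seq_len(L2)) {
    rows <- ((t - 1L) * B + 1L):(t * B)
    Ht <- H[rows, , drop = FALSE]
    better <- Ht > M
    M[better] <- Ht[better]
    amax[better] <- t
  }
  A1pre <- M %*% p$W1 + rep(p$b1, each = B)
  A1 <- pmax(A1pre, 0)
  logits <- A1 %*% p$W2 + rep(p$b2, each = B)
  P <- softmax_rows(logits)
  if (!keep_cache) return(list(prob = P))
  list(prob = P, Z = Z, H = H, M = M, amax = amax, A1 = A1, L2 = L2, B = B)
}

cnn_backward <- function(model, ids, cache, Y) {
  p <- model$params
  B <- cache$B; L2 <- cache$L2; L <- ncol(ids)
  dlogits <- (cache$prob - Y) / B
  dW2 <- crossprod(cache$A1, dlogits)
  db2 <- colSums(dlogits)
  dA1 <- (dlogits %*% t(p$W2)) * (cache$A1 > 0)
  dW1 <- crossprod(cache$M, dA1)
  db1 <- colSums(dA1)
  dM <- dA1 %*% t(p$W1)
  nf <- ncol(dM)
  dH <- matrix(0, nrow(cache$H), nf)
  # scatter pooled gradients back to the argmax time steps
  rowidx <- (cache$amax - 1L) * B + row(cache$amax)
  dH[cbind(as.vector(rowidx), as.vector(col(cache$amax)))] <- as.vector(dM)
  dH <- dH * (cache$H > 0)
  dWc <- crossprod(cache$Z, dH)
  dbc <- colSums(dH)
  dZ <- dH %*% t(p$Wc)
  d <- model$emb_dim
  dE <- matrix(0, model$vocab_size, d)
  for (s in 1:3) {
    tok <- as.vector(ids[, s:(s + L2 - 1L), drop = FALSE])
    blk <- dZ[, ((s - 1L) * d + 1L):(s * d), drop = FALSE]
    nz <- tok > 0L
    if (any(nz)) {
      acc <- rowsum(blk[nz, , drop = FALSE], tok[nz])
      dE[as.integer(rownames(acc)), ] <-
        dE[as.integer(rownames(acc)), , drop = FALSE] + acc
    }
  }
  list(E = dE, Wc = dWc, bc = dbc, W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

# --- bidirectional LSTM forward/backward ------------------------------------

lstm_direction <- function(E0, ids, order_t, Wx, Wh, bg, h) {
  B <- nrow(ids)
  hh <- matrix(0, B, h); cc <- matrix(0, B, h)
  cache <- vector("list", length(order_t))
  for (s in seq_along(order_t)) {
    t <- order_t[s]
    x <- E0[ids[, t] + 1L, , drop = FALSE]
    A <- x %*% Wx + hh %*% Wh + rep(bg, each = B)
    i <- sigm(A[, 1:h, drop = FALSE])
    f <- sigm(A[, (h + 1):(2 * h), drop = FALSE])
    o <- sigm(A[, (2 * h + 1):(3 * h), drop = FALSE])
    g <- tanh(A[, (3 * h + 1):(4 * h), drop = FALSE])
    c_raw <- f * cc + i * g
    tc <- tanh(c_raw)
    h_raw <- o * tc
    m <- (ids[, t] > 0L) * 1
    h_new <- m * h_raw + (1 - m) * hh
    c_new <- m * c_raw + (1 - m) * cc
    cache[[s]] <- list(x = x, i = i, f = f, o = o, g = g,
                       c_prev = cc, h_prev = hh, c_raw = c_raw, tc = tc,
                       m = m, t = t)
    hh <- h_new; cc <- c_new
  }
  list(h_final = hh, cache = cache)
}

lstm_direction_backward <- function(dh_final, cache, Wx, Wh, h, ids,
                                    vocab_size, emb_dim) {
  B <- nrow(dh_final)
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  dbg <- numeric(4 * h)
  dE <- matrix(0, vocab_size, emb_dim)
  dh <- dh_final
  dc <- matrix(0, B, h)
  for (s in rev(seq_along(cache))) {
    cs <- cache[[s]]
    m <- cs$m
    dh_raw <- m * dh
    dh_carry <- (1 - m) * dh
    dc_raw <- m * dc
    dc_carry <- (1 - m) * dc
    do <- dh_raw * cs$tc
    dc_raw <- dc_raw + dh_raw * cs$o * (1 - cs$tc^2)
    di <- dc_raw * cs$g
    dg <- dc_raw * cs$i
    df <- dc_raw * cs$c_prev
    dc_prev <- dc_raw * cs$f + dc_carry
    dA <- cbind(
      di * cs$i * (1 - cs$i),
      df * cs$f * (1 - cs$f),
      do * cs$o * (1 - cs$o),
      dg * (1 - cs$g^2)
    )
    dWx <- dWx + crossprod(cs$x, dA)
    dWh <- dWh + crossprod(cs$h_prev, dA)
    dbg <- dbg + colSums(dA)
    dx <- dA %*% t(Wx)
    tok <- ids[, cs$t]
    nz <- tok > 0L
    if (any(nz)) {
      acc <- rowsum(dx[nz, , drop = FALSE], tok[nz])
      dE[as.integer(rownames(acc)), ] <-
        dE[as.integer(rownames(acc)), , drop = FALSE] + acc
    }
    dh <- dA %*% t(Wh) + dh_carry
    dc <- dc_prev
  }
  list(dWx = dWx, dWh = dWh, dbg = dbg, dE = dE)
}

rnn_forward <- function(model, ids, keep_cache = FALSE) {
  p <- model$params
  E0 <- emb_table(p$E)
  h <- model$hidden
  L <- ncol(ids)
  fwd <- lstm_direction(E0, ids, seq_len(L), p$Wx_f, p$Wh_f, p$bg_f, h)
  bwd <- lstm_direction(E0, ids, rev(seq_len(L)), p$Wx_b, p$Wh_b, p$bg_b, h)
  Hcat <- cbind(fwd$h_final, bwd$h_final)
  logits <- Hcat %*% p$Wo + rep(p$bo, each = nrow(ids))
  P <- softmax_rows(logits)
  if (!keep_cache) return(list(prob = P))
  list(prob = P, fwd = fwd, bwd = bwd, Hcat = Hcat)
}

rnn_backward <- function(model, ids, cache, Y) {
  p <- model$params
  h <- model$hidden
  B <- nrow(ids)
  dlogits <- (cache$prob - Y) / B
  dWo <- crossprod(cache$Hcat, dlogits)
  dbo <- colSums(dlogits)
  dH <- dlogits %*% t(p$Wo)
  gf <- lstm_direction_backward(dH[, 1:h, drop = FALSE], cache$fwd$cache,
                                p$Wx_f, p$Wh_f, h, ids,
                                model$vocab_size, model$emb_dim)
  gb <- lstm_direction_backward(dH[, (h + 1):(2 * h), drop = FALSE],
                                cache$bwd$cache, p$Wx_b, p$Wh_b, h, ids,
                                model$vocab_size, model$emb_dim)
  list(
    E = gf$dE + gb$dE,
    Wx_f = gf$dWx, Wh_f = gf$dWh, bg_f = gf$dbg,
    Wx_b = gb$dWx, Wh_b = gb$dWh, bg_b = gb$dbg,
    Wo = dWo, bo = dbo
  )
}

# --- shared driver ----------------------------------------------------------

#' Forward pass of a neural model
#'
#' @param model A `neural_model`.
#' @param ids Padded id matrix as from [encode_sequences()].
#' @return Matrix of class probabilities (rows sum to 1).
#' @export
neural_forward <- function(model, ids) {
  if (model$name == "cnn_embed") cnn_forward(model, ids)$prob
  else rnn_forward(model, ids)$prob
}

#' Train a neural classifier
#'
#' Cross-entropy loss, Adam optimizer, shuffled mini-batches. Documents
#' whose sequences are empty after preprocessing are dropped from
#' training with a warning.
#'
#' @param spec A [classifier_spec()] (`cnn_embed` or `rnn_embed`).
#' @param ids Padded id matrix.
#' @param y Integer labels.
#' @param vocab_size Vocabulary size.
#' @param seed Integer seed.
#' @return A trained `neural_model` (element `classes` maps softmax
#'   columns back to labels).
#' @export
neural_fit <- function(spec, ids, y, vocab_size, seed = spec$seed) {
  hp <- spec$hyperparams
  classes <- sort(unique(y))
  nonempty <- rowSums(ids > 0) > 0
  if (!all(nonempty)) {
    warning(sum(!nonempty), " document(s) empty after preprocessing; ",
            "dropped from training")
    ids <- ids[nonempty, , drop = FALSE]
    y <- y[nonempty]
  }
  model <- build_neural(spec, vocab_size, length(classes))
  model$classes <- classes
  yk <- match(y, classes)
  n <- nrow(ids)
  epochs <- hp$epochs %||% 30L
  batch <- hp$batch %||% 32L
  lr <- hp$lr %||% 5e-3
  adam <- adam_state(model$params, lr)
  with_local_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = batch)) {
        idx <- ord[start:min(start + batch - 1, n)]
        bi <- ids[idx, , drop = FALSE]
        Y <- matrix(0, length(idx), length(classes))
        Y[cbind(seq_along(idx), yk[idx])] <- 1
        if (model$name == "cnn_embed") {
          cache <- cnn_forward(model, bi, keep_cache = TRUE)
          grads <- cnn_backward(model, bi, cache, Y)
        } else {
          cache <- rnn_forward(model, bi, keep_cache = TRUE)
          grads <- rnn_backward(model, bi, cache, Y)
        }
        upd <- adam_step(adam, grads)
        adam <- upd$state
        model$params <- upd$params
      }
    }
  })
  model
}

#' @rdname neural_fit
#' @export
neural_predict <- function(model, ids) {
  P <- neural_forward(model, ids)
  model$classes[max.col(P, ties.method = "first")]
}
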