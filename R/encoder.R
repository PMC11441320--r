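#' Tiny trainable transformer encoder
#'
#' A pre-layer-norm transformer encoder (token + position embeddings,
#' multi-head scaled-dot-product self-attention, ReLU feed-forward,
#' residual connections, final layer norm) with a two-way softmax decision
#' layer on the `[CLS]` position. The pre-norm arrangement keeps the
#' residual stream unnormalized, which trains stably from random
#' initialization at this scale. Forward and backward passes are written out
#' explicitly in matrix form, which keeps the model free of external
#' deep-learning dependencies and makes layer-wise gradients (needed by
#' layer integrated gradients) directly accessible. Gradients are verified
#' against finite differences in the test suite.
#'
#' @param vocab_size vocabulary size (token ids are 1-based).
#' @param config a [model_config] providing `d_model`, `n_layers`,
#'   `n_heads`, `d_ff`, `msl` and `seed`.
#' @return an object of class `re_encoder`: list with `params` (named list
#'   of weight matrices), `config`, `vocab_size`.
#' @export
encoder_init <- function(vocab_size, config) {
  d <- config$d_model; L <- config$n_layers; dff <- config$d_ff
  rnorm_mat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
  params <- with_seed(config$seed, {
    p <- list(E_tok = rnorm_mat(vocab_size, d),
              E_pos = rnorm_mat(config$msl, d))
    for (l in seq_len(L)) {
      pre <- sprintf("L%d.", l)
      p[[paste0(pre, "Wq")]] <- rnorm_mat(d, d)
      p[[paste0(pre, "bq")]] <- numeric(d)
      p[[paste0(pre, "Wk")]] <- rnorm_mat(d, d)
      p[[paste0(pre, "bk")]] <- numeric(d)
      p[[paste0(pre, "Wv")]] <- rnorm_mat(d, d)
      p[[paste0(pre, "bv")]] <- numeric(d)
      p[[paste0(pre, "Wo")]] <- rnorm_mat(d, d)
      p[[paste0(pre, "bo")]] <- numeric(d)
      p[[paste0(pre, "g1")]] <- rep(1, d)
      p[[paste0(pre, "h1")]] <- numeric(d)
      p[[paste0(pre, "W1")]] <- rnorm_mat(d, dff)
      p[[paste0(pre, "c1")]] <- numeric(dff)
      p[[paste0(pre, "W2")]] <- rnorm_mat(dff, d)
      p[[paste0(pre, "c2")]] <- numeric(d)
      p[[paste0(pre, "g2")]] <- rep(1, d)
      p[[paste0(pre, "h2")]] <- numeric(d)
    }
    p$gf <- rep(1, d)
    p$hf <- numeric(d)
    p$Wc <- rnorm_mat(d, 2)
    p$bc <- numeric(2)
    p
  })
  structure(list(params = params, config = config, vocab_size = vocab_size),
            class = "re_encoder")
}

#' @export
print.re_encoder <- function(x, ...) {
  cat(sprintf("<re_encoder: %d layers, d_model=%d, %d heads, vocab=%d>\n",
              x$config$n_layers, x$config$d_model, x$config$n_heads,
              x$vocab_size))
  invisible(x)
}

addb <- function(M, b) M + rep(b, each = nrow(M))

softmax_rows <- function(S) {
  E <- exp(S - max(S))
  E / rowSums(E)
}

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc * Xc)
  inv_std <- 1 / sqrt(v + eps)
  xhat <- Xc * inv_std
  list(xhat = xhat, inv_std = inv_std,
       y = addb(xhat * rep(g, each = nrow(X)), b))
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat; inv_std <- cache$inv_std
  dxhat <- dy * rep(g, each = nrow(dy))
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv_std
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

layer_forward <- function(params, l, X, n_heads) {
  pre <- sprintf("L%d.", l)
  d <- ncol(X); dh <- d %/% n_heads
  ln1 <- layernorm_fwd(X, params[[paste0(pre, "g1")]], params[[paste0(pre, "h1")]])
  Y1 <- ln1$y
  Q <- addb(Y1 %*% params[[paste0(pre, "Wq")]], params[[paste0(pre, "bq")]])
  K <- addb(Y1 %*% params[[paste0(pre, "Wk")]], params[[paste0(pre, "bk")]])
  V <- addb(Y1 %*% params[[paste0(pre, "Wv")]], params[[paste0(pre, "bv")]])
  A <- vector("list", n_heads)
  O <- matrix(0, nrow(X), d)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dh)
    A[[h]] <- softmax_rows(S)
    O[, idx] <- A[[h]] %*% V[, idx, drop = FALSE]
  }
  attn <- addb(O %*% params[[paste0(pre, "Wo")]], params[[paste0(pre, "bo")]])
  R1 <- X + attn
  ln2 <- layernorm_fwd(R1, params[[paste0(pre, "g2")]], params[[paste0(pre, "h2")]])
  Y2 <- ln2$y
  H1 <- addb(Y2 %*% params[[paste0(pre, "W1")]], params[[paste0(pre, "c1")]])
  Hr <- pmax(H1, 0)
  FF <- addb(Hr %*% params[[paste0(pre, "W2")]], params[[paste0(pre, "c2")]])
  list(out = R1 + FF, X = X, Y1 = Y1, Q = Q, K = K, V = V, A = A, O = O,
       ln1 = ln1, ln2 = ln2, Y2 = Y2, H1 = H1, Hr = Hr)
}

layer_backward <- function(params, l, cache, dout, n_heads) {
  pre <- sprintf("L%d.", l)
  d <- ncol(cache$X); dh <- d %/% n_heads
  g <- list()

  # out = R1 + FFN(LN2(R1)); R1 = X + Attn(LN1(X))
  dR1 <- dout
  dFF <- dout
  g[[paste0(pre, "W2")]] <- crossprod(cache$Hr, dFF)
  g[[paste0(pre, "c2")]] <- colSums(dFF)
  dHr <- tcrossprod(dFF, params[[paste0(pre, "W2")]])
  dH1 <- dHr * (cache$H1 > 0)
  g[[paste0(pre, "W1")]] <- crossprod(cache$Y2, dH1)
  g[[paste0(pre, "c1")]] <- colSums(dH1)
  dY2 <- tcrossprod(dH1, params[[paste0(pre, "W1")]])
  b2 <- layernorm_bwd(dY2, cache$ln2, params[[paste0(pre, "g2")]])
  g[[paste0(pre, "g2")]] <- b2$dg; g[[paste0(pre, "h2")]] <- b2$db
  dR1 <- dR1 + b2$dx

  dX <- dR1
  dattn <- dR1
  g[[paste0(pre, "Wo")]] <- crossprod(cache$O, dattn)
  g[[paste0(pre, "bo")]] <- colSums(dattn)
  dO <- tcrossprod(dattn, params[[paste0(pre, "Wo")]])

  dQ <- matrix(0, nrow(dO), d); dK <- dQ; dV <- dQ
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    Ah <- cache$A[[h]]
    dOh <- dO[, idx, drop = FALSE]
    Vh <- cache$V[, idx, drop = FALSE]
    dAh <- tcrossprod(dOh, Vh)
    dV[, idx] <- crossprod(Ah, dOh)
    dS <- Ah * (dAh - rowSums(Ah * dAh))
    dS <- dS / sqrt(dh)
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE]
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE])
  }
  g[[paste0(pre, "Wq")]] <- crossprod(cache$Y1, dQ)
  g[[paste0(pre, "bq")]] <- colSums(dQ)
  g[[paste0(pre, "Wk")]] <- crossprod(cache$Y1, dK)
  g[[paste0(pre, "bk")]] <- colSums(dK)
  g[[paste0(pre, "Wv")]] <- crossprod(cache$Y1, dV)
  g[[paste0(pre, "bv")]] <- colSums(dV)
  dY1 <- tcrossprod(dQ, params[[paste0(pre, "Wq")]]) +
    tcrossprod(dK, params[[paste0(pre, "Wk")]]) +
    tcrossprod(dV, params[[paste0(pre, "Wv")]])
  b1 <- layernorm_bwd(dY1, cache$ln1, params[[paste0(pre, "g1")]])
  g[[paste0(pre, "g1")]] <- b1$dg; g[[paste0(pre, "h1")]] <- b1$db
  dX <- dX + b1$dx
  list(dX = dX, grads = g)
}

#' Forward pass
#'
#' @param model an [encoder_init] model.
#' @param ids integer token ids (length <= `msl`).
#' @param keep_cache cache intermediates for [encoder_backward] /
#'   layer-wise access (`cache$layer_out[[l + 1]]` is the output of layer
#'   `l`, index 1 being the embedding output).
#' @return list with `probs` (length 2, negative/positive), `logits`, and
#'   `cache` when requested.
#' @export
encoder_forward <- function(model, ids, keep_cache = FALSE) {
  p <- model$params
  T_ <- length(ids)
  X <- p$E_tok[ids, , drop = FALSE] + p$E_pos[seq_len(T_), , drop = FALSE]
  layer_out <- vector("list", model$config$n_layers + 1L)
  layer_out[[1]] <- X
  caches <- vector("list", model$config$n_layers)
  for (l in seq_len(model$config$n_layers)) {
    caches[[l]] <- layer_forward(p, l, X, model$config$n_heads)
    X <- caches[[l]]$out
    layer_out[[l + 1L]] <- X
  }
  lnf <- layernorm_fwd(X, p$gf, p$hf)
  h <- lnf$y[1, ]
  logits <- drop(h %*% p$Wc) + p$bc
  m <- max(logits)
  probs <- exp(logits - m); probs <- probs / sum(probs)
  res <- list(probs = probs, logits = logits)
  if (keep_cache)
    res$cache <- list(ids = ids, layer_out = layer_out, caches = caches,
                      lnf = lnf, h = h)
  res
}

#' Forward pass starting from a layer's activations
#'
#' Runs layers `layer + 1 .. L` and the decision layer on supplied
#' activations, as needed by path-integration attribution on an
#' intermediate layer.
#'
#' @param model the encoder model.
#' @param acts activation matrix (tokens x d_model) standing in for the
#'   output of layer `layer` (0 = embedding output).
#' @param layer layer index in `0..n_layers`.
#' @param keep_cache cache intermediates for [encoder_backward_to].
#' @return as [encoder_forward].
#' @export
encoder_forward_from <- function(model, acts, layer, keep_cache = FALSE) {
  p <- model$params
  L <- model$config$n_layers
  if (layer < 0 || layer > L) stop("layer must be in 0..n_layers")
  X <- acts
  caches <- vector("list", L)
  for (l in seq_len(L)) {
    if (l <= layer) next
    caches[[l]] <- layer_forward(p, l, X, model$config$n_heads)
    X <- caches[[l]]$out
  }
  lnf <- layernorm_fwd(X, p$gf, p$hf)
  h <- lnf$y[1, ]
  logits <- drop(h %*% p$Wc) + p$bc
  m <- max(logits)
  probs <- exp(logits - m); probs <- probs / sum(probs)
  res <- list(probs = probs, logits = logits)
  if (keep_cache) res$cache <- list(caches = caches, lnf = lnf, h = h,
                                    from_layer = layer)
  res
}

#' Backward pass: parameter gradients
#'
#' Backpropagates `dlogits` through the decision layer and all encoder
#' layers, returning gradients for every parameter (including the token
#' and position embedding rows touched by the input).
#'
#' @param model the encoder model.
#' @param fwd result of [encoder_forward] with `keep_cache = TRUE`.
#' @param dlogits length-2 gradient at the logits.
#' @return named list of gradients, same shapes as `model$params`.
#' @export
encoder_backward <- function(model, fwd, dlogits) {
  p <- model$params; cache <- fwd$cache
  L <- model$config$n_layers
  g <- list(Wc = outer(cache$h, dlogits), bc = dlogits)
  dXf <- matrix(0, nrow(cache$layer_out[[1]]), model$config$d_model)
  dXf[1, ] <- drop(p$Wc %*% dlogits)
  bf <- layernorm_bwd(dXf, cache$lnf, p$gf)
  g$gf <- bf$dg; g$hf <- bf$db
  dX <- bf$dx
  for (l in rev(seq_len(L))) {
    bk <- layer_backward(p, l, cache$caches[[l]], dX, model$config$n_heads)
    dX <- bk$dX
    g <- c(g, bk$grads)
  }
  ids <- cache$ids
  dE_tok <- matrix(0, model$vocab_size, model$config$d_model)
  for (i in seq_along(ids)) dE_tok[ids[i], ] <- dE_tok[ids[i], ] + dX[i, ]
  dE_pos <- matrix(0, nrow(p$E_pos), model$config$d_model)
  dE_pos[seq_along(ids), ] <- dX
  g$E_tok <- dE_tok
  g$E_pos <- dE_pos
  g
}

#' Backward pass to a layer's activations
#'
#' Gradient of a scalar in logit space (via `dlogits`) with respect to the
#' activations the forward pass in [encoder_forward_from] started from.
#'
#' @param model the encoder model.
#' @param fwd result of [encoder_forward_from] with `keep_cache = TRUE`.
#' @param dlogits length-2 gradient at the logits.
#' @param n_tokens number of token rows.
#' @return matrix (tokens x d_model) of gradients w.r.t. the activations.
#' @export
encoder_backward_to <- function(model, fwd, dlogits, n_tokens) {
  p <- model$params; cache <- fwd$cache
  L <- model$config$n_layers
  dXf <- matrix(0, n_tokens, model$config$d_model)
  dXf[1, ] <- drop(p$Wc %*% dlogits)
  bf <- layernorm_bwd(dXf, cache$lnf, p$gf)
  dX <- bf$dx
  for (l in rev(seq_len(L))) {
    if (l <= cache$from_layer) break
    bk <- layer_backward(p, l, cache$caches[[l]], dX, model$config$n_heads)
    dX <- bk$dX
  }
  dX
}

# gradient of the positive-class probability w.r.t. the logits
dlogits_positive_prob <- function(probs) {
  probs[2] * (c(0, 1) - probs)
}
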