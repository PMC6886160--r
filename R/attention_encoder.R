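#' Sinusoidal positional encoding
#'
#' `pe[t, 2i] = sin(t / 10000^(2i/d_model))`,
#' `pe[t, 2i+1] = cos(t / 10000^(2i/d_model))`, positions `t` counted 0-based
#' from the sequence start (row 1 is `t = 0`). For any fixed offset `k`,
#' `pe[t+k]` is a linear (rotation) function of `pe[t]`, which is what lets
#' an order-agnostic encoder attend by relative position.
#'
#' @param T_len Sequence length.
#' @param d_model Even embedding dimension.
#' @return `T_len x d_model` matrix.
#' @export
positional_encoding <- function(T_len, d_model) {
  if (d_model %% 2L != 0L) stop("d_model must be even")
  t_pos <- seq_len(T_len) - 1
  i <- seq_len(d_model %/% 2L) - 1
  inv_freq <- 1 / (10000^(2 * i / d_model))
  ang <- outer(t_pos, inv_freq)          # T x d/2
  pe <- matrix(0, T_len, d_model)
  pe[, 2L * (i + 1L) - 1L] <- sin(ang)
  pe[, 2L * (i + 1L)] <- cos(ang)
  pe
}

#' Scaled dot-product attention
#'
#' `Softmax(Q K' / sqrt(d_k)) V`, softmax taken row-wise. Masked-off key
#' positions receive `-Inf` scores before the softmax, so their weights are
#' exactly zero and each output row is a convex combination of valid value
#' rows.
#'
#' @param Q `T x d_q` query matrix (`d_q = d_k`).
#' @param K `T x d_k` key matrix.
#' @param V `T x d_v` value matrix.
#' @param mask Length-`T` logical key-validity vector (`NULL` = all valid).
#' @return `T x d_v` output matrix, with the `T x T` weight matrix attached
#'   as attribute `"weights"`.
#' @export
scaled_dot_product_attention <- function(Q, K, V, mask = NULL) {
  if (ncol(Q) != ncol(K)) stop("d_q must equal d_k")
  d_k <- ncol(K)
  S <- Q %*% t(K) / sqrt(d_k)
  if (!is.null(mask)) {
    if (!any(mask)) stop("attention with zero valid keys")
    S[, !mask] <- -Inf
  }
  P <- row_softmax(S)
  out <- P %*% V
  attr(out, "weights") <- P
  out
}

#' Multi-head attention parameters
#'
#' Per head `i`: projections `W_Q`, `W_K`, `W_V` of shape
#' `d_model x d_model/h` (so `d_q = d_k = d_v = d_model / h`), plus the
#' output projection `W_O` (`h * d_v x d_model`). Initialization uniform on
#' `[-1/sqrt(d_model), 1/sqrt(d_model)]` from the current RNG stream.
#'
#' @param d_model Model dimension; must be divisible by `heads`.
#' @param heads Number of attention heads `h`.
#' @param init `"uniform"` or `"zero"`.
#' @return Object of class `attention_params`: list with `heads` (list of
#'   `W_Q`, `W_K`, `W_V` per head), `W_O`, `h`, `d_model`, `d_k`.
#' @export
attention_params <- function(d_model, heads, init = c("uniform", "zero")) {
  init <- match.arg(init)
  if (d_model %% heads != 0L) stop("heads must divide d_model")
  d_k <- d_model %/% heads
  mk <- function(nr, nc) {
    if (init == "zero") matrix(0, nr, nc) else runif_mat(nr, nc, 1 / sqrt(d_model))
  }
  head_list <- lapply(seq_len(heads), function(i) {
    list(W_Q = mk(d_model, d_k), W_K = mk(d_model, d_k), W_V = mk(d_model, d_k))
  })
  structure(list(heads = head_list, W_O = mk(heads * d_k, d_model),
                 h = as.integer(heads), d_model = as.integer(d_model),
                 d_k = as.integer(d_k)),
            class = "attention_params")
}

#' Multi-head self-attention
#'
#' `head_i = Attention(X W_Q_i, X W_K_i, X W_V_i)`; the heads are
#' concatenated and projected by `W_O`, so the output has the same
#' `T x d_model` shape as the input (enabling the residual connection).
#'
#' @param X `T x d_model` input.
#' @param p An [attention_params()].
#' @param mask Length-`T` logical key mask (`NULL` = all valid).
#' @return `T x d_model` matrix.
#' @export
multi_head_attention <- function(X, p, mask = NULL) {
  if (ncol(X) != nrow(p$heads[[1]]$W_Q)) stop("X column count must equal d_model")
  outs <- lapply(p$heads, function(hp) {
    scaled_dot_product_attention(X %*% hp$W_Q, X %*% hp$W_K, X %*% hp$W_V, mask)
  })
  do.call(cbind, outs) %*% p$W_O
}

#' Position-wise feed-forward parameters
#'
#' Both weight matrices are `d_model x d_model` (the inner dimension equals
#' the model dimension in this architecture).
#'
#' @param d_model Model dimension.
#' @param init `"uniform"` or `"zero"`.
#' @return Object of class `ffn_params`: `W_1`, `W_2`, `b_1`, `b_2`.
#' @export
ffn_params <- function(d_model, init = c("uniform", "zero")) {
  init <- match.arg(init)
  mk <- function() {
    if (init == "zero") matrix(0, d_model, d_model)
    else runif_mat(d_model, d_model, 1 / sqrt(d_model))
  }
  structure(list(W_1 = mk(), W_2 = mk(),
                 b_1 = numeric(d_model), b_2 = numeric(d_model)),
            class = "ffn_params")
}

#' Position-wise feed-forward network
#'
#' `FFN(z_t) = max(0, z_t W_1 + b_1) W_2 + b_2`, applied to each position
#' independently and identically, so permuting positions permutes outputs.
#'
#' @param Z `T x d_model` input.
#' @param p An [ffn_params()].
#' @return `T x d_model` matrix.
#' @export
positionwise_ffn <- function(Z, p) {
  U <- sweep(Z %*% p$W_1, 2L, p$b_1, "+")
  sweep(pmax(U, 0) %*% p$W_2, 2L, p$b_2, "+")
}

# Row-wise layer normalization with learned gain/bias; eps inside the sqrt.
layer_norm <- function(M, gain, bias, eps = 1e-6) {
  mu <- rowMeans(M)
  v <- rowMeans((M - mu)^2)
  xhat <- (M - mu) / sqrt(v + eps)
  sweep(sweep(xhat, 2L, gain, "*"), 2L, bias, "+")
}

#' Parameters of one encoder layer
#'
#' A multi-head self-attention sub-layer and a position-wise FFN sub-layer,
#' each wrapped in a post-norm residual `LayerNorm(X + Sublayer(X))` with
#' learned gain/bias (initialized 1/0) and `eps = 1e-6`.
#'
#' @param d_model Model dimension.
#' @param heads Head count.
#' @param init `"uniform"` or `"zero"` (attention/FFN weights only).
#' @return Object of class `encoder_layer_params`.
#' @export
encoder_layer_params <- function(d_model, heads, init = c("uniform", "zero")) {
  init <- match.arg(init)
  structure(
    list(attention = attention_params(d_model, heads, init),
         ffn = ffn_params(d_model, init),
         ln1_gain = rep(1, d_model), ln1_bias = numeric(d_model),
         ln2_gain = rep(1, d_model), ln2_bias = numeric(d_model)),
    class = "encoder_layer_params"
  )
}

#' One encoder layer
#'
#' `A = LayerNorm(X + MultiHead(X))`; `out = LayerNorm(A + FFN(A))`.
#'
#' @param X `T x d_model` input.
#' @param p An [encoder_layer_params()].
#' @param mask Length-`T` logical key mask (`NULL` = all valid).
#' @return `T x d_model` matrix.
#' @export
encoder_layer <- function(X, p, mask = NULL) {
  A <- layer_norm(X + multi_head_attention(X, p$attention, mask),
                  p$ln1_gain, p$ln1_bias)
  layer_norm(A + positionwise_ffn(A, p$ffn), p$ln2_gain, p$ln2_bias)
}

# Scale a whole input matrix to unit root-mean-square (computed over the
# valid rows). Both encoders apply this to the frozen input embeddings:
# softmax attention is sensitive to the absolute input scale relative to the
# additive positional code, and gradient magnitudes throughout the network
# track the input scale, so normalizing makes the training dynamics
# invariant to the arbitrary overall scale of the pre-trained table. For
# unit-scale embeddings this is close to a no-op. One scalar per sequence,
# permutation-invariant.
scale_to_unit_rms <- function(X, mask = NULL) {
  v <- if (is.null(mask)) X else X[mask, , drop = FALSE]
  r <- sqrt(mean(v^2))
  if (r < 1e-8) X else X / r
}

#' Two-layer self-attention encoder
#'
#' Input embeddings are normalized to unit root-mean-square (one scalar per
#' sequence), then the sinusoidal positional encoding is added once, before
#' layer 1 (set `use_pe = FALSE` for an order-agnostic encoder). `Y` is the
#' layer-1 output and `Z` the layer-2 output; masked rows are zeroed in
#' both.
#'
#' @param X `T x d_model` input embeddings.
#' @param mask Length-`T` logical (`NULL` = all valid).
#' @param layers List of two [encoder_layer_params()].
#' @param use_pe Add positional encoding (default `TRUE`).
#' @return Object of class `encoder_outputs` (`Y`, `Z`, `mask`, `D`).
#' @export
encode_attention <- function(X, mask = NULL, layers, use_pe = TRUE) {
  if (length(layers) != 2L) stop("the encoder is a stack of two identical layers")
  if (is.null(mask)) mask <- rep(TRUE, nrow(X))
  Xs <- scale_to_unit_rms(X, mask)
  Xin <- if (use_pe) Xs + positional_encoding(nrow(X), ncol(X)) else Xs
  Y <- encoder_layer(Xin, layers[[1]], mask)
  Y[!mask, ] <- 0
  Z <- encoder_layer(Y, layers[[2]], mask)
  Z[!mask, ] <- 0
  structure(list(Y = Y, Z = Z, mask = mask, D = ncol(Z)),
            class = "encoder_outputs")
}

# --- internal training path (unmasked per-sequence forward/backward) -------

attention_init_params <- function(d_model, heads) {
  list(layer1 = strip_to_numeric(encoder_layer_params(d_model, heads)),
       layer2 = strip_to_numeric(encoder_layer_params(d_model, heads)))
}

layer_norm_forward <- function(M, gain, bias, eps = 1e-6) {
  mu <- rowMeans(M)
  v <- rowMeans((M - mu)^2)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- (M - mu) * inv_sd
  list(out = sweep(sweep(xhat, 2L, gain, "*"), 2L, bias, "+"),
       xhat = xhat, inv_sd = inv_sd, gain = gain)
}

layer_norm_backward <- function(dOut, cache) {
  dgain <- colSums(dOut * cache$xhat)
  dbias <- colSums(dOut)
  dxhat <- sweep(dOut, 2L, cache$gain, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- cache$inv_sd * (dxhat - m1 - cache$xhat * m2)
  list(dX = dX, dgain = dgain, dbias = dbias)
}

mha_forward <- function(X, p) {
  d_k <- ncol(p$heads[[1]]$W_Q)
  hs <- lapply(p$heads, function(hp) {
    Q <- X %*% hp$W_Q; K <- X %*% hp$W_K; V <- X %*% hp$W_V
    S <- Q %*% t(K) / sqrt(d_k)
    P <- row_softmax(S)
    list(Q = Q, K = K, V = V, P = P, out = P %*% V)
  })
  Cc <- do.call(cbind, lapply(hs, `[[`, "out"))
  list(out = Cc %*% p$W_O, hs = hs, Cc = Cc, X = X)
}

mha_backward <- function(dOut, cache, p) {
  dW_O <- crossprod(cache$Cc, dOut)
  dCc <- dOut %*% t(p$W_O)
  d_k <- ncol(p$heads[[1]]$W_Q)
  n_heads <- length(p$heads)
  dX <- matrix(0, nrow(cache$X), ncol(cache$X))
  head_grads <- vector("list", n_heads)
  for (i in seq_len(n_heads)) {
    hc <- cache$hs[[i]]
    dHd <- dCc[, (i - 1L) * d_k + seq_len(d_k), drop = FALSE]
    dP <- dHd %*% t(hc$V)
    dV <- crossprod(hc$P, dHd)
    dS <- hc$P * (dP - rowSums(dP * hc$P))
    dQ <- dS %*% hc$K / sqrt(d_k)
    dK <- crossprod(dS, hc$Q) / sqrt(d_k)
    hp <- p$heads[[i]]
    head_grads[[i]] <- list(W_Q = crossprod(cache$X, dQ),
                            W_K = crossprod(cache$X, dK),
                            W_V = crossprod(cache$X, dV))
    dX <- dX + dQ %*% t(hp$W_Q) + dK %*% t(hp$W_K) + dV %*% t(hp$W_V)
  }
  list(grads = list(heads = head_grads, W_O = dW_O), dX = dX)
}

ffn_forward <- function(A, p) {
  U <- sweep(A %*% p$W_1, 2L, p$b_1, "+")
  R <- pmax(U, 0)
  list(out = sweep(R %*% p$W_2, 2L, p$b_2, "+"), U = U, R = R, A = A)
}

ffn_backward <- function(dOut, cache, p) {
  dW_2 <- crossprod(cache$R, dOut)
  db_2 <- colSums(dOut)
  dR <- dOut %*% t(p$W_2)
  dU <- dR * (cache$U > 0)
  list(grads = list(W_1 = crossprod(cache$A, dU), W_2 = dW_2,
                    b_1 = colSums(dU), b_2 = db_2),
       dX = dU %*% t(p$W_1))
}

encoder_layer_forward <- function(X, p) {
  mha <- mha_forward(X, p$attention)
  ln1 <- layer_norm_forward(X + mha$out, p$ln1_gain, p$ln1_bias)
  ffn <- ffn_forward(ln1$out, p$ffn)
  ln2 <- layer_norm_forward(ln1$out + ffn$out, p$ln2_gain, p$ln2_bias)
  list(out = ln2$out, mha = mha, ln1 = ln1, ffn = ffn, ln2 = ln2)
}

encoder_layer_backward <- function(dOut, cache, p) {
  b_ln2 <- layer_norm_backward(dOut, cache$ln2)
  dR2 <- b_ln2$dX
  b_ffn <- ffn_backward(dR2, cache$ffn, p$ffn)
  dA <- dR2 + b_ffn$dX
  b_ln1 <- layer_norm_backward(dA, cache$ln1)
  dR1 <- b_ln1$dX
  b_mha <- mha_backward(dR1, cache$mha, p$attention)
  list(grads = list(attention = b_mha$grads, ffn = b_ffn$grads,
                    ln1_gain = b_ln1$dgain, ln1_bias = b_ln1$dbias,
                    ln2_gain = b_ln2$dgain, ln2_bias = b_ln2$dbias),
       dX = dR1 + b_mha$dX)
}

attention_forward_train <- function(X, params, use_pe = TRUE) {
  Xs <- scale_to_unit_rms(X)
  Xin <- if (use_pe) Xs + positional_encoding(nrow(X), ncol(X)) else Xs
  c1 <- encoder_layer_forward(Xin, params$layer1)
  c2 <- encoder_layer_forward(c1$out, params$layer2)
  list(Y = c1$out, Z = c2$out, c1 = c1, c2 = c2)
}

attention_backward_train <- function(dY_ext, dZ, fwd, params) {
  b2 <- encoder_layer_backward(dZ, fwd$c2, params$layer2)
  dY <- dY_ext + b2$dX
  b1 <- encoder_layer_backward(dY, fwd$c1, params$layer1)
  list(grads = list(layer1 = b1$grads, layer2 = b2$grads), dX = b1$dX)
}
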