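#' LSTM cell parameters
#'
#' One direction of one layer. Gate order in all internal combined matrices
#' is (input, forget, candidate, output). Initialization is uniform on
#' `[-1/sqrt(H), 1/sqrt(H)]`, drawn from the current RNG stream; pass
#' `init = "zero"` for all-zero parameters.
#'
#' @param input_dim Input vector dimension `d`.
#' @param hidden_size Hidden/cell dimension `H`.
#' @param init `"uniform"` (default) or `"zero"`.
#' @return Object of class `lstm_params`: fields `W_xi`, `W_xf`, `W_xc`,
#'   `W_xo` (`d x H`), `W_hi`, `W_hf`, `W_hc`, `W_ho` (`H x H`), `b_i`,
#'   `b_f`, `b_c`, `b_o` (length `H`).
#' @export
lstm_params <- function(input_dim, hidden_size, init = c("uniform", "zero")) {
  init <- match.arg(init)
  H <- as.integer(hidden_size); d <- as.integer(input_dim)
  mk <- function(nr, nc) {
    if (init == "zero") matrix(0, nr, nc) else runif_mat(nr, nc, 1 / sqrt(H))
  }
  vk <- function(n) {
    if (init == "zero") numeric(n) else stats::runif(n, -1 / sqrt(H), 1 / sqrt(H))
  }
  structure(
    list(W_xi = mk(d, H), W_xf = mk(d, H), W_xc = mk(d, H), W_xo = mk(d, H),
         W_hi = mk(H, H), W_hf = mk(H, H), W_hc = mk(H, H), W_ho = mk(H, H),
         b_i = vk(H), b_f = vk(H), b_c = vk(H), b_o = vk(H)),
    class = "lstm_params"
  )
}

# combined (d x 4H), (H x 4H), (4H) views in gate order i, f, c, o
lstm_combined <- function(p) {
  list(Wx = cbind(p$W_xi, p$W_xf, p$W_xc, p$W_xo),
       Wh = cbind(p$W_hi, p$W_hf, p$W_hc, p$W_ho),
       b = c(p$b_i, p$b_f, p$b_c, p$b_o),
       H = length(p$b_i))
}

# split combined (.. x 4H) gradients back into named per-gate pieces
lstm_split_grads <- function(dWx, dWh, db, H) {
  g <- function(M, k) M[, (k - 1L) * H + seq_len(H), drop = FALSE]
  v <- function(x, k) x[(k - 1L) * H + seq_len(H)]
  list(W_xi = g(dWx, 1L), W_xf = g(dWx, 2L), W_xc = g(dWx, 3L), W_xo = g(dWx, 4L),
       W_hi = g(dWh, 1L), W_hf = g(dWh, 2L), W_hc = g(dWh, 3L), W_ho = g(dWh, 4L),
       b_i = v(db, 1L), b_f = v(db, 2L), b_c = v(db, 3L), b_o = v(db, 4L))
}

#' One LSTM cell step
#'
#' Gate equations with sigmoid gates and tanh candidate/cell activations:
#' `i = sigma(W_xi x + W_hi h + b_i)`, `f`, `o` analogous,
#' `c_t = f * c_{t-1} + i * tanh(W_xc x + W_hc h + b_c)`,
#' `h_t = o * tanh(c_t)`.
#'
#' @param x_t Input vector, length `input_dim`.
#' @param state List with `h` and `c`, each length `H`.
#' @param p An [lstm_params()].
#' @return New state: list with `h`, `c` and the transient gate activations
#'   `i`, `f`, `o`, `g` (candidate).
#' @export
lstm_cell_step <- function(x_t, state, p) {
  if (length(x_t) != nrow(p$W_xi)) stop("x_t length does not match input_dim")
  if (length(state$h) != ncol(p$W_xi)) stop("state h length does not match H")
  h <- state$h; c_prev <- state$c
  i <- sigmoid(drop(x_t %*% p$W_xi) + drop(h %*% p$W_hi) + p$b_i)
  f <- sigmoid(drop(x_t %*% p$W_xf) + drop(h %*% p$W_hf) + p$b_f)
  g <- tanh(drop(x_t %*% p$W_xc) + drop(h %*% p$W_hc) + p$b_c)
  o <- sigmoid(drop(x_t %*% p$W_xo) + drop(h %*% p$W_ho) + p$b_o)
  c_t <- f * c_prev + i * g
  h_t <- o * tanh(c_t)
  list(h = h_t, c = c_t, i = i, f = f, o = o, g = g)
}

# Run one direction over a full (unmasked) sequence. X is T x d. Returns
# h-outputs (T x H) plus, when cache = TRUE, everything backprop needs.
lstm_run <- function(X, p, cache = FALSE) {
  cm <- lstm_combined(p)
  H <- cm$H
  T_ <- nrow(X)
  Zx <- X %*% cm$Wx              # precompute input contributions for all t
  Hs <- matrix(0, T_, H)
  if (cache) {
    I <- matrix(0, T_, H); F_ <- I; G <- I; O <- I; C <- I; Th <- I
  }
  h <- numeric(H); c_ <- numeric(H)
  idx_i <- seq_len(H); idx_f <- H + idx_i; idx_g <- 2L * H + idx_i; idx_o <- 3L * H + idx_i
  for (t in seq_len(T_)) {
    z <- Zx[t, ] + drop(h %*% cm$Wh) + cm$b
    i <- sigmoid(z[idx_i]); f <- sigmoid(z[idx_f])
    g <- tanh(z[idx_g]); o <- sigmoid(z[idx_o])
    c_new <- f * c_ + i * g
    th <- tanh(c_new)
    h <- o * th
    Hs[t, ] <- h
    if (cache) {
      I[t, ] <- i; F_[t, ] <- f; G[t, ] <- g; O[t, ] <- o
      C[t, ] <- c_new; Th[t, ] <- th
    }
    c_ <- c_new
  }
  if (cache) {
    list(Hs = Hs, I = I, F = F_, G = G, O = O, C = C, Th = Th, X = X, cm = cm)
  } else {
    list(Hs = Hs)
  }
}

# Backprop one direction. dH is T x H (gradient w.r.t. outputs Hs).
# Returns combined-parameter gradients and dX.
lstm_run_backward <- function(dH, cache) {
  cm <- cache$cm; H <- cm$H
  T_ <- nrow(dH)
  dZ <- matrix(0, T_, 4L * H)
  dX <- matrix(0, T_, ncol(cache$X))
  dh_rec <- numeric(H); dc <- numeric(H)
  WhT <- t(cm$Wh)
  idx_i <- seq_len(H); idx_f <- H + idx_i; idx_g <- 2L * H + idx_i; idx_o <- 3L * H + idx_i
  for (t in rev(seq_len(T_))) {
    dh <- dH[t, ] + dh_rec
    i <- cache$I[t, ]; f <- cache$F[t, ]; g <- cache$G[t, ]; o <- cache$O[t, ]
    th <- cache$Th[t, ]
    do_ <- dh * th
    dc <- dc + dh * o * (1 - th^2)
    di <- dc * g
    dg <- dc * i
    c_prev <- if (t > 1L) cache$C[t - 1L, ] else numeric(H)
    df <- dc * c_prev
    dz <- numeric(4L * H)
    dz[idx_i] <- di * i * (1 - i)
    dz[idx_f] <- df * f * (1 - f)
    dz[idx_g] <- dg * (1 - g^2)
    dz[idx_o] <- do_ * o * (1 - o)
    dZ[t, ] <- dz
    dh_rec <- drop(dz %*% WhT)
    dc <- dc * f
  }
  Hprev <- rbind(numeric(H), cache$Hs[-T_, , drop = FALSE])
  dWx <- crossprod(cache$X, dZ)
  dWh <- crossprod(Hprev, dZ)
  db <- colSums(dZ)
  dX <- dZ %*% t(cm$Wx)
  list(grads = lstm_split_grads(dWx, dWh, db, H), dX = dX)
}

#' One bidirectional LSTM layer
#'
#' Runs independent forward and backward LSTMs over the valid (unmasked)
#' subsequence and concatenates per-step outputs; the backward pass consumes
#' the reversed valid subsequence. Masked positions contribute nothing and
#' output zero rows.
#'
#' @param X `T x d` input matrix.
#' @param mask Length-`T` logical validity vector (`NULL` = all valid).
#' @param p_fwd,p_bwd [lstm_params()] for each direction (same `H`).
#' @return `T x 2H` output matrix, row `t` is `[h_t_fwd, h_t_bwd]`.
#' @export
bilstm_layer <- function(X, mask = NULL, p_fwd, p_bwd) {
  T_ <- nrow(X)
  if (is.null(mask)) mask <- rep(TRUE, T_)
  valid <- which(mask)
  if (length(valid) == 0L) stop("bilstm_layer: all positions are masked")
  H <- ncol(p_fwd$W_xi)
  if (ncol(p_bwd$W_xi) != H) stop("both directions must share hidden size H")
  Xv <- X[valid, , drop = FALSE]
  out_f <- lstm_run(Xv, p_fwd)$Hs
  out_b <- lstm_run(Xv[rev(seq_len(nrow(Xv))), , drop = FALSE], p_bwd)$Hs
  out_b <- out_b[rev(seq_len(nrow(out_b))), , drop = FALSE]
  out <- matrix(0, T_, 2L * H)
  out[valid, ] <- cbind(out_f, out_b)
  out
}

#' Two-layer BiLSTM encoder
#'
#' Input embeddings are normalized to unit root-mean-square (one scalar per
#' sequence, over the valid rows), as in the attention encoder, so training
#' dynamics do not depend on the overall scale of the pre-trained table.
#' Layer 1 produces `Y`; inverted-scaling dropout is applied to `Y` (only
#' while training, drawn from the current RNG stream) before it feeds layer
#' 2, which produces `Z`. The returned `Y` is the pre-dropout layer-1 output.
#'
#' @param X `T x d` input matrix.
#' @param mask Length-`T` logical (`NULL` = all valid).
#' @param layer1,layer2 Lists with elements `fwd` and `bwd`
#'   ([lstm_params()]); layer 2's input dim must be `2H` of layer 1.
#' @param dropout_rate In `[0, 1)`.
#' @param training Logical; dropout is a no-op when `FALSE`.
#' @return Object of class `encoder_outputs`: list with `Y`, `Z` (each
#'   `T x D`, `D = 2H` of layer 2, masked rows zero), `mask`, `D`.
#' @export
encode_bilstm <- function(X, mask = NULL, layer1, layer2, dropout_rate = 0,
                          training = FALSE) {
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (is.null(mask)) mask <- rep(TRUE, nrow(X))
  X <- scale_to_unit_rms(X, mask)
  Y <- bilstm_layer(X, mask, layer1$fwd, layer1$bwd)
  Yin <- Y
  if (training && dropout_rate > 0) {
    keep <- matrix(stats::runif(length(Y)) >= dropout_rate, nrow(Y), ncol(Y))
    Yin <- Y * keep / (1 - dropout_rate)
  }
  Z <- bilstm_layer(Yin, mask, layer2$fwd, layer2$bwd)
  structure(list(Y = Y, Z = Z, mask = mask, D = ncol(Z)),
            class = "encoder_outputs")
}

#' @export
print.encoder_outputs <- function(x, ...) {
  cat("<encoder_outputs> T=", nrow(x$Z), " D=", x$D, "\n", sep = "")
  invisible(x)
}

# --- internal training path (unmasked per-sequence forward/backward) -------

bilstm_init_params <- function(input_dim, hidden_size) {
  strip_to_numeric(list(
    layer1 = list(fwd = lstm_params(input_dim, hidden_size),
                  bwd = lstm_params(input_dim, hidden_size)),
    layer2 = list(fwd = lstm_params(2L * hidden_size, hidden_size),
                  bwd = lstm_params(2L * hidden_size, hidden_size))
  ))
}

bilstm_dir_forward <- function(X, layer, cache = TRUE) {
  T_ <- nrow(X)
  rev_idx <- rev(seq_len(T_))
  cf <- lstm_run(X, layer$fwd, cache = cache)
  cb <- lstm_run(X[rev_idx, , drop = FALSE], layer$bwd, cache = cache)
  out <- cbind(cf$Hs, cb$Hs[rev_idx, , drop = FALSE])
  list(out = out, cf = cf, cb = cb)
}

bilstm_dir_backward <- function(dOut, fwd_cache) {
  H <- ncol(fwd_cache$cf$Hs)
  T_ <- nrow(dOut)
  rev_idx <- rev(seq_len(T_))
  bf <- lstm_run_backward(dOut[, seq_len(H), drop = FALSE], fwd_cache$cf)
  bb <- lstm_run_backward(dOut[rev_idx, H + seq_len(H), drop = FALSE], fwd_cache$cb)
  list(grads = list(fwd = bf$grads, bwd = bb$grads),
       dX = bf$dX + bb$dX[rev_idx, , drop = FALSE])
}

# Full-sequence (no padding) training forward. Returns Y, Z and caches.
bilstm_forward_train <- function(X, params, dropout_rate, training) {
  X <- scale_to_unit_rms(X)
  l1 <- bilstm_dir_forward(X, params$layer1)
  Y <- l1$out
  keep_scale <- NULL
  Yin <- Y
  if (training && dropout_rate > 0) {
    keep <- matrix(stats::runif(length(Y)) >= dropout_rate, nrow(Y), ncol(Y))
    keep_scale <- keep / (1 - dropout_rate)
    Yin <- Y * keep_scale
  }
  l2 <- bilstm_dir_forward(Yin, params$layer2)
  list(Y = Y, Z = l2$out, l1 = l1, l2 = l2, keep_scale = keep_scale)
}

# dY_ext: gradient flowing directly into Y from the head (may be 0 matrix).
bilstm_backward_train <- function(dY_ext, dZ, fwd) {
  b2 <- bilstm_dir_backward(dZ, fwd$l2)
  dYin <- b2$dX
  if (!is.null(fwd$keep_scale)) dYin <- dYin * fwd$keep_scale
  dY <- dY_ext + dYin
  b1 <- bilstm_dir_backward(dY, fwd$l1)
  list(grads = list(layer1 = b1$grads, layer2 = b2$grads), dX = b1$dX)
}
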