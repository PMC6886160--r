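#' Head configuration: structure choice, hint layer, classifier sizes
#'
#' The four output-combination structures over the encoder's layer outputs
#' `Y` and `Z` (both `T x D`):
#' \describe{
#'   \item{direct}{`H = Z` (`T x D`).}
#'   \item{weighted_sum}{`H = lambda * Y + (1 - lambda) * Z` with a trainable
#'     `lambda` constrained to `(0, 1)` by a logistic squashing of an
#'     unconstrained scalar (initialized so `lambda = 0.5`).}
#'   \item{concat_time}{`Y` and `Z` stacked along time (`2T x D`), the mask
#'     duplicated.}
#'   \item{concat_vector}{`Y` and `Z` concatenated per position (`T x 2D`).}
#' }
#' After max-pooling over time, the optional hint layer concatenates the
#' target word's pre-trained embedding to the pooled context vector before
#' the dense 256/64 softmax classifier.
#'
#' @param structure One of `"direct"`, `"weighted_sum"`, `"concat_time"`,
#'   `"concat_vector"`.
#' @param use_hint Logical; concatenate the target-word embedding.
#' @param lambda Initial mixing weight in `(0, 1)` (weighted_sum only).
#' @param dense_sizes Hidden sizes of the two dense layers.
#' @param n_labels Number of sense classes `K`.
#' @return Object of class `head_config`.
#' @export
head_config <- function(structure = c("direct", "weighted_sum", "concat_time",
                                      "concat_vector"),
                        use_hint = FALSE, lambda = 0.5,
                        dense_sizes = c(256L, 64L), n_labels = 2L) {
  structure <- match.arg(structure)
  if (lambda <= 0 || lambda >= 1) stop("initial lambda must be in (0, 1)")
  structure(list(structure = structure, use_hint = isTRUE(use_hint),
                 lambda = lambda, dense_sizes = as.integer(dense_sizes),
                 n_labels = as.integer(n_labels)),
            class = "head_config")
}

#' Combine the two encoder layer outputs
#'
#' @param Y,Z `T x D` layer-1 and layer-2 outputs.
#' @param mask Length-`T` logical (`NULL` = all valid).
#' @param cfg A [head_config()] (or a structure tag string); for
#'   `weighted_sum` the mixing weight is `cfg$lambda`.
#' @return List with `H` (the combined matrix) and `mask_H` (its row mask).
#' @export
combine_layers <- function(Y, Z, mask = NULL, cfg) {
  if (is.character(cfg)) cfg <- head_config(structure = cfg)
  if (!identical(dim(Y), dim(Z))) stop("Y and Z must share shape")
  if (is.null(mask)) mask <- rep(TRUE, nrow(Y))
  switch(cfg$structure,
    direct = list(H = Z, mask_H = mask),
    weighted_sum = list(H = cfg$lambda * Y + (1 - cfg$lambda) * Z, mask_H = mask),
    concat_time = list(H = rbind(Y, Z), mask_H = c(mask, mask)),
    concat_vector = list(H = cbind(Y, Z), mask_H = mask),
    stop("unknown structure: ", cfg$structure)
  )
}

#' Max-pool a combined output over time steps
#'
#' Picks, within each dimension, the maximum value across the valid
#' (unmasked) rows.
#'
#' @param H Combined matrix from [combine_layers()].
#' @param mask_H Logical row mask (`NULL` = all valid).
#' @return Pooled numeric vector of length `ncol(H)`.
#' @export
max_pool_time <- function(H, mask_H = NULL) {
  if (is.null(mask_H)) mask_H <- rep(TRUE, nrow(H))
  if (!any(mask_H)) stop("max_pool_time: zero valid rows")
  Hv <- H[mask_H, , drop = FALSE]
  apply(Hv, 2L, max)
}

# internal: pooled vector plus, per dimension, the (valid-space) argmax row
max_pool_time_cache <- function(H) {
  am <- max.col(t(H), ties.method = "first")
  list(h = H[cbind(am, seq_len(ncol(H)))], argmax = am)
}

#' Concatenate the target-word hint to the pooled context vector
#'
#' The hint is the target word's raw pre-trained embedding; the result is
#' the context-word embedding `xi = [h, x_k]`. Identity on `h` when the hint
#' layer is disabled.
#'
#' @param h Pooled context vector.
#' @param x_k Target-word embedding.
#' @param cfg A [head_config()].
#' @return Numeric vector.
#' @export
apply_hint <- function(h, x_k, cfg) {
  if (isTRUE(cfg$use_hint)) c(h, x_k) else h
}

#' Dense classifier parameters
#'
#' Two ReLU dense layers (default 256 and 64 units) and a linear softmax
#' output layer. Initialization uniform on `[-1/sqrt(fan_in), 1/sqrt(fan_in)]`
#' from the current RNG stream; biases zero.
#'
#' @param input_len Length of the (possibly hint-augmented) pooled vector.
#' @param dense_sizes Hidden sizes.
#' @param n_labels Output classes `K`.
#' @param init `"uniform"` or `"zero"`. Uniform initialization gives the two
#'   ReLU layers a small positive bias (0.1) so no unit starts dead.
#' @return Object of class `head_params`: `W_1`, `b_1`, `W_2`, `b_2`,
#'   `W_out`, `b_out`.
#' @export
head_params <- function(input_len, dense_sizes = c(256L, 64L), n_labels = 2L,
                        init = c("uniform", "zero")) {
  init <- match.arg(init)
  mk <- function(nr, nc) {
    if (init == "zero") matrix(0, nr, nc) else runif_mat(nr, nc, 1 / sqrt(nr))
  }
  b0 <- if (init == "zero") 0 else 0.1
  structure(
    list(W_1 = mk(input_len, dense_sizes[[1]]),
         b_1 = rep(b0, dense_sizes[[1]]),
         W_2 = mk(dense_sizes[[1]], dense_sizes[[2]]),
         b_2 = rep(b0, dense_sizes[[2]]),
         W_out = mk(dense_sizes[[2]], n_labels), b_out = numeric(n_labels)),
    class = "head_params"
  )
}

#' Classify a pooled (or hint-augmented) vector
#'
#' `dense(256) + ReLU -> dense(64) + ReLU -> dense(K) -> softmax`.
#'
#' @param v Numeric vector, or a matrix with one row per item.
#' @param hp A [head_params()].
#' @return Probability vector over the `K` labels (or a matrix of row
#'   probability vectors); rows are non-negative and sum to 1.
#' @export
classify <- function(v, hp) {
  V <- if (is.matrix(v)) v else matrix(v, nrow = 1L)
  A1 <- pmax(sweep(V %*% hp$W_1, 2L, hp$b_1, "+"), 0)
  A2 <- pmax(sweep(A1 %*% hp$W_2, 2L, hp$b_2, "+"), 0)
  logits <- sweep(A2 %*% hp$W_out, 2L, hp$b_out, "+")
  P <- row_softmax(logits)
  if (is.matrix(v)) P else drop(P)
}

# --- internal training path ------------------------------------------------

head_forward <- function(V, hp) {
  U1 <- sweep(V %*% hp$W_1, 2L, hp$b_1, "+"); A1 <- pmax(U1, 0)
  U2 <- sweep(A1 %*% hp$W_2, 2L, hp$b_2, "+"); A2 <- pmax(U2, 0)
  logits <- sweep(A2 %*% hp$W_out, 2L, hp$b_out, "+")
  list(P = row_softmax(logits), V = V, U1 = U1, A1 = A1, U2 = U2, A2 = A2)
}

# dLogits is B x K; returns parameter grads and dV (B x input_len)
head_backward <- function(dLogits, cache, hp) {
  dW_out <- crossprod(cache$A2, dLogits)
  db_out <- colSums(dLogits)
  dA2 <- dLogits %*% t(hp$W_out)
  dU2 <- dA2 * (cache$U2 > 0)
  dW_2 <- crossprod(cache$A1, dU2)
  db_2 <- colSums(dU2)
  dA1 <- dU2 %*% t(hp$W_2)
  dU1 <- dA1 * (cache$U1 > 0)
  list(grads = list(W_1 = crossprod(cache$V, dU1), b_1 = colSums(dU1),
                    W_2 = dW_2, b_2 = db_2, W_out = dW_out, b_out = db_out),
       dV = dU1 %*% t(hp$W_1))
}
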