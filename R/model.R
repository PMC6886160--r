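#' Construct a WSD model
#'
#' Binds a context encoder (two-layer BiLSTM or two-layer self-attention) to
#' the shared upper layer: one of the four combination structures,
#' max-pooling over time, the optional target-word hint, and the dense
#' 256/64 softmax classifier. All parameters are initialized from the
#' current RNG stream (wrap in a seeded context for reproducibility, or pass
#' `seed`).
#'
#' @param encoder `"bilstm"` or `"attention"`.
#' @param input_dim Embedding dimension of the inputs (for the attention
#'   encoder this is also `d_model` and must be even and divisible by
#'   `heads`).
#' @param n_labels Number of sense classes `K`.
#' @param hidden_size BiLSTM hidden size `H` per direction (output
#'   `D = 2H`); default 100 so that `D` matches the 200-dimensional inputs.
#' @param heads Attention head count (`d_k = d_v = d_model / heads`).
#' @param structure Combination structure, see [head_config()].
#' @param use_hint Concatenate the target-word embedding before the
#'   classifier.
#' @param dense_sizes Classifier hidden sizes.
#' @param dropout Dropout rate between the two BiLSTM layers (training only).
#' @param use_pe Add sinusoidal positional encoding (attention encoder).
#' @param lambda Initial mixing weight for `weighted_sum`.
#' @param seed Optional integer seed for parameter initialization.
#' @return Object of class `wsd_model`.
#' @export
wsd_model <- function(encoder = c("bilstm", "attention"), input_dim, n_labels,
                      hidden_size = 100L, heads = 2L,
                      structure = c("concat_time", "direct", "weighted_sum",
                                    "concat_vector"),
                      use_hint = FALSE, dense_sizes = c(256L, 64L),
                      dropout = 0.5, use_pe = TRUE, lambda = 0.5,
                      seed = NULL) {
  encoder <- match.arg(encoder)
  structure_tag <- match.arg(structure)
  D <- if (encoder == "bilstm") 2L * as.integer(hidden_size) else as.integer(input_dim)
  pooled_len <- if (structure_tag == "concat_vector") 2L * D else D
  input_len <- pooled_len + if (isTRUE(use_hint)) as.integer(input_dim) else 0L
  params <- with_seed(seed, {
    enc <- if (encoder == "bilstm") {
      bilstm_init_params(input_dim, hidden_size)
    } else {
      attention_init_params(input_dim, heads)
    }
    p <- list(encoder = enc,
              head = strip_to_numeric(head_params(input_len, dense_sizes, n_labels)))
    if (structure_tag == "weighted_sum") {
      p$rho <- log(lambda / (1 - lambda))   # logistic squashing keeps lambda in (0,1)
    }
    p
  })
  structure(
    list(encoder = encoder, structure = structure_tag,
         use_hint = isTRUE(use_hint), n_labels = as.integer(n_labels),
         input_dim = as.integer(input_dim), hidden_size = as.integer(hidden_size),
         heads = as.integer(heads), D = D, pooled_len = pooled_len,
         dense_sizes = as.integer(dense_sizes), dropout = dropout,
         use_pe = isTRUE(use_pe), params = params),
    class = "wsd_model"
  )
}

#' @export
print.wsd_model <- function(x, ...) {
  cat("<wsd_model> encoder=", x$encoder, " structure=", x$structure,
      " hint=", x$use_hint, " K=", x$n_labels,
      " params=", length(flatten_params(x$params)), "\n", sep = "")
  invisible(x)
}

model_lambda <- function(model) {
  if (model$structure == "weighted_sum") sigmoid(model$params$rho) else NA_real_
}

label_to_index <- function(labels) {
  k <- suppressWarnings(as.integer(sub("^M", "", labels)))
  if (anyNA(k)) stop("labels must match M<k>")
  k
}

# Forward pass over a list of encoded_instance objects (full sequences, no
# padding: each sequence is processed at its own length).
model_forward_batch <- function(model, batch, training = FALSE) {
  B <- length(batch)
  lambda <- model_lambda(model)
  enc_caches <- vector("list", B)
  pool_caches <- vector("list", B)
  V <- matrix(0, B, model$pooled_len +
                if (model$use_hint) model$input_dim else 0L)
  for (b in seq_len(B)) {
    inst <- batch[[b]]
    fwd <- if (model$encoder == "bilstm") {
      bilstm_forward_train(inst$X, model$params$encoder,
                           dropout_rate = model$dropout, training = training)
    } else {
      attention_forward_train(inst$X, model$params$encoder, use_pe = model$use_pe)
    }
    H <- switch(model$structure,
      direct = fwd$Z,
      weighted_sum = lambda * fwd$Y + (1 - lambda) * fwd$Z,
      concat_time = rbind(fwd$Y, fwd$Z),
      concat_vector = cbind(fwd$Y, fwd$Z))
    pc <- max_pool_time_cache(H)
    # the hint embedding is RMS-normalized like the encoder inputs, so its
    # magnitude is commensurate with the pooled context vector
    v <- if (model$use_hint) {
      c(pc$h, scale_to_unit_rms(matrix(inst$target_embedding, nrow = 1L)))
    } else {
      pc$h
    }
    V[b, ] <- v
    enc_caches[[b]] <- fwd
    pool_caches[[b]] <- pc
  }
  hf <- head_forward(V, model$params$head)
  list(P = hf$P, head_cache = hf, enc_caches = enc_caches,
       pool_caches = pool_caches, lambda = lambda)
}

# Mean cross-entropy of a forward pass against integer class indices.
model_loss <- function(P, y_idx) {
  mean(-log(pmax(P[cbind(seq_len(nrow(P)), y_idx)], 1e-12)))
}

# Backward pass; returns gradients shaped like model$params.
model_backward_batch <- function(model, batch, fwd, y_idx) {
  B <- length(batch)
  P <- fwd$P
  dLogits <- P
  dLogits[cbind(seq_len(B), y_idx)] <- dLogits[cbind(seq_len(B), y_idx)] - 1
  dLogits <- dLogits / B
  hb <- head_backward(dLogits, fwd$head_cache, model$params$head)
  lambda <- fwd$lambda
  enc_grads <- NULL
  drho <- 0
  for (b in seq_len(B)) {
    ec <- fwd$enc_caches[[b]]
    pc <- fwd$pool_caches[[b]]
    dh <- hb$dV[b, seq_len(model$pooled_len)]
    T_ <- nrow(ec$Z); D <- ncol(ec$Z)
    nH <- switch(model$structure, concat_time = 2L * T_, T_)
    wH <- switch(model$structure, concat_vector = 2L * D, D)
    dH <- matrix(0, nH, wH)
    dH[cbind(pc$argmax, seq_len(wH))] <- dh
    g <- switch(model$structure,
      direct = list(dY = matrix(0, T_, D), dZ = dH),
      weighted_sum = {
        Ymat <- ec$Y; Zmat <- ec$Z
        drho_b <- sum(dH * (Ymat - Zmat)) * lambda * (1 - lambda)
        drho <- drho + drho_b
        list(dY = lambda * dH, dZ = (1 - lambda) * dH)
      },
      concat_time = list(dY = dH[seq_len(T_), , drop = FALSE],
                         dZ = dH[T_ + seq_len(T_), , drop = FALSE]),
      concat_vector = list(dY = dH[, seq_len(D), drop = FALSE],
                           dZ = dH[, D + seq_len(D), drop = FALSE]))
    bk <- if (model$encoder == "bilstm") {
      bilstm_backward_train(g$dY, g$dZ, ec)
    } else {
      attention_backward_train(g$dY, g$dZ, ec, model$params$encoder)
    }
    enc_grads <- if (is.null(enc_grads)) bk$grads else {
      map2_params(enc_grads, bk$grads, `+`)
    }
  }
  grads <- list(encoder = enc_grads, head = hb$grads)
  if (model$structure == "weighted_sum") grads$rho <- drho
  grads
}

#' Predict sense probabilities for encoded instances
#'
#' @param model A [wsd_model()].
#' @param encoded List of `encoded_instance` objects (see
#'   [encode_instance()]).
#' @return List with `probs` (`N x K` matrix), `pred` (character labels
#'   `M<k>`), `doc_id`.
#' @export
predict_wsd <- function(model, encoded) {
  fwd <- model_forward_batch(model, encoded, training = FALSE)
  pred_idx <- max.col(fwd$P, ties.method = "first")
  list(probs = fwd$P, pred = paste0("M", pred_idx),
       doc_id = vapply(encoded, function(x) x$doc_id, character(1)))
}
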