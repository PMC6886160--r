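# Independent oracles used across tests. These are deliberately written as
# plain loops / closed forms, independent of the package's vectorized paths.

# Multinomial naive Bayes on unigram counts with Laplace smoothing: the
# known-optimal-family baseline for the two-pool synthetic generative model.
nb_fit <- function(train_ds, alpha = 1) {
  labels <- vapply(train_ds$instances, function(x) x$label, character(1))
  classes <- sort(unique(labels))
  vocab <- sort(unique(unlist(lapply(train_ds$instances, `[[`, "tokens"))))
  counts <- matrix(alpha, nrow = length(classes), ncol = length(vocab),
                   dimnames = list(classes, vocab))
  prior <- table(labels)[classes]
  for (i in seq_along(train_ds$instances)) {
    toks <- train_ds$instances[[i]]$tokens
    tb <- table(toks[toks %in% vocab])
    counts[labels[[i]], names(tb)] <- counts[labels[[i]], names(tb)] + as.numeric(tb)
  }
  list(classes = classes, vocab = vocab,
       log_prior = log(as.numeric(prior) / sum(prior)),
       log_lik = log(counts / rowSums(counts)))
}

nb_predict <- function(fit, instances) {
  vapply(instances, function(inst) {
    toks <- inst$tokens[inst$tokens %in% fit$vocab]
    scores <- fit$log_prior
    for (tok in toks) scores <- scores + fit$log_lik[, tok]
    fit$classes[[which.max(scores)]]
  }, character(1))
}

nb_oracle_accuracy <- function(train_ds, test_ds) {
  fit <- nb_fit(train_ds)
  pred <- nb_predict(fit, test_ds$instances)
  gold <- vapply(test_ds$instances, function(x) x$label, character(1))
  mean(pred == gold)
}

# Scalar, loop-only evaluation of the LSTM gate equations; no matrix algebra
# beyond scalar products, so it is independent of the vectorized cell.
lstm_cell_scalar_oracle <- function(x, h_prev, c_prev, p) {
  H <- length(p$b_i)
  dotrow <- function(W, v) {
    out <- numeric(ncol(W))
    for (j in seq_len(ncol(W))) {
      s <- 0
      for (k in seq_along(v)) s <- s + v[[k]] * W[k, j]
      out[[j]] <- s
    }
    out
  }
  sig <- function(z) 1 / (1 + exp(-z))
  i <- sig(dotrow(p$W_xi, x) + dotrow(p$W_hi, h_prev) + p$b_i)
  f <- sig(dotrow(p$W_xf, x) + dotrow(p$W_hf, h_prev) + p$b_f)
  g <- tanh(dotrow(p$W_xc, x) + dotrow(p$W_hc, h_prev) + p$b_c)
  o <- sig(dotrow(p$W_xo, x) + dotrow(p$W_ho, h_prev) + p$b_o)
  c_t <- f * c_prev + i * g
  h_t <- o * tanh(c_t)
  list(h = h_t, c = c_t)
}

# Per-position loop oracle for scaled dot-product attention.
sdpa_loop_oracle <- function(Q, K, V) {
  T_ <- nrow(Q); d_k <- ncol(K)
  out <- matrix(0, T_, ncol(V))
  for (q in seq_len(T_)) {
    p <- numeric(T_)
    for (t in seq_len(T_)) p[[t]] <- sum(Q[q, ] * K[t, ]) / sqrt(d_k)
    s <- exp(p - max(p)); s <- s / sum(s)
    acc <- numeric(ncol(V))
    for (t in seq_len(T_)) acc <- acc + s[[t]] * V[t, ]
    out[q, ] <- acc
  }
  out
}

# Sequential per-head oracle for multi-head attention.
mha_loop_oracle <- function(X, p) {
  outs <- list()
  for (i in seq_along(p$heads)) {
    hp <- p$heads[[i]]
    outs[[i]] <- sdpa_loop_oracle(X %*% hp$W_Q, X %*% hp$W_K, X %*% hp$W_V)
  }
  do.call(cbind, outs) %*% p$W_O
}

# Small random encoded "instances" for model-level tests (no corpus needed).
random_encoded_batch <- function(n, d, t_range = 3:5, n_labels = 2L) {
  lapply(seq_len(n), function(i) {
    T_ <- sample(t_range, 1L)
    list(X = matrix(stats::rnorm(T_ * d, sd = 0.5), T_, d),
         mask = rep(TRUE, T_), target_index = 0L,
         target_embedding = stats::rnorm(d, sd = 0.3),
         label = paste0("M", sample.int(n_labels, 1L)),
         doc_id = paste0("doc", i))
  })
}

# Central-difference gradient check on a random subset of coordinates.
# Coordinates where the two-step-size numeric estimates disagree are locally
# non-smooth (a ReLU kink or a max-pool tie under perturbation) and are
# excluded -- the derivative is not defined there, so the comparison is
# meaningless. At least 80% of sampled coordinates must remain checkable.
max_grad_relerr <- function(model, batch, n_coords = 50L, eps = 1e-5) {
  ns <- asNamespace("biowsd")
  y <- ns$label_to_index(vapply(batch, function(b) b$label, character(1)))
  fwd <- ns$model_forward_batch(model, batch, training = FALSE)
  ga <- ns$flatten_params(ns$model_backward_batch(model, batch, fwd, y))
  th <- ns$flatten_params(model$params)
  f <- function(v) {
    m <- model
    m$params <- ns$unflatten_params(model$params, v)
    fw <- ns$model_forward_batch(m, batch, training = FALSE)
    ns$model_loss(fw$P, y)
  }
  central <- function(i, h) {
    v1 <- th; v1[i] <- v1[i] + h
    v2 <- th; v2[i] <- v2[i] - h
    (f(v1) - f(v2)) / (2 * h)
  }
  idx <- sort(sample(length(th), min(n_coords, length(th))))
  worst <- 0
  smooth <- 0L
  for (i in idx) {
    g1 <- central(i, eps)
    g2 <- central(i, 2 * eps)
    if (abs(g1 - g2) > 0.1 * max(abs(g1), abs(g2), 1e-7)) next
    smooth <- smooth + 1L
    err <- abs(g1 - ga[i]) / max(1e-3, abs(g1) + abs(ga[i]))
    if (err > worst) worst <- err
  }
  stopifnot(smooth >= 0.8 * length(idx))
  worst
}
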