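#' Training configuration
#'
#' Defaults follow the training recipe: Adagrad with learning rate starting
#' at 0.05 and decaying every 2500 optimizer steps by base 0.96 (staircase),
#' a checkpoint at every new minimum of the validation loss, stop after 5
#' epochs without improvement and restore the best checkpoint; with no
#' validation set, train for exactly `fixed_epochs` (50) with no restore.
#'
#' @param lr0 Initial learning rate.
#' @param decay_every Steps between decay events (one step = one batch).
#' @param decay_base Multiplicative decay base.
#' @param patience Epochs without validation-loss improvement before stopping.
#' @param max_epochs Epoch cap when a validation set is present.
#' @param fixed_epochs Exact epoch count when no validation set exists.
#' @param batch_size Minibatch size (`NULL`: 16 word-specific, 32 universal).
#' @param seed Integer seed controlling init, shuffling and dropout.
#' @param mode `"word_specific"` or `"universal"`.
#' @param input_mode `"whole_paragraph"` or `"window25"`.
#' @param window_half_width Tokens kept each side in `"window25"` mode.
#' @param encoder,hidden_size,heads,structure,use_hint,dense_sizes,dropout,use_pe
#'   Model hyperparameters (see [wsd_model()]); `use_hint = NULL` resolves to
#'   `TRUE` for universal mode and `FALSE` for word-specific mode, the
#'   settings found to work best in each regime.
#' @param split_fractions Train/valid/test fractions for the per-word split.
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr0 = 0.05, decay_every = 2500L, decay_base = 0.96,
                         patience = 5L, max_epochs = 200L, fixed_epochs = 50L,
                         batch_size = NULL, seed = 1L,
                         mode = c("word_specific", "universal"),
                         input_mode = c("whole_paragraph", "window25"),
                         window_half_width = 25L,
                         encoder = c("bilstm", "attention"),
                         hidden_size = 100L, heads = 2L,
                         structure = "concat_time", use_hint = NULL,
                         dense_sizes = c(256L, 64L), dropout = 0.5,
                         use_pe = TRUE, split_fractions = c(0.7, 0.1, 0.2)) {
  mode <- match.arg(mode)
  input_mode <- match.arg(input_mode)
  encoder <- match.arg(encoder)
  if (lr0 <= 0) stop("lr0 must be positive")
  if (decay_base <= 0 || decay_base >= 1) stop("decay_base must be in (0, 1)")
  if (patience < 1L) stop("patience must be >= 1")
  if (is.null(batch_size)) batch_size <- if (mode == "universal") 32L else 16L
  if (is.null(use_hint)) use_hint <- (mode == "universal")
  structure(
    list(lr0 = lr0, decay_every = as.integer(decay_every),
         decay_base = decay_base, patience = as.integer(patience),
         max_epochs = as.integer(max_epochs),
         fixed_epochs = as.integer(fixed_epochs),
         batch_size = as.integer(batch_size), seed = as.integer(seed),
         mode = mode, input_mode = input_mode,
         window_half_width = as.integer(window_half_width),
         encoder = encoder, hidden_size = as.integer(hidden_size),
         heads = as.integer(heads), structure = structure,
         use_hint = isTRUE(use_hint), dense_sizes = as.integer(dense_sizes),
         dropout = dropout, use_pe = isTRUE(use_pe),
         split_fractions = split_fractions),
    class = "train_config"
  )
}

#' Learning rate at a given optimizer step
#'
#' Staircase exponential decay: `lr0 * decay_base ^ floor(step / decay_every)`.
#'
#' @param step Non-negative step count (one step = one batch update).
#' @param cfg A [train_config()] (or any list with `lr0`, `decay_every`,
#'   `decay_base`).
#' @return Learning rate.
#' @export
lr_at <- function(step, cfg) {
  cfg$lr0 * cfg$decay_base^(step %/% cfg$decay_every)
}

#' Early-stopping trace over a validation-loss sequence
#'
#' A checkpoint is (notionally) taken at every new minimum; training stops
#' once the loss has failed to improve for `patience` consecutive epochs,
#' and the best checkpoint is restored.
#'
#' @param losses Numeric per-epoch validation losses.
#' @param patience Epochs without improvement tolerated.
#' @return List with `best_epoch` (the restored checkpoint) and `stop_epoch`
#'   (last epoch run; `length(losses)` if never triggered).
#' @export
early_stop_trace <- function(losses, patience) {
  best <- Inf; best_epoch <- 0L; since <- 0L
  stop_epoch <- length(losses)
  for (e in seq_along(losses)) {
    if (losses[[e]] < best) {
      best <- losses[[e]]; best_epoch <- e; since <- 0L
    } else {
      since <- since + 1L
      if (since >= patience) { stop_epoch <- e; break }
    }
  }
  list(best_epoch = best_epoch, stop_epoch = stop_epoch)
}

# Adagrad: per-parameter accumulated squared gradients divide the step.
adagrad_update <- function(theta, grads, accum, lr, eps = 1e-8) {
  if (is.list(theta)) {
    for (i in seq_along(theta)) {
      upd <- adagrad_update(theta[[i]], grads[[i]], accum[[i]], lr, eps)
      theta[[i]] <- upd$theta
      accum[[i]] <- upd$accum
    }
    list(theta = theta, accum = accum)
  } else {
    accum <- accum + grads^2
    list(theta = theta - lr * grads / (sqrt(accum) + eps), accum = accum)
  }
}

# Window (if configured) and embed a dataset's instances.
prepare_encoded <- function(ds, table, cfg) {
  lapply(ds$instances, function(inst) {
    if (cfg$input_mode == "window25") {
      inst <- window_context(inst, cfg$window_half_width)
    }
    encode_instance(inst, table)
  })
}

#' Train one WSD model
#'
#' Runs the Adagrad training loop with the decayed learning rate and
#' checkpoint-restore early stopping on the validation loss. With an empty
#' (or `NULL`) validation set, trains for exactly `cfg$fixed_epochs` epochs
#' with no checkpointing. Deterministic for a fixed `cfg$seed`.
#'
#' @param train_ds Training [wsd_dataset()] (non-empty).
#' @param valid_ds Validation [wsd_dataset()], possibly empty or `NULL`.
#' @param table An `embedding_table`.
#' @param cfg A [train_config()].
#' @param n_labels Number of classes `K`; default is the largest label index
#'   observed in `train_ds`/`valid_ds`.
#' @return List with `model` (trained, best checkpoint restored) and
#'   `report`: per-epoch `train_loss`, `valid_loss`, `valid_accuracy`,
#'   plus `best_epoch`, `epochs_run`, `steps_taken`, `checkpointed`.
#' @export
train_model <- function(train_ds, valid_ds = NULL, table, cfg, n_labels = NULL) {
  if (length(train_ds$instances) == 0L) stop("training set is empty")
  has_valid <- !is.null(valid_ds) && length(valid_ds$instances) > 0L
  if (is.null(n_labels)) {
    labs <- dataset_labels(train_ds)
    if (has_valid) labs <- c(labs, dataset_labels(valid_ds))
    n_labels <- max(label_to_index(labs))
  }
  enc_train <- prepare_encoded(train_ds, table, cfg)
  y_train <- label_to_index(vapply(enc_train, function(x) x$label, character(1)))
  if (has_valid) {
    enc_valid <- prepare_encoded(valid_ds, table, cfg)
    y_valid <- label_to_index(vapply(enc_valid, function(x) x$label, character(1)))
  }
  n <- length(enc_train)
  max_epochs <- if (has_valid) cfg$max_epochs else cfg$fixed_epochs

  train_loss <- numeric(0); valid_loss <- numeric(0); valid_acc <- numeric(0)
  best_loss <- Inf; best_epoch <- 0L; since_best <- 0L
  checkpoint <- NULL
  step <- 0L

  model <- NULL
  with_seed(cfg$seed, {
    model <- wsd_model(
      encoder = cfg$encoder, input_dim = table$dim, n_labels = n_labels,
      hidden_size = cfg$hidden_size, heads = cfg$heads,
      structure = cfg$structure, use_hint = cfg$use_hint,
      dense_sizes = cfg$dense_sizes, dropout = cfg$dropout,
      use_pe = cfg$use_pe
    )
    # accumulators start at 0.1: damps the first updates, where a zero
    # accumulator would take full-lr steps of magnitude lr in every coordinate
    accum <- map_params(model$params, function(x) x * 0 + 0.1)
    for (epoch in seq_len(max_epochs)) {
      idx <- sample.int(n)
      epoch_losses <- numeric(0)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        bidx <- idx[start:min(start + cfg$batch_size - 1L, n)]
        fwd <- model_forward_batch(model, enc_train[bidx], training = TRUE)
        loss <- model_loss(fwd$P, y_train[bidx])
        if (!is.finite(loss)) {
          stop("training diverged: non-finite loss at step ", step,
               " (epoch ", epoch, ")")
        }
        grads <- model_backward_batch(model, enc_train[bidx], fwd, y_train[bidx])
        upd <- adagrad_update(model$params, grads, accum, lr_at(step, cfg))
        model$params <- upd$theta
        accum <- upd$accum
        step <- step + 1L
        epoch_losses <- c(epoch_losses, loss)
      }
      train_loss <- c(train_loss, mean(epoch_losses))
      if (has_valid) {
        vf <- model_forward_batch(model, enc_valid, training = FALSE)
        vl <- model_loss(vf$P, y_valid)
        va <- mean(max.col(vf$P, ties.method = "first") == y_valid)
        valid_loss <- c(valid_loss, vl)
        valid_acc <- c(valid_acc, va)
        if (vl < best_loss) {
          best_loss <- vl; best_epoch <- epoch; since_best <- 0L
          checkpoint <- model$params
        } else {
          since_best <- since_best + 1L
          if (since_best >= cfg$patience) break
        }
      }
    }
  })
  if (has_valid && !is.null(checkpoint)) model$params <- checkpoint
  list(
    model = model,
    report = list(
      train_loss = train_loss, valid_loss = valid_loss,
      valid_accuracy = valid_acc,
      best_epoch = if (has_valid) best_epoch else length(train_loss),
      epochs_run = length(train_loss), steps_taken = step,
      checkpointed = has_valid
    )
  )
}

#' Evaluate a trained model on a dataset
#'
#' @param model A trained [wsd_model()].
#' @param ds A non-empty [wsd_dataset()].
#' @param table An `embedding_table`.
#' @param cfg The [train_config()] used for training (fixes the input
#'   windowing so evaluation matches the training representation).
#' @return List with `accuracy` and `predictions`, a data frame with
#'   `doc_id`, `gold`, `pred` and one probability column per label.
#' @export
evaluate_wsd <- function(model, ds, table, cfg) {
  if (length(ds$instances) == 0L) stop("cannot evaluate on an empty dataset")
  enc <- prepare_encoded(ds, table, cfg)
  pr <- predict_wsd(model, enc)
  gold <- vapply(enc, function(x) x$label, character(1))
  probs <- as.data.frame(pr$probs)
  names(probs) <- paste0("prob_M", seq_len(ncol(pr$probs)))
  predictions <- cbind(
    data.frame(doc_id = pr$doc_id, gold = gold, pred = pr$pred,
               stringsAsFactors = FALSE),
    probs
  )
  list(accuracy = mean(pr$pred == gold), predictions = predictions)
}

#' Train one model per ambiguous word
#'
#' Each word's dataset is split (stratified) into train/valid/test with
#' `cfg$split_fractions`, an independent model is trained on each, and test
#' accuracy is reported per word together with the macro average. Datasets
#' with fewer than two senses are skipped with a warning.
#'
#' @param datasets List of per-word [wsd_dataset()] objects.
#' @param table An `embedding_table`.
#' @param cfg A [train_config()] with `mode = "word_specific"`.
#' @return List with `words` (per-word list: `report`, `test_accuracy`,
#'   `valid_accuracy`, `predictions`, `model`) and `macro_average`.
#' @export
train_word_specific <- function(datasets, table, cfg) {
  words <- list()
  for (i in seq_along(datasets)) {
    ds <- datasets[[i]]
    if (ds$sense_count < 2L) {
      warning("skipping '", ds$word_key, "': fewer than 2 senses")
      next
    }
    parts <- split_dataset(ds, cfg$split_fractions, seed = cfg$seed + i)
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    fit <- train_model(parts$train, parts$valid, table, cfg_i)
    ev <- evaluate_wsd(fit$model, parts$test, table, cfg_i)
    va <- fit$report$valid_accuracy
    words[[ds$word_key]] <- list(
      report = fit$report, test_accuracy = ev$accuracy,
      valid_accuracy = if (length(va) && fit$report$best_epoch > 0)
        va[[fit$report$best_epoch]] else NA_real_,
      predictions = ev$predictions, model = fit$model
    )
  }
  if (length(words) == 0L) stop("no trainable datasets (all have < 2 senses)")
  list(words = words,
       macro_average = mean(vapply(words, `[[`, numeric(1), "test_accuracy")))
}

#' Train a single universal model on all words merged
#'
#' Merges the per-word datasets into one corpus and trains one model for all
#' ambiguous words simultaneously. The target-word hint layer defaults to ON
#' in this regime (it re-emphasizes which word is being disambiguated); the
#' label count is the maximum sense count over the merged labels.
#'
#' @param datasets List of per-word [wsd_dataset()] objects.
#' @param table An `embedding_table`.
#' @param cfg A [train_config()] with `mode = "universal"`.
#' @return List with `report`, `test_accuracy`, `predictions`, `model`.
#' @export
train_universal <- function(datasets, table, cfg) {
  merged <- merge_datasets(datasets)
  parts <- split_dataset(merged, cfg$split_fractions, seed = cfg$seed)
  fit <- train_model(parts$train, parts$valid, table, cfg)
  ev <- evaluate_wsd(fit$model, parts$test, table, cfg)
  list(report = fit$report, test_accuracy = ev$accuracy,
       predictions = ev$predictions, model = fit$model)
}

as_prediction_map <- function(x) {
  if (is.data.frame(x)) stats::setNames(as.character(x$pred), x$doc_id) else x
}

#' Combine per-model predictions by (weighted) voting
#'
#' Unweighted: plurality label. Weighted: label with the largest summed
#' weight (models with better validation performance should get larger
#' weights). Ties go to the label chosen by the highest-weight model -- for
#' unweighted voting, the model with the best `val_accuracy`, falling back
#' to input order.
#'
#' @param predictions List of prediction maps: named character vectors
#'   (names are doc ids) or prediction data frames from [evaluate_wsd()].
#'   All maps must cover the same doc ids.
#' @param weights Optional positive per-model weights.
#' @param val_accuracy Optional per-model validation accuracies used to rank
#'   models for unweighted tie-breaking.
#' @return Named character vector of voted labels.
#' @export
ensemble_vote <- function(predictions, weights = NULL, val_accuracy = NULL) {
  maps <- lapply(predictions, as_prediction_map)
  ids <- sort(names(maps[[1]]))
  for (m in maps) {
    if (!identical(sort(names(m)), ids)) stop("prediction maps cover different doc ids")
  }
  n_models <- length(maps)
  if (!is.null(weights)) {
    if (length(weights) != n_models || any(weights <= 0)) {
      stop("weights must be positive, one per model")
    }
    w <- weights
  } else {
    w <- rep(1, n_models)
  }
  rank_order <- if (!is.null(weights)) {
    order(weights, decreasing = TRUE)
  } else if (!is.null(val_accuracy)) {
    order(val_accuracy, decreasing = TRUE)
  } else {
    seq_len(n_models)
  }
  out <- character(length(ids))
  names(out) <- ids
  for (id in ids) {
    votes <- vapply(maps, function(m) m[[id]], character(1))
    tally <- tapply(w, votes, sum)
    top <- names(tally)[tally == max(tally)]
    if (length(top) == 1L) {
      out[[id]] <- top
    } else {
      pick <- votes[rank_order][votes[rank_order] %in% top][[1]]
      out[[id]] <- pick
    }
  }
  out
}

#' Report instances on which every model agrees on the same wrong label
#'
#' Such consensus errors -- paragraphs every ensemble member labels
#' identically and incorrectly -- flag instances that are intrinsically hard
#' or possibly mislabeled, and bound the achievable accuracy on a dataset.
#'
#' @param predictions As in [ensemble_vote()].
#' @param truth A [wsd_dataset()] (gold labels by doc id) or a named
#'   character vector.
#' @return List with `doc_ids`, `count`, `fraction` (of the evaluated set),
#'   `consensus_label` (named vector of the agreed wrong labels).
#' @export
consensus_error_report <- function(predictions, truth) {
  maps <- lapply(predictions, as_prediction_map)
  ids <- sort(names(maps[[1]]))
  for (m in maps) {
    if (!identical(sort(names(m)), ids)) stop("prediction maps cover different doc ids")
  }
  gold <- if (inherits(truth, "wsd_dataset")) {
    stats::setNames(dataset_labels(truth),
                    vapply(truth$instances, function(x) x$doc_id, character(1)))
  } else {
    truth
  }
  if (!all(ids %in% names(gold))) stop("truth does not cover all predicted doc ids")
  votes <- vapply(maps, function(m) m[ids], character(length(ids)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1L, dimnames = list(ids, NULL))
  unanimous <- apply(votes, 1L, function(v) length(unique(v)) == 1L)
  agreed <- votes[, 1L]
  wrong <- unanimous & (agreed != gold[ids])
  list(doc_ids = ids[wrong], count = sum(wrong),
       fraction = sum(wrong) / length(ids),
       consensus_label = stats::setNames(agreed[wrong], ids[wrong]))
}
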