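small_corpus <- function(seed = 51, n_words = 1, n_paragraphs = 60,
                         separability = 0.95) {
  generate_corpus(synth_spec(
    n_words = n_words, senses_per_word = 2, n_paragraphs = n_paragraphs,
    paragraph_len_range = c(8L, 14L), vocab_size = 400, dim = 8,
    separability = separability, seed = seed))
}

fast_cfg <- function(...) {
  train_config(hidden_size = 8L, heads = 2L, dense_sizes = c(16L, 8L),
               batch_size = 8L, ...)
}

test_that("the learning-rate schedule is a staircase exponential decay", {
  cfg <- train_config()
  expect_equal(lr_at(0, cfg), 0.05)
  expect_equal(lr_at(2499, cfg), 0.05)
  expect_equal(lr_at(2500, cfg), 0.048)          # 0.05 * 0.96
  expect_equal(lr_at(4999, cfg), 0.048)
  expect_equal(lr_at(5000, cfg), 0.05 * 0.96^2)
  expect_equal(lr_at(25000, cfg), 0.05 * 0.96^10)
})

test_that("early stopping restores the checkpoint of the best epoch", {
  tr <- early_stop_trace(c(1.0, 0.9, 0.95, 0.96, 0.94, 0.97, 0.98, 0.99),
                         patience = 5)
  expect_equal(tr$best_epoch, 2L)
  expect_equal(tr$stop_epoch, 7L)
  # monotonically decreasing loss never triggers the stop
  tr2 <- early_stop_trace(seq(1, 0.1, by = -0.1), patience = 5)
  expect_equal(tr2$best_epoch, 10L)
  expect_equal(tr2$stop_epoch, 10L)
})

test_that("training is deterministic, learns, and respects the two regimes", {
  corpus <- small_corpus()
  parts <- split_dataset(corpus$datasets[[1]], c(0.7, 0.1, 0.2), seed = 51)
  cfg <- fast_cfg(encoder = "bilstm", structure = "direct", max_epochs = 8L,
                  seed = 7L)
  fit1 <- train_model(parts$train, parts$valid, corpus$table, cfg)
  fit2 <- train_model(parts$train, parts$valid, corpus$table, cfg)
  expect_identical(fit1$report, fit2$report)     # bitwise reproducible metrics
  expect_identical(fit1$model$params, fit2$model$params)
  expect_equal(length(fit1$report$valid_loss), fit1$report$epochs_run)
  expect_true(fit1$report$best_epoch <= fit1$report$epochs_run)

  # losses are finite and generally decreasing on separable data
  expect_true(all(is.finite(fit1$report$train_loss)))
  expect_lt(tail(fit1$report$train_loss, 1), fit1$report$train_loss[[1]])

  # the fixed-epoch regime (no validation set) runs exactly fixed_epochs
  cfg50 <- fast_cfg(encoder = "bilstm", structure = "direct",
                    fixed_epochs = 4L, seed = 7L)
  fit50 <- train_model(parts$train, NULL, corpus$table, cfg50)
  expect_equal(fit50$report$epochs_run, 4L)
  expect_false(fit50$report$checkpointed)
  expect_length(fit50$report$valid_loss, 0L)

  # a trained model beats the majority-class baseline by a wide margin
  cfg_full <- fast_cfg(encoder = "bilstm", structure = "concat_time",
                       max_epochs = 25L, seed = 7L)
  fit <- train_model(parts$train, parts$valid, corpus$table, cfg_full)
  ev <- evaluate_wsd(fit$model, parts$test, corpus$table, cfg_full)
  labs <- vapply(parts$test$instances, function(x) x$label, character(1))
  majority <- max(table(labs)) / length(labs)
  expect_gte(ev$accuracy, majority + 0.3)
  expect_error(evaluate_wsd(fit$model, wsd_dataset("w", list()), corpus$table,
                            cfg_full), "empty")
})

test_that("evaluation reports accuracy as the fraction of correct predictions", {
  corpus <- small_corpus(seed = 52)
  parts <- split_dataset(corpus$datasets[[1]], c(0.7, 0.1, 0.2), seed = 52)
  cfg <- fast_cfg(encoder = "bilstm", structure = "direct", max_epochs = 6L,
                  seed = 3L)
  fit <- train_model(parts$train, parts$valid, corpus$table, cfg)
  ev <- evaluate_wsd(fit$model, parts$test, corpus$table, cfg)
  # accuracy matches a hand tally over the prediction table
  expect_equal(ev$accuracy, mean(ev$predictions$pred == ev$predictions$gold))
  expect_equal(nrow(ev$predictions), length(parts$test$instances))
  expect_true(all(c("doc_id", "gold", "pred", "prob_M1", "prob_M2") %in%
                    names(ev$predictions)))
  probs <- as.matrix(ev$predictions[, c("prob_M1", "prob_M2")])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-6)
})

test_that("window25 and whole-paragraph runs differ only in the windowing", {
  corpus <- small_corpus(seed = 53)
  ds <- corpus$datasets[[1]]
  cfg_win <- fast_cfg(encoder = "bilstm", structure = "direct",
                      input_mode = "window25", window_half_width = 25L,
                      max_epochs = 3L, seed = 9L)
  cfg_full <- fast_cfg(encoder = "bilstm", structure = "direct",
                       input_mode = "whole_paragraph", max_epochs = 3L,
                       seed = 9L)
  # paragraphs here are shorter than 2*25+1, so the window never truncates
  # and the two input modes must produce identical training trajectories
  parts <- split_dataset(ds, c(0.7, 0.1, 0.2), seed = 53)
  fit_w <- train_model(parts$train, parts$valid, corpus$table, cfg_win)
  fit_f <- train_model(parts$train, parts$valid, corpus$table, cfg_full)
  expect_identical(fit_w$report$train_loss, fit_f$report$train_loss)
  # with a small window the inputs genuinely differ
  cfg_w2 <- fast_cfg(encoder = "bilstm", structure = "direct",
                     input_mode = "window25", window_half_width = 2L,
                     max_epochs = 3L, seed = 9L)
  fit_w2 <- train_model(parts$train, parts$valid, corpus$table, cfg_w2)
  expect_false(identical(fit_w2$report$train_loss, fit_f$report$train_loss))
})

test_that("word-specific training yields per-word reports and a macro average", {
  corpus <- small_corpus(seed = 54, n_words = 3, n_paragraphs = 40)
  cfg <- fast_cfg(mode = "word_specific", encoder = "bilstm",
                  structure = "direct", max_epochs = 6L, seed = 11L)
  res <- train_word_specific(corpus$datasets, corpus$table, cfg)
  expect_length(res$words, 3L)
  accs <- vapply(res$words, `[[`, numeric(1), "test_accuracy")
  expect_equal(res$macro_average, mean(accs))
  expect_named(res$words, vapply(corpus$datasets, function(d) d$word_key,
                                 character(1)))
  # single-sense datasets are skipped with a warning
  degenerate <- wsd_dataset("onesense", lapply(1:4, function(i)
    wsd_instance(paste0("d", i), c("a", "onesense", "b"), 1L, "M1", "onesense")))
  expect_warning(
    res2 <- train_word_specific(c(corpus$datasets[1], list(degenerate)),
                                corpus$table, cfg),
    "fewer than 2 senses")
  expect_length(res2$words, 1L)
})

test_that("universal training merges words and defaults the hint layer on", {
  corpus <- small_corpus(seed = 55, n_words = 2, n_paragraphs = 30)
  cfg <- train_config(mode = "universal", encoder = "bilstm",
                      hidden_size = 8L, dense_sizes = c(16L, 8L),
                      structure = "direct", max_epochs = 4L, seed = 13L,
                      batch_size = 16L)
  expect_true(cfg$use_hint)                       # universal default: hint ON
  expect_false(train_config(mode = "word_specific")$use_hint)
  res <- train_universal(corpus$datasets, corpus$table, cfg)
  expect_true(res$model$use_hint)
  expect_equal(nrow(res$predictions), floor(0.2 * 60))
  expect_true(res$test_accuracy >= 0 && res$test_accuracy <= 1)
})

test_that("ensemble voting matches a brute-force tally oracle", {
  # the worked example: weights make the minority label win
  votes <- list(c(d1 = "M1"), c(d1 = "M1"), c(d1 = "M2"), c(d1 = "M2"))
  expect_equal(unname(ensemble_vote(votes, weights = c(1, 1, 1, 2))["d1"]), "M2")
  # unanimity wins regardless of weights
  unan <- list(c(d1 = "M3"), c(d1 = "M3"), c(d1 = "M3"))
  expect_equal(unname(ensemble_vote(unan, weights = c(5, 1, 1))["d1"]), "M3")

  # random 4-model, 20-instance case against an independent counting loop
  set.seed(56)
  ids <- paste0("doc", 1:20)
  maps <- lapply(1:4, function(m) {
    stats::setNames(paste0("M", sample(1:3, 20, replace = TRUE)), ids)
  })
  w <- c(0.9, 1.7, 1.1, 0.4)
  got <- ensemble_vote(maps, weights = w)
  for (id in ids) {
    tot <- c(M1 = 0, M2 = 0, M3 = 0)
    for (m in 1:4) tot[[maps[[m]][[id]]]] <- tot[[maps[[m]][[id]]]] + w[[m]]
    top <- names(tot)[tot == max(tot)]
    if (length(top) == 1L) {
      expect_equal(unname(got[[id]]), top)
    } else {
      # ties resolve to the highest-weight model voting for a tied label
      ord <- order(w, decreasing = TRUE)
      lead <- vapply(ord, function(m) maps[[m]][[id]], character(1))
      expect_equal(unname(got[[id]]), lead[lead %in% top][[1]])
    }
  }
  # unweighted plurality
  got_u <- ensemble_vote(maps)
  for (id in ids) {
    tab <- table(vapply(maps, `[[`, character(1), id))
    expect_true(got_u[[id]] %in% names(tab)[tab == max(tab)])
  }
  expect_error(ensemble_vote(list(c(d1 = "M1"), c(d2 = "M1"))), "different doc ids")
  expect_error(ensemble_vote(votes, weights = c(1, 1)), "one per model")
})

test_that("the consensus-error report isolates unanimous wrong predictions", {
  truth <- wsd_dataset("w", lapply(1:6, function(i)
    wsd_instance(paste0("d", i), c("x", "w", "y"), 1L,
                 c("M1", "M1", "M2", "M2", "M1", "M2")[[i]], "w")))
  perfect <- stats::setNames(c("M1", "M1", "M2", "M2", "M1", "M2"),
                             paste0("d", 1:6))
  rep0 <- consensus_error_report(list(perfect, perfect, perfect), truth)
  expect_equal(rep0$count, 0L)
  expect_equal(rep0$fraction, 0)

  # unanimous wrong on d1, d3; split disagreement on d5 does not count
  m1 <- perfect; m1[c("d1", "d3", "d5")] <- c("M2", "M1", "M2")
  m2 <- perfect; m2[c("d1", "d3")] <- c("M2", "M1")
  m3 <- perfect; m3[c("d1", "d3")] <- c("M2", "M1")
  rep1 <- consensus_error_report(list(m1, m2, m3), truth)
  expect_equal(sort(rep1$doc_ids), c("d1", "d3"))
  expect_equal(rep1$count, 2L)
  expect_equal(rep1$fraction, 2 / 6)
  expect_equal(unname(rep1$consensus_label[["d1"]]), "M2")
})
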