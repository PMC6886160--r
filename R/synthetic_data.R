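#' Specification for a synthetic sense-annotated corpus
#'
#' The generator emulates the shape of a benchmark WSD collection: one file
#' per ambiguous word, around 200 sense-annotated paragraphs each, the target
#' occurrence marked inside the paragraph. Text is generated from a two-pool
#' mixture: each (word, sense) pair owns a disjoint pool of cue tokens, and
#' every non-target token is drawn from the sense's cue pool with probability
#' `separability`, otherwise from a shared noise pool. `separability = 0`
#' makes label and context statistically independent; `separability = 1`
#' makes the task solvable to arbitrary accuracy as paragraphs grow, with a
#' unigram Naive-Bayes rule on cue counts as a known oracle.
#'
#' `cue_sharing` in `[0, 1]` is the fraction of words arranged into pairs
#' whose senses reuse the *same* cue pools with a swapped sense-to-label
#' mapping. For shared pairs, context tokens alone cannot determine the
#' label; the identity of the target word is required -- the situation the
#' target-word hint layer is designed for. Default 0 (all pools disjoint).
#'
#' @param n_words Number of ambiguous words.
#' @param senses_per_word Senses per word, `>= 2`.
#' @param n_paragraphs Paragraphs per word; labels balanced within ±1.
#' @param paragraph_len_range Integer `(min, max)` token counts, min `>= 3`.
#' @param vocab_size Total vocabulary (targets + cue pools + noise pool).
#' @param dim Embedding dimension.
#' @param separability Probability a context token is a sense cue.
#' @param cue_pool_size Cue tokens per (word, sense) pool.
#' @param cue_sharing Fraction of words in label-swapped shared-cue pairs.
#' @param seed Integer seed; regeneration is byte-identical for a fixed spec.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_words = 10L, senses_per_word = 2L,
                       n_paragraphs = 200L, paragraph_len_range = c(20L, 60L),
                       vocab_size = 2000L, dim = 200L, separability = 0.9,
                       cue_pool_size = 20L, cue_sharing = 0, seed = 1L) {
  if (paragraph_len_range[[1]] < 3L) stop("paragraph_len_range min must be >= 3")
  if (paragraph_len_range[[2]] < paragraph_len_range[[1]]) {
    stop("paragraph_len_range must be (min, max) with max >= min")
  }
  if (separability < 0 || separability > 1) stop("separability must be in [0, 1]")
  if (cue_sharing < 0 || cue_sharing > 1) stop("cue_sharing must be in [0, 1]")
  if (senses_per_word < 2L) stop("senses_per_word must be >= 2")
  structure(
    list(n_words = as.integer(n_words),
         senses_per_word = as.integer(senses_per_word),
         n_paragraphs = as.integer(n_paragraphs),
         paragraph_len_range = as.integer(paragraph_len_range),
         vocab_size = as.integer(vocab_size), dim = as.integer(dim),
         separability = separability,
         cue_pool_size = as.integer(cue_pool_size),
         cue_sharing = cue_sharing, seed = as.integer(seed)),
    class = "synth_spec"
  )
}

#' Generate a synthetic corpus and matching embedding table
#'
#' Each paragraph embeds its ambiguous word exactly once at a uniformly
#' random position; paragraph lengths are uniform in the configured range;
#' labels are balanced across senses within ±1. Embedding vectors are i.i.d.
#' uniform in `[-0.5/dim, 0.5/dim]` (the word2vec initialization convention).
#' Fully deterministic for a fixed spec.
#'
#' @param spec A [synth_spec()].
#' @return List with `datasets` (list of [wsd_dataset()], one per word),
#'   `table` (an `embedding_table`) and `cue_pools` (per word, per sense,
#'   the cue token vectors -- exposed so tests can verify pool disjointness
#'   and build oracles).
#' @export
generate_corpus <- function(spec) {
  n_shared <- 2L * (floor(spec$cue_sharing * spec$n_words / 2))
  n_pairs <- n_shared %/% 2L
  n_pool_owners <- spec$n_words - n_pairs        # shared pairs reuse one pool set
  n_cue <- n_pool_owners * spec$senses_per_word * spec$cue_pool_size
  n_noise <- spec$vocab_size - spec$n_words - n_cue
  if (n_noise < 1L) {
    stop("vocab_size too small: need > ", spec$n_words + n_cue,
         " tokens for targets and cue pools")
  }

  target_tokens <- sprintf("term%03d", seq_len(spec$n_words))
  cue_tokens <- sprintf("cue%05d", seq_len(n_cue))
  noise_tokens <- sprintf("noise%05d", seq_len(n_noise))

  # word w -> list of cue-token vectors, one per sense (label index order).
  # Words 1..n_shared form pairs (1,2), (3,4), ...: the even member reuses the
  # odd member's pools with the sense order rotated by one.
  cue_pools <- vector("list", spec$n_words)
  names(cue_pools) <- target_tokens
  next_cue <- 0L
  for (w in seq_len(spec$n_words)) {
    if (w <= n_shared && w %% 2L == 0L) {
      prev <- cue_pools[[w - 1L]]
      cue_pools[[w]] <- prev[c(seq_len(spec$senses_per_word)[-1], 1L)]
    } else {
      pools <- vector("list", spec$senses_per_word)
      for (s in seq_len(spec$senses_per_word)) {
        pools[[s]] <- cue_tokens[next_cue + seq_len(spec$cue_pool_size)]
        next_cue <- next_cue + spec$cue_pool_size
      }
      cue_pools[[w]] <- pools
    }
  }

  datasets <- vector("list", spec$n_words)
  with_seed(spec$seed, {
    for (w in seq_len(spec$n_words)) {
      word <- target_tokens[[w]]
      base <- spec$n_paragraphs %/% spec$senses_per_word
      extra <- spec$n_paragraphs %% spec$senses_per_word
      per_sense <- rep(base, spec$senses_per_word) +
        as.integer(seq_len(spec$senses_per_word) <= extra)
      instances <- vector("list", spec$n_paragraphs)
      k <- 0L
      for (s in seq_len(spec$senses_per_word)) {
        pool <- cue_pools[[w]][[s]]
        for (p in seq_len(per_sense[[s]])) {
          L <- sample(spec$paragraph_len_range[[1]]:spec$paragraph_len_range[[2]], 1L)
          pos <- sample.int(L, 1L)                    # 1-based target slot
          n_ctx <- L - 1L
          from_cue <- stats::runif(n_ctx) < spec$separability
          ctx <- character(n_ctx)
          if (any(from_cue)) {
            ctx[from_cue] <- sample(pool, sum(from_cue), replace = TRUE)
          }
          if (any(!from_cue)) {
            ctx[!from_cue] <- sample(noise_tokens, sum(!from_cue), replace = TRUE)
          }
          toks <- append(ctx, word, after = pos - 1L)
          k <- k + 1L
          instances[[k]] <- wsd_instance(
            doc_id = sprintf("%s_p%04d", word, k), tokens = toks,
            target_index = pos - 1L, label = paste0("M", s), word_key = word
          )
        }
      }
      datasets[[w]] <- wsd_dataset(word, instances)
    }
    all_tokens <- c(target_tokens, cue_tokens, noise_tokens)
    M <- matrix(stats::runif(length(all_tokens) * spec$dim,
                             -0.5 / spec$dim, 0.5 / spec$dim),
                nrow = length(all_tokens), ncol = spec$dim)
    rownames(M) <- all_tokens
    table <- embedding_table(M)
  })
  list(datasets = datasets, table = table, cue_pools = cue_pools)
}

#' Flip a fraction of labels to exercise the consensus-error report
#'
#' Flips exactly `floor(flip_fraction * N)` labels, each to a different label
#' drawn from the dataset's observed label set; flipped doc ids are recorded
#' in the returned dataset's metadata.
#'
#' @param ds A [wsd_dataset()] with at least 2 senses.
#' @param flip_fraction In `[0, 0.5)`.
#' @param seed Integer seed; the flip set is deterministic.
#' @return A [wsd_dataset()] with `metadata$flipped_doc_ids` and
#'   `metadata$flipped_indices` (1-based positions).
#' @export
generate_mislabeled_variant <- function(ds, flip_fraction, seed = 1L) {
  if (ds$sense_count < 2L) stop("need at least 2 senses to flip labels")
  if (flip_fraction < 0 || flip_fraction >= 0.5) {
    stop("flip_fraction must be in [0, 0.5)")
  }
  n <- length(ds$instances)
  n_flip <- floor(flip_fraction * n)
  labels <- unique(dataset_labels(ds))
  instances <- ds$instances
  flipped <- integer(0)
  with_seed(seed, {
    flipped <- sort(sample.int(n, n_flip))
    for (i in flipped) {
      others <- setdiff(labels, instances[[i]]$label)
      new_lab <- if (length(others) == 1L) others else sample(others, 1L)
      instances[[i]]$label <- new_lab
    }
  })
  wsd_dataset(ds$word_key, instances,
              metadata = list(
                flipped_indices = flipped,
                flipped_doc_ids = vapply(instances[flipped],
                                         function(x) x$doc_id, character(1))))
}
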