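#' Construct a sense-annotated instance
#'
#' One training item: a tokenized paragraph containing exactly one occurrence
#' of an ambiguous word, the position of that occurrence, and its sense label.
#' Sense labels are opaque symbols `M1`, `M2`, ... shared by all ambiguous
#' words; they carry no cross-word semantics.
#'
#' @param doc_id Opaque document identifier.
#' @param tokens Character vector of lowercase tokens, length \eqn{T \ge 1}.
#' @param target_index 0-based position of the ambiguous word within `tokens`.
#' @param label Sense symbol matching `M<k>`, `k >= 1`.
#' @param word_key Canonical surface form of the ambiguous word.
#' @return An object of class `wsd_instance`.
#' @export
wsd_instance <- function(doc_id, tokens, target_index, label, word_key) {
  if (length(tokens) < 1L || any(!nzchar(tokens))) {
    stop("tokens must be non-empty strings (doc ", doc_id, ")")
  }
  if (target_index < 0L || target_index >= length(tokens)) {
    stop("target_index ", target_index, " out of range for T=", length(tokens),
         " (doc ", doc_id, ")")
  }
  if (!grepl("^M[1-9][0-9]*$", label)) {
    stop("label '", label, "' does not match M<k> (doc ", doc_id, ")")
  }
  structure(
    list(doc_id = as.character(doc_id), tokens = as.character(tokens),
         target_index = as.integer(target_index), label = as.character(label),
         word_key = as.character(word_key)),
    class = "wsd_instance"
  )
}

#' Construct a dataset of instances for one ambiguous word
#'
#' @param word_key Ambiguous word (or `"ALL"` for a merged corpus).
#' @param instances List of [wsd_instance()] objects.
#' @param metadata Optional list of extra fields (e.g. flipped indices from
#'   [generate_mislabeled_variant()]).
#' @return An object of class `wsd_dataset` with fields `word_key`,
#'   `instances`, `sense_count`.
#' @export
wsd_dataset <- function(word_key, instances, metadata = list()) {
  labels <- vapply(instances, function(x) x$label, character(1))
  structure(
    list(word_key = as.character(word_key), instances = instances,
         sense_count = length(unique(labels)), metadata = metadata),
    class = "wsd_dataset"
  )
}

#' @export
print.wsd_dataset <- function(x, ...) {
  cat("<wsd_dataset> word_key=", x$word_key,
      " instances=", length(x$instances),
      " senses=", x$sense_count, "\n", sep = "")
  invisible(x)
}

dataset_labels <- function(ds) vapply(ds$instances, function(x) x$label, character(1))

# lowercase, whitespace-split, strip leading/trailing ASCII punctuation
tokenize_text <- function(text) {
  toks <- strsplit(tolower(trimws(text)), "[[:space:]]+")[[1]]
  toks <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks)
  toks[nzchar(toks)]
}

#' Read a sense-annotated paragraph file
#'
#' The on-disk dialect is TSV, UTF-8, one record per line:
#' `doc_id<TAB>paragraph<TAB>label`, with the single target occurrence wrapped
#' as `<e>...</e>` inside the paragraph. Multi-token targets become one token
#' joined by underscores. Tokenization lowercases, splits on whitespace and
#' strips flanking ASCII punctuation.
#'
#' @param path File path.
#' @return A [wsd_dataset()]; `word_key` is the target token of the first
#'   record.
#' @export
read_sense_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty sense file: ", path)
  instances <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 3L) {
      stop("line ", i, ": expected 3 tab-separated fields, got ", length(fields))
    }
    doc_id <- fields[[1]]; para <- fields[[2]]; label <- fields[[3]]
    n_open <- lengths(regmatches(para, gregexpr("<e>", para, fixed = TRUE)))
    n_close <- lengths(regmatches(para, gregexpr("</e>", para, fixed = TRUE)))
    if (n_open != 1L || n_close != 1L) {
      stop("line ", i, ": target must be marked with exactly one <e>...</e> span")
    }
    if (!grepl("^M[1-9][0-9]*$", label)) {
      stop("line ", i, ": label '", label, "' does not match M<k>")
    }
    m <- regexec("^(.*)<e>(.+?)</e>(.*)$", para)
    parts <- regmatches(para, m)[[1]]
    if (length(parts) != 4L) stop("line ", i, ": malformed <e>...</e> span")
    pre <- tokenize_text(parts[[2]])
    target_toks <- tokenize_text(parts[[3]])
    if (length(target_toks) == 0L) stop("line ", i, ": empty target span")
    target <- paste(target_toks, collapse = "_")
    post <- tokenize_text(parts[[4]])
    instances[[i]] <- wsd_instance(
      doc_id = doc_id, tokens = c(pre, target, post),
      target_index = length(pre), label = label, word_key = target
    )
  }
  wsd_dataset(word_key = instances[[1]]$word_key, instances = instances)
}

#' Write a dataset in the TSV sense-file dialect
#'
#' Inverse of [read_sense_file()] up to whitespace/punctuation normalization:
#' `read_sense_file(write_sense_file(ds))` reproduces `ds` exactly when `ds`
#' was itself produced by the reader or the synthetic generator.
#'
#' @param ds A [wsd_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sense_file <- function(ds, path) {
  lines <- vapply(ds$instances, function(inst) {
    toks <- inst$tokens
    ti <- inst$target_index + 1L
    toks[ti] <- paste0("<e>", toks[ti], "</e>")
    paste(inst$doc_id, paste(toks, collapse = " "), inst$label, sep = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Restrict an instance to a window around the target word
#'
#' Keeps `half_width` tokens on each side of the ambiguous word (the 25-25
#' window used to shorten recurrent training), truncating silently at
#' paragraph boundaries. At full availability the result has
#' `2 * half_width + 1` tokens.
#'
#' @param inst A [wsd_instance()].
#' @param half_width Positive integer number of tokens kept on each side.
#' @return A new [wsd_instance()] with remapped `target_index`.
#' @export
window_context <- function(inst, half_width) {
  if (half_width < 1L) stop("half_width must be >= 1")
  t0 <- inst$target_index                      # 0-based
  start <- max(0L, t0 - as.integer(half_width))
  end <- min(length(inst$tokens), t0 + as.integer(half_width) + 1L)  # half-open
  wsd_instance(
    doc_id = inst$doc_id,
    tokens = inst$tokens[(start + 1L):end],
    target_index = t0 - start,
    label = inst$label,
    word_key = inst$word_key
  )
}

#' Merge several per-word datasets into one corpus
#'
#' Used for the universal training regime: all words are pooled and a single
#' model is trained on the merged corpus. Labels are not remapped -- the label
#' set `{M_i}` is shared by all ambiguous words and carries no semantics.
#'
#' @param datasets Non-empty list of [wsd_dataset()] objects.
#' @return A [wsd_dataset()] with `word_key = "ALL"`, instances in input order.
#' @export
merge_datasets <- function(datasets) {
  if (length(datasets) < 1L) stop("merge_datasets: need at least one dataset")
  instances <- do.call(c, lapply(datasets, function(d) d$instances))
  wsd_dataset(word_key = "ALL", instances = instances)
}

#' Split a dataset into train/validation/test parts
#'
#' Stratified by label: within each label, floor-proportional quotas are
#' drawn for the validation and test parts (largest-remainder rounding so the
#' overall sizes are exactly `floor(f * N)` with the remainder going to
#' train), then instances are assigned by a seeded shuffle. Deterministic for
#' a fixed seed; the caller's RNG state is untouched.
#'
#' @param ds A [wsd_dataset()].
#' @param fractions Numeric length-3 `(train, valid, test)` summing to 1.
#' @param seed Integer seed.
#' @return List of three [wsd_dataset()]s named `train`, `valid`, `test`
#'   (empty parts allowed, except train).
#' @export
split_dataset <- function(ds, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be three non-negative numbers summing to 1")
  }
  n <- length(ds$instances)
  labels <- dataset_labels(ds)
  n_valid <- floor(fractions[[2]] * n)
  n_test <- floor(fractions[[3]] * n)
  n_train <- n - n_valid - n_test
  if (n_train < 1L) stop("split would leave the training set empty")

  counts <- table(labels)
  lab_names <- names(counts)
  quota <- function(total) {
    # largest-remainder allocation of `total` across labels, prop. to counts
    raw <- as.numeric(counts) / n * total
    base <- floor(raw)
    left <- total - sum(base)
    if (left > 0L) {
      ord <- order(raw - base, decreasing = TRUE)
      base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1L
    }
    stats::setNames(as.integer(base), lab_names)
  }
  q_valid <- quota(n_valid)
  q_test <- quota(n_test)

  idx_train <- integer(0); idx_valid <- integer(0); idx_test <- integer(0)
  with_seed(seed, {
    for (lab in lab_names) {
      pool <- sample(which(labels == lab))
      nv <- q_valid[[lab]]; nt <- q_test[[lab]]
      if (nv + nt > length(pool)) stop("split quotas exceed label count for ", lab)
      idx_test <- c(idx_test, pool[seq_len(nt)])
      idx_valid <- c(idx_valid, pool[nt + seq_len(nv)])
      idx_train <- c(idx_train, pool[nt + nv + seq_len(length(pool) - nv - nt)])
    }
  })
  take <- function(idx) {
    wsd_dataset(ds$word_key, ds$instances[sort(idx)])
  }
  list(train = take(idx_train), valid = take(idx_valid), test = take(idx_test))
}
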