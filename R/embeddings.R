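#' Load a word-embedding table in word2vec text format
#'
#' Expects the standard layout: a header line `V D`, then `V` lines of
#' `token v1 ... vD`. Duplicate tokens keep the first occurrence. The table is
#' frozen: embeddings are model inputs and are never updated during training.
#'
#' @param path File path.
#' @return An object of class `embedding_table`: list with `dim`, `vectors`
#'   (numeric matrix, one row per token, rownames are tokens) and
#'   `vocab_size`.
#' @export
load_embedding_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) < 1L) stop("empty embedding file: ", path)
  header <- strsplit(trimws(lines[[1]]), "[[:space:]]+")[[1]]
  if (length(header) != 2L) stop("line 1: expected header 'V D'")
  V <- as.integer(header[[1]]); D <- as.integer(header[[2]])
  if (is.na(V) || is.na(D) || V < 1L || D < 1L) {
    stop("line 1: invalid header 'V D' (V=", header[[1]], ", D=", header[[2]], ")")
  }
  if (length(lines) - 1L < V) stop("expected ", V, " vector lines, found ", length(lines) - 1L)
  tokens <- character(V)
  M <- matrix(0, nrow = V, ncol = D)
  for (i in seq_len(V)) {
    fields <- strsplit(trimws(lines[[i + 1L]]), "[[:space:]]+")[[1]]
    if (length(fields) != D + 1L) {
      stop("line ", i + 1L, ": expected ", D + 1L, " fields, got ", length(fields))
    }
    vals <- suppressWarnings(as.numeric(fields[-1L]))
    if (anyNA(vals)) stop("line ", i + 1L, ": non-numeric embedding value")
    tokens[[i]] <- fields[[1]]
    M[i, ] <- vals
  }
  keep <- !duplicated(tokens)
  M <- M[keep, , drop = FALSE]
  rownames(M) <- tokens[keep]
  structure(list(dim = D, vectors = M, vocab_size = nrow(M)),
            class = "embedding_table")
}

#' Write an embedding table in word2vec text format
#'
#' Values are printed with 17 significant digits so a write/read round trip is
#' bitwise exact.
#'
#' @param table An `embedding_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embedding_table <- function(table, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(table$vocab_size, table$dim), con)
  toks <- rownames(table$vectors)
  for (i in seq_len(table$vocab_size)) {
    writeLines(paste(toks[[i]],
                     paste(sprintf("%.17g", table$vectors[i, ]), collapse = " ")),
               con)
  }
  invisible(path)
}

#' Build an embedding table from a matrix
#'
#' @param vectors Numeric matrix with token rownames.
#' @return An `embedding_table`.
#' @export
embedding_table <- function(vectors) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  structure(list(dim = ncol(vectors), vectors = vectors,
                 vocab_size = nrow(vectors)),
            class = "embedding_table")
}

in_vocab <- function(tokens, table) tokens %in% rownames(table$vectors)

#' Map an instance's tokens to embedding vectors
#'
#' Out-of-vocabulary (OOV) tokens map to the all-zero vector and keep their
#' position, so sequence length, target index and positional encodings are
#' unaffected. The target-word embedding used by the hint layer is the raw
#' pre-trained vector of the target token; if that token is OOV and is an
#' underscore-joined multiword, the mean of its in-vocabulary components is
#' used instead, else a zero vector (with a warning).
#'
#' @param inst A [wsd_instance()].
#' @param table An `embedding_table`.
#' @return An object of class `encoded_instance`: list with `X` (T x dim
#'   matrix), `mask` (length-T logical, all `TRUE` here; padding masks are a
#'   batching concern), `target_index`, `target_embedding`, `label`,
#'   `doc_id`, `word_key`.
#' @export
encode_instance <- function(inst, table) {
  idx <- match(inst$tokens, rownames(table$vectors))
  X <- matrix(0, nrow = length(inst$tokens), ncol = table$dim)
  hit <- !is.na(idx)
  if (any(hit)) X[hit, ] <- table$vectors[idx[hit], , drop = FALSE]
  ti <- inst$target_index + 1L
  if (hit[[ti]]) {
    target_embedding <- X[ti, ]
  } else {
    parts <- strsplit(inst$tokens[[ti]], "_", fixed = TRUE)[[1]]
    pidx <- match(parts, rownames(table$vectors))
    pidx <- pidx[!is.na(pidx)]
    if (length(parts) > 1L && length(pidx) > 0L) {
      target_embedding <- colMeans(table$vectors[pidx, , drop = FALSE])
    } else {
      warning("target token '", inst$tokens[[ti]], "' is out of vocabulary; ",
              "hint embedding is the zero vector (doc ", inst$doc_id, ")")
      target_embedding <- numeric(table$dim)
    }
  }
  structure(
    list(X = X, mask = rep(TRUE, length(inst$tokens)),
         target_index = inst$target_index,
         target_embedding = as.numeric(target_embedding),
         label = inst$label, doc_id = inst$doc_id, word_key = inst$word_key),
    class = "encoded_instance"
  )
}

#' Keep only datasets whose ambiguous word has a pre-trained embedding
#'
#' Mirrors the corpus-coverage filter applied before training: words whose
#' surface form (or, for underscore-joined multiwords, every component) is
#' missing from the embedding vocabulary are dropped.
#'
#' @param datasets List of [wsd_dataset()] objects.
#' @param table An `embedding_table`.
#' @return The covered subset, in input order.
#' @export
filter_covered_words <- function(datasets, table) {
  covered <- vapply(datasets, function(ds) {
    key <- ds$word_key
    if (key %in% rownames(table$vectors)) return(TRUE)
    parts <- strsplit(key, "_", fixed = TRUE)[[1]]
    length(parts) > 1L && all(parts %in% rownames(table$vectors))
  }, logical(1))
  datasets[covered]
}
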