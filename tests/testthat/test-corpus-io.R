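write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("the TSV dialect is parsed into instances with correct target indices", {
  path <- write_lines_tmp(c(
    "d1\tthe <e>cold</e> virus spread\tM1",
    "d2\tpatient had a <e>heart attack</e> last night\tM2",
    "d3\tsevere <e>cold</e> this winter, said MD.\tM1",
    "d4\t<e>cold</e> at sequence start\tM2",
    "d5\tending with a <e>cold</e>\tM1"
  ))
  ds <- read_sense_file(path)
  expect_s3_class(ds, "wsd_dataset")
  expect_length(ds$instances, 5L)
  expect_equal(ds$sense_count, 2L)

  i1 <- ds$instances[[1]]
  expect_equal(i1$tokens, c("the", "cold", "virus", "spread"))
  expect_equal(i1$target_index, 1L)
  expect_equal(i1$label, "M1")

  # multiword targets collapse to a single underscore-joined token
  i2 <- ds$instances[[2]]
  expect_equal(i2$tokens[i2$target_index + 1L], "heart_attack")
  expect_length(i2$tokens, 6L)

  # punctuation is stripped, text lowercased
  i3 <- ds$instances[[3]]
  expect_true(all(i3$tokens == tolower(i3$tokens)))
  expect_true("winter" %in% i3$tokens && "md" %in% i3$tokens)

  # boundary positions
  expect_equal(ds$instances[[4]]$target_index, 0L)
  i5 <- ds$instances[[5]]
  expect_equal(i5$target_index, length(i5$tokens) - 1L)
})

test_that("malformed sense files are rejected with the offending line", {
  expect_error(read_sense_file(write_lines_tmp("d1\tno marker here\tM1")),
               "exactly one <e>")
  expect_error(read_sense_file(write_lines_tmp("d1\t<e>a</e> and <e>b</e>\tM1")),
               "exactly one <e>")
  expect_error(read_sense_file(write_lines_tmp("d1\tthe <e>cold</e> virus\tSENSE1")),
               "label")
  expect_error(read_sense_file(write_lines_tmp(character(0))), "empty")
  expect_error(read_sense_file(write_lines_tmp("d1\tonly two fields")), "fields")
})

test_that("write/read round trip reproduces the dataset exactly", {
  corpus <- generate_corpus(synth_spec(n_words = 2, n_paragraphs = 12,
                                       paragraph_len_range = c(5, 9),
                                       vocab_size = 200, dim = 4, seed = 9))
  ds <- corpus$datasets[[1]]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sense_file(ds, path)
  ds2 <- read_sense_file(path)
  expect_equal(ds2$word_key, ds$word_key)
  for (i in seq_along(ds$instances)) {
    expect_equal(ds2$instances[[i]]$tokens, ds$instances[[i]]$tokens)
    expect_equal(ds2$instances[[i]]$target_index, ds$instances[[i]]$target_index)
    expect_equal(ds2$instances[[i]]$label, ds$instances[[i]]$label)
  }
})

test_that("window_context slices [t-w, t+w] with silent boundary truncation", {
  mk <- function(T_, t0) {
    wsd_instance("d", paste0("tok", seq_len(T_) - 1L), t0, "M1", "w")
  }
  # full availability: 2w+1 tokens, target centered
  w1 <- window_context(mk(100L, 50L), 25L)
  expect_length(w1$tokens, 51L)
  expect_equal(w1$target_index, 25L)
  expect_equal(w1$tokens[[26]], "tok50")
  # left truncation
  w2 <- window_context(mk(10L, 0L), 25L)
  expect_length(w2$tokens, 10L)
  expect_equal(w2$target_index, 0L)
  # partial left truncation: tokens 0..30 inclusive
  w3 <- window_context(mk(60L, 5L), 25L)
  expect_length(w3$tokens, 31L)
  expect_equal(w3$target_index, 5L)
  expect_equal(w3$tokens[[1]], "tok0")
  expect_equal(w3$tokens[[31]], "tok30")
  # brute-force comparison over many (T, t, w) cases: the window is exactly
  # the index set {i : max(0, t-w) <= i < min(T, t+w+1)}
  for (trial in 1:40) {
    T_ <- sample(1:30, 1L); t0 <- sample(seq_len(T_), 1L) - 1L
    w <- sample(1:10, 1L)
    inst <- mk(T_, t0)
    got <- window_context(inst, w)
    keep <- which(seq_len(T_) - 1L >= max(0L, t0 - w) &
                    seq_len(T_) - 1L < min(T_, t0 + w + 1L))
    expect_equal(got$tokens, inst$tokens[keep])
    # the target token string itself never changes
    expect_equal(got$tokens[[got$target_index + 1L]],
                 inst$tokens[[t0 + 1L]])
  }
  expect_error(window_context(mk(5L, 2L), 0L), "half_width")
})

test_that("merge_datasets concatenates instances without remapping labels", {
  corpus <- generate_corpus(synth_spec(n_words = 4, n_paragraphs = 10,
                                       paragraph_len_range = c(4, 6),
                                       vocab_size = 400, dim = 4, seed = 2))
  m2 <- merge_datasets(corpus$datasets[1:2])
  expect_equal(m2$word_key, "ALL")
  expect_length(m2$instances, 20L)
  # order preserved, labels untouched
  expect_equal(m2$instances[[1]]$doc_id, corpus$datasets[[1]]$instances[[1]]$doc_id)
  expect_equal(m2$instances[[11]]$doc_id, corpus$datasets[[2]]$instances[[1]]$doc_id)
  # identity merge
  m1 <- merge_datasets(corpus$datasets[1])
  expect_equal(lapply(m1$instances, `[[`, "doc_id"),
               lapply(corpus$datasets[[1]]$instances, `[[`, "doc_id"))
  # summation oracle
  mall <- merge_datasets(corpus$datasets)
  expect_length(mall$instances,
                sum(vapply(corpus$datasets, function(d) length(d$instances), numeric(1))))
  expect_error(merge_datasets(list()), "at least one")
})

test_that("split_dataset produces exact floor-sized, stratified, disjoint parts", {
  corpus <- generate_corpus(synth_spec(n_words = 1, n_paragraphs = 200,
                                       paragraph_len_range = c(4, 6),
                                       vocab_size = 300, dim = 4, seed = 5))
  ds <- corpus$datasets[[1]]
  parts <- split_dataset(ds, c(0.7, 0.1, 0.2), seed = 3)
  expect_equal(vapply(parts, function(p) length(p$instances), numeric(1)),
               c(train = 140, valid = 20, test = 40))
  parts2 <- split_dataset(ds, c(0.9, 0, 0.1), seed = 3)
  expect_equal(vapply(parts2, function(p) length(p$instances), numeric(1)),
               c(train = 180, valid = 0, test = 20))
  # stratification: the 100/100 label balance carries into every part
  for (p in parts) {
    labs <- vapply(p$instances, function(x) x$label, character(1))
    if (length(labs)) expect_equal(sum(labs == "M1"), length(labs) / 2)
  }
  # disjoint and exhaustive: multiset union of doc ids equals the input
  ids <- sort(unname(unlist(lapply(parts, function(p)
    vapply(p$instances, function(x) x$doc_id, character(1))))))
  expect_equal(ids, sort(vapply(ds$instances, function(x) x$doc_id, character(1))))
  # determinism / seed sensitivity
  rerun <- split_dataset(ds, c(0.7, 0.1, 0.2), seed = 3)
  expect_identical(vapply(rerun$test$instances, function(x) x$doc_id, character(1)),
                   vapply(parts$test$instances, function(x) x$doc_id, character(1)))
  other <- split_dataset(ds, c(0.7, 0.1, 0.2), seed = 4)
  expect_false(identical(
    vapply(other$test$instances, function(x) x$doc_id, character(1)),
    vapply(parts$test$instances, function(x) x$doc_id, character(1))))
  expect_error(split_dataset(ds, c(0.5, 0.2, 0.2), seed = 1), "summing to 1")
  expect_error(split_dataset(ds, c(0, 0.5, 0.5), seed = 1), "empty")
})

test_that("instance invariants are enforced", {
  expect_error(wsd_instance("d", character(0), 0L, "M1", "w"), "tokens")
  expect_error(wsd_instance("d", c("a", ""), 0L, "M1", "w"), "tokens")
  expect_error(wsd_instance("d", c("a", "b"), 2L, "M1", "w"), "target_index")
  expect_error(wsd_instance("d", c("a", "b"), -1L, "M1", "w"), "target_index")
  expect_error(wsd_instance("d", c("a", "b"), 0L, "M0", "w"), "label")
  expect_error(wsd_instance("d", c("a", "b"), 0L, "sense1", "w"), "label")
})
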