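test_that("TSV and JSONL round-trips are the identity on a corpus", {
  corp <- synth_corpus(default_synth_spec(n = 50, seed = 3))
  for (fmt in c("tsv", "jsonl")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_corpus(corp, path, fmt)
    back <- read_corpus(path, fmt)
    expect_identical(back$id, corp$id)
    expect_identical(back$text, corp$text)
    expect_identical(back$temporal, corp$temporal)
    expect_identical(back$sentiment, corp$sentiment)
    expect_identical(back$emotions, corp$emotions)
  }
})

test_that("an empty corpus writes a header-only file and reads back empty", {
  corp <- mt_corpus(character(0), character(0))
  path <- tempfile(fileext = ".tsv")
  write_corpus(corp, path)
  expect_length(readLines(path), 1L)   # header only
  expect_length(read_corpus(path), 0L)
})

test_that("ordered multi-emotion cells parse and serialize correctly", {
  corp <- table1_corpus()
  path <- tempfile(fileext = ".tsv")
  write_corpus(corp, path)
  lines <- readLines(path)
  expect_match(lines[5L], "blame\\|anger\\|information")
  back <- read_corpus(path)
  expect_identical(back$emotions[[1L]], c("sorrow", "hopelessness"))
  expect_identical(back$emotions[[1L]][1L], "sorrow")   # primary first
  expect_identical(back$temporal[1L], "past")
})

test_that("label validation names the offending row and value", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("id\ttext\ttemporal\tsentiment\temotions",
               "a\thello\tpast\tpositive\tlove",
               "b\tworld\tyesterday\t\t"), path)
  expect_error(read_corpus(path), "row 2.*yesterday")
  writeLines(c("id\ttext\ttemporal\tsentiment\temotions",
               "a\thello\t\t\t", "a\tworld\t\t\t"), path)
  expect_error(read_corpus(path), "duplicate")
})

test_that("corpus constructor enforces emotion-list invariants", {
  expect_error(mt_corpus("a", "x", emotions = list(c("love", "love"))),
               "duplicated")
  expect_error(mt_corpus("a", "x",
                         emotions = list(c("love", "pride", "fear", "guilt"))),
               "more than 3")
  expect_error(mt_corpus("a", "x", emotions = list("serenity")), "unknown")
})

test_that("embedding files parse exactly and malformed lines are skipped", {
  path <- tempfile()
  writeLines(c("a 0.1 0.2", "b 0.3 0.4"), path)
  tab <- load_embeddings(path, 2)
  expect_equal(nrow(tab$vectors), 2L)
  expect_equal(as.vector(embedding_lookup(tab, "b")), c(0.3, 0.4))
  writeLines(c("a 0.1 0.2", "c 0.1 0.2 0.3", "b 0.3 0.4"), path)
  expect_message(tab2 <- load_embeddings(path, 2), "skipped 1")
  expect_identical(attr(tab2, "skipped"), 1L)
  expect_equal(nrow(tab2$vectors), 2L)
  writeLines("not parseable at all", path)
  expect_error(load_embeddings(path, 2), "no parseable")
})

test_that("random embeddings are seed-deterministic with total OOV lookup", {
  v <- paste0("w", 1:10)
  t1 <- random_embeddings(v, 4, seed = 7)
  t2 <- random_embeddings(v, 4, seed = 7)
  t3 <- random_embeddings(v, 4, seed = 8)
  expect_identical(t1$vectors, t2$vectors)
  expect_false(identical(t1$vectors, t3$vectors))
  expect_equal(dim(random_embeddings(v, 1, seed = 1)$vectors), c(10L, 1L))
  # lookups always resolve at the stated dimension
  m <- embedding_lookup(t1, c("w1", "never_seen", "<pad>"))
  expect_equal(dim(m), c(3L, 4L))
  expect_equal(m[3L, ], rep(0, 4))                  # padding is zero
  expect_equal(m[2L, ], t1$oov_vector)              # shared OOV vector
})

test_that("vocabulary building matches a brute-force counter", {
  corp <- mt_corpus(c("a", "b"), c("a a b", "b c a"))
  expect_identical(build_vocab(corp, 1), c("<pad>", "<oov>", "a", "b", "c"))
  expect_identical(build_vocab(corp, 2), c("<pad>", "<oov>", "a", "b"))
  big <- synth_corpus(default_synth_spec(n = 80, seed = 9))
  vocab <- build_vocab(big, 1)
  counts <- table(unlist(big$tokens))
  expect_setequal(setdiff(vocab, c("<pad>", "<oov>")), names(counts))
  # deterministic order under record shuffling
  shuf <- big[sample(length(big))]
  expect_identical(build_vocab(shuf, 1), vocab)
})
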