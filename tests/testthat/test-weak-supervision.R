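test_that("the polarity map partitions the 15 emotions into 6/7/2", {
  m <- sentiment_map()
  expect_length(m$positive, 6L)
  expect_length(m$negative, 7L)
  expect_length(m$neutral, 2L)
  all_lab <- c(m$positive, m$negative, m$neutral)
  expect_length(all_lab, 15L)
  expect_setequal(all_lab, label_spaces()$emotions)
  expect_error(sentiment_map(positive = c("love", "love")), "disjoint|cover")
  expect_error(sentiment_map(neutral = "information"), "cover")
})

test_that("single emotions map to their printed polarity", {
  expect_identical(emotion_to_sentiment("sorrow"), "negative")
  expect_identical(emotion_to_sentiment("hopefulness"), "positive")
  expect_identical(emotion_to_sentiment("information"), "neutral")
  expect_error(emotion_to_sentiment("serenity"), "serenity")
})

test_that("derived sentiments depend only on the primary emotion", {
  corp <- table1_corpus()
  out <- derive_sentiment_labels(corp)
  expect_identical(out$sentiment, table1_sentiments)
  # permuting trailing emotions never changes the result
  corp2 <- corp
  corp2$emotions[[4L]] <- c("blame", "information", "anger")
  expect_identical(derive_sentiment_labels(corp2)$sentiment, out$sentiment)
  # idempotent
  expect_identical(derive_sentiment_labels(out)$sentiment, out$sentiment)
  # derived counts equal per-polarity sums of primary-emotion counts
  big <- synth_corpus(default_synth_spec(n = 400, seed = 17))
  big$sentiment <- rep(NA_character_, length(big))
  lab <- derive_sentiment_labels(big)
  prim <- vapply(big$emotions, `[`, character(1L), 1L)
  m <- sentiment_map()
  for (p in c("positive", "negative", "neutral"))
    expect_identical(sum(lab$sentiment == p), sum(prim %in% m[[p]]))
})

test_that("records without emotions are rejected with their ids", {
  corp <- mt_corpus(c("a", "b"), c("x", "y"),
                    emotions = list("love", NULL))
  expect_error(derive_sentiment_labels(corp), "b")
  empty <- mt_corpus(character(0), character(0))
  expect_length(derive_sentiment_labels(empty), 0L)
})

test_that("existing sentiments survive unless overwrite is requested", {
  corp <- mt_corpus("a", "x", sentiment = "positive",
                    emotions = list("sorrow"))
  expect_identical(derive_sentiment_labels(corp)$sentiment, "positive")
  expect_identical(derive_sentiment_labels(corp, overwrite = TRUE)$sentiment,
                   "negative")
})

test_that("Cohen's kappa matches the closed form and an external check", {
  expect_equal(cohen_kappa(c("x", "y", "x"), c("x", "y", "x")), 1)
  # confusion counts (40, 10, 10, 40): p_o = 0.8, p_e = 0.5, kappa = 0.6
  a <- rep(c("p", "p", "n", "n"), c(40, 10, 10, 40))
  b <- rep(c("p", "n", "p", "n"), c(40, 10, 10, 40))
  expect_equal(cohen_kappa(a, b), 0.6)
  expect_equal(cohen_kappa(b, a), 0.6)     # symmetric
  # constructed chance-level agreement: kappa = 0
  a2 <- rep(c("p", "p", "n", "n"), c(25, 25, 25, 25))
  b2 <- rep(c("p", "n", "p", "n"), c(25, 25, 25, 25))
  expect_equal(cohen_kappa(a2, b2), 0)
  expect_error(cohen_kappa(c("x", "y"), "x"), "length")
  # cross-check against an independent implementation on random tables
  set.seed(42)
  for (i in 1:5) {
    x <- sample(letters[1:3], 200, replace = TRUE)
    y <- ifelse(runif(200) < 0.6, x, sample(letters[1:3], 200, replace = TRUE))
    expect_equal(cohen_kappa(x, y),
                 e1071::classAgreement(table(x, y))$kappa, tolerance = 1e-10)
  }
})

test_that("audit samples are uniform, seeded and bounded", {
  corp <- synth_corpus(default_synth_spec(n = 20, seed = 1))
  expect_length(sample_for_audit(corp, 0, seed = 4), 0L)
  s1 <- sample_for_audit(corp, 7, seed = 4)
  s2 <- sample_for_audit(corp, 7, seed = 4)
  expect_identical(s1$id, s2$id)
  expect_error(sample_for_audit(corp, 21), "exceeds")
  # Monte-Carlo inclusion frequency close to n/N per record
  hits <- integer(length(corp))
  names(hits) <- corp$id
  R <- 2000
  for (r in seq_len(R)) {
    s <- sample_for_audit(corp, 5, seed = 10000 + r)
    hits[s$id] <- hits[s$id] + 1L
  }
  p <- 5 / 20
  ci <- 4 * sqrt(p * (1 - p) / R)     # ~4 sd
  expect_true(all(abs(hits / R - p) < ci))
})
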