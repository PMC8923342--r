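test_that("a balanced single-label corpus splits exactly evenly", {
  # 10 classes x 10 single-label records, k = 10: every fold gets one of
  # each class
  emo <- label_spaces()$emotions[1:10]
  corp <- mt_corpus(id = sprintf("r%03d", 1:100),
                    text = rep("x y z", 100),
                    emotions = as.list(rep(emo, each = 10)))
  fa <- stratified_folds(corp, 10, seed = 2)
  expect_equal(unname(tabulate(fa$fold, 10)), rep(10L, 10))
  for (cl in emo) {
    per_fold <- tabulate(fa$fold[vapply(corp$emotions, `[`, character(1), 1)
                                 == cl], 10)
    expect_equal(unname(per_fold), rep(1L, 10), label = cl)
  }
})

test_that("folds partition the corpus and respect class proportions", {
  corp <- synth_corpus(default_synth_spec(n = 500, seed = 21))
  k <- 10
  fa <- stratified_folds(corp, k, seed = 3)
  expect_length(fa$fold, 500L)
  expect_true(all(fa$fold %in% 1:k))                    # every record once
  expect_true(all(tabulate(fa$fold, k) > 0))
  # per-class per-fold proportions within 5 points of global, for classes
  # with at least k positives (exhaustive counting)
  classes <- corp$spaces$emotions
  Y <- sapply(classes, function(cl)
    vapply(corp$emotions, function(e) cl %in% e, logical(1)))
  for (cl in classes[colSums(Y) >= k]) {
    glob <- mean(Y[, cl])
    for (j in 1:k) {
      in_fold <- fa$fold == j
      expect_lt(abs(mean(Y[in_fold, cl]) - glob), 0.05 + 1e-9,
                label = sprintf("%s fold %d", cl, j))
    }
  }
  # deterministic given the seed
  expect_identical(stratified_folds(corp, k, seed = 3)$fold, fa$fold)
  expect_error(stratified_folds(corp[1:5], 10), "more folds")
})

test_that("cross-validation with an oracle model scores 100 everywhere", {
  corp <- synth_corpus(default_synth_spec(n = 120, seed = 31))
  seen <- new.env()
  oracle_fit <- function(tr, cfg) tr                 # "model" = training set
  oracle_predict <- function(model, te) {
    assign(paste(te$id, collapse = ","), TRUE, envir = seen)
    list(temporal = te$temporal, sentiment = te$sentiment,
         emotions = te$emotions)
  }
  cv <- cross_validate(corp, mt_config(), k = 5, seed = 7,
                       fit_fun = oracle_fit, predict_fun = oracle_predict)
  expect_equal(unname(cv$mean), rep(100, 6), tolerance = 1e-9)
  expect_equal(nrow(cv$per_fold), 5L)
  # per-fold test sets reconstruct the corpus exactly once
  test_ids <- unlist(strsplit(ls(envir = seen), ","))
  expect_setequal(test_ids, corp$id)
  expect_length(test_ids, length(corp))
  # the mean report is the arithmetic mean of the fold reports
  expect_equal(unname(cv$mean),
               unname(colMeans(cv$per_fold[, -1])), tolerance = 1e-12)
})

test_that("cross-validation writes TSV and JSON summaries", {
  corp <- synth_corpus(default_synth_spec(n = 60, seed = 13))
  cv <- cross_validate(corp, mt_config(), k = 3, seed = 1,
                       fit_fun = function(tr, cfg) tr,
                       predict_fun = function(m, te)
                         list(temporal = te$temporal,
                              sentiment = te$sentiment,
                              emotions = te$emotions))
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_cv_results(cv, tsv, js)
  long <- read.delim(tsv)
  expect_identical(sort(unique(long$fold)), 1:3)
  expect_true("emotion_mean_recall" %in% long$metric)
  expect_equal(jsonlite::fromJSON(js)$emotion_mean_recall, 100)
})

test_that("an end-to-end small cross-validation runs and reports", {
  corp <- separable_corpus(60, seed = 41)
  cfg <- fast_config("mtl4", epochs = 2)
  cv <- cross_validate(corp, cfg, k = 3, seed = 5)
  expect_true(all(cv$mean >= 0 & cv$mean <= 100))
  expect_identical(nrow(cv$per_fold), 3L)
})

test_that("the loss-weight grid search returns the arg-max candidate", {
  grid <- list(c(1, 1, 1), c(0.3, 0.3, 1), c(0.1, 0.1, 1))
  known <- c(10, 50, 30)
  i <- 0
  res <- grid_search_loss_weights(NULL, grid = grid,
                                  evaluator = function(w) {
                                    i <<- i + 1; known[i]
                                  })
  expect_identical(res$best, c(0.3, 0.3, 1))
  expect_equal(res$scores$score, known)
  single <- grid_search_loss_weights(NULL, grid = list(c(2, 2, 1)),
                                     evaluator = function(w) 1)
  expect_identical(single$best, c(2, 2, 1))
  expect_error(grid_search_loss_weights(NULL, grid = list(),
                                        evaluator = function(w) 1), "empty")
  # the default grid offers the adopted down-weighting
  expect_true(any(vapply(default_loss_weight_grid(),
                         function(w) all(w == c(0.3, 0.3, 1)), logical(1))))
})
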