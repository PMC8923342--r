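#' Multilabel-stratified k-fold assignment
#'
#' Iterative stratification over the 15-class emotion multi-hot matrix:
#' labels are processed rarest-first and each example goes to the fold
#' with the greatest remaining demand for that label (ties broken by
#' remaining fold capacity, then by a seeded draw).  This keeps the
#' per-fold proportion of every emotion class close to its global
#' proportion even under heavy class skew.  Records without emotion
#' labels are spread by capacity.  Optionally stratifies on the primary
#' emotion only.
#'
#' @param corpus an [mt_corpus()].
#' @param k number of folds (`>= 2`, `<=` corpus size).
#' @param seed integer seed; the assignment is deterministic given it.
#' @param primary_only stratify on the primary emotion as a single label
#'   instead of the full label sets?
#' @return An object of class `fold_assignment`: list with `k` and
#'   `fold`, an integer vector in `1..k` aligned to the corpus records
#'   (named by record id).
#' @export
stratified_folds <- function(corpus, k = 10L, seed = 1L,
                             primary_only = FALSE) {
  stopifnot(inherits(corpus, "mt_corpus"), is_count(k), k >= 2)
  n <- length(corpus)
  if (k > n) stop("more folds than records", call. = FALSE)
  classes <- corpus$spaces$emotions
  sets <- lapply(corpus$emotions, function(e) {
    if (is.null(e)) character(0)
    else if (primary_only) e[1L] else e
  })
  Y <- matrix(FALSE, n, length(classes))
  for (i in seq_len(n)) Y[i, match(sets[[i]], classes)] <- TRUE
  fold <- integer(n)
  cap <- rep(n / k, k)                      # remaining fold capacity
  demand <- outer(rep(1 / k, k), colSums(Y))  # fold x class remaining demand
  with_seed(seed, {
    repeat {
      open <- fold == 0L & rowSums(Y) > 0L
      if (!any(open)) break
      remaining <- colSums(Y[open, , drop = FALSE])
      lab <- which(remaining == min(remaining[remaining > 0]) &
                     remaining > 0)[1L]
      idxs <- which(open & Y[, lab])
      idxs <- idxs[sample.int(length(idxs))]
      for (i in idxs) {
        cand <- which(demand[, lab] == max(demand[, lab]))
        if (length(cand) > 1L) {
          # secondary: total demand over all of the example's labels
          s2 <- rowSums(demand[cand, Y[i, ], drop = FALSE])
          cand <- cand[s2 == max(s2)]
        }
        if (length(cand) > 1L)
          cand <- cand[cap[cand] == max(cap[cand])]
        j <- if (length(cand) > 1L) sample(cand, 1L) else cand
        fold[i] <- j
        cap[j] <- cap[j] - 1
        demand[j, Y[i, ]] <- demand[j, Y[i, ]] - 1
      }
    }
    for (i in which(fold == 0L)) {
      cand <- which(cap == max(cap))
      j <- if (length(cand) > 1L) sample(cand, 1L) else cand
      fold[i] <- j
      cap[j] <- cap[j] - 1
    }
  })
  structure(list(k = as.integer(k),
                 fold = stats::setNames(fold, corpus$id)),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("<fold_assignment> k = %d, sizes: %s\n", x$k,
              paste(tabulate(x$fold, x$k), collapse = ", ")))
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' For each fold, trains on the remaining `k - 1` folds and evaluates all
#' metrics the architecture supports on the held-out fold: accuracy and
#' macro-F1 for the temporal and sentiment tasks, mean recall and
#' samples-F1 for the emotion task.  The mean report is the arithmetic
#' mean of the per-fold reports.  Fully deterministic given `seed`
#' (per-fold model seeds are derived from it).
#'
#' @param corpus a fully labeled [mt_corpus()].
#' @param config an [mt_config()].
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @param fit_fun,predict_fun optional overrides for the model: `fit_fun(
#'   train_corpus, config)` returning an object that `predict_fun(object,
#'   test_corpus)` turns into a label list (as [predict.mtcascade()] with
#'   `type = "label"`).  Used for baselines and testing.
#' @return An object of class `mt_cv`: list with `per_fold` (data frame,
#'   one row per fold), `mean` (named numeric), `assignment`.
#' @export
cross_validate <- function(corpus, config = mt_config(), k = 10L, seed = 1L,
                           fit_fun = NULL, predict_fun = NULL) {
  stopifnot(inherits(corpus, "mt_corpus"), k >= 2)
  assignment <- stratified_folds(corpus, k, seed = derive_seed(seed, 11L))
  fit_fun <- fit_fun %||% function(tr, cfg) mtcascade(tr, cfg)
  predict_fun <- predict_fun %||%
    function(model, te) predict(model, te, type = "label")
  reports <- vector("list", k)
  for (j in seq_len(k)) {
    tr <- corpus[assignment$fold != j]
    te <- corpus[assignment$fold == j]
    cfg <- config
    cfg$seed <- derive_seed(seed, 100L + j)
    model <- fit_fun(tr, cfg)
    reports[[j]] <- metrics_report(te, predict_fun(model, te))
  }
  per_fold <- as.data.frame(do.call(rbind, reports))
  per_fold <- cbind(fold = seq_len(k), per_fold)
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[, -1L, drop = FALSE]),
                 assignment = assignment, k = as.integer(k)),
            class = "mt_cv")
}

#' @export
print.mt_cv <- function(x, ...) {
  cat(sprintf("<mt_cv> %d-fold cross-validation\n", x$k))
  m <- x$mean[!is.na(x$mean)]
  for (nm in names(m)) cat(sprintf("  mean %-20s %6.2f\n", nm, m[[nm]]))
  invisible(x)
}

#' Write cross-validation results to TSV and JSON
#'
#' @param cv an `mt_cv` result.
#' @param tsv_path long-format TSV (`fold`, `metric`, `value`).
#' @param json_path JSON summary of the mean report.
#' @return `cv`, invisibly.
#' @export
write_cv_results <- function(cv, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(cv, "mt_cv"))
  if (!is.null(tsv_path)) {
    long <- do.call(rbind, lapply(seq_len(nrow(cv$per_fold)), function(i) {
      row <- cv$per_fold[i, ]
      data.frame(fold = row$fold,
                 metric = setdiff(names(row), "fold"),
                 value = as.numeric(row[setdiff(names(row), "fold")]))
    }))
    utils::write.table(long, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path))
    jsonlite::write_json(as.list(cv$mean), json_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(cv)
}

#' Grid search over joint-loss weights
#'
#' Evaluates each candidate `(p, q, r)` by emotion mean recall on a
#' held-out split (stratified 1/5 of the corpus unless an `evaluator` is
#' supplied) and returns the arg-max, ties resolved in grid order.  The
#' default grid covers down-weightings of the two weakly labeled
#' auxiliary tasks and includes `(0.3, 0.3, 1)`.
#'
#' @param corpus a fully labeled [mt_corpus()].
#' @param config an [mt_config()]; `loss_weights` is overridden per
#'   candidate.
#' @param grid list of numeric triples.
#' @param seed integer seed.
#' @param evaluator optional `function(weights)` returning a score;
#'   replaces the train-and-score default (useful for tests).
#' @return List with `best` (the winning triple), and `scores`, a data
#'   frame of candidates and their scores.
#' @export
grid_search_loss_weights <- function(corpus, config = mt_config(),
                                     grid = default_loss_weight_grid(),
                                     seed = 1L, evaluator = NULL) {
  if (!length(grid)) stop("empty loss-weight grid", call. = FALSE)
  if (is.null(evaluator)) {
    assignment <- stratified_folds(corpus, 5L, seed = derive_seed(seed, 5L))
    tr <- corpus[assignment$fold != 1L]
    va <- corpus[assignment$fold == 1L]
    evaluator <- function(w) {
      cfg <- config
      cfg$loss_weights <- w
      cfg$seed <- derive_seed(seed, 7L)
      model <- mtcascade(tr, cfg)
      pr <- predict(model, va, type = "label")
      mean_recall(va$emotions, pr$emotions, va$spaces$emotions)
    }
  }
  scores <- vapply(grid, evaluator, numeric(1L))
  best <- grid[[which.max(scores)]]
  list(best = best,
       scores = data.frame(p = vapply(grid, `[`, numeric(1L), 1L),
                           q = vapply(grid, `[`, numeric(1L), 2L),
                           r = vapply(grid, `[`, numeric(1L), 3L),
                           score = scores))
}

#' Default loss-weight grid
#'
#' Candidate `(p, q, r)` triples with the emotion weight fixed at 1 and
#' the auxiliary weights varied; contains `(0.3, 0.3, 1)`.
#' @return List of numeric triples.
#' @export
default_loss_weight_grid <- function() {
  vals <- c(0.1, 0.3, 0.5, 1)
  out <- list()
  for (p in vals) for (q in vals) out[[length(out) + 1L]] <- c(p, q, 1)
  out
}
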