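#' Decide emotion labels from sigmoid probabilities
#'
#' Labels whose probability reaches `threshold`, truncated to the
#' `max_labels` most probable; when none reaches the threshold the single
#' arg-max label is returned, so the decision is never empty and never
#' exceeds `max_labels` (sentences carry at most 3 emotions).
#'
#' @param probs numeric vector of per-class probabilities in `[0, 1]`.
#' @param threshold decision threshold (default 0.5).
#' @param max_labels maximum number of labels kept (default 3).
#' @param classes optional class names; defaults to the canonical
#'   15-emotion space when `probs` has length 15, else `e1..eK`.
#' @return Character vector of decided labels, most probable first.
#' @export
decide_emotions <- function(probs, threshold = 0.5, max_labels = 3L,
                            classes = NULL) {
  stopifnot(all(probs >= 0), all(probs <= 1), max_labels >= 1)
  if (is.null(classes))
    classes <- if (length(probs) == 15L) label_spaces()$emotions
      else paste0("e", seq_along(probs))
  stopifnot(length(classes) == length(probs))
  pass <- which(probs >= threshold)
  if (!length(pass)) return(classes[which.max(probs)])
  pass <- pass[order(-probs[pass], pass)]
  classes[pass[seq_len(min(length(pass), max_labels))]]
}

as_label_sets <- function(x, classes) {
  if (is.matrix(x)) {
    apply(x, 1L, function(r) classes[r > 0], simplify = FALSE)
  } else {
    lapply(x, function(e) if (is.null(e)) character(0) else as.character(e))
  }
}

#' Mean recall over emotion classes
#'
#' Unweighted macro-average of per-class recall over classes that have at
#' least one actual positive in `truth`, scaled to a percentage.  Classes
#' with no positives are dropped from the average (their recall is
#' undefined), so predictions on absent classes never move the score.
#'
#' @param truth multi-hot matrix (`n x K`) or list of true label sets.
#' @param predicted list of predicted label sets (character vectors).
#' @param classes class-name vector; the columns of a matrix `truth`.
#' @return Percentage in `[0, 100]`.
#' @export
mean_recall <- function(truth, predicted, classes = label_spaces()$emotions) {
  t_sets <- as_label_sets(truth, classes)
  if (!length(t_sets)) stop("empty batch", call. = FALSE)
  if (length(t_sets) != length(predicted))
    stop("truth and predicted batch sizes differ", call. = FALSE)
  recalls <- vapply(classes, function(cl) {
    pos <- vapply(t_sets, function(s) cl %in% s, logical(1L))
    if (!any(pos)) return(NA_real_)
    tp <- sum(vapply(which(pos), function(i) cl %in% predicted[[i]],
                     logical(1L)))
    tp / sum(pos)
  }, numeric(1L))
  100 * mean(recalls, na.rm = TRUE)
}

#' Samples-F1 for multi-label prediction
#'
#' Per-sample F1 between the true and predicted label sets, averaged over
#' samples and scaled to a percentage.  A sample where both sets are empty
#' scores F1 = 1.
#'
#' @inheritParams mean_recall
#' @return Percentage in `[0, 100]`.
#' @export
samples_f1 <- function(truth, predicted, classes = label_spaces()$emotions) {
  t_sets <- as_label_sets(truth, classes)
  if (!length(t_sets)) stop("empty batch", call. = FALSE)
  if (length(t_sets) != length(predicted))
    stop("truth and predicted batch sizes differ", call. = FALSE)
  f1 <- vapply(seq_along(t_sets), function(i) {
    tr <- t_sets[[i]]
    pr <- unique(as.character(predicted[[i]]))
    if (!length(tr) && !length(pr)) return(1)
    inter <- length(intersect(tr, pr))
    if (inter == 0L) return(0)
    p <- inter / length(pr)
    r <- inter / length(tr)
    2 * p * r / (p + r)
  }, numeric(1L))
  100 * mean(f1)
}

#' Accuracy and macro-F1 for a single-label task
#'
#' Standard accuracy plus the unweighted mean of per-class F1 over classes
#' present in the truth (a class absent from the truth is dropped; its F1
#' is undefined in that fold).  Per-class F1 is 0 when the class is never
#' predicted correctly.
#'
#' @param truth,predicted equal-length label vectors.
#' @param classes the label space.
#' @return Named numeric vector `c(accuracy =, macro_f1 =)`, percentages.
#' @export
single_label_metrics <- function(truth, predicted, classes) {
  if (length(truth) != length(predicted))
    stop("truth and predicted lengths differ", call. = FALSE)
  if (!length(truth)) stop("empty batch", call. = FALSE)
  acc <- 100 * mean(truth == predicted)
  f1s <- vapply(classes, function(cl) {
    pos <- truth == cl
    if (!any(pos)) return(NA_real_)
    tp <- sum(pos & predicted == cl)
    fp <- sum(!pos & predicted == cl)
    fn <- sum(pos & predicted != cl)
    if (tp == 0L) return(0)
    p <- tp / (tp + fp)
    r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1L))
  c(accuracy = acc, macro_f1 = 100 * mean(f1s, na.rm = TRUE))
}

# full metrics report for the tasks a model predicts
metrics_report <- function(corpus, pred_labels) {
  sp <- corpus$spaces
  out <- c(temporal_accuracy = NA_real_, temporal_macro_f1 = NA_real_,
           sentiment_accuracy = NA_real_, sentiment_macro_f1 = NA_real_,
           emotion_mean_recall = NA_real_, emotion_samples_f1 = NA_real_)
  if (!is.null(pred_labels$temporal)) {
    m <- single_label_metrics(corpus$temporal, pred_labels$temporal,
                              sp$temporal)
    out["temporal_accuracy"] <- m[["accuracy"]]
    out["temporal_macro_f1"] <- m[["macro_f1"]]
  }
  if (!is.null(pred_labels$sentiment)) {
    m <- single_label_metrics(corpus$sentiment, pred_labels$sentiment,
                              sp$sentiment)
    out["sentiment_accuracy"] <- m[["accuracy"]]
    out["sentiment_macro_f1"] <- m[["macro_f1"]]
  }
  if (!is.null(pred_labels$emotions)) {
    out["emotion_mean_recall"] <- mean_recall(corpus$emotions,
                                              pred_labels$emotions,
                                              sp$emotions)
    out["emotion_samples_f1"] <- samples_f1(corpus$emotions,
                                            pred_labels$emotions,
                                            sp$emotions)
  }
  out
}
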