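#' Emotion-to-sentiment polarity map
#'
#' The 15 fine-grained emotion classes partition cleanly into the three
#' sentiment polarities; this deterministic map is the weak-supervision
#' rule that labels each sentence's sentiment from its primary emotion.
#' The default is the standard partition for this tagset: 6 positive, 7
#' negative, 2 neutral classes.
#'
#' @param positive,negative,neutral character vectors of emotion labels.
#' @param spaces a [label_spaces()] object the partition must cover.
#' @return An object of class `sentiment_map`.
#' @export
sentiment_map <- function(positive = c("forgiveness", "happiness_peacefulness",
                                       "hopefulness", "love", "pride",
                                       "thankfulness"),
                          negative = c("abuse", "anger", "blame", "fear",
                                       "guilt", "hopelessness", "sorrow"),
                          neutral = c("information", "instructions"),
                          spaces = label_spaces()) {
  positive <- tolower(positive); negative <- tolower(negative)
  neutral <- tolower(neutral)
  all_lab <- c(positive, negative, neutral)
  if (anyDuplicated(all_lab))
    stop("sentiment map sets must be disjoint", call. = FALSE)
  if (!setequal(all_lab, spaces$emotions))
    stop("sentiment map must cover exactly the 15 emotion classes",
         call. = FALSE)
  structure(list(positive = positive, negative = negative, neutral = neutral),
            class = "sentiment_map")
}

#' @export
print.sentiment_map <- function(x, ...) {
  cat("Emotion -> sentiment map:\n")
  for (p in c("positive", "negative", "neutral"))
    cat(sprintf("  %-8s (%d): %s\n", p, length(x[[p]]),
                paste(x[[p]], collapse = ", ")))
  invisible(x)
}

#' Map a primary emotion to its sentiment polarity
#'
#' @param primary_emotion an emotion label.
#' @param map a [sentiment_map()].
#' @return `"positive"`, `"negative"` or `"neutral"`.
#' @examples
#' emotion_to_sentiment("sorrow")       # "negative"
#' emotion_to_sentiment("hopefulness")  # "positive"
#' @export
emotion_to_sentiment <- function(primary_emotion, map = sentiment_map()) {
  e <- tolower(primary_emotion)
  for (p in c("positive", "negative", "neutral"))
    if (e %in% map[[p]]) return(p)
  stop("unknown emotion label: ", primary_emotion, call. = FALSE)
}

#' Derive weak sentiment labels from primary emotions
#'
#' Sets each record's sentiment from its first (primary) emotion via the
#' polarity map.  Secondary and tertiary emotions never influence the
#' result.  Existing sentiment labels are kept unless `overwrite = TRUE`.
#'
#' @param corpus an [mt_corpus()] in which every record has at least one
#'   emotion label.
#' @param map a [sentiment_map()].
#' @param overwrite replace already-present sentiment labels?
#' @return The corpus with sentiment labels filled in.
#' @export
derive_sentiment_labels <- function(corpus, map = sentiment_map(),
                                    overwrite = FALSE) {
  stopifnot(inherits(corpus, "mt_corpus"))
  unlabeled <- vapply(corpus$emotions, is.null, logical(1L))
  if (any(unlabeled))
    stop("records without emotion labels: ",
         paste(corpus$id[unlabeled], collapse = ", "), call. = FALSE)
  derived <- vapply(corpus$emotions,
                    function(e) emotion_to_sentiment(e[1L], map),
                    character(1L))
  keep <- !overwrite & !is.na(corpus$sentiment)
  corpus$sentiment <- ifelse(keep, corpus$sentiment, derived)
  corpus
}

#' Cohen's unweighted kappa
#'
#' Chance-corrected agreement between two label sequences:
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e` from the product of marginals.  Returns 1 when
#' both raters agree everywhere with degenerate marginals (`p_e = 1`).
#'
#' @param labels_a,labels_b equal-length label vectors over a shared space.
#' @return Agreement score in `[-1, 1]`.
#' @examples
#' cohen_kappa(c("x", "x", "y"), c("x", "x", "y"))  # 1
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors differ in length", call. = FALSE)
  if (!length(labels_a)) stop("empty label vectors", call. = FALSE)
  lev <- sort(unique(c(labels_a, labels_b)))
  a <- factor(labels_a, levels = lev)
  b <- factor(labels_b, levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < .Machine$double.eps^0.5)
    return(if (p_o >= 1 - .Machine$double.eps^0.5) 1 else 0)
  (p_o - p_e) / (1 - p_e)
}

#' Draw a uniform audit sample from a corpus
#'
#' Weak labels are audited by manually annotating a random subset and
#' comparing; this draws that subset: `n` records uniformly without
#' replacement, deterministic given `seed`.
#'
#' @param corpus an [mt_corpus()].
#' @param n sample size (`<=` corpus size).
#' @param seed integer seed.
#' @return An [mt_corpus()] holding the sampled records.
#' @export
sample_for_audit <- function(corpus, n, seed = 1L) {
  stopifnot(inherits(corpus, "mt_corpus"))
  if (n > length(corpus))
    stop("sample size exceeds corpus size", call. = FALSE)
  idx <- with_seed(seed, sample.int(length(corpus), n))
  corpus[idx]
}

#' Train the weak temporal-orientation classifier
#'
#' Fits the single-task temporal architecture (embedding, bidirectional GRU
#' encoder, word attention, 3-way softmax head) used to produce weak
#' temporal labels.  This is the same architecture as
#' `mtcascade(architecture = "single_temporal")`; the wrapper exists so the
#' weak-labeling workflow reads naturally.
#'
#' @param corpus an [mt_corpus()] with temporal labels on every record.
#' @param embeddings an [embedding_table()], or `NULL` for a seeded random
#'   table over the corpus vocabulary.
#' @param config an [mt_config()]; the architecture is forced to
#'   `"single_temporal"`.
#' @param seed integer seed (overrides `config$seed`).
#' @return A fitted [mtcascade] model.
#' @export
train_temporal_classifier <- function(corpus, embeddings = NULL,
                                      config = mt_config(), seed = NULL) {
  stopifnot(inherits(corpus, "mt_corpus"))
  if (anyNA(corpus$temporal))
    stop("all records need temporal labels for training", call. = FALSE)
  present <- unique(corpus$temporal)
  missing_cls <- setdiff(corpus$spaces$temporal, present)
  if (length(missing_cls))
    stop("temporal class absent from training data: ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  config$architecture <- "single_temporal"
  if (!is.null(seed)) config$seed <- as.integer(seed)
  mtcascade(corpus, config = config, embeddings = embeddings)
}

#' Predict weak temporal labels for a corpus
#'
#' Labels each record with the arg-max class of the trained weak temporal
#' classifier.  Records with empty token lists are predicted from the
#' all-padding sequence, with a warning.
#'
#' @param corpus an [mt_corpus()].
#' @param model a fitted model from [train_temporal_classifier()].
#' @return The corpus with temporal labels set to the predictions.
#' @export
predict_temporal_labels <- function(corpus, model) {
  stopifnot(inherits(corpus, "mt_corpus"), inherits(model, "mtcascade"))
  if (!length(corpus)) return(corpus)
  empties <- !vapply(corpus$tokens, length, integer(1L))
  if (any(empties))
    warning(sprintf("%d record(s) have no tokens; predicted from padding",
                    sum(empties)))
  pr <- predict(model, corpus, type = "prob")
  corpus$temporal <- corpus$spaces$temporal[max.col(pr$temporal,
                                                    ties.method = "first")]
  corpus
}
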