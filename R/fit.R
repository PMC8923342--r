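# token sequences -> padded index matrix + mask, aligned to a model vocab.
# rows with no tokens keep one unmasked padding position so the attention
# stays defined; the padding embedding is zero so they predict from a null
# context.
vectorize_tokens <- function(token_list, vocab, max_len) {
  B <- length(token_list)
  idx <- matrix(1L, B, max_len)      # 1 = <pad>
  mask <- matrix(0, B, max_len)
  for (i in seq_len(B)) {
    tk <- token_list[[i]]
    if (length(tk) > max_len) tk <- tk[seq_len(max_len)]
    if (!length(tk)) { mask[i, 1L] <- 1; next }
    m <- match(tk, vocab)
    m[is.na(m)] <- 2L                # 2 = <oov>
    idx[i, seq_along(tk)] <- m
    mask[i, seq_along(tk)] <- 1
  }
  list(idx = idx, mask = mask)
}

one_hot <- function(labels, space) {
  m <- matrix(0, length(labels), length(space))
  m[cbind(seq_along(labels), match(labels, space))] <- 1
  m
}

multi_hot <- function(emotion_list, space) {
  m <- matrix(0, length(emotion_list), length(space))
  for (i in seq_along(emotion_list))
    if (!is.null(emotion_list[[i]]))
      m[i, match(emotion_list[[i]], space)] <- 1
  m
}

corpus_targets <- function(corpus, tasks) {
  sp <- corpus$spaces
  out <- list()
  if ("temporal" %in% tasks) {
    bad <- which(is.na(corpus$temporal))
    if (length(bad))
      stop("temporal labels missing for ids: ",
           paste(utils::head(corpus$id[bad], 5L), collapse = ", "),
           call. = FALSE)
    out$temporal <- one_hot(corpus$temporal, sp$temporal)
  }
  if ("sentiment" %in% tasks) {
    bad <- which(is.na(corpus$sentiment))
    if (length(bad))
      stop("sentiment labels missing for ids: ",
           paste(utils::head(corpus$id[bad], 5L), collapse = ", "),
           call. = FALSE)
    out$sentiment <- one_hot(corpus$sentiment, sp$sentiment)
  }
  if ("emotion" %in% tasks) {
    bad <- which(vapply(corpus$emotions, is.null, logical(1L)))
    if (length(bad))
      stop("emotion labels missing for ids: ",
           paste(utils::head(corpus$id[bad], 5L), collapse = ", "),
           call. = FALSE)
    out$emotion <- multi_hot(corpus$emotions, sp$emotions)
  }
  out
}

#' Fit a cascaded shared-private attentive multitask model
#'
#' Trains one of the six architectures (see [assemble()]) on a labeled
#' corpus by minimizing the weighted joint loss
#' `L = p*L1 + q*L2 + r*L3` (single-task models minimize their own loss)
#' with Adam over `config$epochs` epochs of shuffled minibatches.  Word
#' embeddings are a fixed lookup table: supplied pre-trained vectors or a
#' seeded random table over the training vocabulary.  All stochastic
#' elements (initialization, batch order, dropout) are governed by
#' `config$seed`.
#'
#' @param corpus an [mt_corpus()] labeled for every task the architecture
#'   requires.
#' @param config an [mt_config()].
#' @param embeddings an [embedding_table()], or `NULL` for a random table.
#' @param vocab optional vocabulary (default [build_vocab()] on `corpus`).
#' @return An object of class `mtcascade` with components `params`,
#'   `config`, `desc`, `vocab`, `history` (per-epoch mean training loss),
#'   `max_len` and the label `spaces`.  Methods: [predict.mtcascade()],
#'   `print`, `summary`, `coef`, `plot`.
#' @examples
#' \donttest{
#' corp <- synth_corpus(default_synth_spec(n = 200, seed = 7))
#' cfg <- mt_config(embedding_dim = 16, encoder_units = 8, mlp_units = 8,
#'                  epochs = 2, architecture = "spanmlc", seed = 7)
#' fit <- mtcascade(corp, cfg)
#' print(fit)
#' }
#' @export
mtcascade <- function(corpus, config = mt_config(), embeddings = NULL,
                      vocab = NULL) {
  stopifnot(inherits(corpus, "mt_corpus"), inherits(config, "mt_config"))
  if (!length(corpus)) stop("cannot fit on an empty corpus", call. = FALSE)
  desc <- assemble(config, corpus$spaces)
  targets <- corpus_targets(corpus, desc$tasks)
  vocab <- vocab %||% build_vocab(corpus)
  if (is.null(embeddings))
    embeddings <- random_embeddings(vocab, config$embedding_dim,
                                    seed = derive_seed(config$seed, 3L))
  if (embeddings$dimension != config$embedding_dim)
    stop("embedding dimension does not match config$embedding_dim",
         call. = FALSE)
  emb <- vocab_embedding_matrix(embeddings, vocab)
  lens <- vapply(corpus$tokens, length, integer(1L))
  max_len <- config$max_len %||%
    max(1L, min(64L, as.integer(ceiling(stats::quantile(lens, 0.95)))))
  vec <- vectorize_tokens(corpus$tokens, vocab, max_len)
  params <- init_params(desc, config$embedding_dim,
                        derive_seed(config$seed, 1L))
  n <- length(corpus)
  history <- numeric(0)
  weights <- config$loss_weights
  if (config$epochs > 0L) {
    trained <- with_seed(derive_seed(config$seed, 2L), {
      opt <- adam_init(params)
      for (ep in seq_len(config$epochs)) {
        ord <- sample.int(n)
        starts <- seq(1L, n, by = config$batch_size)
        ep_loss <- 0
        for (s in starts) {
          bi <- ord[s:min(s + config$batch_size - 1L, n)]
          fwd <- network_forward(params, desc, emb,
                                 vec$idx[bi, , drop = FALSE],
                                 vec$mask[bi, , drop = FALSE],
                                 train = TRUE)
          tr <- lapply(targets, function(m) m[bi, , drop = FALSE])
          lb <- joint_loss(tr, fwd$probs, weights)
          loss <- if (desc$single)
            lb$l1 + lb$l2 + lb$l3 else lb$total
          ep_loss <- ep_loss + loss * length(bi)
          grads <- network_backward(params, desc, fwd, tr, weights)
          st <- adam_step(params, grads, opt, lr = config$learning_rate)
          params <- st$params
          opt <- st$state
        }
        history <- c(history, ep_loss / n)
      }
      list(params = params, history = history)
    })
    params <- trained$params
    history <- trained$history
  }
  structure(list(params = params, config = config, desc = desc,
                 vocab = vocab, emb = emb, max_len = max_len,
                 spaces = corpus$spaces, history = history,
                 n_train = n, call = match.call()),
            class = "mtcascade")
}

#' Predict from a fitted multitask model
#'
#' Evaluation-mode forward pass (dropout off, hence deterministic).
#'
#' @param object a fitted [mtcascade()] model.
#' @param newdata an [mt_corpus()] or a list of token vectors.
#' @param type `"prob"` for per-task probability matrices (softmax rows
#'   for temporal/sentiment, independent sigmoids for emotion), `"label"`
#'   for decided labels (arg-max for the single-label tasks, the
#'   threshold/top-k rule of [decide_emotions()] for emotions).
#' @param ... unused.
#' @return For `"prob"`: named list of probability matrices.  For
#'   `"label"`: a list with `temporal`, `sentiment` (character vectors)
#'   and/or `emotions` (list of character vectors), as the architecture
#'   provides.
#' @export
predict.mtcascade <- function(object, newdata, type = c("prob", "label"),
                              ...) {
  type <- match.arg(type)
  tokens <- if (inherits(newdata, "mt_corpus")) newdata$tokens else newdata
  if (!length(tokens))
    return(if (type == "prob") list() else list())
  vec <- vectorize_tokens(tokens, object$vocab, object$max_len)
  # batched evaluation keeps memory flat on large corpora
  bs <- max(object$config$batch_size, 256L)
  n <- length(tokens)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / bs))
  probs <- NULL
  for (ch in chunks) {
    fwd <- network_forward(object$params, object$desc, object$emb,
                           vec$idx[ch, , drop = FALSE],
                           vec$mask[ch, , drop = FALSE], train = FALSE)
    probs <- if (is.null(probs)) fwd$probs else
      mapply(rbind, probs, fwd$probs, SIMPLIFY = FALSE)
  }
  if (type == "prob") return(probs)
  sp <- object$spaces
  out <- list()
  if (!is.null(probs$temporal))
    out$temporal <- sp$temporal[max.col(probs$temporal,
                                        ties.method = "first")]
  if (!is.null(probs$sentiment))
    out$sentiment <- sp$sentiment[max.col(probs$sentiment,
                                          ties.method = "first")]
  if (!is.null(probs$emotion))
    out$emotions <- unname(apply(probs$emotion, 1L, function(p)
      decide_emotions(p, object$config$emotion_threshold,
                      object$config$max_emotion_labels, sp$emotions),
      simplify = FALSE))
  out
}

#' @export
print.mtcascade <- function(x, ...) {
  cat(sprintf("<mtcascade> %s model\n", x$desc$arch))
  cat(sprintf("  trained on %d sentences, %d epochs, vocab %d, max_len %d\n",
              x$n_train, length(x$history), length(x$vocab), x$max_len))
  if (length(x$history))
    cat(sprintf("  training loss: %.4f -> %.4f\n",
                x$history[1L], x$history[length(x$history)]))
  cat(sprintf("  parameters: %s\n",
              format(param_count(x$desc), big.mark = ",")))
  invisible(x)
}

#' @export
summary.mtcascade <- function(object, ...) {
  x <- object
  print(x)
  print(x$desc)
  cat(sprintf("  loss weights (p, q, r): %s\n",
              paste(x$config$loss_weights, collapse = ", ")))
  invisible(x)
}

#' Extract model parameters
#' @param object a fitted [mtcascade()] model.
#' @param ... unused.
#' @return The nested list of weight matrices and bias vectors.
#' @export
coef.mtcascade <- function(object, ...) object$params

#' Plot the training-loss history
#' @param x a fitted [mtcascade()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mtcascade <- function(x, ...) {
  if (!length(x$history)) {
    warning("no training history to plot")
    return(invisible(x))
  }
  graphics::plot(seq_along(x$history), x$history, type = "b",
                 xlab = "epoch", ylab = "mean training loss",
                 main = paste("training loss:", x$desc$arch), ...)
  invisible(x)
}
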