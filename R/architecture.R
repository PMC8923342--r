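#' Model hyperparameter configuration
#'
#' Collects every tunable of the multitask network.  Defaults follow the
#' study configuration: 300-dimensional embeddings, a bidirectional GRU
#' with 256 units per direction (encoder output width 512), ReLU dense
#' layers, dropout 0.25 after each attention and dense layer, batch size
#' 32, 20 epochs of Adam, and joint loss weights (0.3, 0.3, 1) that
#' down-weight the two weakly labeled auxiliary tasks relative to the
#' emotion task.
#'
#' @param embedding_dim word-vector dimension (default 300).
#' @param encoder_units GRU units per direction; encoder states have width
#'   `2 * encoder_units`.
#' @param attn_units width of the attention projection space (default
#'   `2 * encoder_units`).
#' @param mlp_units width of each task's dense layer output `Phi_i`.
#' @param dropout_rate dropout fraction in `[0, 1)`.
#' @param batch_size minibatch size.
#' @param epochs training epochs (no early stopping).
#' @param loss_weights numeric triple `(p, q, r)` weighting the temporal,
#'   sentiment and emotion losses in the joint objective.
#' @param learning_rate Adam step size.
#' @param optimizer_name optimizer; only `"adam"` is implemented.
#' @param max_len sequence cap; `NULL` = 95th percentile of training
#'   lengths, capped at 64.
#' @param architecture one of `"single_temporal"`, `"single_sentiment"`,
#'   `"single_emotion"`, `"mtl1"`, `"mtl2"`, `"mtl3"`, `"mtl4"`,
#'   `"spanmlc"`.
#' @param emotion_threshold probability cut-off of the emotion decision
#'   rule.
#' @param max_emotion_labels maximum emotions retained per sentence.
#' @param seed integer seed controlling initialization, batching and
#'   dropout.
#' @return An object of class `mt_config`.
#' @export
mt_config <- function(embedding_dim = 300L, encoder_units = 256L,
                      attn_units = NULL, mlp_units = 128L,
                      dropout_rate = 0.25, batch_size = 32L, epochs = 20L,
                      loss_weights = c(0.3, 0.3, 1), learning_rate = 1e-3,
                      optimizer_name = "adam", max_len = NULL,
                      architecture = "spanmlc", emotion_threshold = 0.5,
                      max_emotion_labels = 3L, seed = 1L) {
  architecture <- match.arg(architecture, c("single_temporal",
                                            "single_sentiment",
                                            "single_emotion", "mtl1", "mtl2",
                                            "mtl3", "mtl4", "spanmlc"))
  stopifnot(is_count(embedding_dim), embedding_dim >= 1,
            is_count(encoder_units), encoder_units >= 1,
            is_count(mlp_units), mlp_units >= 1,
            is.numeric(dropout_rate), dropout_rate >= 0, dropout_rate < 1,
            is_count(batch_size), batch_size >= 1,
            is_count(epochs), epochs >= 0,
            length(loss_weights) == 3L, all(loss_weights >= 0),
            is_count(max_emotion_labels), max_emotion_labels >= 1)
  if (!identical(optimizer_name, "adam"))
    stop("only the adam optimizer is implemented", call. = FALSE)
  structure(list(embedding_dim = as.integer(embedding_dim),
                 encoder_units = as.integer(encoder_units),
                 attn_units = as.integer(attn_units %||% (2L * encoder_units)),
                 mlp_units = as.integer(mlp_units),
                 dropout_rate = dropout_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 loss_weights = as.numeric(loss_weights),
                 learning_rate = learning_rate,
                 optimizer_name = optimizer_name,
                 max_len = if (!is.null(max_len)) as.integer(max_len),
                 architecture = architecture,
                 emotion_threshold = emotion_threshold,
                 max_emotion_labels = as.integer(max_emotion_labels),
                 seed = as.integer(seed)),
            class = "mt_config")
}

arch_tasks <- function(architecture) {
  switch(architecture,
         single_temporal = "temporal",
         single_sentiment = "sentiment",
         single_emotion = "emotion",
         c("temporal", "sentiment", "emotion"))
}

arch_has_private <- function(architecture)
  architecture %in% c("spanmlc", "mtl2", "mtl4",
                      "single_temporal", "single_sentiment", "single_emotion")

#' Assemble a model description for an architecture
#'
#' Resolves an architecture name into its wiring: which attention layers
#' exist, how the intermediate representations `IR_i` are concatenated,
#' and the width of every layer.  The six topologies are:
#' \describe{
#'   \item{single_*}{encoder, one attention, dense, task head.}
#'   \item{mtl1}{encoder, one shared attention, three task dense layers,
#'     heads on the dense outputs.}
#'   \item{spanmlc}{shared + three private attentions;
#'     `Phi_i = dense_i(private attention_i)`; cascaded
#'     `IR_1 = [Phi_1; SAtt]`, `IR_2 = [Phi_2; SAtt; IR_1]`,
#'     `IR_3 = [Phi_3; SAtt; IR_2]`; heads read `IR_i`; subnet order
#'     temporal, sentiment, emotion.}
#'   \item{mtl2}{like spanmlc but the cascade carries the previous
#'     subnet's predicted probability vector: `IR_2 = [Phi_2; SAtt; O_T]`,
#'     `IR_3 = [Phi_3; SAtt; O_S]`.}
#'   \item{mtl3}{spanmlc with the private attentions removed; the shared
#'     attention feeds all dense layers, cascade retained.}
#'   \item{mtl4}{shared + private attentions but no cascade:
#'     `IR_i = [Phi_i; SAtt]`.}
#' }
#'
#' @param config an [mt_config()].
#' @param spaces a [label_spaces()].
#' @return An object of class `mt_architecture` with the layer widths
#'   (`$ir_widths`, `$head_inputs`), task list and flags.
#' @examples
#' a <- assemble(mt_config(encoder_units = 256, mlp_units = 128))
#' a$ir_widths   # 640 1280 1920
#' @export
assemble <- function(config, spaces = label_spaces()) {
  stopifnot(inherits(config, "mt_config"))
  H <- 2L * config$encoder_units
  M <- config$mlp_units
  arch <- config$architecture
  tasks <- arch_tasks(arch)
  out_dims <- c(temporal = 3L, sentiment = 3L, emotion = 15L)
  single <- length(tasks) == 1L
  if (single) {
    ir <- stats::setNames(integer(0), character(0))
    head_inputs <- stats::setNames(M, tasks)
  } else {
    ir <- switch(arch,
      mtl1 = c(NA_integer_, NA_integer_, NA_integer_),
      mtl2 = c(M + H, M + H + 3L, M + H + 3L),
      mtl4 = c(M + H, M + H, M + H),
      c(M + H, M + H + (M + H), M + H + (M + H + (M + H))))  # spanmlc, mtl3
    names(ir) <- c("temporal", "sentiment", "emotion")
    head_inputs <- if (arch == "mtl1")
      stats::setNames(rep(M, 3L), names(ir)) else ir
  }
  structure(list(config = config, spaces = spaces, arch = arch,
                 tasks = tasks, single = single,
                 state_dim = H, mlp_dim = M,
                 attn_dim = config$attn_units,
                 has_private = arch_has_private(arch),
                 cascade = switch(arch, spanmlc = , mtl3 = "ir",
                                  mtl2 = "output", "none"),
                 ir_widths = ir, head_inputs = head_inputs,
                 out_dims = out_dims),
            class = "mt_architecture")
}

#' @export
print.mt_architecture <- function(x, ...) {
  cat(sprintf("<mt_architecture> %s\n", x$arch))
  cat(sprintf("  encoder width %d, attention dim %d, dense width %d\n",
              x$state_dim, x$attn_dim, x$mlp_dim))
  if (!x$single && x$arch != "mtl1")
    cat("  IR widths:", paste(x$ir_widths, collapse = ", "), "\n")
  cat("  tasks:", paste(x$tasks, collapse = ", "), "\n")
  invisible(x)
}

# allocate and initialize all trainable parameters for a description
init_params <- function(desc, embedding_dim, seed) {
  with_seed(seed, {
    U <- desc$config$encoder_units
    H <- desc$state_dim
    A <- desc$attn_dim
    M <- desc$mlp_dim
    p <- list(enc_f = new_gru_params(embedding_dim, U),
              enc_b = new_gru_params(embedding_dim, U))
    if (desc$single) {
      p$att <- new_attention_params(H, A)
      p$dense <- list(task = new_dense_params(H, M))
      p$head <- stats::setNames(
        list(new_dense_params(M, desc$out_dims[[desc$tasks]])), desc$tasks)
    } else {
      p$att_shared <- new_attention_params(H, A)
      if (desc$has_private)
        p$att_private <- stats::setNames(
          lapply(1:3, function(i) new_attention_params(H, A)),
          c("temporal", "sentiment", "emotion"))
      p$dense <- stats::setNames(
        lapply(1:3, function(i) new_dense_params(H, M)),
        c("temporal", "sentiment", "emotion"))
      p$head <- stats::setNames(
        lapply(c("temporal", "sentiment", "emotion"), function(tk)
          new_dense_params(desc$head_inputs[[tk]], desc$out_dims[[tk]])),
        c("temporal", "sentiment", "emotion"))
    }
    p
  })
}

#' Count trainable parameters of an architecture
#'
#' Computed from layer dimensions alone (no allocation), including the
#' word embeddings' exclusion: embeddings are a fixed lookup table here,
#' not trained parameters.
#'
#' @param desc an [assemble()] description.
#' @param embedding_dim word-vector dimension (needed for the encoder
#'   input weights).
#' @return Integer parameter count.
#' @export
param_count <- function(desc, embedding_dim = desc$config$embedding_dim) {
  U <- desc$config$encoder_units
  H <- desc$state_dim
  A <- desc$attn_dim
  M <- desc$mlp_dim
  gru <- embedding_dim * 3L * U + U * 2L * U + U * U + 3L * U
  att <- H * A + A + A
  n <- 2L * gru
  if (desc$single) {
    n <- n + att + (H * M + M) +
      (M * desc$out_dims[[desc$tasks]] + desc$out_dims[[desc$tasks]])
  } else {
    n_att <- 1L + if (desc$has_private) 3L else 0L
    n <- n + n_att * att + 3L * (H * M + M)
    for (tk in c("temporal", "sentiment", "emotion"))
      n <- n + desc$head_inputs[[tk]] * desc$out_dims[[tk]] +
        desc$out_dims[[tk]]
  }
  as.integer(n)
}

#' Weighted joint multitask loss
#'
#' `total = p * l1 + q * l2 + r * l3` where `l1`, `l2` are the categorical
#' cross-entropies of the temporal and sentiment softmax heads and `l3`
#' the mean binary cross-entropy over the 15 independent sigmoid emotion
#' outputs.  Tasks absent from `preds` contribute a zero term (single-task
#' models).
#'
#' @param truth list with any of `temporal`, `sentiment` (one-hot
#'   `batch x 3` matrices) and `emotion` (multi-hot `batch x 15`).
#' @param preds list of predicted probability matrices with matching
#'   names and shapes.
#' @param weights numeric triple `(p, q, r)`.
#' @return List with per-task losses `l1`, `l2`, `l3` and weighted
#'   `total`.
#' @examples
#' y <- list(temporal = diag(3))
#' joint_loss(y, list(temporal = diag(3)), c(0.3, 0.3, 1))$total  # 0
#' @export
joint_loss <- function(truth, preds, weights = c(0.3, 0.3, 1)) {
  stopifnot(length(weights) == 3L)
  eps <- 1e-12
  ce <- function(y, p) {
    if (is.null(y) || is.null(p)) return(0)
    if (!identical(dim(y), dim(p))) stop("shape mismatch", call. = FALSE)
    mean(-rowSums(y * log(pmax(p, eps))))
  }
  bce <- function(y, p) {
    if (is.null(y) || is.null(p)) return(0)
    if (!identical(dim(y), dim(p))) stop("shape mismatch", call. = FALSE)
    mean(-(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps))))
  }
  l1 <- ce(truth$temporal, preds$temporal)
  l2 <- ce(truth$sentiment, preds$sentiment)
  l3 <- bce(truth$emotion, preds$emotion)
  list(l1 = l1, l2 = l2, l3 = l3,
       total = weights[1L] * l1 + weights[2L] * l2 + weights[3L] * l3)
}
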