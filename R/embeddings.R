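#' Construct an embedding table
#'
#' Wraps a token-by-dimension matrix of word vectors together with the
#' out-of-vocabulary (OOV) policy: every lookup resolves, unseen tokens
#' all map to one shared seeded random vector, and the padding token
#' `"<pad>"` maps to the zero vector (masked downstream, so its value never
#' influences predictions).
#'
#' @param vectors numeric matrix, one row per token, rownames = tokens.
#' @param oov_seed seed for the shared OOV vector.
#' @return An object of class `embedding_table` with fields `dimension`,
#'   `vectors`, `oov_vector`.
#' @export
embedding_table <- function(vectors, oov_seed = 104729L) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  d <- ncol(vectors)
  oov <- with_seed(oov_seed, stats::rnorm(d, sd = 0.1))
  structure(list(dimension = d, vectors = vectors, oov_vector = oov),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d tokens x %d dims\n",
              nrow(x$vectors), x$dimension))
  invisible(x)
}

#' Load word embeddings from a GloVe-style text file
#'
#' Each line holds a token followed by `dimension` whitespace-separated
#' floats, no header.  Lines whose float count does not match `dimension`
#' (or that fail to parse) are skipped; the number skipped is recorded in
#' the `"skipped"` attribute and reported via a message.
#'
#' @param path embedding text file.
#' @param dimension expected vector length (e.g. 300 for the usual
#'   pre-trained GloVe tables).
#' @return An [embedding_table()].
#' @export
load_embeddings <- function(path, dimension) {
  stopifnot(is_count(dimension), dimension >= 1)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  toks <- character(0)
  rows <- list()
  skipped <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[ \t]+")[[1L]]
    if (length(parts) != dimension + 1L) { skipped <- skipped + 1L; next }
    vals <- suppressWarnings(as.numeric(parts[-1L]))
    if (anyNA(vals)) { skipped <- skipped + 1L; next }
    toks <- c(toks, parts[1L])
    rows[[length(rows) + 1L]] <- vals
  }
  if (!length(rows))
    stop("no parseable embedding line in ", path, call. = FALSE)
  if (skipped > 0L)
    message(sprintf("load_embeddings: skipped %d malformed line%s", skipped,
                    if (skipped == 1L) "" else "s"))
  m <- do.call(rbind, rows)
  rownames(m) <- toks
  out <- embedding_table(m)
  attr(out, "skipped") <- skipped
  out
}

#' Seeded random embedding table
#'
#' Offline fallback when no pre-trained table is available: i.i.d.
#' zero-mean Gaussian vectors (sd 0.1) for every vocabulary token,
#' fully determined by `seed`.
#'
#' @param vocab character vector of tokens.
#' @param dimension vector length.
#' @param seed integer seed.
#' @return An [embedding_table()]; empty vocab gives an empty table.
#' @export
random_embeddings <- function(vocab, dimension, seed = 1L) {
  stopifnot(is_count(dimension), dimension >= 1)
  vocab <- unique(as.character(vocab))
  m <- with_seed(seed,
    matrix(stats::rnorm(length(vocab) * dimension, sd = 0.1),
           nrow = length(vocab), ncol = dimension))
  rownames(m) <- vocab
  embedding_table(m, oov_seed = derive_seed(seed, 17L))
}

#' Look up embedding vectors for tokens
#'
#' Total lookup: known tokens return their stored row, `"<pad>"` returns
#' the zero vector, anything else the shared OOV vector.
#'
#' @param table an [embedding_table()].
#' @param tokens character vector.
#' @return numeric matrix `length(tokens)` x `dimension`.
#' @export
embedding_lookup <- function(table, tokens) {
  stopifnot(inherits(table, "embedding_table"))
  d <- table$dimension
  out <- matrix(0, nrow = length(tokens), ncol = d)
  if (!length(tokens)) return(out)
  hit <- match(tokens, rownames(table$vectors))
  for (i in seq_along(tokens)) {
    if (tokens[i] == "<pad>") next
    out[i, ] <- if (is.na(hit[i])) table$oov_vector else
      table$vectors[hit[i], ]
  }
  out
}

# embedding matrix aligned to a model vocabulary: row 1 = <pad> (zeros),
# row 2 = <oov> (shared vector), remaining rows = vocab tokens
vocab_embedding_matrix <- function(table, vocab) {
  stopifnot(identical(vocab[1:2], c("<pad>", "<oov>")))
  m <- embedding_lookup(table, vocab)
  m[1L, ] <- 0
  m[2L, ] <- table$oov_vector
  rownames(m) <- vocab
  m
}
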