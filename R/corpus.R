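#' Construct a labeled sentence corpus
#'
#' A corpus is an ordered collection of sentence records, each carrying raw
#' text, a token sequence, and up to three task labels: a temporal
#' orientation, a sentiment polarity, and an ordered list of 1-3 distinct
#' emotion labels whose first element is the primary emotion.  Any label may
#' be absent (`NA` / empty), e.g. before weak labeling has run.
#'
#' @param id character vector of unique record identifiers.
#' @param text character vector of raw sentences.
#' @param temporal temporal labels (or `NA`); validated against `spaces`.
#' @param sentiment sentiment labels (or `NA`); validated against `spaces`.
#' @param emotions list of character vectors (each of length 1-3, distinct,
#'   first element = primary emotion), or `NULL` entries when unlabeled.
#' @param tokens list of token vectors; when `NULL`, a basic
#'   lower-case word tokenization of `text` is used.  Replace with
#'   [preprocess_corpus()] output for the full normalization pipeline.
#' @param spaces a [label_spaces()] object.
#' @return An object of class `mt_corpus`.
#' @seealso [read_corpus()], [write_corpus()], [synth_corpus()]
#' @export
mt_corpus <- function(id, text, temporal = NULL, sentiment = NULL,
                      emotions = NULL, tokens = NULL,
                      spaces = label_spaces()) {
  n <- length(text)
  id <- as.character(id)
  text <- as.character(text)
  if (length(id) != n) stop("`id` and `text` lengths differ", call. = FALSE)
  if (anyDuplicated(id))
    stop("duplicate record id: ", id[duplicated(id)][1L], call. = FALSE)
  norm_lab <- function(x, space, what) {
    if (is.null(x)) return(rep(NA_character_, n))
    x <- tolower(as.character(x))
    x[!nzchar(x) | is.na(x)] <- NA_character_
    bad <- which(!is.na(x) & !(x %in% space))
    if (length(bad))
      stop(sprintf("row %d: unknown %s label '%s'", bad[1L], what, x[bad[1L]]),
           call. = FALSE)
    if (length(x) != n) stop("`", what, "` has wrong length", call. = FALSE)
    x
  }
  temporal <- norm_lab(temporal, spaces$temporal, "temporal")
  sentiment <- norm_lab(sentiment, spaces$sentiment, "sentiment")
  if (is.null(emotions)) emotions <- vector("list", n)
  if (length(emotions) != n) stop("`emotions` has wrong length", call. = FALSE)
  emotions <- lapply(seq_len(n), function(i) {
    e <- emotions[[i]]
    if (is.null(e) || !length(e) || all(is.na(e) | !nzchar(e))) return(NULL)
    e <- tolower(as.character(e[!is.na(e) & nzchar(e)]))
    if (length(e) > 3L)
      stop(sprintf("row %d: more than 3 emotion labels", i), call. = FALSE)
    if (anyDuplicated(e))
      stop(sprintf("row %d: duplicated emotion label '%s'", i,
                   e[duplicated(e)][1L]), call. = FALSE)
    bad <- setdiff(e, spaces$emotions)
    if (length(bad))
      stop(sprintf("row %d: unknown emotion label '%s'", i, bad[1L]),
           call. = FALSE)
    e
  })
  if (is.null(tokens)) tokens <- lapply(text, tokenize_basic)
  if (length(tokens) != n) stop("`tokens` has wrong length", call. = FALSE)
  structure(list(id = id, text = text, temporal = temporal,
                 sentiment = sentiment, emotions = emotions,
                 tokens = tokens, spaces = spaces),
            class = "mt_corpus")
}

#' @export
length.mt_corpus <- function(x) length(x$id)

#' Subset a corpus by record position
#' @param x an `mt_corpus`.
#' @param i integer or logical index over records.
#' @param ... unused.
#' @return The sub-corpus, records in the order of `i`.
#' @export
`[.mt_corpus` <- function(x, i, ...) {
  structure(list(id = x$id[i], text = x$text[i], temporal = x$temporal[i],
                 sentiment = x$sentiment[i], emotions = x$emotions[i],
                 tokens = x$tokens[i], spaces = x$spaces),
            class = "mt_corpus")
}

#' @export
print.mt_corpus <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<mt_corpus> %d record%s\n", n, if (n == 1L) "" else "s"))
  lab <- function(v) sum(!is.na(v))
  cat(sprintf("  labeled: temporal %d, sentiment %d, emotions %d\n",
              lab(x$temporal), lab(x$sentiment),
              sum(!vapply(x$emotions, is.null, logical(1L)))))
  if (n) {
    show <- seq_len(min(3L, n))
    for (i in show)
      cat(sprintf("  [%s] %s\n", x$id[i],
                  substr(x$text[i], 1L, 60L)))
    if (n > 3L) cat("  ...\n")
  }
  invisible(x)
}

#' Basic word tokenizer
#'
#' Lower-cases and splits on anything that is not a letter, digit,
#' apostrophe, `#` or `_`, keeping placeholder tokens such as `url` intact.
#' Used as the default tokenization; the full pipeline is in
#' [preprocess_text()].
#'
#' @param text a single string.
#' @return character vector of tokens (possibly empty).
#' @export
tokenize_basic <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(tolower(text), "[^a-z0-9'#_]+")[[1L]]
  toks[nzchar(toks)]
}

emotions_to_string <- function(e) {
  if (is.null(e)) "" else paste(e, collapse = "|")
}

string_to_emotions <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  strsplit(s, "|", fixed = TRUE)[[1L]]
}

#' Read a labeled sentence corpus from TSV or JSONL
#'
#' The TSV dialect has columns `id`, `text`, `temporal`, `sentiment`,
#' `emotions`, the last holding 0-3 `|`-separated emotion names in order of
#' predominance.  The JSONL dialect has one object per line with the same
#' keys and `emotions` as an array.  Label strings are lower-cased on read
#' and validated against `spaces`; an unknown label raises an error naming
#' the row and offending value.
#'
#' @param path file to read.
#' @param format `"tsv"` or `"jsonl"`; default guessed from the extension.
#' @param spaces a [label_spaces()] object.
#' @return An [mt_corpus()].
#' @export
read_corpus <- function(path, format = c("tsv", "jsonl"), spaces = label_spaces()) {
  if (missing(format))
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "tsv"
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "tsv") {
    df <- utils::read.delim(path, colClasses = "character", quote = "",
                            na.strings = NULL, check.names = FALSE)
    if (!("text" %in% names(df)))
      stop("corpus file lacks a 'text' column", call. = FALSE)
    if (!nrow(df))
      return(mt_corpus(character(0), character(0), spaces = spaces))
    get_col <- function(nm) if (nm %in% names(df)) df[[nm]] else NULL
    mt_corpus(id = get_col("id") %||% as.character(seq_len(nrow(df))),
              text = df$text,
              temporal = get_col("temporal"),
              sentiment = get_col("sentiment"),
              emotions = if ("emotions" %in% names(df))
                lapply(df$emotions, string_to_emotions),
              spaces = spaces)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
      return(mt_corpus(character(0), character(0), spaces = spaces))
    recs <- lapply(lines, jsonlite::fromJSON)
    if (!all(vapply(recs, function(r) "text" %in% names(r), logical(1L))))
      stop("jsonl record lacks a 'text' key", call. = FALSE)
    pick <- function(key) vapply(recs, function(r) {
      v <- r[[key]]
      if (is.null(v) || !length(v)) NA_character_ else as.character(v[1L])
    }, character(1L))
    mt_corpus(id = pick("id"),
              text = pick("text"),
              temporal = pick("temporal"),
              sentiment = pick("sentiment"),
              emotions = lapply(recs, function(r) {
                e <- r[["emotions"]]
                if (is.null(e) || !length(e)) NULL else as.character(e)
              }),
              spaces = spaces)
  }
}

#' Write a corpus to TSV or JSONL
#'
#' Serialization is lossless for labels and text: `read_corpus()` on the
#' written file reproduces the corpus record-for-record (tokens are
#' re-derived from text, so custom tokenizations should be re-applied).
#'
#' @param corpus an [mt_corpus()].
#' @param path output file.
#' @param format `"tsv"` or `"jsonl"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("tsv", "jsonl")) {
  stopifnot(inherits(corpus, "mt_corpus"))
  if (missing(format))
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "tsv"
  format <- match.arg(format)
  if (any(grepl("[\t\n\r]", corpus$text)))
    stop("text contains tab or newline; cannot serialize", call. = FALSE)
  blank <- function(v) ifelse(is.na(v), "", v)
  if (format == "tsv") {
    df <- data.frame(id = corpus$id, text = corpus$text,
                     temporal = blank(corpus$temporal),
                     sentiment = blank(corpus$sentiment),
                     emotions = vapply(corpus$emotions, emotions_to_string,
                                       character(1L)),
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    lines <- vapply(seq_along(corpus$id), function(i) {
      rec <- list(id = corpus$id[i], text = corpus$text[i])
      if (!is.na(corpus$temporal[i])) rec$temporal <- corpus$temporal[i]
      if (!is.na(corpus$sentiment[i])) rec$sentiment <- corpus$sentiment[i]
      if (!is.null(corpus$emotions[[i]])) rec$emotions <- corpus$emotions[[i]]
      jsonlite::toJSON(rec, auto_unbox = TRUE)
    }, character(1L))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Build a frequency-ordered vocabulary from a corpus
#'
#' Tokens occurring at least `min_count` times, ordered by frequency
#' (descending) with lexicographic tie-break, preceded by the reserved
#' padding token `"<pad>"` (index 1) and out-of-vocabulary token `"<oov>"`
#' (index 2).  The ordering is deterministic and invariant to record order.
#'
#' @param corpus an [mt_corpus()] with tokens.
#' @param min_count minimum token frequency (default 1).
#' @return character vector of vocabulary tokens.
#' @export
build_vocab <- function(corpus, min_count = 1L) {
  stopifnot(inherits(corpus, "mt_corpus"))
  toks <- unlist(corpus$tokens, use.names = FALSE)
  if (!length(toks)) return(c("<pad>", "<oov>"))
  tab <- table(toks)
  tab <- tab[tab >= min_count]
  ord <- order(-as.integer(tab), names(tab), method = "radix")
  c("<pad>", "<oov>", names(tab)[ord])
}
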