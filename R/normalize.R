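#' Text normalization configuration
#'
#' Bundles everything the normalization pipeline needs: entity patterns and
#' their placeholder tokens, a contraction-expansion table, a unigram
#' frequency lexicon for hashtag segmentation and elongation repair, and
#' the run-length cap applied before vocabulary lookup.  The package ships
#' a ~48-entry contraction table and a small demonstration lexicon (high
#' frequency English words plus note-domain vocabulary); both can be
#' overridden with user files.
#'
#' @param contractions_file two-column TSV (`contraction`, `expansion`);
#'   default: the table shipped with the package.
#' @param lexicon_file two-column whitespace-separated text
#'   (`token count`); default: the shipped demonstration lexicon.
#' @param max_repeat run-length cap for elongated characters before
#'   vocabulary lookup (default 2, which recovers e.g. "Soooo" -> "so").
#' @param entity_patterns named character vector of regular expressions;
#'   names are the placeholder tokens (`url`, `email`, `date`, `phone`).
#'   Placeholders are plain lower-case words no pattern re-matches, so
#'   entity normalization is idempotent.
#' @return An object of class `normalizer_config`.
#' @export
normalizer_config <- function(contractions_file = NULL, lexicon_file = NULL,
                              max_repeat = 2L,
                              entity_patterns = c(
                                url = "(https?://|www\\.)[^[:space:]]+",
                                email = "[^[:space:]@]+@[^[:space:]@]+\\.[^[:space:]@]+",
                                date = "\\d{1,4}[-/\\.]\\d{1,2}[-/\\.]\\d{1,4}",
                                phone = "\\+?\\d[\\d() -]{6,}\\d")) {
  contractions_file <- contractions_file %||%
    system.file("extdata", "contractions.tsv", package = "mtcascade")
  lexicon_file <- lexicon_file %||%
    system.file("extdata", "demo_lexicon.txt", package = "mtcascade")
  ct <- utils::read.delim(contractions_file, colClasses = "character",
                          quote = "")
  contraction_table <- stats::setNames(tolower(ct$expansion),
                                       tolower(ct$contraction))
  lx <- utils::read.table(lexicon_file, col.names = c("token", "count"),
                          colClasses = c("character", "numeric"))
  if (any(lx$count <= 0)) stop("lexicon counts must be positive", call. = FALSE)
  lexicon <- stats::setNames(lx$count, tolower(lx$token))
  stopifnot(is_count(max_repeat), max_repeat >= 1)
  structure(list(entity_patterns = entity_patterns,
                 contraction_table = contraction_table,
                 lexicon = lexicon,
                 max_repeat = as.integer(max_repeat)),
            class = "normalizer_config")
}

#' Replace entity spans with placeholder tokens
#'
#' Every maximal span matching an entity class (URL, email, date, phone
#' number) is replaced by that class's placeholder word; all other text is
#' unchanged.  The operation is idempotent because placeholders match no
#' pattern.
#'
#' @param text a single string.
#' @param config a [normalizer_config()].
#' @return The normalized string.
#' @examples
#' cfg <- normalizer_config()
#' normalize_entities("see http://a.b/c now", cfg)   # "see url now"
#' @export
normalize_entities <- function(text, config = normalizer_config()) {
  for (nm in names(config$entity_patterns))
    text <- gsub(config$entity_patterns[[nm]], nm, text, perl = TRUE)
  text
}

# additive segmentation score: log relative frequency for lexicon words,
# length-penalized floor for unknown chunks (so known splits always win
# when available, and all-unknown bodies stay whole)
.seg_score <- function(word, lexicon, total) {
  f <- lexicon[word]
  if (!is.na(f)) log(as.numeric(f)) - log(total)
  else -10 - 10 * nchar(word)
}

#' Segment a hashtag into lexicon words
#'
#' Finds the maximum-score split of the lower-cased hashtag body, scoring a
#' candidate segmentation by the sum of log unigram frequencies of its
#' words (unknown chunks carry a strong length penalty).  Dynamic
#' programming over split points; a body no lexicon word helps with comes
#' back whole.
#'
#' @param tag the hashtag, beginning with `#`.
#' @param lexicon named numeric vector, token -> frequency; default from
#'   [normalizer_config()].
#' @return Character vector of segment tokens ("#BESTFRIENDS" ->
#'   `c("best", "friends")`); empty body gives `character(0)`.
#' @export
segment_hashtag <- function(tag, lexicon = normalizer_config()$lexicon) {
  if (!startsWith(tag, "#")) stop("hashtag must begin with '#'", call. = FALSE)
  body <- tolower(substring(tag, 2L))
  n <- nchar(body)
  if (n == 0L) return(character(0))
  total <- sum(as.numeric(lexicon))
  # best[i]: best score of segmenting the first i characters
  best <- c(0, rep(-Inf, n))
  back <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      w <- substring(body, j, i)
      s <- best[j] + .seg_score(w, lexicon, total)
      if (s > best[i + 1L]) { best[i + 1L] <- s; back[i] <- j }
    }
  }
  out <- character(0)
  i <- n
  while (i > 0L) {
    j <- back[i]
    out <- c(substring(body, j, i), out)
    i <- j - 1L
  }
  out
}

#' Expand contractions in text
#'
#' Token-boundary-aware, case-insensitive replacement of each table entry
#' by its expansion (lower-case output), e.g. "can't" -> "can not",
#' "I'm" -> "i am".  Idempotent: expansions contain no contractions.
#'
#' @param text a single string.
#' @param table named character vector, contraction -> expansion.
#' @return The expanded string.
#' @export
expand_contractions <- function(text,
                                table = normalizer_config()$contraction_table) {
  for (ctr in names(table)) {
    pat <- paste0("(?<![a-z'])", gsub("'", "'", ctr, fixed = TRUE),
                  "(?![a-z'])")
    text <- gsub(pat, table[[ctr]], text, perl = TRUE, ignore.case = TRUE)
  }
  text
}

# per-run character lengths of a token, e.g. "soooo" -> s:1 o:4
.char_runs <- function(token) {
  ch <- strsplit(token, "", fixed = TRUE)[[1L]]
  r <- rle(ch)
  r
}

#' Collapse elongated character runs
#'
#' Runs longer than `max_repeat` are first capped; if the capped token is
#' not a known word, runs are further shortened toward a single character
#' whenever the resulting form is in the vocabulary ("Soooo" -> "so",
#' "YOOOU" -> "you").  Output is lower-cased.  Among in-vocabulary
#' candidates the least-reduced (longest) form is preferred, so ordinary
#' double letters ("all", "good") survive.
#'
#' @param token a single token.
#' @param vocab character vector of known words.
#' @param max_repeat run-length cap (default 2).
#' @return The repaired token.
#' @export
reduce_elongation <- function(token, vocab = names(normalizer_config()$lexicon),
                              max_repeat = 2L) {
  token <- tolower(token)
  r <- .char_runs(token)
  if (!length(r$values)) return(token)
  capped_len <- pmin(r$lengths, max_repeat)
  capped <- paste(rep(r$values, capped_len), collapse = "")
  if (capped %in% vocab) return(capped)
  # enumerate per-run lengths in {1..capped}; runs are few in practice
  multi <- which(capped_len > 1L)
  if (!length(multi)) return(capped)
  choices <- lapply(seq_along(capped_len), function(i)
    if (capped_len[i] > 1L) seq(capped_len[i], 1L) else 1L)
  grid <- expand.grid(choices, KEEP.OUT.ATTRS = FALSE)
  cands <- apply(grid, 1L, function(lens)
    paste(rep(r$values, lens), collapse = ""))
  hits <- cands[cands %in% vocab]
  if (!length(hits)) return(capped)
  hits[order(-nchar(hits), hits)][1L]
}

#' Full normalization pipeline
#'
#' Applies, in order: entity normalization, tokenization, contraction
#' expansion, hashtag segmentation, elongation reduction.  Deterministic
#' and idempotent at the token level: re-running the pipeline on its own
#' joined output returns the same tokens.
#'
#' @param text a single string.
#' @param config a [normalizer_config()].
#' @return Character vector of normalized tokens.
#' @examples
#' preprocess_text("I'm soooo sad #BESTFRIENDS")
#' @export
preprocess_text <- function(text, config = normalizer_config()) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  text <- normalize_entities(text, config)
  toks <- tokenize_basic(text)
  vocab <- names(config$lexicon)
  out <- character(0)
  for (tk in toks) {
    if (!is.na(config$contraction_table[tk])) {
      out <- c(out, strsplit(config$contraction_table[[tk]], " ",
                             fixed = TRUE)[[1L]])
    } else if (startsWith(tk, "#")) {
      out <- c(out, segment_hashtag(tk, config$lexicon))
    } else {
      out <- c(out, reduce_elongation(tk, vocab, config$max_repeat))
    }
  }
  out
}

#' Apply the normalization pipeline to every record of a corpus
#'
#' @param corpus an [mt_corpus()].
#' @param config a [normalizer_config()].
#' @return The corpus with its `tokens` replaced by normalized tokens.
#' @export
preprocess_corpus <- function(corpus, config = normalizer_config()) {
  stopifnot(inherits(corpus, "mt_corpus"))
  corpus$tokens <- lapply(corpus$text, preprocess_text, config = config)
  corpus
}
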