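#' Label spaces for the three tasks
#'
#' The three classification tasks operate over fixed label spaces: three
#' temporal-orientation categories, three sentiment polarities, and fifteen
#' fine-grained emotion classes of which a sentence may carry up to three
#' (ordered by predominance).  The emotion order given here is canonical for
#' the package: it fixes the multi-hot encoding used by the models and
#' metrics, and must not change within a run.
#'
#' @param temporal character vector of 3 temporal class names.
#' @param sentiment character vector of 3 sentiment class names.
#' @param emotions character vector of 15 emotion class names.
#' @return An object of class `label_spaces`: a list with elements
#'   `temporal`, `sentiment`, `emotions`.
#' @examples
#' sp <- label_spaces()
#' sp$emotions[1]   # "forgiveness"
#' @export
label_spaces <- function(temporal = c("past", "present", "future"),
                         sentiment = c("positive", "negative", "neutral"),
                         emotions = c("forgiveness", "happiness_peacefulness",
                                      "love", "pride", "hopefulness",
                                      "thankfulness", "blame", "anger",
                                      "fear", "abuse", "sorrow",
                                      "hopelessness", "guilt", "information",
                                      "instructions")) {
  temporal <- tolower(as.character(temporal))
  sentiment <- tolower(as.character(sentiment))
  emotions <- tolower(as.character(emotions))
  if (length(temporal) != 3L || anyDuplicated(temporal))
    stop("`temporal` must hold 3 distinct class names", call. = FALSE)
  if (length(sentiment) != 3L || anyDuplicated(sentiment))
    stop("`sentiment` must hold 3 distinct class names", call. = FALSE)
  if (length(emotions) != 15L || anyDuplicated(emotions))
    stop("`emotions` must hold 15 distinct class names", call. = FALSE)
  structure(list(temporal = temporal, sentiment = sentiment,
                 emotions = emotions),
            class = "label_spaces")
}

#' @export
print.label_spaces <- function(x, ...) {
  cat("Label spaces:\n")
  cat("  temporal :", paste(x$temporal, collapse = ", "), "\n")
  cat("  sentiment:", paste(x$sentiment, collapse = ", "), "\n")
  cat("  emotions :", paste(x$emotions, collapse = ", "), "\n")
  invisible(x)
}
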