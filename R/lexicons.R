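#' Load a valence lexicon (VAD dialect)
#'
#' Reads a tab-separated table mapping words to a valence score in [0, 1]
#' (0 most negative, 1 most positive) and derives the thresholded positive and
#' negative term sets used for scoring: a word is a positive term when its
#' valence is at least \code{theta_pos} (inclusive) and a negative term when
#' its valence is at most \code{theta_neg}. Extra columns (arousal, dominance)
#' are ignored. Duplicate words keep the last entry, with a warning.
#'
#' @param table A data frame with columns \code{word} and \code{valence}, or a
#'   path to a TSV file whose first two columns are word and valence.
#' @param theta_pos Positive-term threshold (default 0.75).
#' @param theta_neg Negative-term threshold (default 0.25).
#' @return An object of class \code{valence_lexicon}: list with
#'   \code{entries} (named numeric vector), \code{pos_terms},
#'   \code{neg_terms}, and the thresholds.
#' @export
load_valence_lexicon <- function(table, theta_pos = 0.75, theta_neg = 0.25) {
  stopifnot(theta_neg < theta_pos)
  if (is.character(table) && length(table) == 1L) {
    table <- utils::read.delim(table, header = TRUE, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(table), ncol(table) >= 2)
  if (!all(c("word", "valence") %in% names(table))) {
    names(table)[1:2] <- c("word", "valence")
  }
  w <- tolower(as.character(table$word))
  v <- as.numeric(table$valence)
  if (anyNA(v) || any(v < 0 | v > 1)) {
    stop("valence values must be numeric in [0, 1]")
  }
  if (anyDuplicated(w)) {
    warning("duplicate words in valence lexicon; keeping last entry")
    keep <- !duplicated(w, fromLast = TRUE)
    w <- w[keep]; v <- v[keep]
  }
  entries <- stats::setNames(v, w)
  structure(
    list(entries = entries,
         pos_terms = names(entries)[entries >= theta_pos],
         neg_terms = names(entries)[entries <= theta_neg],
         theta_pos = theta_pos, theta_neg = theta_neg),
    class = "valence_lexicon"
  )
}

#' @export
print.valence_lexicon <- function(x, ...) {
  cat("Valence lexicon:", length(x$entries), "words;",
      length(x$pos_terms), "positive (>=", x$theta_pos, "),",
      length(x$neg_terms), "negative (<=", x$theta_neg, ")\n")
  invisible(x)
}

#' The eight discrete emotions scored by the emotion lexicon
#' @export
EMOTIONS <- c("anger", "fear", "anticipation", "trust",
              "surprise", "sadness", "joy", "disgust")

#' Load an emotion lexicon (word-emotion association dialect)
#'
#' Reads a long tab-separated table with columns \code{word}, \code{emotion},
#' \code{association} (association strength in [0, 1]; the common binary
#' lexicons use 0/1, which the same threshold handles). A word counts toward
#' an emotion when its association is at least \code{theta_emo}. Emotions
#' outside the canonical eight are rejected.
#'
#' @param table Data frame (or TSV path) with columns word, emotion,
#'   association.
#' @param theta_emo Association threshold (default 0.75).
#' @return An object of class \code{emotion_lexicon}: list with
#'   \code{terms}, a named list mapping each emotion to its associated word
#'   set, and \code{theta_emo}.
#' @export
load_emotion_lexicon <- function(table, theta_emo = 0.75) {
  if (is.character(table) && length(table) == 1L) {
    table <- utils::read.delim(table, header = TRUE, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(table), ncol(table) >= 3)
  if (!all(c("word", "emotion", "association") %in% names(table))) {
    names(table)[1:3] <- c("word", "emotion", "association")
  }
  emo <- tolower(as.character(table$emotion))
  unknown <- setdiff(unique(emo), EMOTIONS)
  if (length(unknown) > 0) {
    stop("unknown emotion(s) in lexicon: ", paste(unknown, collapse = ", "))
  }
  a <- as.numeric(table$association)
  if (anyNA(a) || any(a < 0 | a > 1)) {
    stop("association values must be numeric in [0, 1]")
  }
  w <- tolower(as.character(table$word))
  hit <- a >= theta_emo
  terms <- lapply(stats::setNames(EMOTIONS, EMOTIONS),
                  function(e) unique(w[hit & emo == e]))
  structure(list(terms = terms, theta_emo = theta_emo),
            class = "emotion_lexicon")
}

#' Load opinion word lists (positive/negative list dialect)
#'
#' Reads two plain word-per-line files (or character vectors): one positive,
#' one negative. Lines beginning with \code{;} are comments; blank lines are
#' skipped. No weighting is applied — membership is binary.
#'
#' @param pos Positive word list: file path or character vector.
#' @param neg Negative word list: file path or character vector.
#' @return A list with \code{pos_terms} and \code{neg_terms} (lowercased,
#'   unique), of class \code{opinion_lexicon}. Words appearing in both lists
#'   are kept in both, with a warning.
#' @export
load_opinion_lexicon <- function(pos, neg) {
  read_list <- function(x) {
    if (length(x) == 1L && file.exists(x)) x <- readLines(x, warn = FALSE)
    x <- trimws(x)
    unique(tolower(x[nzchar(x) & !startsWith(x, ";")]))
  }
  p <- read_list(pos); n <- read_list(neg)
  both <- intersect(p, n)
  if (length(both) > 0) {
    warning(length(both), " word(s) appear in both opinion lists")
  }
  structure(list(pos_terms = p, neg_terms = n), class = "opinion_lexicon")
}
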