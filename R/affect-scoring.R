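#' Score the valence of a token sequence
#'
#' Computes the proportion of word occurrences that belong to the lexicon's
#' thresholded positive and negative term sets. Every token occurrence counts
#' (occurrence counting, not unique types) and the denominator is all tokens,
#' including out-of-lexicon words.
#'
#' @param tokens Character vector of cleaned tokens (length >= 1).
#' @param lexicon A \code{valence_lexicon} from [load_valence_lexicon()].
#' @return Named numeric vector \code{c(pos = ..., neg = ...)}, both in [0,1].
#' @export
score_valence <- function(tokens, lexicon) {
  stopifnot(inherits(lexicon, "valence_lexicon"))
  if (length(tokens) == 0) stop("cannot score an empty page (no tokens)")
  n <- length(tokens)
  c(pos = sum(tokens %in% lexicon$pos_terms) / n,
    neg = sum(tokens %in% lexicon$neg_terms) / n)
}

#' Score the eight discrete emotions of a token sequence
#'
#' For each emotion, the proportion of token occurrences associated with that
#' emotion at or above the lexicon threshold. A token associated with several
#' emotions counts toward each of them.
#'
#' @param tokens Character vector of cleaned tokens (length >= 1).
#' @param lexicon An \code{emotion_lexicon} from [load_emotion_lexicon()].
#' @return Named numeric vector over the eight emotions.
#' @export
score_emotions <- function(tokens, lexicon) {
  stopifnot(inherits(lexicon, "emotion_lexicon"))
  if (length(tokens) == 0) stop("cannot score an empty page (no tokens)")
  n <- length(tokens)
  vapply(lexicon$terms, function(set) sum(tokens %in% set) / n, numeric(1))
}

#' Score tokens against unweighted opinion word lists
#'
#' @param tokens Character vector of cleaned tokens (length >= 1).
#' @param lexicon An \code{opinion_lexicon} from [load_opinion_lexicon()], or
#'   a list with \code{pos_terms}/\code{neg_terms}.
#' @return Named numeric vector \code{c(pos = ..., neg = ...)}.
#' @export
score_opinion <- function(tokens, lexicon) {
  if (length(tokens) == 0) stop("cannot score an empty page (no tokens)")
  n <- length(tokens)
  c(pos = sum(tokens %in% lexicon$pos_terms) / n,
    neg = sum(tokens %in% lexicon$neg_terms) / n)
}

#' Aggregate page scores into a participant profile
#'
#' Page-level affect scores are averaged per day (unweighted over pages) and
#' the daily means are then averaged across days with equal day weights —
#' days with many pages do not dominate days with few. Days with no scored
#' pages are absent from the daily table and do not contribute to the overall
#' mean. Single-day data reduces to the mean over that day's pages.
#'
#' @param scores A data frame with one row per scored page: columns
#'   \code{participant}, \code{day}, plus any numeric score columns
#'   (e.g. \code{pos}, \code{neg}, emotions).
#' @return A list with \code{daily} (data frame participant x day means) and
#'   \code{overall} (data frame of participant-level means of the daily
#'   means). Participants with zero scored pages are absent.
#' @export
aggregate_participant <- function(scores) {
  stopifnot(is.data.frame(scores),
            all(c("participant", "day") %in% names(scores)))
  value_cols <- setdiff(names(scores), c("participant", "day"))
  value_cols <- value_cols[vapply(scores[value_cols], is.numeric, logical(1))]
  if (length(value_cols) == 0) stop("no numeric score columns to aggregate")
  daily <- stats::aggregate(scores[value_cols],
                            by = list(participant = scores$participant,
                                      day = scores$day),
                            FUN = mean)
  overall <- stats::aggregate(daily[value_cols],
                              by = list(participant = daily$participant),
                              FUN = mean)
  daily <- daily[order(daily$participant, daily$day), , drop = FALSE]
  rownames(daily) <- NULL
  list(daily = daily, overall = overall)
}

#' Classify a page as a negative, neutral or positive stimulus
#'
#' Classifies a page's affect scores against a reference population of pages
#' (mean and s.d. of the population's scores) using z-score rules used to
#' assemble stimulus pools:
#' \describe{
#'   \item{\code{"extreme_negative"}}{negative when the negative score exceeds
#'     the reference mean by more than 2.5 s.d.; neutral when the negative
#'     z-score lies within [-1, +1]; otherwise unclassified.}
#'   \item{\code{"extreme_both"}}{positive when the positive z-score exceeds
#'     2.5 while the negative does not; negative when the reverse holds;
#'     neutral when both |z| < 2.5; pages extreme on both axes are
#'     unclassified (stimulus pools are mutually exclusive).}
#' }
#'
#' @param pos,neg The page's positive and negative scores.
#' @param ref Named list with \code{pos_mean}, \code{pos_sd}, \code{neg_mean},
#'   \code{neg_sd} (s.d.s must be positive; for \code{"extreme_negative"} only
#'   the negative pair is required).
#' @param rule \code{"extreme_negative"} or \code{"extreme_both"}.
#' @return One of \code{"negative"}, \code{"neutral"}, \code{"positive"},
#'   \code{"unclassified"}.
#' @export
classify_stimulus <- function(pos, neg, ref,
                              rule = c("extreme_negative", "extreme_both")) {
  rule <- match.arg(rule)
  if (is.null(ref$neg_sd) || ref$neg_sd <= 0) {
    stop("reference s.d. must be positive")
  }
  zn <- (neg - ref$neg_mean) / ref$neg_sd
  if (rule == "extreme_negative") {
    if (zn > 2.5) return("negative")
    if (abs(zn) <= 1) return("neutral")
    return("unclassified")
  }
  if (is.null(ref$pos_sd) || ref$pos_sd <= 0) {
    stop("reference s.d. must be positive")
  }
  zp <- (pos - ref$pos_mean) / ref$pos_sd
  if (zp > 2.5 && zn > 2.5) return("unclassified")
  if (zp > 2.5) return("positive")
  if (zn > 2.5) return("negative")
  if (abs(zp) < 2.5 && abs(zn) < 2.5) return("neutral")
  "unclassified"
}

#' Draw a random contiguous text segment from a page
#'
#' Used to validate whole-page scoring against subsections: draws a contiguous
#' token subsequence whose length is uniform on [\code{min_words}, n] and
#' whose start position is uniform over the valid range. Deterministic for a
#' fixed seed.
#'
#' @param tokens Character vector of page tokens.
#' @param min_words Minimum segment length (default 200).
#' @param seed Optional integer seed.
#' @return Character vector: the sampled segment. Errors when the page is
#'   shorter than \code{min_words}.
#' @export
sample_segment <- function(tokens, min_words = 200, seed = NULL) {
  n <- length(tokens)
  if (n < min_words) {
    stop("page has ", n, " tokens, fewer than min_words = ", min_words)
  }
  if (!is.null(seed)) set.seed(seed)
  len <- if (n == min_words) n else sample(min_words:n, 1L)
  start <- if (n == len) 1L else sample(seq_len(n - len + 1L), 1L)
  tokens[start:(start + len - 1L)]
}
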