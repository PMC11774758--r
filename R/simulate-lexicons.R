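# Pronounceable nonsense words: alternating consonant-vowel syllables.
# Deterministic for a fixed seed; guaranteed unique.
make_nonsense_words <- function(n, seed = NULL, n_syllables = 3) {
  if (!is.null(seed)) set.seed(seed)
  consonants <- strsplit("bcdfghjklmnprstvwz", "")[[1]]
  vowels <- strsplit("aeiou", "")[[1]]
  out <- character(0)
  while (length(out) < n) {
    m <- n - length(out)
    syl <- replicate(n_syllables, paste0(sample(consonants, m, TRUE),
                                         sample(vowels, m, TRUE)))
    w <- if (is.matrix(syl)) apply(syl, 1, paste0, collapse = "") else
      paste0(syl, collapse = "")
    out <- unique(c(out, w))
  }
  out[seq_len(n)]
}

#' Generate fixture lexicons with known composition
#'
#' Builds a synthetic valence lexicon, emotion lexicon and opinion word lists
#' from pronounceable nonsense words, for testing the scoring pipeline
#' without any external lexicon file. Valences are drawn from a mixture so
#' that about 15\% of words fall in the positive set (valence >= 0.75) and
#' about 10\% in the negative set (valence <= 0.25) — positive-heavy, as
#' webpage text tends to be. Emotion associations are sparse (about 3\% of
#' words per emotion, association 1). The opinion lists are subsets of the
#' thresholded valence sets.
#'
#' @param n_words Number of words in the valence lexicon.
#' @param seed Integer seed; fixed seed gives byte-identical tables.
#' @param p_pos,p_neg Expected proportions of positive/negative words.
#' @return List with \code{valence} (data frame word/valence),
#'   \code{emotion} (data frame word/emotion/association), \code{opinion_pos},
#'   \code{opinion_neg} (character vectors).
#' @export
make_fixture_lexicons <- function(n_words = 1000, seed = 1,
                                  p_pos = 0.15, p_neg = 0.10) {
  set.seed(seed)
  words <- make_nonsense_words(n_words)
  cls <- sample(c("pos", "neg", "mid"), n_words, replace = TRUE,
                prob = c(p_pos, p_neg, 1 - p_pos - p_neg))
  valence <- numeric(n_words)
  valence[cls == "pos"] <- stats::runif(sum(cls == "pos"), 0.75, 1)
  valence[cls == "neg"] <- stats::runif(sum(cls == "neg"), 0, 0.25)
  valence[cls == "mid"] <- stats::runif(sum(cls == "mid"), 0.26, 0.74)
  valence_tab <- data.frame(word = words, valence = round(valence, 3),
                            stringsAsFactors = FALSE)
  # keep rounded values on the correct side of the thresholds
  valence_tab$valence[cls == "pos"] <- pmax(valence_tab$valence[cls == "pos"], 0.75)
  valence_tab$valence[cls == "neg"] <- pmin(valence_tab$valence[cls == "neg"], 0.25)

  emotion_tab <- do.call(rbind, lapply(EMOTIONS, function(e) {
    hit <- sample(words, max(1, round(0.03 * n_words)))
    data.frame(word = hit, emotion = e, association = 1,
               stringsAsFactors = FALSE)
  }))

  pos_set <- valence_tab$word[valence_tab$valence >= 0.75]
  neg_set <- valence_tab$word[valence_tab$valence <= 0.25]
  list(
    valence = valence_tab,
    emotion = emotion_tab,
    opinion_pos = sample(pos_set, ceiling(0.8 * length(pos_set))),
    opinion_neg = sample(neg_set, ceiling(0.8 * length(neg_set)))
  )
}

#' Generate a synthetic webpage with controlled affect composition
#'
#' Draws page tokens i.i.d.: a negative-set word with probability
#' \code{target_neg}, a positive-set word with probability \code{target_pos},
#' and a neutral filler word otherwise, then wraps them in a multi-paragraph
#' HTML document with decoy non-paragraph elements (headings, navigation,
#' script) that paragraph extraction must ignore. The realized (not target)
#' token proportions are returned so round-trip tests can compare exactly.
#'
#' @param target_neg,target_pos Target proportions (sum <= 1).
#' @param n_words Number of tokens on the page.
#' @param lexicons Fixture lexicons from [make_fixture_lexicons()] (or any
#'   list with a \code{valence} table).
#' @param seed Optional integer seed.
#' @return List with \code{html} (document text), \code{tokens} (the drawn
#'   tokens), \code{true_pos}, \code{true_neg} (realized proportions).
#' @export
make_webpage <- function(target_neg, target_pos, n_words, lexicons,
                         seed = NULL) {
  stopifnot(target_neg >= 0, target_pos >= 0, target_neg + target_pos <= 1,
            n_words >= 1)
  if (!is.null(seed)) set.seed(seed)
  vt <- lexicons$valence
  pos_set <- vt$word[vt$valence >= 0.75]
  neg_set <- vt$word[vt$valence <= 0.25]
  mid_set <- vt$word[vt$valence > 0.25 & vt$valence < 0.75]
  cls <- sample(c("neg", "pos", "mid"), n_words, replace = TRUE,
                prob = c(target_neg, target_pos, 1 - target_neg - target_pos))
  tokens <- character(n_words)
  tokens[cls == "neg"] <- sample(neg_set, sum(cls == "neg"), replace = TRUE)
  tokens[cls == "pos"] <- sample(pos_set, sum(cls == "pos"), replace = TRUE)
  tokens[cls == "mid"] <- sample(mid_set, sum(cls == "mid"), replace = TRUE)

  n_para <- max(1L, min(4L, n_words %/% 50L))
  cuts <- sort(c(0, n_words,
                 if (n_para > 1) sample(seq_len(n_words - 1), n_para - 1)))
  paras <- vapply(seq_len(n_para), function(i) {
    paste0("<p>", paste(tokens[(cuts[i] + 1):cuts[i + 1]], collapse = " "),
           "</p>")
  }, character(1))
  html <- paste0(
    "<html><head><title>decoy title words</title>",
    "<script>var decoy = 'ignore me';</script></head><body>",
    "<h1>Decoy Heading</h1><div class='nav'>decoy navigation text</div>",
    paste(paras, collapse = "\n"),
    "<div>trailing decoy footer</div></body></html>"
  )
  list(html = html, tokens = tokens,
       true_pos = sum(tokens %in% pos_set) / n_words,
       true_neg = sum(tokens %in% neg_set) / n_words)
}
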