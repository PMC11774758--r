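test_that("valence lexicon thresholds are inclusive and sets disjoint", {
  lex <- tiny_valence_lexicon()
  expect_setequal(lex$pos_terms, "delicious")
  expect_setequal(lex$neg_terms, "danger")

  at_bound <- load_valence_lexicon(data.frame(word = c("edge", "low"),
                                              valence = c(0.75, 0.25)))
  expect_true("edge" %in% at_bound$pos_terms)
  expect_true("low" %in% at_bound$neg_terms)
  expect_length(intersect(at_bound$pos_terms, at_bound$neg_terms), 0)

  expect_warning(load_valence_lexicon(data.frame(word = c("a", "a"),
                                                 valence = c(0.1, 0.9))),
                 "duplicate")
  expect_error(load_valence_lexicon(data.frame(word = "a", valence = 1.2)),
               "\\[0, 1\\]")
})

test_that("score_valence counts occurrences over all tokens", {
  lex <- tiny_valence_lexicon()
  expect_equal(score_valence(c("danger", "delicious", "table", "the"), lex),
               c(pos = 0.25, neg = 0.25))
  expect_equal(score_valence(c("out", "of", "lexicon"), lex),
               c(pos = 0, neg = 0))
  expect_equal(score_valence(c("danger", "danger"), lex), c(pos = 0, neg = 1))
  expect_error(score_valence(character(0), lex), "empty")
})

test_that("emotion scoring is per-emotion with multi-membership", {
  elex <- load_emotion_lexicon(data.frame(
    word = c("dread", "dread", "cheer"),
    emotion = c("fear", "sadness", "joy"),
    association = c(1, 0.8, 1)
  ))
  s <- score_emotions(c("dread", "cheer", "table", "the"), elex)
  expect_equal(unname(s[c("fear", "sadness", "joy")]), c(0.25, 0.25, 0.25))
  expect_equal(sum(s[c("anger", "anticipation", "trust", "surprise",
                       "disgust")]), 0)
  # below-threshold association does not count
  weak <- load_emotion_lexicon(data.frame(word = "meh", emotion = "joy",
                                          association = 0.5))
  expect_equal(unname(score_emotions(c("meh", "x"), weak)["joy"]), 0)
  expect_error(load_emotion_lexicon(data.frame(word = "a", emotion = "bliss",
                                               association = 1)),
               "unknown emotion")
})

test_that("opinion scoring is unweighted list membership", {
  ol <- load_opinion_lexicon(c("good"), c("bad"))
  expect_equal(score_opinion(c("good", "x", "y", "z", "w"), ol),
               c(pos = 0.2, neg = 0))
  expect_warning(both <- load_opinion_lexicon(c("odd"), c("odd")), "both")
  expect_equal(score_opinion(c("odd", "x"), both), c(pos = 0.5, neg = 0.5))
})

test_that("all three scorers agree exactly with the brute-force oracle", {
  lex <- make_fixture_lexicons(200, seed = 9)
  vlex <- load_valence_lexicon(lex$valence)
  elex <- load_emotion_lexicon(lex$emotion)
  olex <- load_opinion_lexicon(lex$opinion_pos, lex$opinion_neg)
  for (tokens in random_token_lists(200, lex, seed = 10)) {
    expect_identical(
      unname(score_valence(tokens, vlex)),
      unname(brute_force_proportions(tokens, list(p = vlex$pos_terms,
                                                  n = vlex$neg_terms))))
    expect_identical(
      unname(score_emotions(tokens, elex)),
      unname(brute_force_proportions(tokens, elex$terms)))
    expect_identical(
      unname(score_opinion(tokens, olex)),
      unname(brute_force_proportions(tokens, list(p = olex$pos_terms,
                                                  n = olex$neg_terms))))
  }
})

test_that("proportions are invariant to duplication, monotone in negative tokens", {
  lex <- make_fixture_lexicons(200, seed = 12)
  vlex <- load_valence_lexicon(lex$valence)
  for (tokens in random_token_lists(30, lex, seed = 13)) {
    s1 <- score_valence(tokens, vlex)
    expect_equal(score_valence(rep(tokens, 2), vlex), s1)
    appended <- score_valence(c(tokens, vlex$neg_terms[1]), vlex)
    expect_gt(appended["neg"], s1["neg"])
    expect_lte(appended["pos"], s1["pos"])
  }
})

test_that("participant aggregation weights days equally, not pages", {
  scores <- data.frame(
    participant = "p1",
    day = c(1, rep(2, 9)),
    neg = c(0.1, rep(0.3, 9)),
    pos = 0
  )
  prof <- aggregate_participant(scores)
  expect_equal(prof$overall$neg, 0.2)          # (0.1 + 0.3) / 2, day weights
  expect_false(isTRUE(all.equal(prof$overall$neg, mean(scores$neg))))

  # equal pages per day: daily-mean-of-means equals the pooled page mean
  bal <- data.frame(participant = "p1", day = rep(1:3, each = 4),
                    neg = runif(12), pos = runif(12))
  prof_bal <- aggregate_participant(bal)
  expect_equal(prof_bal$overall$neg, mean(bal$neg))
  # day means: (0.02 + 0.04)/2 = 0.03
  two <- data.frame(participant = "p1", day = 1:2, neg = c(0.02, 0.04), pos = 0)
  expect_equal(aggregate_participant(two)$overall$neg, 0.03)
})

test_that("stimulus classification follows the z-score rules and partitions", {
  ref <- list(neg_mean = 0.03, neg_sd = 0.01, pos_mean = 0.15, pos_sd = 0.02)
  zneg <- function(zv) 0.03 + zv * 0.01
  zpos <- function(zv) 0.15 + zv * 0.02
  expect_equal(classify_stimulus(0.15, zneg(3.0), ref, "extreme_negative"),
               "negative")
  expect_equal(classify_stimulus(0.15, zneg(0.5), ref, "extreme_negative"),
               "neutral")
  expect_equal(classify_stimulus(0.15, zneg(1.8), ref, "extreme_negative"),
               "unclassified")
  expect_equal(classify_stimulus(zpos(3), zneg(3), ref, "extreme_both"),
               "unclassified")
  expect_equal(classify_stimulus(zpos(3), zneg(0), ref, "extreme_both"),
               "positive")
  expect_equal(classify_stimulus(zpos(0), zneg(3), ref, "extreme_both"),
               "negative")
  expect_equal(classify_stimulus(zpos(0.2), zneg(-0.4), ref, "extreme_both"),
               "neutral")
  expect_error(classify_stimulus(0.1, 0.1, list(neg_mean = 0, neg_sd = 0),
                                 "extreme_negative"), "positive")
  # every grid point maps to exactly one category under either rule
  for (rule in c("extreme_negative", "extreme_both")) {
    for (zp in c(-3, -1.5, 0, 1.5, 3)) {
      for (zn in c(-3, -1.5, 0, 1.5, 3)) {
        out <- classify_stimulus(zpos(zp), zneg(zn), ref, rule)
        expect_length(out, 1)
        expect_true(out %in% c("negative", "neutral", "positive",
                               "unclassified"))
      }
    }
  }
})

test_that("random segments are contiguous, bounded, and seed-deterministic", {
  tokens <- sprintf("w%03d", 1:200)
  expect_identical(sample_segment(tokens, min_words = 200), tokens)
  long <- sprintf("w%04d", 1:1000)
  s1 <- sample_segment(long, min_words = 200, seed = 3)
  s2 <- sample_segment(long, min_words = 200, seed = 3)
  expect_identical(s1, s2)
  expect_gte(length(s1), 200)
  # contiguity: the segment appears verbatim in the page
  start <- match(s1[1], long)
  expect_identical(long[start:(start + length(s1) - 1)], s1)
  expect_error(sample_segment(sprintf("w%d", 1:50), min_words = 200), "fewer")
})

test_that("segment scores track whole-page scores on well-mixed pages", {
  lex <- make_fixture_lexicons(400, seed = 21)
  vlex <- load_valence_lexicon(lex$valence)
  set.seed(22)
  whole <- segment <- matrix(NA_real_, 60, 2)
  for (i in 1:60) {
    pg <- make_webpage(runif(1, 0.01, 0.1), runif(1, 0.05, 0.25), 1000, lex)
    seg <- sample_segment(pg$tokens, min_words = 200)
    whole[i, ] <- score_valence(pg$tokens, vlex)
    segment[i, ] <- score_valence(seg, vlex)
  }
  icc_neg <- icc(cbind(whole[, 2], segment[, 2]))
  icc_pos <- icc(cbind(whole[, 1], segment[, 1]))
  expect_gt(icc_neg$icc, 0.8)
  expect_gt(icc_pos$icc, 0.8)
})
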