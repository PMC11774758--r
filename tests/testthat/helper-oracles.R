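# Independent brute-force scoring oracle: walks the token list one occurrence
# at a time and compares each token against the term sets by linear search.
# Deliberately naive; kept independent of the package's scoring code path.
brute_force_proportions <- function(tokens, term_sets) {
  counts <- stats::setNames(numeric(length(term_sets)), names(term_sets))
  for (tok in tokens) {
    for (set_name in names(term_sets)) {
      hit <- FALSE
      for (w in term_sets[[set_name]]) {
        if (identical(tok, w)) { hit <- TRUE; break }
      }
      if (hit) counts[[set_name]] <- counts[[set_name]] + 1
    }
  }
  counts / length(tokens)
}

# Hand-built four-word valence fixture: danger (neg), delicious (pos),
# table/the neutral or out of lexicon.
tiny_valence_lexicon <- function() {
  load_valence_lexicon(data.frame(
    word = c("danger", "delicious", "table"),
    valence = c(0.10, 0.90, 0.50)
  ))
}

# Random token lists over a small synthetic vocabulary, for oracle-equivalence
# property tests.
random_token_lists <- function(n_lists, lexicons, seed) {
  set.seed(seed)
  vocab <- c(lexicons$valence$word, "zzfiller", "qqfiller", "123")
  lapply(seq_len(n_lists), function(i) {
    sample(vocab, sample(3:40, 1), replace = TRUE)
  })
}
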