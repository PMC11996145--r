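# Shared fixtures, built in code at test time.

.fixture_env <- new.env(parent = emptyenv())

# The seeded study-scale corpus: 102 reports, default generator settings
# (84 malignant / 10 other organ / 2 benign / 5 cytopathology / 1 outside
# review; 30% padded past the token budget). Memoised across test files.
study_corpus <- function() {
  if (is.null(.fixture_env$corpus)) {
    .fixture_env$corpus <- generate_corpus(102, seed = 42)
  }
  .fixture_env$corpus
}

study_included <- function() {
  if (is.null(.fixture_env$included)) {
    .fixture_env$included <- filter_corpus(study_corpus())$included
  }
  .fixture_env$included
}

# random word-soup text of n_words tokens drawn from a small vocabulary
random_text <- function(n_words, vocab = c(
    "thyroid", "lobe", "tumor", "margin", "section", "cm", "cassette",
    "papillary", "node", "level", "capsule", "benign", "cells", "focus",
    "right", "left", "present", "absent", "invasion", "stage")) {
  paste(sample(vocab, n_words, replace = TRUE), collapse = " ")
}

# one-row question tibble for direct extractor/normalizer calls
question_row <- function(qid) {
  qs <- load_questions()
  qs[qs$question_id == qid, ]
}
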