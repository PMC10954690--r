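# Small in-code fixtures shared across test files.

# lexicon over explicit vectors, uniform probabilities unless given
make_lexicon <- function(vectors, p = NULL, sif_a = 1e-3) {
  if (is.null(p)) {
    p <- setNames(rep(1 / nrow(vectors), nrow(vectors)), rownames(vectors))
  }
  embedding_lexicon(vectors, p, sif_a = sif_a)
}

# orthonormal one-word-per-dimension lexicon
basis_lexicon <- function(words) {
  d <- length(words)
  V <- diag(d)
  rownames(V) <- words
  make_lexicon(V)
}

# a transcript with one sentence per element of `sentences`
make_transcript <- function(sentences, ...) {
  tokenize(paste0(paste(sentences, collapse = ". "), "."), ...)
}

# small fast generator settings for tests that need a full cohort
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_participants = 4, n_excerpts = 2, words_per_excerpt = c(60, 10),
         n_topics = 4, vocab_per_topic = 12, embedding_dim = 8),
    list(...))
  do.call(generator_config, args)
}

random_tokens <- function(n, alphabet = letters[1:6]) {
  sample(alphabet, n, replace = TRUE)
}
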