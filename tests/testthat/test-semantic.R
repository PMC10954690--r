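test_that("word2vec text files load with validation", {
  dir <- withr::local_tempdir()
  emb <- file.path(dir, "emb.txt")
  writeLines(c("5 2", "cat 1 0", "dog 0.9 0.1", "sun 0 1", "moon 0.1 0.9",
               "sea 0.7 0.7"), emb)
  fr <- file.path(dir, "freq.csv")
  write.csv(data.frame(word = c("cat", "dog", "sun", "moon"),
                       count = c(40, 30, 20, 10)), fr, row.names = FALSE)
  lex <- suppressMessages(load_embeddings(emb, fr))
  expect_equal(nrow(lex$vectors), 5)
  expect_equal(lex$dim, 2)
  # "sea" is missing from the frequency table: min_prob policy
  expect_equal(lex$p[["sea"]], min(c(40, 30, 20, 10) / 100))
  lex2 <- suppressMessages(load_embeddings(emb, fr, oov_policy = "skip"))
  expect_false("sea" %in% rownames(lex2$vectors))
  # inconsistent dimensions are a format error
  writeLines(c("cat 1 0", "dog 0.9 0.1 0.3"), emb)
  expect_error(load_embeddings(emb, fr), "dimension")
  writeLines(character(0), emb)
  expect_error(load_embeddings(emb, fr), "empty")
})

test_that("SIF embedding matches its closed form", {
  V <- rbind(u = c(1, 0), v = c(0, 1))
  lex <- make_lexicon(V, p = c(u = 0.5, v = 0.5), sif_a = 1e-3)
  # single word: proportional to its vector
  e1 <- sif_embed("u", lex)
  expect_equal(cosine(e1, c(1, 0)), 1)
  # equal-probability pair: v = (w/2) * (1,1) with w = a/(a+p)
  e2 <- sif_embed(c("u", "v"), lex)
  w <- 1e-3 / (1e-3 + 0.5)
  expect_equal(unname(e2), c(w / 2, w / 2), tolerance = 1e-12)
  # out-of-vocabulary only: missing, not an error
  expect_null(sif_embed(c("zzz"), lex))
  # opposite vectors cancel: zero vector, cosine with it is undefined
  V3 <- rbind(a = c(1, 0), b = c(-1, 0))
  lex3 <- make_lexicon(V3)
  e3 <- sif_embed(c("a", "b"), lex3)
  expect_equal(unname(e3), c(0, 0))
  expect_true(is.na(cosine(e3, c(1, 0))))
})

test_that("identical sentences give the identity coherence profile", {
  lex <- basis_lexicon(c("cat", "dog", "sun"))
  t <- make_transcript(rep("cat dog", 3))
  m <- semantic_measures(t, lex, "cat dog")
  expect_equal(m[["coherence"]], 1, tolerance = 1e-9)
  expect_equal(m[["on_topic"]], 1, tolerance = 1e-9)
  expect_equal(m[["repetition"]], 1, tolerance = 1e-9)
  expect_equal(m[["tangentiality"]], 0, tolerance = 1e-9)
  expect_equal(m[["n_sentences"]], 3)
  expect_equal(m[["n_words"]], 6)
  expect_equal(m[["words_per_sentence"]] * m[["n_sentences"]],
               m[["n_words"]])
})

test_that("orthogonal/parallel sentence pattern gives coherence 0, repetition 1", {
  lex <- basis_lexicon(c("cat", "sun", "pen"))
  # sentence embeddings (1,0,0), (0,1,0), (1,0,0)
  t <- make_transcript(c("cat", "sun", "cat"))
  m <- semantic_measures(t, lex, "cat")
  expect_equal(m[["coherence"]], 0, tolerance = 1e-12)
  expect_equal(m[["repetition"]], 1, tolerance = 1e-12)
})

test_that("tangentiality is the OLS slope of stimulus similarity over sentence index", {
  # construct sentences whose stimulus cosines are 0.9, 0.7, 0.5:
  # stimulus along e1, sentence i = cos_i * e1 + sqrt(1-cos_i^2) * e_i
  cosines <- c(0.9, 0.7, 0.5)
  V <- diag(4)
  rownames(V) <- c("stim", "alpha", "beta", "gamma")
  words <- c("alpha", "beta", "gamma")
  vecs <- t(vapply(seq_along(cosines), function(i) {
    cosines[i] * V[1, ] + sqrt(1 - cosines[i]^2) * V[i + 1, ]
  }, numeric(4)))
  rownames(vecs) <- words
  lex <- make_lexicon(rbind(stim = V[1, ], vecs))
  t <- make_transcript(c("alpha", "beta", "gamma"))
  m <- semantic_measures(t, lex, "stim")
  expect_equal(m[["tangentiality"]], -0.2, tolerance = 1e-9)
  expect_equal(m[["on_topic"]], 0.7, tolerance = 1e-9)
})

test_that("sentences that cannot be embedded are dropped and counted", {
  lex <- basis_lexicon(c("cat", "dog"))
  t <- make_transcript(c("cat", "zzz qqq", "dog"))
  m <- semantic_measures(t, lex, "cat")
  expect_equal(m[["n_dropped_sentences"]], 1)
  expect_equal(m[["n_sentences"]], 3)
  # adjacent pairs are taken over the retained sequence: cat ~ dog
  expect_equal(m[["coherence"]], 0)
  t2 <- make_transcript(c("zzz", "qqq"))
  m2 <- semantic_measures(t2, lex, "cat")
  expect_true(is.na(m2[["coherence"]]))
  expect_true(is.na(m2[["on_topic"]]))
  expect_equal(m2[["n_dropped_sentences"]], 2)
})

test_that("cosine outputs stay in [-1,1] and repetition dominates coherence", {
  set.seed(21)
  words <- sprintf("w%02d", 1:12)
  V <- matrix(rnorm(12 * 6), 12, 6, dimnames = list(words, NULL))
  lex <- make_lexicon(V)
  for (i in 1:30) {
    sents <- replicate(sample(2:6, 1),
                       paste(sample(words, sample(1:4, 1)), collapse = " "))
    t <- make_transcript(sents)
    m <- semantic_measures(t, lex, paste(words[1:3], collapse = " "))
    vals <- m[c("coherence", "on_topic", "repetition")]
    vals <- vals[!is.na(vals)]
    expect_true(all(vals >= -1 - 1e-12 & vals <= 1 + 1e-12))
    if (!is.na(m[["repetition"]]) && !is.na(m[["coherence"]])) {
      expect_gte(m[["repetition"]], m[["coherence"]] - 1e-12)
    }
  }
})

test_that("sentence order permutes repetition invariantly and reversal flips tangentiality", {
  lex <- basis_lexicon(sprintf("w%d", 1:8))
  sents <- c("w1 w2", "w3", "w4 w5", "w6", "w7 w8")
  t <- make_transcript(sents)
  stim <- "w1 w3 w4"
  m <- semantic_measures(t, lex, stim)
  set.seed(22)
  for (i in 1:5) {
    tp <- make_transcript(sample(sents))
    mp <- semantic_measures(tp, lex, stim)
    expect_equal(mp[["repetition"]], m[["repetition"]], tolerance = 1e-12)
  }
  tr <- make_transcript(rev(sents))
  mr <- semantic_measures(tr, lex, stim)
  expect_equal(mr[["tangentiality"]], -m[["tangentiality"]],
               tolerance = 1e-12)
})

test_that("common-component removal annihilates a shared direction", {
  set.seed(23)
  common <- c(1, 1, 0, 0) / sqrt(2)
  E <- matrix(rnorm(40, sd = 0.1), 10, 4) + matrix(common, 10, 4,
                                                   byrow = TRUE) * 5
  E2 <- remove_common_component(E)
  expect_lt(max(abs(E2 %*% common)), max(abs(E %*% common)) / 50)
  # rows that cannot be used pass through unchanged
  E[1, ] <- NA
  expect_true(all(is.na(remove_common_component(E)[1, ])))
})

test_that("an unembeddable stimulus is an error", {
  lex <- basis_lexicon(c("cat"))
  t <- make_transcript("cat")
  expect_error(semantic_measures(t, lex, "zzz qqq"), "stimulus")
})
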