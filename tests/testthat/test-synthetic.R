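test_that("generated topic clusters separate in embedding space", {
  cfg <- generator_config(n_topics = 2, vocab_per_topic = 15,
                          embedding_dim = 4, seed = 51)
  lx <- gen_lexicon(cfg)
  V <- lx$lexicon$vectors
  within <- between <- c()
  for (t in 1:2) {
    rows <- which(lx$word_topic == t)
    G <- V[rows, ] %*% t(V[rows, ])
    within <- c(within, G[upper.tri(G)])
  }
  between <- V[lx$word_topic == 1, ] %*% t(V[lx$word_topic == 2, ])
  expect_gt(mean(within), mean(between))
  expect_gt(mean(within) - mean(between), 0.3)
})

test_that("the lexicon is reproducible from its seed and validates dimensions", {
  cfg <- generator_config(seed = 52)
  l1 <- gen_lexicon(cfg)
  l2 <- gen_lexicon(cfg)
  expect_identical(l1$lexicon$vectors, l2$lexicon$vectors)
  expect_identical(l1$stimuli, l2$stimuli)
  expect_error(generator_config(embedding_dim = 1, n_topics = 3),
               "separated")
})

test_that("zero drift keeps every sentence on the stimulus topic", {
  cfg <- tiny_config(drift_base = 0, drift_slope = 0, seed = 53)
  lx <- gen_lexicon(cfg)
  stim_words <- lx$words[lx$word_topic == lx$stim_topic[1]]
  t <- gen_transcript(2, "1", lx, cfg, seed = 54)
  content <- t$tokens_flat[t$tokens_flat %in% lx$words]
  expect_true(all(content %in% stim_words))
})

test_that("positive drift lowers the on-topic score on average", {
  cfg0 <- tiny_config(drift_base = 0, drift_slope = 0, seed = 55)
  cfg1 <- tiny_config(drift_base = 0.6, drift_slope = 0, seed = 55)
  lx <- gen_lexicon(cfg0)
  on_topic <- function(cfg, seeds) {
    vapply(seeds, function(s) {
      t <- gen_transcript(0, "1", lx, cfg, seed = s)
      semantic_measures(t, lx$lexicon, lx$stimuli[["1"]])[["on_topic"]]
    }, numeric(1))
  }
  expect_gt(mean(on_topic(cfg0, 1:40)), mean(on_topic(cfg1, 1:40)))
})

test_that("zero repeat probability yields loop1 = 0 on every excerpt", {
  cfg <- tiny_config(repeat_base = 0, repeat_slope = 0, seed = 56)
  co <- gen_cohort(cfg)
  for (key in grep("/manual$", names(co$transcripts), value = TRUE)) {
    toks <- co$transcripts[[key]]$tokens_flat
    expect_equal(graph_measures(toks)[["loop1"]], 0)
  }
})

test_that("a zero-rate channel is the identity and deletion-only never grows", {
  cfg <- tiny_config(asr_error_rate = 0, punct_error_rate = 0, seed = 57)
  lx <- gen_lexicon(cfg)
  t <- gen_transcript(0, "1", lx, cfg, seed = 58)
  out <- corrupt_transcript(t, lx, cfg, seed = 59)
  expect_identical(out$transcript$tokens_flat, t$tokens_flat)
  expect_equal(unname(out$counts), c(0, 0, 0))
  expect_equal(quality_metrics(align(t, out$transcript))[["wer"]], 0)
  cfg_del <- tiny_config(asr_error_rate = 0.3, punct_error_rate = 0,
                         error_mix = c(0, 1, 0), seed = 57)
  for (s in 1:10) {
    outd <- corrupt_transcript(t, lx, cfg_del, seed = s)
    expect_lte(length(outd$transcript$tokens_flat), length(t$tokens_flat))
  }
})

test_that("cohorts have the full factorial layout and are seed-reproducible", {
  cfg <- tiny_config(n_participants = 3, seed = 60)
  co <- gen_cohort(cfg)
  expect_equal(nrow(co$manifest), 3 * 2 * 2)
  expect_length(co$transcripts, 12)
  expect_setequal(unique(co$manifest$version), c("manual", "automated"))
  expect_equal(nrow(co$ground_truth$theta), 3)
  expect_equal(nrow(co$ground_truth$errors), 6)
  co2 <- gen_cohort(cfg)
  expect_identical(co$outcomes, co2$outcomes)
  expect_identical(co$transcripts[["P0002/2/automated"]]$raw_text,
                   co2$transcripts[["P0002/2/automated"]]$raw_text)
})

test_that("outcomes respect their questionnaire ranges and track theta", {
  cfg <- generator_config(n_participants = 120, n_excerpts = 1,
                          words_per_excerpt = c(25, 3), n_topics = 2,
                          vocab_per_topic = 8, embedding_dim = 4,
                          seed = 61)
  co <- gen_cohort(cfg)
  expect_true(all(co$outcomes$spq >= 0 & co$outcomes$spq <= 74))
  expect_true(all(co$outcomes$pdi >= 0 & co$outcomes$pdi <= 21))
  rho <- cor(co$ground_truth$theta$theta, co$outcomes$spq,
             method = "spearman")
  expect_gt(rho, 0.4)
})

test_that("zero outcome loading breaks the trait-outcome association", {
  reps <- 30
  sig <- logical(reps)
  for (i in seq_len(reps)) {
    cfg <- generator_config(n_participants = 30, n_excerpts = 1,
                            words_per_excerpt = c(22, 2), n_topics = 2,
                            vocab_per_topic = 6, embedding_dim = 4,
                            spq_loading = 0, seed = 6100 + i)
    co <- gen_cohort(cfg)
    p <- suppressWarnings(
      cor.test(co$ground_truth$theta$theta, co$outcomes$spq,
               method = "spearman", exact = FALSE)$p.value)
    sig[i] <- !is.na(p) && p < 0.05
  }
  expect_lte(mean(sig), 0.2)
})

test_that("two-group cohorts carry separated groups", {
  cfg <- tiny_config(n_participants = 20, two_group = TRUE, seed = 62)
  co <- gen_cohort(cfg)
  expect_true("group" %in% names(co$outcomes))
  th <- merge(co$outcomes, co$ground_truth$theta)
  expect_gt(mean(th$theta[th$group == "high"]),
            mean(th$theta[th$group == "low"]))
})

test_that("presets fix the two channel regimes", {
  p1 <- cohort_preset("noisy_asr")
  expect_equal(p1$asr_error_rate, 0.21)
  expect_false(p1$two_group)
  p2 <- cohort_preset("clean_asr", n_participants = 10)
  expect_equal(p2$asr_error_rate, 0.08)
  expect_true(p2$two_group)
  expect_equal(p2$n_participants, 10L)
})
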