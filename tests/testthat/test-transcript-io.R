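test_that("tokenize splits sentences and counts tokens", {
  t <- tokenize("The cat sat. The cat slept.")
  expect_length(t$sentences, 2)
  expect_length(t$tokens_flat, 6)
  expect_identical(t$tokens_flat,
                   c("the", "cat", "sat", "the", "cat", "slept"))
  expect_identical(unlist(t$tokens, use.names = FALSE), t$tokens_flat)
})

test_that("filler words are removed from the filtered view only", {
  cfg <- filter_config(stop_words = character(0), fillers = c("um"))
  t <- tokenize("Um, the cat um sat", cfg)
  expect_identical(unlist(t$tokens_filtered, use.names = FALSE),
                   c("the", "cat", "sat"))
  expect_identical(t$tokens_flat, c("um", "the", "cat", "um", "sat"))
})

test_that("degenerate text raises an empty-transcript error", {
  expect_error(tokenize("???"), "empty transcript")
  expect_error(tokenize("   "), "non-empty")
  expect_error(tokenize("!!! ... ?!"), "empty transcript")
})

test_that("tokenization handles hyphens, contractions and case", {
  t <- tokenize("Don't re-enter the well-lit room!")
  expect_true("don't" %in% t$tokens_flat)
  expect_true(all(c("re", "enter", "well", "lit") %in% t$tokens_flat))
  expect_false(any(grepl("[A-Z]", t$tokens_flat)))
})

test_that("tokenize is idempotent on its own detokenized output", {
  set.seed(11)
  for (i in 1:10) {
    words <- sample(c(letters, "cat", "sat", "don't"), 30, replace = TRUE)
    raw <- paste0(paste(words[1:15], collapse = " "), ". ",
                  paste(words[16:30], collapse = " "), ".")
    t1 <- tokenize(raw)
    detok <- paste0(vapply(t1$tokens, paste, "", collapse = " "),
                    ".", collapse = " ")
    t2 <- tokenize(detok)
    expect_identical(t2$tokens_flat, t1$tokens_flat)
    expect_identical(lengths(t2$tokens), lengths(t1$tokens))
  }
})

test_that("filtering never grows the token stream and empty filters are identity", {
  set.seed(12)
  for (i in 1:10) {
    raw <- paste(sample(c("the", "a", "cat", "dog", "ran", "um"), 25,
                        replace = TRUE), collapse = " ")
    t <- tokenize(raw)
    expect_lte(length(unlist(t$tokens_filtered)), length(t$tokens_flat))
    t0 <- tokenize(raw, filter_config(stop_words = character(0),
                                      fillers = character(0)))
    expect_identical(unlist(t0$tokens_filtered, use.names = FALSE),
                     t0$tokens_flat)
  }
})

test_that("removing stop words twice equals removing once", {
  cfg <- filter_config(stop_words = c("the", "um"), fillers = c("um"))
  t <- tokenize("Um the cat um the dog.", cfg)
  once <- unlist(t$tokens_filtered, use.names = FALSE)
  again <- once[!once %in% c(cfg$stop_words, cfg$fillers)]
  expect_identical(again, once)
})

test_that("a synthetic cohort written to disk loads back identically", {
  dir <- withr::local_tempdir()
  co <- gen_cohort(tiny_config(seed = 301))
  write_cohort(co, dir)
  man <- suppressMessages(load_corpus(file.path(dir, "manifest.csv"),
                                      file.path(dir, "outcomes.csv")))
  expect_equal(nrow(man$transcripts), 4 * 2 * 2)
  expect_setequal(man$outcomes$participant_id,
                  co$outcomes$participant_id)
  trs <- read_transcripts(man)
  key <- "P0001/1/manual"
  expect_identical(trs[[key]]$tokens_flat,
                   co$transcripts[[key]]$tokens_flat)
  lex <- suppressMessages(load_embeddings(file.path(dir, "embeddings.txt"),
                                          file.path(dir, "word_freq.csv")))
  expect_equal(nrow(lex$vectors), nrow(co$lexicon$lexicon$vectors))
  expect_equal(lex$dim, co$lexicon$lexicon$dim)
  stim <- read_stimuli(file.path(dir, "stimuli.csv"))
  expect_identical(unname(stim), unname(co$lexicon$stimuli))
})

test_that("manifest validation names the offending rows", {
  dir <- withr::local_tempdir()
  man <- data.frame(participant_id = c("P1", "P1", "P2"),
                    excerpt_id = c("1", "1", "1"),
                    version = c("manual", "manual", "manual"),
                    path = "x.txt")
  write.csv(man, file.path(dir, "m.csv"), row.names = FALSE)
  out <- data.frame(participant_id = c("P1", "P2"), spq = 1, pdi = 1,
                    age = 30, gender = "female", education = 3,
                    device = "computer")
  write.csv(out, file.path(dir, "o.csv"), row.names = FALSE)
  expect_error(load_corpus(file.path(dir, "m.csv"), file.path(dir, "o.csv")),
               "P1/1/manual")
  man2 <- man[-2, ]
  man2$participant_id[2] <- "P3"
  write.csv(man2, file.path(dir, "m2.csv"), row.names = FALSE)
  expect_error(load_corpus(file.path(dir, "m2.csv"), file.path(dir, "o.csv")),
               "P3")
  man3 <- man[-2, ]
  man3$version[1] <- "robot"
  write.csv(man3, file.path(dir, "m3.csv"), row.names = FALSE)
  expect_error(load_corpus(file.path(dir, "m3.csv"), file.path(dir, "o.csv")),
               "robot")
})

test_that("feature tables round-trip through CSV", {
  dir <- withr::local_tempdir()
  tab <- data.frame(participant_id = rep(sprintf("P%d", 1:3), each = 2),
                    version = rep(c("manual", "automated"), 3),
                    nodes = rnorm(6), on_topic = runif(6))
  p <- file.path(dir, "features.csv")
  write_features(tab, p)
  back <- read_features(p)
  expect_equal(nrow(back), 6)
  expect_equal(back$nodes, tab$nodes)
  expect_identical(back$participant_id, tab$participant_id)
  expect_error(write_features(tab[0, ], p), "empty")
})
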