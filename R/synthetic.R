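# Function words woven into generated sentences. All are closed-class
# words the default tagger knows and the default stop-word list removes,
# so the semantic path sees content words only.
.function_words <- c("the", "a", "this", "that", "it", "he", "she", "they",
                     "i", "we", "his", "her", "their", "my", "is", "was",
                     "and", "but", "of", "in", "on", "with", "under",
                     "over", "there", "which", "what", "where", "when",
                     "how", "who", "very", "to", "more")

#' Synthetic cohort generator configuration
#'
#' Parameters of the synthetic speech study: a cohort of participants, each
#' with a latent disorganization trait theta, produces `n_excerpts`
#' one-minute picture-description excerpts; each excerpt exists as a clean
#' "manual" transcript and as an "automated" transcript pushed through a
#' parametric transcription-noise channel. Disorganization shows up in the
#' text as topic drift (off-stimulus sentences) and immediate word
#' repetition, both increasing linearly in theta; questionnaire outcomes
#' are linear in theta plus noise, rounded and clipped to their scales
#' (SPQ-like 0-74, PDI-like 0-21).
#'
#' @param n_participants number of participants.
#' @param n_excerpts speech excerpts per participant (default 8, one per
#'   picture prompt).
#' @param words_per_excerpt mean and sd of the per-excerpt word count
#'   (default c(100, 20), a typical one-minute description).
#' @param n_topics number of semantic topics; each excerpt prompt is
#'   assigned one topic.
#' @param vocab_per_topic content words per topic.
#' @param embedding_dim embedding dimension (must be >= `n_topics` so topic
#'   clusters can be mutually separated).
#' @param theta_mean,theta_sd latent trait distribution (standard normal by
#'   default).
#' @param drift_base,drift_slope probability that a sentence switches to a
#'   random other topic: `clamp(drift_base + drift_slope * theta, 0, 1)`.
#' @param repeat_base,repeat_slope per-word probability of an injected
#'   immediate repetition, same linear form.
#' @param spq_base,spq_loading,pdi_base,pdi_loading outcome model
#'   `round(clip(base + loading * (theta + noise)))`; positive loadings make
#'   disorganized speakers score higher.
#' @param outcome_noise_sd sd of the outcome noise, in latent-trait units.
#' @param asr_error_rate per-word corruption probability of the
#'   transcription channel.
#' @param error_mix simplex weights over substitution/deletion/insertion.
#' @param punct_error_rate probability of perturbing each sentence boundary
#'   (and of splitting a sentence), modelling unreliable automated
#'   punctuation.
#' @param two_group if `TRUE`, theta is drawn from a low/high two-component
#'   design (N(-1.2, 0.6) and N(+1.2, 0.6), equal halves) and the outcome
#'   table gains a `group` column — an extreme-groups screening design.
#' @param seed integer seed; the whole cohort is reproducible from
#'   (config, seed).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_participants = 50,
                             n_excerpts = 8,
                             words_per_excerpt = c(100, 20),
                             n_topics = 8,
                             vocab_per_topic = 40,
                             embedding_dim = 50,
                             theta_mean = 0, theta_sd = 1,
                             drift_base = 0.15, drift_slope = 0.15,
                             repeat_base = 0.02, repeat_slope = 0.02,
                             spq_base = 26, spq_loading = 6,
                             pdi_base = 7, pdi_loading = 2.5,
                             outcome_noise_sd = 1,
                             asr_error_rate = 0.1,
                             error_mix = c(substitution = 0.5,
                                           deletion = 0.25,
                                           insertion = 0.25),
                             punct_error_rate = 0.05,
                             two_group = FALSE,
                             seed = NULL) {
  stopifnot(n_participants >= 1, n_excerpts >= 1,
            length(words_per_excerpt) == 2, words_per_excerpt[1] > 0,
            n_topics >= 1, vocab_per_topic >= 2,
            theta_sd > 0, outcome_noise_sd >= 0,
            asr_error_rate >= 0, asr_error_rate <= 1,
            punct_error_rate >= 0, punct_error_rate <= 1,
            drift_base >= 0, drift_base <= 1,
            repeat_base >= 0, repeat_base <= 1,
            length(error_mix) == 3, all(error_mix >= 0), sum(error_mix) > 0)
  if (embedding_dim < n_topics) {
    stop("embedding_dim must be >= n_topics: topic clusters cannot be separated")
  }
  if (abs(sum(error_mix) - 1) > 1e-8) {
    stop("error_mix weights must sum to 1")
  }
  names(error_mix) <- c("substitution", "deletion", "insertion")
  structure(list(n_participants = as.integer(n_participants),
                 n_excerpts = as.integer(n_excerpts),
                 words_per_excerpt = as.numeric(words_per_excerpt),
                 n_topics = as.integer(n_topics),
                 vocab_per_topic = as.integer(vocab_per_topic),
                 embedding_dim = as.integer(embedding_dim),
                 theta_mean = theta_mean, theta_sd = theta_sd,
                 drift_base = drift_base, drift_slope = drift_slope,
                 repeat_base = repeat_base, repeat_slope = repeat_slope,
                 spq_base = spq_base, spq_loading = spq_loading,
                 pdi_base = pdi_base, pdi_loading = pdi_loading,
                 outcome_noise_sd = outcome_noise_sd,
                 asr_error_rate = asr_error_rate,
                 error_mix = error_mix,
                 punct_error_rate = punct_error_rate,
                 two_group = isTRUE(two_group),
                 seed = seed),
            class = "generator_config")
}

#' Generator presets for the two transcription-noise regimes
#'
#' `"noisy_asr"`: word corruption rate 0.21, single continuous cohort —
#' the regime of a consumer transcription service on heterogeneous home
#' recordings. `"clean_asr"`: corruption rate 0.08 and a two-group
#' (low/high trait) screening design — the regime of cleaner recordings
#' scored against an extreme-groups outcome.
#'
#' @param preset `"noisy_asr"` or `"clean_asr"`.
#' @param ... overrides passed to [generator_config()].
#' @return object of class `generator_config`.
#' @export
cohort_preset <- function(preset = c("noisy_asr", "clean_asr"), ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
                 noisy_asr = list(asr_error_rate = 0.21, two_group = FALSE),
                 clean_asr = list(asr_error_rate = 0.08, two_group = TRUE))
  override <- list(...)
  do.call(generator_config, utils::modifyList(args, override))
}

# ---- lexicon -------------------------------------------------------------

.gen_lexicon <- function(cfg) {
  d <- cfg$embedding_dim
  k <- cfg$n_topics
  # mutually orthonormal topic centres
  centres <- qr.Q(qr(matrix(stats::rnorm(d * k), d, k)))
  vpt <- cfg$vocab_per_topic
  V <- k * vpt
  vectors <- matrix(0, V, d)
  topic <- integer(V)
  words <- character(V)
  spread <- 0.5  # within-topic angular spread (unit-vector perturbation)
  for (t in seq_len(k)) {
    rows <- ((t - 1) * vpt + 1):(t * vpt)
    z <- matrix(stats::rnorm(vpt * d), vpt, d)
    z <- z / sqrt(rowSums(z^2))
    v <- matrix(centres[, t], vpt, d, byrow = TRUE) + spread * z
    vectors[rows, ] <- v / sqrt(rowSums(v^2))
    topic[rows] <- t
    words[rows] <- sprintf("topic%02dword%02d", t, seq_len(vpt))
  }
  rownames(vectors) <- words
  # Zipf-like probabilities over the content vocabulary
  rank <- sample.int(V)
  p <- (1 / rank) / sum(1 / rank)
  names(p) <- words
  lex <- embedding_lexicon(vectors, p)
  # one stimulus description per excerpt, drawn from its assigned topic
  stim_topic <- ((seq_len(cfg$n_excerpts) - 1) %% k) + 1
  stimuli <- vapply(stim_topic, function(t) {
    w <- words[topic == t]
    pw <- p[w] / sum(p[w])
    paste0(paste(sample(w, min(12, length(w)), replace = FALSE, prob = pw),
                 collapse = " "), ".")
  }, character(1))
  names(stimuli) <- as.character(seq_len(cfg$n_excerpts))
  list(lexicon = lex, stimuli = stimuli, word_topic = topic,
       words = words, p = p, stim_topic = stim_topic)
}

#' Generate the synthetic embedding lexicon and stimulus descriptions
#'
#' Builds `n_topics` clusters of unit word vectors around mutually
#' orthonormal topic centres (high within-topic, low between-topic cosine),
#' Zipf-like word probabilities, and one stimulus-description text per
#' excerpt drawn from that excerpt's assigned topic.
#'
#' @param cfg a [generator_config()]; `cfg$seed` fixes the lexicon.
#' @return list with elements `lexicon` (an [embedding_lexicon()]),
#'   `stimuli` (named character vector by excerpt id), `word_topic`,
#'   `words`, `p`, `stim_topic`.
#' @export
gen_lexicon <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, .gen_lexicon(cfg))
}

# ---- transcripts ---------------------------------------------------------

.gen_transcript <- function(theta, excerpt_id, lexobj, cfg,
                            participant_id = NA_character_) {
  drift <- clamp01(cfg$drift_base + cfg$drift_slope * theta)
  repeat_p <- clamp01(cfg$repeat_base + cfg$repeat_slope * theta)
  stim_topic <- lexobj$stim_topic[as.integer(excerpt_id)]
  n_target <- max(20, round(stats::rnorm(1, cfg$words_per_excerpt[1],
                                         cfg$words_per_excerpt[2])))
  sent_tokens <- list()
  total <- 0
  last_word <- ""
  while (total < n_target) {
    len <- 4 + stats::rpois(1, 5)
    top <- stim_topic
    if (cfg$n_topics > 1 && stats::runif(1) < drift) {
      top <- sample(setdiff(seq_len(cfg$n_topics), stim_topic), 1)
    }
    w <- lexobj$words[lexobj$word_topic == top]
    pw <- lexobj$p[w] / sum(lexobj$p[w])
    content <- sample(w, len, replace = TRUE, prob = pw)
    fw <- stats::runif(len) < 0.35
    ins <- character(len)
    if (any(fw)) ins[fw] <- sample(.function_words, sum(fw), replace = TRUE)
    toks <- as.vector(rbind(ins, content))
    toks <- toks[nzchar(toks)]
    # immediate repetition is a planted signal, never an accident: collapse
    # chance duplicates (within and across sentence boundaries) before the
    # repeat channel runs
    toks <- toks[c(TRUE, toks[-1] != toks[-length(toks)])]
    if (toks[1] == last_word && length(toks) > 1) toks <- toks[-1]
    last_word <- toks[length(toks)]
    if (repeat_p > 0) {
      toks <- rep(toks, times = 1 + stats::rbinom(length(toks), 1, repeat_p))
    }
    sent_tokens[[length(sent_tokens) + 1]] <- toks
    total <- total + length(toks)
  }
  .new_transcript(sent_tokens, participant_id, excerpt_id, "manual")
}

#' Generate one manual-version transcript
#'
#' Samples sentences from the excerpt's stimulus topic; each sentence
#' switches to a random other topic with the theta-dependent drift
#' probability, and immediate word repetitions are injected with the
#' theta-dependent repeat probability — the planted text-level signatures
#' of disorganization.
#'
#' @param theta latent disorganization trait.
#' @param excerpt_id excerpt (prompt) id, `1..n_excerpts`.
#' @param lexobj a [gen_lexicon()] result.
#' @param cfg a [generator_config()].
#' @param seed optional seed for this transcript alone.
#' @return a `transcript` (version `"manual"`).
#' @export
gen_transcript <- function(theta, excerpt_id, lexobj, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(seed, .gen_transcript(theta, excerpt_id, lexobj, cfg))
}

.corrupt_transcript <- function(t, lexobj, cfg) {
  vocab <- c(lexobj$words, .function_words)
  mix <- cfg$error_mix / sum(cfg$error_mix)
  rate <- cfg$asr_error_rate
  n_sub <- n_del <- n_ins <- 0L
  sent_toks <- t$tokens
  new_sents <- vector("list", length(sent_toks))
  for (s in seq_along(sent_toks)) {
    toks <- sent_toks[[s]]
    if (rate > 0 && length(toks) > 0) {
      hit <- stats::runif(length(toks)) < rate
      if (any(hit)) {
        act <- sample(c("substitution", "deletion", "insertion"),
                      sum(hit), replace = TRUE, prob = mix)
        out <- as.list(toks)
        hi <- which(hit)
        for (k in seq_along(hi)) {
          i <- hi[k]
          if (act[k] == "substitution") {
            repl <- sample(vocab, 1)
            while (repl == toks[i]) repl <- sample(vocab, 1)
            out[[i]] <- repl
            n_sub <- n_sub + 1L
          } else if (act[k] == "deletion") {
            out[[i]] <- character(0)
            n_del <- n_del + 1L
          } else {
            out[[i]] <- c(toks[i], sample(vocab, 1))
            n_ins <- n_ins + 1L
          }
        }
        toks <- unlist(out, use.names = FALSE)
      }
    }
    new_sents[[s]] <- toks
  }
  new_sents <- new_sents[lengths(new_sents) > 0]
  if (length(new_sents) == 0) new_sents <- list(t$tokens_flat[1])
  # punctuation channel: merge some boundaries, split some sentences
  pe <- cfg$punct_error_rate
  if (pe > 0 && length(new_sents) > 1) {
    merge <- stats::runif(length(new_sents) - 1) < pe
    merged <- list(new_sents[[1]])
    for (s in seq_along(merge)) {
      if (merge[s]) {
        merged[[length(merged)]] <- c(merged[[length(merged)]],
                                      new_sents[[s + 1]])
      } else {
        merged[[length(merged) + 1]] <- new_sents[[s + 1]]
      }
    }
    new_sents <- merged
  }
  if (pe > 0) {
    split_out <- list()
    for (s in seq_along(new_sents)) {
      toks <- new_sents[[s]]
      if (length(toks) > 4 && stats::runif(1) < pe) {
        cut <- sample(2:(length(toks) - 2), 1)
        split_out <- c(split_out, list(toks[1:cut]),
                       list(toks[(cut + 1):length(toks)]))
      } else {
        split_out <- c(split_out, list(toks))
      }
    }
    new_sents <- split_out
  }
  list(transcript = .new_transcript(new_sents, t$participant_id,
                                    t$excerpt_id, "automated"),
       counts = c(substitutions = n_sub, deletions = n_del,
                  insertions = n_ins))
}

#' Corrupt a manual transcript through the transcription-noise channel
#'
#' Each word is independently corrupted with probability
#' `cfg$asr_error_rate`; the action (substitution by a random vocabulary
#' word, deletion, or insertion of a random word) is drawn from
#' `cfg$error_mix`. Each corrupted word contributes exactly one unit edit,
#' so the expected word error rate of long excerpts equals the nominal
#' rate. Sentence punctuation is perturbed separately (boundary merges and
#' splits at `cfg$punct_error_rate`), because sentence-level semantic
#' measures are sensitive to automated punctuation.
#'
#' @param t a manual `transcript`.
#' @param lexobj a [gen_lexicon()] result (supplies the vocabulary).
#' @param cfg a [generator_config()].
#' @param seed optional seed.
#' @return list with `transcript` (the automated version) and `counts`
#'   (named vector of injected substitutions/deletions/insertions).
#' @export
corrupt_transcript <- function(t, lexobj, cfg, seed = NULL) {
  stopifnot(inherits(t, "transcript"), inherits(cfg, "generator_config"))
  with_seed(seed, .corrupt_transcript(t, lexobj, cfg))
}

# ---- cohort --------------------------------------------------------------

#' Generate a full synthetic cohort
#'
#' Draws a latent trait per participant, generates the manual and automated
#' transcript versions of every excerpt, and builds the outcome table
#' (SPQ-like 0-74 and PDI-like 0-21 questionnaire totals linear in the
#' trait plus noise, with independently drawn demographics). Ground truth
#' (the latent traits and the injected channel error counts) is retained
#' for validation.
#'
#' @param cfg a [generator_config()].
#' @return object of class `speech_cohort`: list with `manifest`
#'   (data.frame), `transcripts` (named list, key
#'   `participant/excerpt/version`), `outcomes`, `ground_truth`
#'   (list `theta`, `errors`), `lexicon` (the [gen_lexicon()] result) and
#'   `config`.
#' @export
gen_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    lexobj <- .gen_lexicon(cfg)
    n <- cfg$n_participants
    pid <- sprintf("P%04d", seq_len(n))
    if (cfg$two_group) {
      half <- n %/% 2
      grp <- rep(c("low", "high"), c(n - half, half))
      theta <- cfg$theta_mean + ifelse(grp == "high", 1, -1) * 1.2 *
        cfg$theta_sd + stats::rnorm(n, 0, 0.6 * cfg$theta_sd)
    } else {
      grp <- NULL
      theta <- stats::rnorm(n, cfg$theta_mean, cfg$theta_sd)
    }
    spq <- pmin(74, pmax(0, round(cfg$spq_base + cfg$spq_loading *
      (theta + stats::rnorm(n, 0, cfg$outcome_noise_sd)))))
    pdi <- pmin(21, pmax(0, round(cfg$pdi_base + cfg$pdi_loading *
      (theta + stats::rnorm(n, 0, cfg$outcome_noise_sd)))))
    outcomes <- data.frame(
      participant_id = pid, spq = spq, pdi = pdi,
      age = sample(18:40, n, replace = TRUE),
      gender = sample(c("female", "male", "other"), n, replace = TRUE,
                      prob = c(0.49, 0.48, 0.03)),
      education = sample(1:5, n, replace = TRUE),
      device = sample(c("computer", "smartphone"), n, replace = TRUE,
                      prob = c(0.7, 0.3)),
      stringsAsFactors = FALSE)
    if (!is.null(grp)) outcomes$group <- grp
    n_tr <- n * cfg$n_excerpts * 2L
    transcripts <- vector("list", n_tr)
    keys <- character(n_tr)
    man_rows <- vector("list", n_tr)
    err_rows <- vector("list", n * cfg$n_excerpts)
    k <- 0L; e_k <- 0L
    for (i in seq_len(n)) {
      for (e in seq_len(cfg$n_excerpts)) {
        eid <- as.character(e)
        man <- .gen_transcript(theta[i], eid, lexobj, cfg,
                               participant_id = pid[i])
        aut <- .corrupt_transcript(man, lexobj, cfg)
        for (v in list(man, aut$transcript)) {
          k <- k + 1L
          key <- paste(pid[i], eid, v$version, sep = "/")
          keys[k] <- key
          transcripts[[k]] <- v
          man_rows[[k]] <- c(pid[i], eid, v$version, NA_character_)
        }
        e_k <- e_k + 1L
        err_rows[[e_k]] <- data.frame(participant_id = pid[i],
                                      excerpt_id = eid,
                                      t(aut$counts),
                                      stringsAsFactors = FALSE)
      }
    }
    names(transcripts) <- keys
    manifest <- as.data.frame(do.call(rbind, man_rows),
                              stringsAsFactors = FALSE)
    names(manifest) <- c("participant_id", "excerpt_id", "version", "path")
    structure(list(manifest = manifest, transcripts = transcripts,
                   outcomes = outcomes,
                   ground_truth = list(
                     theta = data.frame(participant_id = pid, theta = theta,
                                        stringsAsFactors = FALSE),
                     errors = do.call(rbind, err_rows)),
                   lexicon = lexobj, config = cfg),
              class = "speech_cohort")
  })
}

#' @export
print.speech_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<speech_cohort: %d participants x %d excerpts x 2 ",
                     "versions (%d transcripts)>\n"),
              cfg$n_participants, cfg$n_excerpts, length(x$transcripts)))
  cat(sprintf("  channel: error rate %.2f (sub/del/ins %.2f/%.2f/%.2f), punctuation %.2f\n",
              cfg$asr_error_rate, cfg$error_mix[1], cfg$error_mix[2],
              cfg$error_mix[3], cfg$punct_error_rate))
  if (cfg$two_group) cat("  design: two-group (low/high)\n")
  invisible(x)
}

#' Write a synthetic cohort to disk in the package's exchange formats
#'
#' Writes transcript text files, the corpus manifest and outcome CSVs, the
#' embedding lexicon in word2vec text format with its word-frequency CSV,
#' the stimulus descriptions with their manifest, and the ground-truth
#' CSVs. The result can be reloaded with [load_corpus()],
#' [load_embeddings()] and [read_stimuli()].
#'
#' @param cohort a [gen_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "speech_cohort"))
  dir.create(file.path(dir, "transcripts"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "stimuli"), showWarnings = FALSE)
  man <- cohort$manifest
  man$path <- sprintf("transcripts/%s_%s_%s.txt", man$participant_id,
                      man$excerpt_id, man$version)
  for (i in seq_len(nrow(man))) {
    key <- paste(man$participant_id[i], man$excerpt_id[i], man$version[i],
                 sep = "/")
    writeLines(cohort$transcripts[[key]]$raw_text, file.path(dir, man$path[i]))
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE)
  lex <- cohort$lexicon$lexicon
  con <- file(file.path(dir, "embeddings.txt"), "w")
  writeLines(sprintf("%d %d", nrow(lex$vectors), lex$dim), con)
  writeLines(paste(rownames(lex$vectors),
                   apply(lex$vectors, 1, function(v)
                     paste(formatC(v, format = "g", digits = 8),
                           collapse = " "))), con)
  close(con)
  utils::write.csv(data.frame(word = names(cohort$lexicon$p),
                              count = pmax(1, round(cohort$lexicon$p * 1e7))),
                   file.path(dir, "word_freq.csv"), row.names = FALSE)
  stim <- cohort$lexicon$stimuli
  stim_path <- sprintf("stimuli/stimulus_%s.txt", names(stim))
  for (i in seq_along(stim)) {
    writeLines(stim[i], file.path(dir, stim_path[i]))
  }
  utils::write.csv(data.frame(excerpt_id = names(stim), path = stim_path),
                   file.path(dir, "stimuli.csv"), row.names = FALSE)
  utils::write.csv(cohort$ground_truth$theta,
                   file.path(dir, "ground_truth_theta.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$ground_truth$errors,
                   file.path(dir, "ground_truth_errors.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a stimulus manifest
#'
#' @param path stimuli manifest CSV (`excerpt_id,path`); stimulus paths are
#'   resolved relative to the manifest's directory.
#' @return named character vector of stimulus texts, keyed by excerpt id.
#' @export
read_stimuli <- function(path) {
  if (!file.exists(path)) stop("stimuli manifest not found: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  stopifnot(all(c("excerpt_id", "path") %in% names(man)))
  base <- dirname(normalizePath(path))
  out <- vapply(man$path, function(p) {
    f <- if (file.exists(p)) p else file.path(base, p)
    paste(readLines(f, warn = FALSE), collapse = " ")
  }, character(1))
  names(out) <- man$excerpt_id
  out
}
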