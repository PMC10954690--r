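.marker_names <- function() {
  c("nodes", "edges", "repeated_edges", "parallel_edges", "loop1", "loop2",
    "loop3", "lcc", "lsc", "average_total_degree", "density", "diameter",
    "average_shortest_path", "clustering",
    "n_words", "n_sentences", "words_per_sentence", "coherence",
    "repetition", "tangentiality", "on_topic",
    "all_tags", "comparative_adjectives", "personal_pronouns",
    "possessive_pronouns", "wh_determiners", "wh_pronouns", "wh_adverbs")
}

#' Extract the full marker set from one transcript
#'
#' Computes the 14 window-averaged connectivity measures (on the unfiltered
#' token stream), the 7 semantic-coherence measures (on SIF sentence
#' embeddings of the filtered stream) and the 7 part-of-speech frequency
#' counts — 28 markers in total.
#'
#' @param t a `transcript`.
#' @param lex an [embedding_lexicon()].
#' @param stimulus stimulus-description text for the transcript's prompt.
#' @param graph_cfg a [graph_config()].
#' @param tagger tagger backend (see [default_tagger()]).
#' @param cfg [filter_config()] used to tokenize the stimulus.
#' @return named numeric vector of 28 markers.
#' @export
extract_markers <- function(t, lex, stimulus, graph_cfg = graph_config(),
                            tagger = default_tagger(),
                            cfg = filter_config()) {
  g <- windowed_measures(t, graph_cfg)
  sem <- semantic_measures(t, lex, stimulus, cfg)
  syn <- tag_frequencies(tag(t, tagger))
  out <- c(g, sem[c("n_words", "n_sentences", "words_per_sentence",
                    "coherence", "repetition", "tangentiality", "on_topic")],
           syn[c("all_tags", "comparative_adjectives", "personal_pronouns",
                 "possessive_pronouns", "wh_determiners", "wh_pronouns",
                 "wh_adverbs")])
  names(out) <- .marker_names()
  out
}

#' Extract excerpt-level markers for a whole corpus
#'
#' Runs [extract_markers()] over every transcript of a synthetic cohort or
#' of a loaded corpus manifest and returns the tidy excerpt-level table.
#' With `sif_pc_remove = TRUE` the corpus-wide common component of all
#' sentence embeddings is removed (from sentence and stimulus embeddings
#' alike) before the semantic measures are computed.
#'
#' @param x a `speech_cohort`, a `corpus_manifest`, or a list of
#'   `transcript` objects.
#' @param lex an [embedding_lexicon()]; defaults to the cohort's own
#'   lexicon when `x` is a `speech_cohort`.
#' @param stimuli named character vector of stimulus texts keyed by excerpt
#'   id; defaults to the cohort's own stimuli.
#' @param graph_cfg a [graph_config()].
#' @param tagger tagger backend.
#' @param cfg a [filter_config()] (used to tokenize manifest transcripts
#'   and stimuli).
#' @param sif_pc_remove remove the corpus-level common embedding component
#'   before computing semantic measures? Default `FALSE`: one-minute
#'   excerpts carry few sentences, so the common direction is estimated
#'   per-corpus only on request.
#' @return a `marker_table` data.frame: one row per
#'   (participant, excerpt, version) with 28 marker columns.
#' @export
extract_corpus <- function(x, lex = NULL, stimuli = NULL,
                           graph_cfg = graph_config(),
                           tagger = default_tagger(),
                           cfg = filter_config(),
                           sif_pc_remove = FALSE) {
  if (inherits(x, "speech_cohort")) {
    transcripts <- x$transcripts
    lex <- lex %||% x$lexicon$lexicon
    stimuli <- stimuli %||% x$lexicon$stimuli
  } else if (inherits(x, "corpus_manifest")) {
    transcripts <- read_transcripts(x, cfg)
  } else {
    transcripts <- x
  }
  if (is.null(lex) || is.null(stimuli)) {
    stop("lex and stimuli are required unless x is a speech_cohort")
  }
  n <- length(transcripts)
  if (n == 0) stop("no transcripts to extract")
  stim_emb <- lapply(stimuli, .stimulus_embedding, lex = lex, cfg = cfg)
  mnames <- .marker_names()
  M <- matrix(NA_real_, n, length(mnames), dimnames = list(NULL, mnames))
  meta <- data.frame(participant_id = character(n), excerpt_id = character(n),
                     version = character(n), stringsAsFactors = FALSE)
  embs <- vector("list", n)
  for (i in seq_len(n)) {
    t <- transcripts[[i]]
    meta$participant_id[i] <- t$participant_id
    meta$excerpt_id[i] <- t$excerpt_id
    meta$version[i] <- t$version
    M[i, 1:14] <- .windowed_measures_cpp(.token_ids(t$tokens_flat),
                                         graph_cfg$window_size,
                                         graph_cfg$window_step)
    tags <- tagger(t$tokens_flat)
    if (length(tags) != length(t$tokens_flat)) {
      stop("tagger contract violation on ", t$participant_id, "/",
           t$excerpt_id)
    }
    M[i, 22:28] <- c(length(tags), sum(tags == "JJR"), sum(tags == "PRP"),
                     sum(tags == "PRP$"), sum(tags == "WDT"),
                     sum(tags == "WP"), sum(tags == "WRB"))
    embs[[i]] <- .sentence_embedding_matrix(t, lex)
  }
  if (sif_pc_remove) {
    pooled <- do.call(rbind, embs)
    ok <- stats::complete.cases(pooled) & rowSums(abs(pooled)) > 0
    if (sum(ok) >= 2) {
      u <- svd(pooled[ok, , drop = FALSE], nu = 0, nv = 1)$v[, 1]
      strip <- function(E) E - (E %*% u) %*% t(u)
      embs <- lapply(embs, function(E) {
        okr <- stats::complete.cases(E)
        E[okr, ] <- strip(E[okr, , drop = FALSE])
        E
      })
      stim_emb <- lapply(stim_emb, function(v) drop(strip(matrix(v, 1))))
    }
  }
  for (i in seq_len(n)) {
    t <- transcripts[[i]]
    stim <- stim_emb[[as.character(t$excerpt_id)]]
    if (is.null(stim)) stop("no stimulus for excerpt_id ", t$excerpt_id)
    sem <- .semantic_from_embeddings(embs[[i]], stim,
                                     n_words = length(t$tokens_flat),
                                     n_sentences = length(t$sentences))
    M[i, 15:21] <- sem[c("n_words", "n_sentences", "words_per_sentence",
                         "coherence", "repetition", "tangentiality",
                         "on_topic")]
  }
  out <- cbind(meta, as.data.frame(M))
  class(out) <- c("marker_table", "data.frame")
  attr(out, "level") <- "excerpt"
  out
}

#' Average excerpt-level markers to participant level
#'
#' Takes, per (participant, version) and marker, the arithmetic mean over
#' that participant's available excerpts — the participant-level marker a
#' short speech battery reports. Excerpt-level missing values are excluded
#' pairwise; the number of excluded cells is reported in a message.
#'
#' @param features an excerpt-level `marker_table` from [extract_corpus()].
#' @return a participant-level `marker_table`: one row per
#'   (participant, version).
#' @export
aggregate_participants <- function(features) {
  stopifnot(is.data.frame(features),
            all(c("participant_id", "version") %in% names(features)))
  markers <- setdiff(names(features),
                     c("participant_id", "excerpt_id", "version"))
  key <- paste(features$participant_id, features$version, sep = "\r")
  M <- as.matrix(features[, markers, drop = FALSE])
  obs <- !is.na(M)
  M0 <- M
  M0[!obs] <- 0
  sums <- rowsum(M0, key)
  counts <- rowsum(obs + 0, key)
  means <- sums / counts
  means[counts == 0] <- NA_real_
  parts <- strsplit(rownames(means), "\r", fixed = TRUE)
  out <- cbind(data.frame(participant_id = vapply(parts, `[`, "", 1),
                          version = vapply(parts, `[`, "", 2),
                          stringsAsFactors = FALSE),
               as.data.frame(means))
  rownames(out) <- NULL
  n_missing <- sum(is.na(features[, markers]))
  if (n_missing > 0) {
    message(sprintf("aggregate_participants: %d missing excerpt-level values excluded pairwise",
                    n_missing))
  }
  class(out) <- c("marker_table", "data.frame")
  attr(out, "level") <- "participant"
  out
}
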