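#' Construct an embedding lexicon
#'
#' Pairs a word-vector table with word probabilities and the SIF (smooth
#' inverse frequency) smoothing weight `a`. Sentence embeddings downweight
#' frequent words by `a / (a + p(w))`.
#'
#' @param vectors numeric matrix, one row per word, rownames = words.
#' @param p named numeric vector of word probabilities in (0, 1]; names must
#'   cover the rownames of `vectors` (subject to `oov_policy`).
#' @param sif_a SIF smoothing weight (default 1e-3, the standard choice).
#' @param oov_policy what to do with a vocabulary word absent from the
#'   probability table: `"min_prob"` assigns the minimum observed
#'   probability, `"skip"` treats the word as out-of-vocabulary.
#' @return object of class `embedding_lexicon`.
#' @export
embedding_lexicon <- function(vectors, p, sif_a = 1e-3,
                              oov_policy = c("min_prob", "skip")) {
  oov_policy <- match.arg(oov_policy)
  stopifnot(is.matrix(vectors), is.numeric(vectors),
            !is.null(rownames(vectors)), is.numeric(p), !is.null(names(p)))
  if (nrow(vectors) == 0) stop("empty vocabulary")
  if (!(sif_a > 0)) stop("sif_a must be positive")
  if (any(p <= 0 | p > 1)) stop("word probabilities must lie in (0, 1]")
  words <- rownames(vectors)
  pv <- p[words]
  miss <- is.na(pv)
  if (any(miss)) {
    if (oov_policy == "min_prob") {
      pv[miss] <- min(p)
    } else {
      vectors <- vectors[!miss, , drop = FALSE]
      pv <- pv[!miss]
      words <- words[!miss]
      if (nrow(vectors) == 0) stop("empty vocabulary after dropping words without frequencies")
    }
  }
  names(pv) <- words
  structure(list(vectors = vectors, p = pv, sif_a = sif_a,
                 oov_policy = oov_policy, dim = ncol(vectors)),
            class = "embedding_lexicon")
}

#' @export
print.embedding_lexicon <- function(x, ...) {
  cat(sprintf("<embedding_lexicon: %d words, dim %d, a = %g>\n",
              nrow(x$vectors), x$dim, x$sif_a))
  invisible(x)
}

#' Load word embeddings and word frequencies
#'
#' Reads a word2vec text-format embedding file (optional first line
#' `"vocab_size dim"`, then rows `"word v1 ... vd"`) and a word-frequency
#' CSV (`word,count`), normalizes counts to probabilities, and returns an
#' [embedding_lexicon()].
#'
#' @param path embedding file path.
#' @param freq_path frequency CSV path.
#' @inheritParams embedding_lexicon
#' @return object of class `embedding_lexicon`.
#' @export
load_embeddings <- function(path, freq_path, sif_a = 1e-3,
                            oov_policy = c("min_prob", "skip")) {
  if (!file.exists(path)) stop("embedding file not found: ", path)
  if (!file.exists(freq_path)) stop("frequency file not found: ", freq_path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty vocabulary in embedding file")
  fields <- strsplit(trimws(lines), "[ \t]+")
  # optional "vocab dim" header: exactly two numeric fields
  f1 <- fields[[1]]
  if (length(f1) == 2 && !anyNA(suppressWarnings(as.numeric(f1)))) {
    fields <- fields[-1]
    if (length(fields) == 0) stop("empty vocabulary in embedding file")
  }
  lens <- lengths(fields)
  if (length(unique(lens)) != 1) {
    stop("embedding format error: rows have inconsistent dimension (",
         paste(unique(lens) - 1, collapse = ", "), ")")
  }
  d <- lens[1] - 1
  if (d < 1) stop("embedding format error: no vector components")
  words <- vapply(fields, `[`, character(1), 1)
  vals <- suppressWarnings(
    vapply(fields, function(f) as.numeric(f[-1]), numeric(d)))
  if (anyNA(vals)) stop("embedding format error: non-numeric vector entry")
  vectors <- t(matrix(vals, nrow = d))
  rownames(vectors) <- words
  freq <- utils::read.csv(freq_path, stringsAsFactors = FALSE)
  if (!all(c("word", "count") %in% names(freq))) {
    stop("frequency table must have columns word,count")
  }
  if (any(freq$count <= 0)) stop("frequency counts must be positive")
  p <- freq$count / sum(freq$count)
  names(p) <- freq$word
  lex <- embedding_lexicon(vectors, p, sif_a = sif_a, oov_policy = oov_policy)
  message(sprintf("loaded embeddings: %d words, dim %d", nrow(lex$vectors), d))
  lex
}

#' SIF sentence embedding
#'
#' Smooth-inverse-frequency embedding of one sentence:
#' `v = (1/k) * sum over in-vocabulary tokens of a/(a + p(w)) * vec(w)`,
#' where `k` is the number of in-vocabulary tokens. Tokens should already be
#' stop-word/filler filtered. Returns `NULL` when no token is in vocabulary
#' (a missing embedding, not an error). A sentence whose weighted vectors
#' cancel returns the zero vector; downstream cosines with it are missing.
#'
#' @param tokens character vector of filtered sentence tokens.
#' @param lex an [embedding_lexicon()].
#' @return numeric vector of length `lex$dim`, or `NULL` if no token is in
#'   vocabulary.
#' @export
sif_embed <- function(tokens, lex) {
  stopifnot(inherits(lex, "embedding_lexicon"))
  idx <- match(tokens, rownames(lex$vectors))
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) return(NULL)
  w <- lex$sif_a / (lex$sif_a + lex$p[idx])
  colSums(lex$vectors[idx, , drop = FALSE] * w) / length(idx)
}

#' Cosine similarity
#'
#' Missing (`NA`) when either vector is absent, contains `NA`, or has zero
#' norm: similarity with an undefined direction is never fabricated as 0.
#'
#' @param a,b numeric vectors of equal length (or `NULL`).
#' @return cosine in `[-1, 1]`, or `NA`.
#' @export
cosine <- function(a, b) {
  if (is.null(a) || is.null(b) || anyNA(a) || anyNA(b)) return(NA_real_)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

#' Remove the common component from sentence embeddings
#'
#' Subtracts the projection onto the first principal direction of a matrix
#' of sentence embeddings (rows = sentences). In the full SIF recipe this
#' removes the corpus-wide common discourse direction; it is applied
#' per-corpus and is off by default in this package because one-minute
#' excerpts contain too few sentences to estimate the direction stably
#' per excerpt.
#'
#' @param embeddings numeric matrix, one sentence embedding per row.
#' @return matrix of the same shape with the first principal component
#'   removed.
#' @export
remove_common_component <- function(embeddings) {
  stopifnot(is.matrix(embeddings))
  ok <- stats::complete.cases(embeddings) & rowSums(abs(embeddings)) > 0
  if (sum(ok) < 2) return(embeddings)
  sv <- svd(embeddings[ok, , drop = FALSE], nu = 0, nv = 1)
  u <- sv$v[, 1]
  embeddings[ok, ] <- embeddings[ok, , drop = FALSE] -
    (embeddings[ok, , drop = FALSE] %*% u) %*% t(u)
  embeddings
}

# Embed every sentence of a transcript; rows of NA mark missing embeddings.
.sentence_embedding_matrix <- function(t, lex) {
  m <- length(t$tokens_filtered)
  out <- matrix(NA_real_, nrow = m, ncol = lex$dim)
  for (i in seq_len(m)) {
    v <- sif_embed(t$tokens_filtered[[i]], lex)
    if (!is.null(v)) out[i, ] <- v
  }
  out
}

# Core semantic statistics from precomputed sentence embeddings.
# emb: m x d matrix (NA rows = missing); stim: stimulus embedding vector.
.semantic_from_embeddings <- function(emb, stim, n_words, n_sentences) {
  norms <- sqrt(rowSums(emb^2))
  valid <- !is.na(norms) & norms > 0
  ev <- emb[valid, , drop = FALSE] / norms[valid]
  m <- nrow(ev)
  coherence <- tangentiality <- on_topic <- repetition <- NA_real_
  if (m >= 1) {
    stim_cos <- drop(ev %*% (stim / sqrt(sum(stim^2))))
    on_topic <- mean(stim_cos)
    if (m >= 2) {
      coherence <- mean(rowSums(ev[-m, , drop = FALSE] *
                                  ev[-1, , drop = FALSE]))
      idx <- seq_len(m) - 1
      tangentiality <- stats::cov(idx, stim_cos) / stats::var(idx)
      G <- tcrossprod(ev)
      repetition <- max(G[upper.tri(G)])
    }
  }
  c(n_words = n_words,
    n_sentences = n_sentences,
    words_per_sentence = n_words / n_sentences,
    coherence = coherence,
    repetition = repetition,
    tangentiality = tangentiality,
    on_topic = on_topic,
    n_dropped_sentences = sum(!valid))
}

#' Semantic coherence statistics of a transcript
#'
#' Embeds each sentence with [sif_embed()] (on the filtered token view) and
#' computes: `coherence` — mean cosine similarity between adjacent valid
#' sentences; `on_topic` — mean cosine between each sentence and the
#' stimulus description; `tangentiality` — ordinary-least-squares slope of
#' the sentence-to-stimulus cosine over sentence index 0, 1, ...;
#' `repetition` — maximum cosine over all sentence pairs; plus the
#' verbosity counts `n_words` (unfiltered tokens), `n_sentences` and
#' `words_per_sentence`. Sentences with missing or zero-norm embeddings are
#' dropped and counted in `n_dropped_sentences`; the pairwise statistics
#' are missing when fewer than 2 valid sentences remain.
#'
#' @param t a `transcript`.
#' @param lex an [embedding_lexicon()].
#' @param stimulus stimulus-description text (string) for the excerpt's
#'   prompt; must embed to a non-missing, non-zero vector.
#' @param cfg [filter_config()] used to tokenize the stimulus text.
#' @return named numeric vector of the semantic measures.
#' @export
semantic_measures <- function(t, lex, stimulus, cfg = filter_config()) {
  stopifnot(inherits(t, "transcript"), inherits(lex, "embedding_lexicon"))
  stim <- .stimulus_embedding(stimulus, lex, cfg)
  emb <- .sentence_embedding_matrix(t, lex)
  .semantic_from_embeddings(emb, stim,
                            n_words = length(t$tokens_flat),
                            n_sentences = length(t$sentences))
}

.stimulus_embedding <- function(stimulus, lex, cfg) {
  toks <- if (is.character(stimulus) && length(stimulus) == 1) {
    st <- tokenize(stimulus, cfg)
    unlist(st$tokens_filtered, use.names = FALSE)
  } else {
    as.character(stimulus)
  }
  stim <- sif_embed(toks, lex)
  if (is.null(stim) || sum(abs(stim)) == 0) {
    stop("stimulus description does not embed to a usable vector")
  }
  stim
}
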