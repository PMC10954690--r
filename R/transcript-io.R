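#' Token filtering configuration
#'
#' Controls tokenization and the stop-word/filler filtering that feeds the
#' semantic-coherence path. Graph and part-of-speech features always use the
#' unfiltered token stream; only sentence embeddings consume the filtered
#' view, so the two views are kept side by side on every [tokenize()]d
#' transcript.
#'
#' @param stop_words character vector of stop words to remove from the
#'   filtered view. Defaults to a small packaged English list
#'   ([default_stop_words()]); pass your own list to override.
#' @param fillers character vector of spoken-disfluency fillers ("um", "uh",
#'   ...) removed alongside stop words. Removal is idempotent: words in both
#'   sets are removed once.
#' @param lowercase lowercase tokens? (default `TRUE`)
#' @param strip_punctuation strip non-word punctuation from tokens?
#'   Apostrophe contractions are kept as single tokens; hyphenated words are
#'   split at the hyphen.
#' @return an object of class `filter_config`.
#' @export
#' @examples
#' cfg <- filter_config(fillers = c("um", "uh"))
#' tokenize("Um, the cat um sat.", cfg)
filter_config <- function(stop_words = default_stop_words(),
                          fillers = c("um", "uh", "uhm", "er", "erm",
                                      "hmm", "mm", "mhm", "ah", "eh"),
                          lowercase = TRUE,
                          strip_punctuation = TRUE) {
  stopifnot(is.character(stop_words), is.character(fillers),
            is.logical(lowercase), is.logical(strip_punctuation))
  structure(list(stop_words = unique(tolower(stop_words)),
                 fillers = unique(tolower(fillers)),
                 lowercase = isTRUE(lowercase),
                 strip_punctuation = isTRUE(strip_punctuation)),
            class = "filter_config")
}

#' Packaged English stop-word list
#'
#' A compact list of English function words (articles, pronouns, auxiliaries,
#' prepositions, conjunctions and common adverbs). Used by default when
#' filtering tokens before sentence embedding; override through
#' [filter_config()] when a different list is required.
#'
#' @return character vector of lowercase stop words.
#' @export
default_stop_words <- function() {
  c("a", "an", "the", "this", "that", "these", "those", "some", "any",
    "each", "every", "no", "i", "me", "my", "mine", "myself", "you",
    "your", "yours", "yourself", "he", "him", "his", "himself", "she",
    "her", "hers", "herself", "it", "its", "itself", "we", "us", "our",
    "ours", "ourselves", "they", "them", "their", "theirs", "themselves",
    "what", "which", "who", "whom", "whose", "when", "where", "why",
    "how", "am", "is", "are", "was", "were", "be", "been", "being",
    "have", "has", "had", "having", "do", "does", "did", "doing",
    "will", "would", "shall", "should", "can", "could", "may", "might",
    "must", "of", "in", "on", "at", "by", "for", "with", "about",
    "against", "between", "into", "through", "during", "before",
    "after", "above", "below", "to", "from", "up", "down", "out",
    "off", "over", "under", "again", "further", "then", "once",
    "here", "there", "all", "both", "few", "more", "most", "other",
    "such", "only", "own", "same", "so", "than", "too", "very",
    "just", "and", "but", "or", "nor", "not", "as", "if", "because",
    "while", "until")
}

.norm_apostrophes <- function(x) {
  gsub("[’‘ʼ]", "'", x)
}

.sentence_split <- function(text) {
  s <- strsplit(trimws(text), "[.!?]+(\\s+|$)")[[1]]
  s <- trimws(s)
  s[nzchar(s)]
}

# vectorized over sentences: returns a list of token vectors
.word_tokens <- function(sentences, cfg) {
  s <- .norm_apostrophes(sentences)
  if (cfg$lowercase) s <- tolower(s)
  s <- gsub("-", " ", s, fixed = TRUE)
  if (cfg$strip_punctuation) s <- gsub("[^a-z0-9' ]", " ", s)
  lapply(strsplit(s, "[ \t\r\n]+"), function(tok) {
    tok <- sub("^'+", "", sub("'+$", "", tok))
    tok[nzchar(tok)]
  })
}

# the default filter_config, built once per session
.filter_default <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- filter_config()
    cached
  }
})

#' Tokenize and sentence-segment a raw transcript
#'
#' Splits the text into sentences at terminal punctuation (`.`, `!`, `?`
#' followed by whitespace or end of text — automated-transcript punctuation
#' is trusted as-is), lowercases and strips punctuation from tokens, and
#' keeps two token views: the unfiltered stream (used for word graphs and
#' part-of-speech features) and the stop-word/filler-filtered stream (used
#' for sentence embeddings).
#'
#' @param raw_text transcript text, non-empty.
#' @param cfg a [filter_config()].
#' @param participant_id,excerpt_id optional identifiers carried on the
#'   transcript.
#' @param version `"manual"` or `"automated"`.
#' @return an object of class `transcript` with fields `sentences`
#'   (character), `tokens` (list of per-sentence token vectors),
#'   `tokens_flat`, `tokens_filtered` (per-sentence filtered vectors), and
#'   the identifiers.
#' @export
#' @examples
#' t <- tokenize("The cat sat. The cat slept.")
#' length(t$sentences)  # 2
#' t$tokens_flat        # 6 tokens
tokenize <- function(raw_text, cfg = .filter_default(),
                     participant_id = NA_character_,
                     excerpt_id = NA_character_,
                     version = c("manual", "automated")) {
  if (!identical(version, "manual") && !identical(version, "automated")) {
    version <- match.arg(version)
  }
  stopifnot(inherits(cfg, "filter_config"))
  if (!is.character(raw_text) || length(raw_text) != 1 ||
      !nzchar(trimws(raw_text))) {
    stop("raw_text must be a non-empty string")
  }
  sentences <- .sentence_split(raw_text)
  toks <- .word_tokens(sentences, cfg)
  keep <- lengths(toks) > 0
  sentences <- sentences[keep]
  toks <- toks[keep]
  flat <- unlist(toks, use.names = FALSE)
  if (length(flat) == 0 || !any(grepl("[a-z]", flat))) {
    stop("empty transcript: no alphabetic tokens in raw_text")
  }
  drop <- c(cfg$stop_words, cfg$fillers)
  filtered <- lapply(toks, function(x) x[!x %in% drop])
  structure(list(participant_id = as.character(participant_id),
                 excerpt_id = as.character(excerpt_id),
                 version = version,
                 raw_text = raw_text,
                 sentences = sentences,
                 tokens = toks,
                 tokens_flat = flat,
                 tokens_filtered = filtered),
            class = "transcript")
}

# Fast internal constructor for transcripts whose sentence token lists are
# already clean (lowercase, punctuation-free): used by the synthetic
# generator, where raw_text is assembled from the same tokens, so
# tokenize(raw_text) would reproduce the object exactly.
.new_transcript <- function(sent_tokens, participant_id, excerpt_id,
                            version, cfg = .filter_default()) {
  sent_tokens <- sent_tokens[lengths(sent_tokens) > 0]
  sentences <- vapply(sent_tokens, paste, character(1), collapse = " ")
  drop <- c(cfg$stop_words, cfg$fillers)
  structure(list(participant_id = as.character(participant_id),
                 excerpt_id = as.character(excerpt_id),
                 version = version,
                 raw_text = paste0(paste(sentences, collapse = ". "), "."),
                 sentences = sentences,
                 tokens = sent_tokens,
                 tokens_flat = unlist(sent_tokens, use.names = FALSE),
                 tokens_filtered = lapply(sent_tokens,
                                          function(x) x[!x %in% drop])),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript %s/%s [%s]: %d sentences, %d tokens>\n",
              x$participant_id, x$excerpt_id, x$version,
              length(x$sentences), length(x$tokens_flat)))
  invisible(x)
}

#' Load a corpus manifest and its outcome table
#'
#' Reads the transcript manifest (`participant_id,excerpt_id,version,path`)
#' and the per-participant outcome table
#' (`participant_id,spq,pdi,age,gender,education,device`), validates
#' referential integrity, and returns them together. Paths in the manifest
#' are resolved relative to the manifest's own directory.
#'
#' @param manifest_path path to the manifest CSV.
#' @param outcomes_path path to the outcomes CSV.
#' @return an object of class `corpus_manifest`: a list with elements
#'   `transcripts` (data.frame) and `outcomes` (data.frame).
#' @export
load_corpus <- function(manifest_path, outcomes_path) {
  if (!file.exists(manifest_path)) stop("manifest file not found: ", manifest_path)
  if (!file.exists(outcomes_path)) stop("outcomes file not found: ", outcomes_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("participant_id", "excerpt_id", "version", "path")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  bad_version <- setdiff(unique(man$version), c("manual", "automated"))
  if (length(bad_version)) {
    stop("unknown transcript version(s): ", paste(bad_version, collapse = ", "))
  }
  key <- paste(man$participant_id, man$excerpt_id, man$version, sep = "/")
  dup <- key[duplicated(key)]
  if (length(dup)) {
    stop("duplicated manifest row(s): ", paste(unique(dup), collapse = ", "))
  }
  out <- utils::read.csv(outcomes_path, stringsAsFactors = FALSE)
  need_out <- c("participant_id", "spq", "pdi", "age", "gender",
                "education", "device")
  if (!all(need_out %in% names(out))) {
    stop("outcomes must have columns: ", paste(need_out, collapse = ", "))
  }
  out$participant_id <- as.character(out$participant_id)
  if (anyDuplicated(out$participant_id)) {
    stop("duplicated participant_id in outcomes table")
  }
  if (any(out$spq < 0, na.rm = TRUE) || any(out$pdi < 0, na.rm = TRUE)) {
    stop("spq and pdi must be non-negative")
  }
  orphan <- setdiff(unique(man$participant_id), out$participant_id)
  if (length(orphan)) {
    stop("participants missing from outcome table: ",
         paste(orphan, collapse = ", "))
  }
  message(sprintf("corpus manifest: %d manual, %d automated transcripts, %d participants",
                  sum(man$version == "manual"), sum(man$version == "automated"),
                  length(unique(man$participant_id))))
  structure(list(transcripts = man, outcomes = out,
                 dir = dirname(normalizePath(manifest_path))),
            class = "corpus_manifest")
}

#' @export
print.corpus_manifest <- function(x, ...) {
  cat(sprintf("<corpus_manifest: %d transcript rows, %d participants>\n",
              nrow(x$transcripts), nrow(x$outcomes)))
  invisible(x)
}

#' Read the transcripts listed in a corpus manifest
#'
#' @param manifest a [load_corpus()] result.
#' @param cfg a [filter_config()].
#' @return named list of `transcript` objects, keyed
#'   `participant/excerpt/version`.
#' @export
read_transcripts <- function(manifest, cfg = filter_config()) {
  stopifnot(inherits(manifest, "corpus_manifest"))
  man <- manifest$transcripts
  out <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(manifest$dir, man$path[i])
    if (!file.exists(p)) stop("transcript file not found: ", man$path[i])
    txt <- paste(readLines(p, warn = FALSE), collapse = " ")
    out[[i]] <- tokenize(txt, cfg,
                         participant_id = man$participant_id[i],
                         excerpt_id = man$excerpt_id[i],
                         version = man$version[i])
  }
  names(out) <- paste(man$participant_id, man$excerpt_id, man$version,
                      sep = "/")
  out
}

#' Write and read tidy feature tables
#'
#' `write_features()` writes a marker table as CSV with a stable column
#' order; `read_features()` reads it back losslessly.
#'
#' @param table non-empty data.frame of markers.
#' @param path output path.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   returns the data.frame.
#' @export
write_features <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0) stop("feature table is empty")
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("feature file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(participant_id = "character"))
}
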