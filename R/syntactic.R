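# Penn-tagset lexicon for the built-in rule tagger. Closed-class words are
# listed explicitly; open-class words fall back to suffix rules, then NN.
.penn_lexicon <- function() {
  lex <- c(
    # determiners
    the = "DT", a = "DT", an = "DT", this = "DT", that = "DT",
    these = "DT", those = "DT", each = "DT", every = "DT", some = "DT",
    any = "DT", no = "DT", another = "DT", all = "DT", both = "DT",
    # personal pronouns
    i = "PRP", me = "PRP", you = "PRP", he = "PRP", him = "PRP",
    she = "PRP", it = "PRP", we = "PRP", us = "PRP", they = "PRP",
    them = "PRP", myself = "PRP", yourself = "PRP", himself = "PRP",
    herself = "PRP", itself = "PRP", ourselves = "PRP",
    themselves = "PRP", hers = "PRP", theirs = "PRP", yours = "PRP",
    mine = "PRP",
    # possessive pronouns
    my = "PRP$", your = "PRP$", his = "PRP$", her = "PRP$", its = "PRP$",
    our = "PRP$", their = "PRP$",
    # wh words
    which = "WDT", whichever = "WDT", whatever = "WDT",
    who = "WP", whom = "WP", what = "WP", whoever = "WP",
    whose = "WP$",
    when = "WRB", where = "WRB", why = "WRB", how = "WRB",
    whenever = "WRB", wherever = "WRB",
    # verbs (be/have/do), modals, particles
    is = "VBZ", has = "VBZ", does = "VBZ",
    am = "VBP", are = "VBP", have = "VBP", do = "VBP",
    was = "VBD", were = "VBD", had = "VBD", did = "VBD",
    be = "VB", being = "VBG", been = "VBN",
    will = "MD", would = "MD", can = "MD", could = "MD", shall = "MD",
    should = "MD", may = "MD", might = "MD", must = "MD",
    to = "TO", there = "EX", not = "RB", very = "RB", quite = "RB",
    # prepositions and conjunctions
    of = "IN", "in" = "IN", on = "IN", at = "IN", by = "IN",
    with = "IN", from = "IN", under = "IN", over = "IN", about = "IN",
    into = "IN", through = "IN", after = "IN", before = "IN",
    between = "IN", during = "IN", against = "IN", as = "IN",
    "if" = "IN", because = "IN", "while" = "IN", like = "IN",
    and = "CC", or = "CC", but = "CC", nor = "CC", so = "CC", yet = "CC",
    # common comparatives (JJR is listed, not inferred from "-er")
    more = "JJR", less = "JJR", better = "JJR", worse = "JJR",
    bigger = "JJR", smaller = "JJR", larger = "JJR", older = "JJR",
    younger = "JJR", higher = "JJR", lower = "JJR", greater = "JJR",
    fewer = "JJR", closer = "JJR", darker = "JJR", brighter = "JJR",
    happier = "JJR", sadder = "JJR",
    # fillers
    um = "UH", uh = "UH", oh = "UH", ah = "UH", hmm = "UH"
  )
  lex
}

#' Build a dictionary tagger
#'
#' Returns a tagger backend (a function token vector -> tag vector of the
#' same length) that looks each lowercased token up in `dict` and falls
#' back to `default`. Deterministic and dependency-free; mainly useful for
#' testing and for corpora with a known closed vocabulary.
#'
#' @param dict named character vector mapping lowercase word -> Penn tag.
#' @param default tag for words not in `dict` (default `"NN"`).
#' @return a tagger function.
#' @export
dictionary_tagger <- function(dict, default = "NN") {
  stopifnot(is.character(dict), !is.null(names(dict)))
  force(default)
  function(tokens) {
    tags <- unname(dict[tolower(tokens)])
    tags[is.na(tags)] <- default
    tags
  }
}

#' Default part-of-speech tagger backend
#'
#' A deterministic Penn-tagset tagger combining a closed-class lexicon
#' (determiners, pronouns, wh-words, auxiliaries, modals, prepositions,
#' conjunctions, listed comparatives) with suffix rules for open-class
#' words (`-ing` -> VBG, `-ed` -> VBD, `-ly` -> RB, plural `-s` -> NNS,
#' digits -> CD) and an NN fallback. The tagger backend is pluggable
#' throughout the package: any function mapping a token vector to an
#' equal-length Penn tag vector can replace it.
#'
#' @return a tagger function.
#' @export
#' @examples
#' default_tagger()(c("the", "cat", "is", "under", "the", "table"))
default_tagger <- function() {
  lex <- .penn_lexicon()
  function(tokens) {
    low <- tolower(tokens)
    tags <- unname(lex[low])
    open <- is.na(tags)
    if (any(open)) {
      w <- low[open]
      t2 <- rep("NN", length(w))
      t2[grepl("^[0-9]+$", w)] <- "CD"
      t2[nchar(w) > 4 & endsWith(w, "ing")] <- "VBG"
      t2[nchar(w) > 3 & endsWith(w, "ed")] <- "VBD"
      t2[nchar(w) > 3 & endsWith(w, "ly")] <- "RB"
      plain_s <- nchar(w) > 3 & endsWith(w, "s") & !endsWith(w, "ss") &
        !endsWith(w, "us") & !endsWith(w, "is") &
        t2 == "NN"
      t2[plain_s] <- "NNS"
      tags[open] <- t2
    }
    tags
  }
}

#' Tag a transcript with part-of-speech labels
#'
#' Applies a tagger backend to the unfiltered token stream and returns one
#' Penn-Treebank tag per token. The backend must return exactly one tag per
#' token; anything else is a contract error.
#'
#' @param t a `transcript` or a character token vector.
#' @param tagger tagger backend; see [default_tagger()].
#' @return object of class `tag_sequence`: data.frame with columns `token`
#'   and `tag`.
#' @export
tag <- function(t, tagger = default_tagger()) {
  tokens <- if (inherits(t, "transcript")) t$tokens_flat else as.character(t)
  if (length(tokens) == 0) stop("cannot tag an empty token sequence")
  tags <- tagger(tokens)
  if (!is.character(tags) || length(tags) != length(tokens) || anyNA(tags)) {
    stop("tagger contract violation: expected ", length(tokens),
         " character tags, got ", length(tags))
  }
  structure(data.frame(token = tokens, tag = tags, stringsAsFactors = FALSE),
            class = c("tag_sequence", "data.frame"))
}

#' Part-of-speech tag frequency features
#'
#' Counts, over a tag sequence, all tags and the six focal categories:
#' comparative adjectives (JJR), personal pronouns (PRP), possessive
#' pronouns (PRP$), wh-determiners (WDT), wh-pronouns (WP), wh-adverbs
#' (WRB). Both raw counts and per-word rates are returned; analyses default
#' to the raw counts, which track verbosity the same way the all-tags count
#' does.
#'
#' @param s a [tag()] result.
#' @return named numeric vector: `all_tags`, the six category counts, and
#'   one `<category>_rate` per category.
#' @export
tag_frequencies <- function(s) {
  stopifnot(inherits(s, "tag_sequence"))
  n <- nrow(s)
  if (n == 0) stop("empty tag sequence")
  cats <- c(comparative_adjectives = "JJR",
            personal_pronouns = "PRP",
            possessive_pronouns = "PRP$",
            wh_determiners = "WDT",
            wh_pronouns = "WP",
            wh_adverbs = "WRB")
  counts <- vapply(cats, function(tg) sum(s$tag == tg), numeric(1))
  rates <- counts / n
  names(rates) <- paste0(names(cats), "_rate")
  c(all_tags = n, counts, rates)
}
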