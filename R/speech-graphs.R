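#' Speech-graph configuration
#'
#' Parameters for sliding-window connectivity analysis. The defaults follow
#' the standard non-semantic speech-graph protocol: 30-word windows with a
#' 15-word step (i.e. 15 words of overlap) to control for verbosity
#' differences, and a 100-permutation word-shuffle null.
#'
#' @param window_size window length in words (default 30).
#' @param window_step step between window starts in words (default 15);
#'   must satisfy `0 < window_step <= window_size`.
#' @param n_shuffles number of random word shuffles for the null
#'   distribution (default 100).
#' @param seed optional integer seed for the shuffle null.
#' @return an object of class `graph_config`.
#' @export
graph_config <- function(window_size = 30, window_step = 15,
                         n_shuffles = 100, seed = NULL) {
  stopifnot(window_step > 0, window_step <= window_size, n_shuffles >= 1)
  structure(list(window_size = as.integer(window_size),
                 window_step = as.integer(window_step),
                 n_shuffles = as.integer(n_shuffles),
                 seed = seed),
            class = "graph_config")
}

#' Build a word-trajectory graph
#'
#' Builds the directed multigraph whose nodes are the unique words of a
#' token window and whose edges are the consecutive word transitions, in
#' order. Immediate word repetitions become self-loops.
#'
#' @param tokens character vector of at least 2 word tokens.
#' @return an object of class `word_graph`: list with `nodes` (unique
#'   words) and `edges` (data.frame `from`, `to`, one row per transition).
#' @export
#' @examples
#' g <- build_graph(c("the", "cat", "sat", "on", "the", "mat"))
#' length(g$nodes)   # 5
#' nrow(g$edges)     # 5
build_graph <- function(tokens) {
  tokens <- as.character(tokens)
  n <- length(tokens)
  if (n < 2) stop("degenerate window: need at least 2 tokens")
  structure(list(nodes = unique(tokens),
                 edges = data.frame(from = tokens[-n], to = tokens[-1],
                                    stringsAsFactors = FALSE)),
            class = "word_graph")
}

#' @export
print.word_graph <- function(x, ...) {
  cat(sprintf("<word_graph: %d nodes, %d edges>\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

.token_ids <- function(tokens) {
  match(tokens, unique(tokens))
}

.graph_tokens <- function(x) {
  if (inherits(x, "word_graph")) c(x$edges$from[1], x$edges$to)
  else if (inherits(x, "transcript")) x$tokens_flat
  else as.character(x)
}

#' The 14 connectivity measures of a word graph
#'
#' Computes, for one window: `nodes`, `edges` (multigraph), `repeated_edges`
#' (surplus same-direction duplicate edges), `parallel_edges` (unordered
#' word pairs linked in both directions), `loop1`/`loop2`/`loop3` (loops of
#' one, two and three nodes: immediate repeats, back-and-forth pairs and
#' 3-cycles; self-loops are never counted towards longer loops), `lcc` and
#' `lsc` (node counts of the largest connected and largest strongly
#' connected components), `average_total_degree` (2E/N on the multigraph),
#' `density` (directed simple density, self-loops excluded), `diameter` and
#' `average_shortest_path` (over reachable ordered node pairs of the
#' directed simple graph; 0 when no pair is reachable), and `clustering`
#' (mean undirected local clustering coefficient, nodes of degree < 2
#' contributing 0).
#'
#' @param g a [build_graph()] result, a `transcript`, or a token vector.
#' @return named numeric vector of the 14 measures.
#' @export
#' @examples
#' graph_measures(c("a", "b", "a", "b"))[c("loop2", "lsc")]
graph_measures <- function(g) {
  tokens <- .graph_tokens(g)
  if (length(tokens) < 2) stop("degenerate window: need at least 2 tokens")
  .graph_measures_cpp(.token_ids(tokens))
}

#' Sliding-window averaged connectivity measures
#'
#' Splits the token sequence into windows of `window_size` tokens starting
#' at multiples of `window_step` and averages each connectivity measure
#' across windows, which controls for verbosity differences between
#' excerpts. A sequence shorter than one window is analysed as a single
#' whole-sequence window; trailing tokens beyond the last full window are
#' dropped.
#'
#' @param tokens token vector or `transcript` (uses the unfiltered stream).
#' @param cfg a [graph_config()].
#' @return named numeric vector of window-averaged measures, with attribute
#'   `n_windows`.
#' @export
windowed_measures <- function(tokens, cfg = graph_config()) {
  stopifnot(inherits(cfg, "graph_config"))
  tokens <- .graph_tokens(tokens)
  if (length(tokens) < 2) stop("degenerate window: need at least 2 tokens")
  .windowed_measures_cpp(.token_ids(tokens), cfg$window_size, cfg$window_step)
}

#' Random-shuffle null distribution of connectivity measures
#'
#' Compares the observed windowed measures of an excerpt against random
#' speech obtained by uniformly permuting the excerpt's word sequence
#' `n_shuffles` times (the whole excerpt is permuted, then windowed).
#' Reports, per measure, the null mean and standard deviation and the
#' z-score `(observed - null mean) / null sd`; z is `NA` where the null
#' standard deviation is 0.
#'
#' @param tokens token vector or `transcript`.
#' @param cfg a [graph_config()]; `cfg$seed` makes the null reproducible.
#' @return object of class `shuffle_null`: list with `observed`,
#'   `null_mean`, `null_sd`, `z` (named numeric vectors) and `n_shuffles`.
#' @export
shuffle_null <- function(tokens, cfg = graph_config()) {
  stopifnot(inherits(cfg, "graph_config"))
  tokens <- .graph_tokens(tokens)
  if (length(tokens) < 2) stop("degenerate window: need at least 2 tokens")
  ids <- .token_ids(tokens)
  observed <- .windowed_measures_cpp(ids, cfg$window_size, cfg$window_step)
  null <- with_seed(cfg$seed, {
    vapply(seq_len(cfg$n_shuffles), function(i) {
      .windowed_measures_cpp(sample(ids), cfg$window_size, cfg$window_step)
    }, numeric(length(observed)))
  })
  null_mean <- rowMeans(null)
  null_sd <- apply(null, 1, stats::sd)
  z <- ifelse(null_sd > 0, (observed - null_mean) / null_sd, NA_real_)
  names(z) <- names(observed)
  structure(list(observed = observed, null_mean = null_mean,
                 null_sd = null_sd, z = z, n_shuffles = cfg$n_shuffles),
            class = "shuffle_null")
}

#' @export
print.shuffle_null <- function(x, ...) {
  cat(sprintf("<shuffle_null: %d shuffles>\n", x$n_shuffles))
  print(round(rbind(observed = x$observed, null_mean = x$null_mean,
                    null_sd = x$null_sd, z = x$z), 3))
  invisible(x)
}
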