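# Independent oracles, kept deliberately naive and separate from the
# package's implementation paths.

# all permutations of a vector (exhaustive; use only for tiny n)
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

# brute-force/igraph oracle for the connectivity measures of one window
oracle_graph_measures <- function(tokens) {
  n <- length(tokens)
  stopifnot(n >= 2)
  from <- tokens[-n]
  to <- tokens[-1]
  nodes <- unique(tokens)
  N <- length(nodes)
  E <- n - 1
  pair <- paste(from, to, sep = "\r")
  RE <- E - length(unique(pair))
  simple <- unique(data.frame(from = from, to = to,
                              stringsAsFactors = FALSE))
  simple_ns <- simple[simple$from != simple$to, , drop = FALSE]
  has_edge <- function(u, v) any(simple_ns$from == u & simple_ns$to == v)
  PE <- 0
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (i < j && has_edge(nodes[i], nodes[j]) &&
          has_edge(nodes[j], nodes[i])) PE <- PE + 1
    }
  }
  L1 <- sum(from == to)
  L2 <- PE  # 2-cycles of the binary off-diagonal adjacency
  L3 <- 0
  for (u in nodes) for (v in nodes) for (w in nodes) {
    if (u != v && v != w && u != w &&
        has_edge(u, v) && has_edge(v, w) && has_edge(w, u)) L3 <- L3 + 1
  }
  L3 <- L3 / 3
  g <- igraph::graph_from_data_frame(data.frame(from, to), vertices = nodes)
  LCC <- max(igraph::components(g, mode = "weak")$csize)
  LSC <- max(igraph::components(g, mode = "strong")$csize)
  gs <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  D <- igraph::distances(gs, mode = "out")
  fin <- is.finite(D) & D > 0
  diam <- if (any(fin)) max(D[fin]) else 0
  asp <- if (any(fin)) mean(D[fin]) else 0
  gu <- igraph::as_undirected(gs, mode = "collapse")
  loc <- igraph::transitivity(gu, type = "local", isolates = "zero")
  cc <- mean(loc)
  c(nodes = N, edges = E, repeated_edges = RE, parallel_edges = PE,
    loop1 = L1, loop2 = L2, loop3 = L3, lcc = LCC, lsc = LSC,
    average_total_degree = 2 * E / N,
    density = nrow(simple_ns) / if (N > 1) (N * (N - 1)) else 1,
    diameter = diam, average_shortest_path = asp, clustering = cc)
}

# plain recursive edit distance (no memoization)
oracle_edit_cost <- function(r, h) {
  if (length(r) == 0) return(length(h))
  if (length(h) == 0) return(length(r))
  min(oracle_edit_cost(r[-1], h[-1]) + (r[1] != h[1]),
      oracle_edit_cost(r[-1], h) + 1,
      oracle_edit_cost(r, h[-1]) + 1)
}

# word sequences -> single-character strings, for utils::adist
adist_cost <- function(r, h) {
  vocab <- unique(c(r, h))
  stopifnot(length(vocab) <= 50)
  code <- setNames(strsplit(intToUtf8(96 + seq_along(vocab)), "")[[1]], vocab)
  drop(utils::adist(paste(code[r], collapse = ""),
                    paste(code[h], collapse = "")))
}

# literal step-up rule
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) / m * alpha)
  reject <- rep(FALSE, m)
  if (length(k) > 0) reject[o[seq_len(max(k))]] <- TRUE
  reject
}

# exact two-sided Mann-Whitney p by enumerating group assignments
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, u_of)
  mu <- n1 * (length(y)) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}
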