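#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <functional>
using namespace Rcpp;

// Connectivity measures of the directed word-trajectory multigraph built
// from one window of token ids. Conventions:
//  - edges: multigraph count = window length - 1
//  - repeated_edges: surplus same-direction duplicates
//  - parallel_edges: unordered pairs {u,v}, u != v, linked in both directions
//  - loop1: adjacent identical tokens (multigraph self-loops)
//  - loop2/loop3: 2-/3-cycles of the binary directed adjacency with zeroed
//    diagonal, so self-loops never inflate longer cycles
//  - lcc: largest weakly connected component (node count)
//  - lsc: largest strongly connected component (node count)
//  - diameter / average_shortest_path: over reachable ordered pairs (u != v)
//    of the directed simple graph; 0 when no pair is reachable
//  - clustering: mean undirected local clustering, degree < 2 contributes 0
//  - density: simple directed density E_simple / (N (N-1)), 0 for N = 1

static const int NMEAS = 14;

static void measures_one_window(const int* toks, int n, double* out) {
  std::unordered_map<int, int> id;
  std::vector<int> seq(n);
  for (int i = 0; i < n; ++i) {
    auto it = id.find(toks[i]);
    if (it == id.end()) {
      int k = (int)id.size();
      id[toks[i]] = k;
      seq[i] = k;
    } else {
      seq[i] = it->second;
    }
  }
  const int N = (int)id.size();
  const int E = n - 1;

  std::vector<int> C(N * N, 0);  // multi-edge counts
  int loop1 = 0;
  for (int i = 0; i + 1 < n; ++i) {
    C[seq[i] * N + seq[i + 1]]++;
    if (seq[i] == seq[i + 1]) loop1++;
  }

  std::vector<char> A(N * N, 0);  // binary, zero diagonal
  int nnz_pairs = 0, simple_edges = 0;
  for (int u = 0; u < N; ++u)
    for (int v = 0; v < N; ++v)
      if (C[u * N + v] > 0) {
        nnz_pairs++;
        if (u != v) { A[u * N + v] = 1; simple_edges++; }
      }
  const int repeated = E - nnz_pairs;

  int parallel = 0, loop2 = 0;
  for (int u = 0; u < N; ++u)
    for (int v = u + 1; v < N; ++v)
      if (A[u * N + v] && A[v * N + u]) { parallel++; loop2++; }

  // trace(A^3)/3 counts directed 3-cycles
  long trace3 = 0;
  for (int u = 0; u < N; ++u)
    for (int v = 0; v < N; ++v)
      if (A[u * N + v])
        for (int w = 0; w < N; ++w)
          if (A[v * N + w] && A[w * N + u]) trace3++;
  const int loop3 = (int)(trace3 / 3);

  // weakly connected components: union-find
  std::vector<int> parent(N);
  for (int i = 0; i < N; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int u = 0; u < N; ++u)
    for (int v = 0; v < N; ++v)
      if (u != v && (A[u * N + v] || A[v * N + u])) {
        int ru = find(u), rv = find(v);
        if (ru != rv) parent[ru] = rv;
      }
  std::vector<int> csize(N, 0);
  int lcc = 0;
  for (int i = 0; i < N; ++i) {
    int r = find(i);
    if (++csize[r] > lcc) lcc = csize[r];
  }

  // strongly connected components: Kosaraju
  std::vector<int> order;
  order.reserve(N);
  std::vector<char> seen(N, 0);
  std::function<void(int)> dfs1 = [&](int u) {
    seen[u] = 1;
    for (int v = 0; v < N; ++v)
      if (A[u * N + v] && !seen[v]) dfs1(v);
    order.push_back(u);
  };
  for (int u = 0; u < N; ++u)
    if (!seen[u]) dfs1(u);
  std::fill(seen.begin(), seen.end(), 0);
  int lsc = 0;
  std::function<int(int)> dfs2 = [&](int u) {
    seen[u] = 1;
    int sz = 1;
    for (int v = 0; v < N; ++v)
      if (A[v * N + u] && !seen[v]) sz += dfs2(v);
    return sz;
  };
  for (int i = N - 1; i >= 0; --i) {
    int u = order[i];
    if (!seen[u]) {
      int sz = dfs2(u);
      if (sz > lsc) lsc = sz;
    }
  }

  // all-pairs shortest paths on the simple directed graph
  const double INF = 1e18;
  std::vector<double> D(N * N, INF);
  for (int u = 0; u < N; ++u)
    for (int v = 0; v < N; ++v)
      if (u != v && A[u * N + v]) D[u * N + v] = 1.0;
  for (int k = 0; k < N; ++k)
    for (int u = 0; u < N; ++u) {
      double duk = D[u * N + k];
      if (duk >= INF) continue;
      for (int v = 0; v < N; ++v) {
        double alt = duk + D[k * N + v];
        if (alt < D[u * N + v]) D[u * N + v] = alt;
      }
    }
  double diam = 0.0, spsum = 0.0;
  long spn = 0;
  for (int u = 0; u < N; ++u)
    for (int v = 0; v < N; ++v)
      if (u != v && D[u * N + v] < INF) {
        spsum += D[u * N + v];
        spn++;
        if (D[u * N + v] > diam) diam = D[u * N + v];
      }
  const double asp = spn > 0 ? spsum / spn : 0.0;

  // mean undirected local clustering
  std::vector<char> U(N * N, 0);
  for (int u = 0; u < N; ++u)
    for (int v = 0; v < N; ++v)
      if (u != v && (A[u * N + v] || A[v * N + u])) U[u * N + v] = 1;
  double ccsum = 0.0;
  for (int u = 0; u < N; ++u) {
    std::vector<int> nbr;
    for (int v = 0; v < N; ++v)
      if (U[u * N + v]) nbr.push_back(v);
    const int k = (int)nbr.size();
    if (k < 2) continue;
    int links = 0;
    for (size_t a = 0; a < nbr.size(); ++a)
      for (size_t b = a + 1; b < nbr.size(); ++b)
        if (U[nbr[a] * N + nbr[b]]) links++;
    ccsum += 2.0 * links / (k * (double)(k - 1));
  }
  const double cc = N > 0 ? ccsum / N : 0.0;

  out[0] = N;
  out[1] = E;
  out[2] = repeated;
  out[3] = parallel;
  out[4] = loop1;
  out[5] = loop2;
  out[6] = loop3;
  out[7] = lcc;
  out[8] = lsc;
  out[9] = 2.0 * E / N;
  out[10] = N > 1 ? simple_edges / (N * (double)(N - 1)) : 0.0;
  out[11] = diam;
  out[12] = asp;
  out[13] = cc;
}

static CharacterVector measure_names() {
  return CharacterVector::create(
      "nodes", "edges", "repeated_edges", "parallel_edges", "loop1", "loop2",
      "loop3", "lcc", "lsc", "average_total_degree", "density", "diameter",
      "average_shortest_path", "clustering");
}

// [[Rcpp::export(name = ".graph_measures_cpp")]]
NumericVector graph_measures_cpp(IntegerVector tokens) {
  const int n = tokens.size();
  if (n < 2) stop("window must contain at least 2 tokens");
  NumericVector out(NMEAS);
  measures_one_window(INTEGER(tokens), n, REAL(out));
  out.attr("names") = measure_names();
  return out;
}

// Sliding windows of `window` tokens starting at multiples of `step`;
// trailing tokens beyond the last full window are dropped. A sequence
// shorter than `window` forms one whole-sequence window. Returns the
// per-measure arithmetic mean over windows.
// [[Rcpp::export(name = ".windowed_measures_cpp")]]
NumericVector windowed_measures_cpp(IntegerVector tokens, int window, int step) {
  const int n = tokens.size();
  if (n < 2) stop("sequence must contain at least 2 tokens");
  if (step < 1 || window < step) stop("need 0 < step <= window");
  NumericVector acc(NMEAS);
  double buf[NMEAS];
  int nwin = 0;
  if (n < window) {
    measures_one_window(INTEGER(tokens), n, buf);
    for (int j = 0; j < NMEAS; ++j) acc[j] += buf[j];
    nwin = 1;
  } else {
    for (int start = 0; start + window <= n; start += step) {
      measures_one_window(INTEGER(tokens) + start, window, buf);
      for (int j = 0; j < NMEAS; ++j) acc[j] += buf[j];
      nwin++;
    }
  }
  for (int j = 0; j < NMEAS; ++j) acc[j] /= nwin;
  acc.attr("names") = measure_names();
  acc.attr("n_windows") = nwin;
  return acc;
}
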