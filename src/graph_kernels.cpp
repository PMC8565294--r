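// Core graph kernels for binary undirected networks.
//
// All functions take a 0/1 integer adjacency matrix (symmetric, zero
// diagonal); validation happens on the R side. Distances are unweighted
// hop counts from breadth-first search. Betweenness follows Brandes'
// accumulation. Rewiring is the Maslov-Sneppen double-edge swap and draws
// from R's RNG so set.seed() controls the ensemble.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <stack>
#include <limits>
#include <cstdint>

using namespace Rcpp;

// Bitset rows of the adjacency matrix: row i holds the neighbor set of
// node i packed into 64-bit words, enabling word-parallel BFS frontiers.
struct BitRows {
  int n, nw;
  std::vector<uint64_t> w;
  explicit BitRows(const IntegerMatrix& A)
      : n(A.nrow()), nw((A.nrow() + 63) / 64), w((size_t) A.nrow() * nw, 0) {
    const int* a = INTEGER(A);  // column-major
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i)
        if (a[i + (size_t) j * n] != 0 && i != j)
          w[(size_t) i * nw + j / 64] |= 1ULL << (j % 64);
  }
  const uint64_t* row(int i) const { return &w[(size_t) i * nw]; }
};

static inline int popcount_words(const uint64_t* x, int nw) {
  int c = 0;
  for (int k = 0; k < nw; ++k) c += __builtin_popcountll(x[k]);
  return c;
}

// Accumulate sum over reachable targets of 1/dist from source s, BFS
// restricted to the node set `mask` (s must be in mask). Also counts
// reached nodes (excluding s) via *reached if non-null.
static double bfs_inv_dist_sum(const BitRows& B, int s, const uint64_t* mask,
                               std::vector<uint64_t>& frontier,
                               std::vector<uint64_t>& visited,
                               std::vector<uint64_t>& next,
                               int* reached = 0) {
  const int nw = B.nw;
  for (int k = 0; k < nw; ++k) { frontier[k] = 0; visited[k] = 0; }
  frontier[s / 64] = 1ULL << (s % 64);
  visited[s / 64] = frontier[s / 64];
  double acc = 0.0;
  int nreach = 0;
  int d = 0;
  while (true) {
    ++d;
    for (int k = 0; k < nw; ++k) next[k] = 0;
    for (int k = 0; k < nw; ++k) {
      uint64_t f = frontier[k];
      while (f) {
        int v = k * 64 + __builtin_ctzll(f);
        f &= f - 1;
        const uint64_t* rv = B.row(v);
        for (int q = 0; q < nw; ++q) next[q] |= rv[q];
      }
    }
    int cnt = 0;
    for (int k = 0; k < nw; ++k) {
      next[k] &= mask[k] & ~visited[k];
      visited[k] |= next[k];
      cnt += __builtin_popcountll(next[k]);
    }
    if (cnt == 0) break;
    acc += (double) cnt / d;
    nreach += cnt;
    std::swap(frontier, next);
  }
  if (reached) *reached = nreach;
  return acc;
}

static std::vector<std::vector<int> > adj_list(const IntegerMatrix& A) {
  const int n = A.nrow();
  std::vector<std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (A(i, j) != 0 && i != j) nb[i].push_back(j);
  return nb;
}

// BFS hop distances from one source; -1 marks unreachable.
static void bfs_from(const std::vector<std::vector<int> >& nb, int s,
                     std::vector<int>& dist) {
  std::fill(dist.begin(), dist.end(), -1);
  dist[s] = 0;
  std::queue<int> q;
  q.push(s);
  while (!q.empty()) {
    int v = q.front(); q.pop();
    for (size_t k = 0; k < nb[v].size(); ++k) {
      int w = nb[v][k];
      if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_bfs_distances(IntegerMatrix A) {
  const int n = A.nrow();
  std::vector<std::vector<int> > nb = adj_list(A);
  NumericMatrix D(n, n);
  std::vector<int> dist(n);
  for (int s = 0; s < n; ++s) {
    bfs_from(nb, s, dist);
    for (int t = 0; t < n; ++t)
      D(s, t) = dist[t] < 0 ? R_PosInf : (double) dist[t];
  }
  return D;
}

// Per-source sum of inverse distances over the whole graph (nodal
// efficiency numerators) without materializing the distance matrix.
// [[Rcpp::export]]
NumericVector cpp_inv_dist_sums(IntegerMatrix A) {
  const int n = A.nrow();
  BitRows B(A);
  std::vector<uint64_t> all(B.nw, 0), frontier(B.nw), visited(B.nw),
      next(B.nw);
  for (int i = 0; i < n; ++i) all[i / 64] |= 1ULL << (i % 64);
  NumericVector out(n);
  for (int s = 0; s < n; ++s)
    out[s] = bfs_inv_dist_sum(B, s, all.data(), frontier, visited, next);
  return out;
}

// Per-node clustering coefficient: 2 t_i / (k_i (k_i - 1)), 0 for k_i < 2.
// [[Rcpp::export]]
NumericVector cpp_clustering(IntegerMatrix A) {
  const int n = A.nrow();
  BitRows B(A);
  NumericVector C(n);
  for (int i = 0; i < n; ++i) {
    const uint64_t* mi = B.row(i);
    const int k = popcount_words(mi, B.nw);
    if (k < 2) { C[i] = 0.0; continue; }
    long t2 = 0;  // twice the triangle count at i
    for (int kw = 0; kw < B.nw; ++kw) {
      uint64_t f = mi[kw];
      while (f) {
        int j = kw * 64 + __builtin_ctzll(f);
        f &= f - 1;
        const uint64_t* mj = B.row(j);
        for (int q = 0; q < B.nw; ++q)
          t2 += __builtin_popcountll(mi[q] & mj[q]);
      }
    }
    C[i] = (double) t2 / ((double) k * (k - 1));
  }
  return C;
}

// Brandes betweenness; returned as unordered-pair counts (ordered sum / 2).
// [[Rcpp::export]]
NumericVector cpp_betweenness(IntegerMatrix A) {
  const int n = A.nrow();
  std::vector<std::vector<int> > nb = adj_list(A);
  NumericVector BC(n);
  std::vector<int> dist(n);
  std::vector<double> sigma(n), delta(n);
  std::vector<std::vector<int> > pred(n);
  for (int s = 0; s < n; ++s) {
    std::stack<int> order;
    for (int i = 0; i < n; ++i) { pred[i].clear(); sigma[i] = 0.0; dist[i] = -1; }
    sigma[s] = 1.0; dist[s] = 0;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      order.push(v);
      for (size_t k = 0; k < nb[v].size(); ++k) {
        int w = nb[v][k];
        if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
        if (dist[w] == dist[v] + 1) { sigma[w] += sigma[v]; pred[w].push_back(v); }
      }
    }
    std::fill(delta.begin(), delta.end(), 0.0);
    while (!order.empty()) {
      int w = order.top(); order.pop();
      for (size_t k = 0; k < pred[w].size(); ++k) {
        int v = pred[w][k];
        delta[v] += (sigma[v] / sigma[w]) * (1.0 + delta[w]);
      }
      if (w != s) BC[w] += delta[w];
    }
  }
  for (int i = 0; i < n; ++i) BC[i] /= 2.0;
  return BC;
}

// Global efficiency of the subgraph induced by each node's neighbors
// (node itself excluded); 0 when degree < 2.
// [[Rcpp::export]]
NumericVector cpp_local_efficiency(IntegerMatrix A) {
  const int n = A.nrow();
  BitRows B(A);
  std::vector<uint64_t> frontier(B.nw), visited(B.nw), next(B.nw);
  NumericVector NEloc(n);
  for (int i = 0; i < n; ++i) {
    const uint64_t* mask = B.row(i);  // BFS restricted to neighbors of i
    const int k = popcount_words(mask, B.nw);
    if (k < 2) { NEloc[i] = 0.0; continue; }
    double acc = 0.0;
    for (int kw = 0; kw < B.nw; ++kw) {
      uint64_t f = mask[kw];
      while (f) {
        int s = kw * 64 + __builtin_ctzll(f);
        f &= f - 1;
        acc += bfs_inv_dist_sum(B, s, mask, frontier, visited, next);
      }
    }
    NEloc[i] = acc / ((double) k * (k - 1));
  }
  return NEloc;
}

// Connected-component membership (1-based labels, BFS).
// [[Rcpp::export]]
IntegerVector cpp_components(IntegerMatrix A) {
  const int n = A.nrow();
  std::vector<std::vector<int> > nb = adj_list(A);
  IntegerVector comp(n, 0);
  int label = 0;
  for (int s = 0; s < n; ++s) {
    if (comp[s] != 0) continue;
    ++label;
    std::queue<int> q;
    q.push(s); comp[s] = label;
    while (!q.empty()) {
      int v = q.front(); q.pop();
      for (size_t k = 0; k < nb[v].size(); ++k) {
        int w = nb[v][k];
        if (comp[w] == 0) { comp[w] = label; q.push(w); }
      }
    }
  }
  return comp;
}

// Degree-preserving randomization: pick two edges (a,b),(c,d) with all four
// endpoints distinct and swap to (a,d),(c,b) when neither new edge exists.
// [[Rcpp::export]]
IntegerMatrix cpp_rewire(IntegerMatrix A, int n_attempts) {
  const int n = A.nrow();
  IntegerMatrix B(clone(A));
  // edge list, i < j
  std::vector<int> ei, ej;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (B(i, j) != 0) { ei.push_back(i); ej.push_back(j); }
  const int m = (int) ei.size();
  if (m < 2) return B;
  RNGScope scope;
  for (int it = 0; it < n_attempts; ++it) {
    int e1 = (int) (unif_rand() * m);
    int e2 = (int) (unif_rand() * m);
    if (e1 >= m) e1 = m - 1;
    if (e2 >= m) e2 = m - 1;
    if (e1 == e2) continue;
    int a = ei[e1], b = ej[e1], c = ei[e2], d = ej[e2];
    // randomize orientation of the second edge
    if (unif_rand() < 0.5) { int tmp = c; c = d; d = tmp; }
    if (a == c || a == d || b == c || b == d) continue;
    if (B(a, d) != 0 || B(c, b) != 0) continue;
    B(a, b) = 0; B(b, a) = 0;
    B(c, d) = 0; B(d, c) = 0;
    B(a, d) = 1; B(d, a) = 1;
    B(c, b) = 1; B(b, c) = 1;
    ei[e1] = a < d ? a : d; ej[e1] = a < d ? d : a;
    ei[e2] = c < b ? c : b; ej[e2] = c < b ? b : c;
  }
  return B;
}
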