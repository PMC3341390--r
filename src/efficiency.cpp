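#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstdint>
using namespace Rcpp;

// Graphs here are small (tens to a few hundred nodes) but efficiency
// sweeps evaluate many thousands of them, so BFS runs on bitset adjacency
// rows: one row = ceil(n/64) 64-bit words, frontier expansion by bitwise
// OR, level counts by popcount.

static inline int popcnt64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

static inline int ctz64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_ctzll(x);
#else
  int c = 0; while (!(x & 1)) { x >>= 1; ++c; } return c;
#endif
}

// rows: n * w words, row i = adjacency bitset of node i.
// Accumulates sum over j != src of 1/d(src, j) into *acc and writes hop
// counts into dist (if non-null; -1 = unreachable).
static void bfs_bitset(const std::vector<uint64_t>& rows, int n, int w,
                       int src, double* acc, int* dist,
                       std::vector<uint64_t>& visited,
                       std::vector<uint64_t>& frontier,
                       std::vector<uint64_t>& next) {
  for (int k = 0; k < w; ++k) visited[k] = frontier[k] = 0;
  visited[src >> 6] = frontier[src >> 6] = 1ULL << (src & 63);
  if (dist) { for (int j = 0; j < n; ++j) dist[j] = -1; dist[src] = 0; }
  double total = 0.0;
  int level = 0;
  for (;;) {
    ++level;
    for (int k = 0; k < w; ++k) next[k] = 0;
    for (int k = 0; k < w; ++k) {
      uint64_t f = frontier[k];
      while (f) {
        int u = (k << 6) + ctz64(f);
        f &= f - 1;
        const uint64_t* row = &rows[(size_t) u * w];
        for (int t = 0; t < w; ++t) next[t] |= row[t];
      }
    }
    int found = 0;
    for (int k = 0; k < w; ++k) {
      next[k] &= ~visited[k];
      found += popcnt64(next[k]);
    }
    if (found == 0) break;
    total += (double) found / level;
    if (dist) {
      for (int k = 0; k < w; ++k) {
        uint64_t f = next[k];
        while (f) { dist[(k << 6) + ctz64(f)] = level; f &= f - 1; }
      }
    }
    for (int k = 0; k < w; ++k) {
      visited[k] |= next[k];
      frontier[k] = next[k];
    }
  }
  if (acc) *acc = total;
}

static std::vector<uint64_t> to_bitset(const IntegerMatrix& adj, int n,
                                       int w) {
  std::vector<uint64_t> rows((size_t) n * w, 0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && adj(i, j) != 0)
        rows[(size_t) i * w + (j >> 6)] |= 1ULL << (j & 63);
  return rows;
}

// Sum over ordered pairs of 1/d; caller divides by n(n-1).
static double inv_path_sum(const std::vector<uint64_t>& rows, int n,
                           int w) {
  std::vector<uint64_t> visited(w), frontier(w), next(w);
  double total = 0.0, acc;
  for (int s = 0; s < n; ++s) {
    bfs_bitset(rows, n, w, s, &acc, 0, visited, frontier, next);
    total += acc;
  }
  return total;
}

// [[Rcpp::export]]
NumericMatrix cpp_shortest_paths(IntegerMatrix adj) {
  int n = adj.nrow();
  int w = (n + 63) / 64;
  std::vector<uint64_t> rows = to_bitset(adj, n, w);
  std::vector<uint64_t> visited(w), frontier(w), next(w);
  std::vector<int> dist(n);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    bfs_bitset(rows, n, w, i, 0, dist.data(), visited, frontier, next);
    for (int j = 0; j < n; ++j)
      out(i, j) = dist[j] < 0 ? R_PosInf : (double) dist[j];
  }
  return out;
}

// [[Rcpp::export]]
double cpp_global_efficiency(IntegerMatrix adj) {
  int n = adj.nrow();
  if (n < 2) return 0.0;
  int w = (n + 63) / 64;
  std::vector<uint64_t> rows = to_bitset(adj, n, w);
  return inv_path_sum(rows, n, w) / ((double) n * (n - 1));
}

// [[Rcpp::export]]
NumericVector cpp_nodal_efficiency(IntegerMatrix adj) {
  int n = adj.nrow();
  int w = (n + 63) / 64;
  std::vector<uint64_t> rows = to_bitset(adj, n, w);
  std::vector<uint64_t> visited(w), frontier(w), next(w);
  NumericVector out(n);
  double acc;
  for (int i = 0; i < n; ++i) {
    bfs_bitset(rows, n, w, i, &acc, 0, visited, frontier, next);
    out[i] = n > 1 ? acc / (double) (n - 1) : 0.0;
  }
  return out;
}

// Mean over nodes of the global efficiency of each node's
// neighbour-induced subgraph (node itself excluded); nodes with fewer
// than two neighbours contribute zero.
// [[Rcpp::export]]
double cpp_local_efficiency(IntegerMatrix adj) {
  int n = adj.nrow();
  if (n < 2) return 0.0;
  int w = (n + 63) / 64;
  std::vector<uint64_t> rows = to_bitset(adj, n, w);
  std::vector<int> nbi(n);
  std::vector<uint64_t> sub((size_t) n * w), visited(w), frontier(w),
      next(w);
  double total = 0.0, acc;
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int k = 0; k < w; ++k) {
      uint64_t f = rows[(size_t) i * w + k];
      while (f) { nbi[m++] = (k << 6) + ctz64(f); f &= f - 1; }
    }
    if (m < 2) continue;
    int ws = (m + 63) / 64;
    for (int a = 0; a < m * ws; ++a) sub[a] = 0;
    for (int a = 0; a < m; ++a)
      for (int b = a + 1; b < m; ++b)
        if (adj(nbi[a], nbi[b]) != 0) {
          sub[(size_t) a * ws + (b >> 6)] |= 1ULL << (b & 63);
          sub[(size_t) b * ws + (a >> 6)] |= 1ULL << (a & 63);
        }
    double s = 0.0;
    for (int src = 0; src < m; ++src) {
      bfs_bitset(sub, m, ws, src, &acc, 0, visited, frontier, next);
      s += acc;
    }
    total += s / ((double) m * (m - 1));
  }
  return total / (double) n;
}

// Degree-preserving randomization by double-edge swaps: pick edges
// (a,b),(c,d), replace with (a,d),(c,b) unless that creates a self-loop
// or duplicate edge. Uses R's RNG so set.seed() governs the result.
// [[Rcpp::export]]
List cpp_rewire(IntegerMatrix adj, int n_swaps, int max_attempts) {
  int n = adj.nrow();
  IntegerMatrix a = clone(adj);
  std::vector<int> ea, eb;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (a(i, j) != 0) { ea.push_back(i); eb.push_back(j); }
  int K = (int) ea.size();
  int done = 0, attempts = 0;
  if (K >= 2) {
    while (done < n_swaps && attempts < max_attempts) {
      ++attempts;
      int e1 = (int) (unif_rand() * K);
      int e2 = (int) (unif_rand() * K);
      if (e1 >= K) e1 = K - 1;
      if (e2 >= K) e2 = K - 1;
      if (e1 == e2) continue;
      int aa = ea[e1], b = eb[e1], c = ea[e2], d = eb[e2];
      // orient the second edge at random so both pairings are reachable
      if (unif_rand() < 0.5) { int tmp = c; c = d; d = tmp; }
      if (aa == d || c == b) continue;              // self-loop
      if (a(aa, d) != 0 || a(c, b) != 0) continue;  // duplicate
      a(aa, b) = a(b, aa) = 0;
      a(c, d) = a(d, c) = 0;
      a(aa, d) = a(d, aa) = 1;
      a(c, b) = a(b, c) = 1;
      ea[e1] = aa < d ? aa : d; eb[e1] = aa < d ? d : aa;
      ea[e2] = c < b ? c : b;  eb[e2] = c < b ? b : c;
      ++done;
    }
  }
  return List::create(_["adjacency"] = a,
                      _["n_swaps_done"] = done,
                      _["n_attempts"] = attempts);
}
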