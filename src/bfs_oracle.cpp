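#include <Rcpp.h>
#include <vector>
#include <cstdint>

// Brute-force distance table for sorting signed permutations by reversals.
//
// State encoding (must match oracle_state_index() on the R side):
//   index = lehmer_rank(|p|) * 2^n + sign_bits,
// where sign bit i-1 is set iff p[i] < 0. BFS runs from the identity over
// all n(n+1)/2 reversal moves; reversals are involutions, so the graph is
// undirected and d(identity -> p) == d(p -> identity).

static inline uint32_t encode(const int *p, int n) {
  uint32_t rank = 0;
  uint32_t bits = 0;
  for (int i = 0; i < n; ++i) {
    int ai = p[i] < 0 ? -p[i] : p[i];
    int smaller = 0;
    for (int j = i + 1; j < n; ++j) {
      int aj = p[j] < 0 ? -p[j] : p[j];
      if (aj < ai) ++smaller;
    }
    rank = rank * (n - i) + smaller;
    if (p[i] < 0) bits |= (1u << i);
  }
  return (rank << n) | bits;
}

static inline void decode(uint32_t idx, int n, int *p) {
  uint32_t bits = idx & ((1u << n) - 1);
  uint32_t rank = idx >> n;
  int lehmer[8];
  for (int i = n - 1; i >= 0; --i) {
    lehmer[i] = rank % (n - i);
    rank /= (n - i);
  }
  bool used[9] = {false};
  for (int i = 0; i < n; ++i) {
    int need = lehmer[i], val = 0;
    for (int v = 1; v <= n; ++v) {
      if (!used[v]) {
        if (need == 0) { val = v; break; }
        --need;
      }
    }
    used[val] = true;
    p[i] = (bits & (1u << i)) ? -val : val;
  }
}

// [[Rcpp::export]]
Rcpp::IntegerVector bfs_distance_table_cpp(int n) {
  if (n < 1 || n > 8) Rcpp::stop("n must be between 1 and 8");
  uint64_t fact = 1;
  for (int i = 2; i <= n; ++i) fact *= i;
  uint64_t nstates = fact << n;

  std::vector<int8_t> dist(nstates, -1);
  std::vector<uint32_t> frontier, nxt;

  int id[8];
  for (int i = 0; i < n; ++i) id[i] = i + 1;
  uint32_t start = encode(id, n);
  dist[start] = 0;
  frontier.push_back(start);

  int p[8], q[8];
  int8_t d = 0;
  while (!frontier.empty()) {
    ++d;
    nxt.clear();
    for (uint32_t s : frontier) {
      decode(s, n, p);
      for (int i = 0; i < n; ++i) {
        for (int j = i; j < n; ++j) {
          for (int t = 0; t < n; ++t) q[t] = p[t];
          for (int a = i, b = j; a <= j; ++a, --b) q[a] = -p[b];
          uint32_t e = encode(q, n);
          if (dist[e] < 0) {
            dist[e] = d;
            nxt.push_back(e);
          }
        }
      }
    }
    frontier.swap(nxt);
  }

  Rcpp::IntegerVector out(nstates);
  for (uint64_t s = 0; s < nstates; ++s) out[s] = dist[s];
  return out;
}
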