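// Core numerical routines: deterministic id-keyed vector initialization,
// second-order (node2vec-style) random walks, and Skip-Gram training with
// negative sampling that accepts an initial embedding state. Everything is
// single-threaded and driven by its own counter-based RNG so that repeated
// runs with the same seed are bitwise identical across platforms.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// ---- deterministic RNG (splitmix64) ----------------------------------------

static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// uniform double in [0, 1)
static inline double unif01(uint64_t &s) {
  return (double)(splitmix64(s) >> 11) * (1.0 / 9007199254740992.0);
}

static inline int unif_int(uint64_t &s, int n) {
  // n is small (window sizes, neighbour counts); modulo bias is negligible
  return (int)(splitmix64(s) % (uint64_t)n);
}

static uint64_t fnv1a(const char *str) {
  uint64_t h = 1469598103934665603ULL;
  for (const char *p = str; *p; ++p) {
    h ^= (uint64_t)(unsigned char)(*p);
    h *= 1099511628211ULL;
  }
  return h;
}

// ---- id-keyed initialization ------------------------------------------------

// One row per key: uniform(-0.5, 0.5)/dim, seeded by hash(key) xor seed.
// Keying on the (unprefixed) node id makes like-named nodes of two jointly
// trained networks start from the same point, which anchors the two halves
// of the shared embedding space.
// [[Rcpp::export]]
NumericMatrix cpp_hash_init(CharacterVector keys, int dim, int seed) {
  int n = keys.size();
  NumericMatrix out(n, dim);
  for (int i = 0; i < n; ++i) {
    uint64_t state = fnv1a(CHAR(STRING_ELT(keys, i))) ^
      (0x9E3779B97F4A7C15ULL * (uint64_t)(seed + 1));
    for (int d = 0; d < dim; ++d)
      out(i, d) = (unif01(state) - 0.5) / (double)dim;
  }
  return out;
}

// ---- random walks -----------------------------------------------------------

static inline bool has_edge(const std::vector<int> &sorted_nbrs, int v) {
  return std::binary_search(sorted_nbrs.begin(), sorted_nbrs.end(), v);
}

// adj: list of 0-based sorted integer neighbour vectors, one per node.
// Returns walks_per_node walks from every node (isolated nodes yield the
// singleton walk). Second-order transitions with return bias 1/p and
// in-out bias 1/q.
// [[Rcpp::export]]
List cpp_sample_walks(List adj, int walks_per_node, int walk_length,
                      double p, double q, int seed) {
  int n = adj.size();
  std::vector< std::vector<int> > nbrs(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = adj[i];
    nbrs[i] = std::vector<int>(v.begin(), v.end());
  }
  uint64_t state = 0x2545F4914F6CDD1DULL ^ (uint64_t)(seed + 7);
  // burn in a few draws so nearby seeds decorrelate
  for (int i = 0; i < 8; ++i) splitmix64(state);

  List out(n * walks_per_node);
  std::vector<double> w;
  int k = 0;
  for (int pass = 0; pass < walks_per_node; ++pass) {
    for (int start = 0; start < n; ++start) {
      std::vector<int> walk;
      walk.reserve(walk_length);
      walk.push_back(start);
      int prev = -1, cur = start;
      while ((int)walk.size() < walk_length) {
        const std::vector<int> &nb = nbrs[cur];
        if (nb.empty()) break;
        int nxt;
        if (prev < 0 || (p == 1.0 && q == 1.0)) {
          nxt = nb[unif_int(state, (int)nb.size())];
        } else {
          w.resize(nb.size());
          double tot = 0.0;
          for (size_t j = 0; j < nb.size(); ++j) {
            double wt;
            if (nb[j] == prev) wt = 1.0 / p;
            else if (has_edge(nbrs[prev], nb[j])) wt = 1.0;
            else wt = 1.0 / q;
            tot += wt;
            w[j] = tot;
          }
          double r = unif01(state) * tot;
          size_t j = std::lower_bound(w.begin(), w.end(), r) - w.begin();
          if (j >= nb.size()) j = nb.size() - 1;
          nxt = nb[j];
        }
        prev = cur;
        cur = nxt;
        walk.push_back(cur);
      }
      out[k++] = IntegerVector(walk.begin(), walk.end());
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// ---- Skip-Gram with negative sampling ---------------------------------------

// walks: list of 0-based token-index vectors; init: V x dim starting input
// embeddings (already holding any carried-over state); counts: token
// frequencies used for the unigram^0.75 negative-sampling distribution.
// Returns the trained input embeddings; epochs = 0 returns init unchanged.
// [[Rcpp::export]]
NumericMatrix cpp_train_sgns(List walks, NumericMatrix init, NumericVector counts,
                             int window, int epochs, int negative,
                             double alpha, int seed) {
  int V = init.nrow(), dim = init.ncol();
  int n_walks = walks.size();

  std::vector<double> syn0((size_t)V * dim), syn1((size_t)V * dim, 0.0);
  for (int v = 0; v < V; ++v)
    for (int d = 0; d < dim; ++d)
      syn0[(size_t)v * dim + d] = init(v, d);

  if (epochs > 0 && n_walks > 0) {
    // cumulative unigram^0.75 table for negative sampling
    std::vector<double> cum(V);
    double tot = 0.0;
    for (int v = 0; v < V; ++v) {
      tot += std::pow(std::max(counts[v], 1.0), 0.75);
      cum[v] = tot;
    }

    long long total_tokens = 0;
    for (int i = 0; i < n_walks; ++i)
      total_tokens += ((IntegerVector)walks[i]).size();
    total_tokens *= epochs;
    long long processed = 0;

    uint64_t state = 0x853C49E6748FEA9BULL ^ (uint64_t)(seed + 11);
    for (int i = 0; i < 8; ++i) splitmix64(state);

    std::vector<double> neu1e(dim);
    double lr = alpha;
    const double min_lr_frac = 1e-4;

    for (int ep = 0; ep < epochs; ++ep) {
      for (int iw = 0; iw < n_walks; ++iw) {
        IntegerVector walk = walks[iw];
        int len = walk.size();
        for (int pos = 0; pos < len; ++pos) {
          if ((processed & 1023) == 0) {
            double frac = 1.0 - (double)processed / (double)(total_tokens + 1);
            lr = alpha * std::max(frac, min_lr_frac);
          }
          ++processed;
          int center = walk[pos];
          int b = unif_int(state, window);   // word2vec-style shrunk window
          int lo = pos - (window - b), hi = pos + (window - b);
          if (lo < 0) lo = 0;
          if (hi > len - 1) hi = len - 1;
          for (int cpos = lo; cpos <= hi; ++cpos) {
            if (cpos == pos) continue;
            int context = walk[cpos];
            std::fill(neu1e.begin(), neu1e.end(), 0.0);
            double *in = &syn0[(size_t)center * dim];
            for (int k = 0; k <= negative; ++k) {
              int target;
              double label;
              if (k == 0) {
                target = context;
                label = 1.0;
              } else {
                double r = unif01(state) * tot;
                target = (int)(std::lower_bound(cum.begin(), cum.end(), r) -
                               cum.begin());
                if (target >= V) target = V - 1;
                if (target == context) continue;
                label = 0.0;
              }
              double *outv = &syn1[(size_t)target * dim];
              double f = 0.0;
              for (int d = 0; d < dim; ++d) f += in[d] * outv[d];
              double g = (label - 1.0 / (1.0 + std::exp(-f))) * lr;
              for (int d = 0; d < dim; ++d) {
                neu1e[d] += g * outv[d];
                outv[d] += g * in[d];
              }
            }
            for (int d = 0; d < dim; ++d) in[d] += neu1e[d];
          }
        }
        if ((iw & 63) == 0) Rcpp::checkUserInterrupt();
      }
    }
  }

  NumericMatrix out(V, dim);
  for (int v = 0; v < V; ++v)
    for (int d = 0; d < dim; ++d)
      out(v, d) = syn0[(size_t)v * dim + d];
  return out;
}
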