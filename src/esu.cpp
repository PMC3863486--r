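// Exact graphlet and orbit counting by ESU enumeration.
//
// Enumerates every connected induced subgraph on 2..5 nodes exactly once
// (Wernicke's ESU scheme), classifies it in O(1) via precomputed lookup
// tables from labelled edge-masks to catalog graphlet ids and per-position
// global orbit ids, and accumulates graphlet counts and per-node orbit touch
// counts.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Esu {
  int n;
  const std::vector<std::vector<int>>* adj;
  std::vector<char> amat;        // n*n adjacency, for O(1) edge tests
  std::vector<char> marked;      // in current sub or its neighbourhood
  int sub[5];
  int sub_size;
  // lookup tables, one per size k = 2..5
  const int* glid[6];
  const int* orbtab[6];          // column-major (2^C(k,2) x k)
  int orbrows[6];
  std::vector<double> counts;    // per graphlet
  std::vector<double> orbits;    // column-major n x n_orbits

  bool edge(int a, int b) const { return amat[(size_t)a * n + b] != 0; }

  void record() {
    int k = sub_size;
    int s[5];
    std::copy(sub, sub + k, s);
    std::sort(s, s + k);
    int mask = 0, bit = 0;
    for (int i = 0; i + 1 < k; ++i)
      for (int j = i + 1; j < k; ++j) {
        if (edge(s[i], s[j])) mask |= (1 << bit);
        ++bit;
      }
    int gid = glid[k][mask];
    counts[gid] += 1.0;
    const int* ot = orbtab[k];
    int rows = orbrows[k];
    for (int p = 0; p < k; ++p) {
      int orb = ot[(size_t)p * rows + mask];
      orbits[(size_t)orb * n + s[p]] += 1.0;
    }
  }

  void extend(std::vector<int>& ext, int v) {
    if (sub_size >= 2) record();
    if (sub_size == 5) return;
    // Each candidate is removed before recursing so no subset repeats.
    while (!ext.empty()) {
      int w = ext.back();
      ext.pop_back();
      sub[sub_size++] = w;
      std::vector<int> newly;
      for (int u : (*adj)[w]) {
        if (u > v && !marked[u]) {
          marked[u] = 1;
          newly.push_back(u);
        }
      }
      std::vector<int> ext2(ext);
      ext2.insert(ext2.end(), newly.begin(), newly.end());
      extend(ext2, v);
      for (int u : newly) marked[u] = 0;
      --sub_size;
    }
  }

  void run() {
    for (int v = 0; v < n; ++v) {
      std::fill(marked.begin(), marked.end(), 0);
      marked[v] = 1;
      std::vector<int> ext;
      for (int u : (*adj)[v]) {
        if (u > v) {
          marked[u] = 1;
          ext.push_back(u);
        }
      }
      sub[0] = v;
      sub_size = 1;
      extend(ext, v);
    }
  }
};

} // namespace

// [[Rcpp::export]]
List esu_count_cpp(int n, List adj0, List glid, List orbtab,
                   int n_graphlets, int n_orbits) {
  std::vector<std::vector<int>> adj(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adj0[i];
    adj[i].assign(nb.begin(), nb.end());
  }

  Esu e;
  e.n = n;
  e.adj = &adj;
  e.amat.assign((size_t)n * n, 0);
  for (int i = 0; i < n; ++i)
    for (int u : adj[i]) e.amat[(size_t)i * n + u] = 1;
  e.marked.assign(n, 0);
  e.counts.assign(n_graphlets, 0.0);
  e.orbits.assign((size_t)n * n_orbits, 0.0);

  std::vector<IntegerVector> glv, otv;
  for (int k = 2; k <= 5; ++k) {
    glv.push_back(as<IntegerVector>(glid[k - 2]));
    otv.push_back(as<IntegerVector>(orbtab[k - 2]));
    e.glid[k] = glv.back().begin();
    e.orbtab[k] = otv.back().begin();
    e.orbrows[k] = glv.back().size();
  }

  e.run();

  NumericVector counts(e.counts.begin(), e.counts.end());
  NumericMatrix orbits(n, n_orbits);
  std::copy(e.orbits.begin(), e.orbits.end(), orbits.begin());
  return List::create(_["counts"] = counts, _["orbits"] = orbits);
}
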