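#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Enumerates every connected induced subgraph on 2..max_size vertices exactly
// once (Wernicke's ESU scheme) and bins each occurrence, per touched vertex,
// by (automorphism orbit, set of node colors present) -- or set of edge
// colors when by_edge is true. Orbit resolution is O(1) per occurrence via a
// precomputed table: the induced adjacency bitmask over the visit-ordered
// vertices indexes a (labeled graph -> global orbit per position) matrix
// supplied from R.

namespace {

struct Counter {
  int n, max_size, ncomb, norb;
  const std::vector<std::vector<int>>* nbr;
  const std::vector<std::vector<int>>* nbrcol; // edge color parallel to nbr
  const std::vector<int>* ncol;                // node color bit (1<<c)
  bool by_edge;
  std::vector<const int*> lut;                 // per size s: column-major 2^C(s,2) x s
  std::vector<int> lutrows;
  double* counts;                              // n x (norb*ncomb), column-major
  std::vector<char> nbh;                       // in sub or N(sub)
  int vs[6];
  int amask[7];
  int cmask[7];

  void count_at(int t) {
    // sub holds t vertices, t >= 2
    const int* tab = lut[t];
    int rows = lutrows[t];
    int am = amask[t];
    int comb = cmask[t] - 1;
    for (int pos = 0; pos < t; ++pos) {
      int orb = tab[am + rows * pos];
      // ESU only yields connected subsets; orb >= 0 always
      long long col = (long long)orb * ncomb + comb;
      counts[vs[pos] + (long long)n * col] += 1.0;
    }
  }

  bool adj_in_sub(int w, int t, int& add_amask, int& add_ecmask) {
    // adjacency bits of w against vs[0..t-1]; w takes position t
    add_amask = 0;
    add_ecmask = 0;
    const std::vector<int>& nw = (*nbr)[w];
    const std::vector<int>& cw = (*nbrcol)[w];
    for (int i = 0; i < t; ++i) {
      int x = vs[i];
      // binary search x in nbr[w]
      size_t lo = 0, hi = nw.size();
      while (lo < hi) {
        size_t mid = (lo + hi) / 2;
        if (nw[mid] < x) lo = mid + 1; else hi = mid;
      }
      if (lo < nw.size() && nw[lo] == x) {
        add_amask |= 1 << (t * (t - 1) / 2 + i);
        if (by_edge) add_ecmask |= cw[lo];
      }
    }
    return add_amask != 0;
  }

  void extend(std::vector<int> ext, int t, int root) {
    while (!ext.empty()) {
      int w = ext.back();
      ext.pop_back();
      int aadd, eadd;
      adj_in_sub(w, t, aadd, eadd);
      vs[t] = w;
      amask[t + 1] = amask[t] | aadd;
      cmask[t + 1] = cmask[t] | (by_edge ? eadd : (*ncol)[w]);
      count_at(t + 1);
      if (t + 1 < max_size) {
        std::vector<int> ext2(ext);
        std::vector<int> marked;
        const std::vector<int>& nw = (*nbr)[w];
        for (int u : nw) {
          if (u > root && !nbh[u]) {
            ext2.push_back(u);
            nbh[u] = 1;
            marked.push_back(u);
          }
        }
        nbh[w] = 1; // w now in sub (it already was in N(sub), keep marked)
        extend(std::move(ext2), t + 1, root);
        for (int u : marked) nbh[u] = 0;
      }
    }
  }

  void run() {
    for (int v = 0; v < n; ++v) {
      vs[0] = v;
      amask[0] = 0; amask[1] = 0;
      cmask[0] = 0;
      cmask[1] = by_edge ? 0 : (*ncol)[v];
      std::fill(nbh.begin(), nbh.end(), 0);
      nbh[v] = 1;
      std::vector<int> ext;
      for (int u : (*nbr)[v]) {
        nbh[u] = 1;
        if (u > v) ext.push_back(u);
      }
      extend(std::move(ext), 1, v);
    }
  }
};

} // namespace

// [[Rcpp::export]]
NumericMatrix count_signatures_cpp(int n, IntegerMatrix edges,
                                   IntegerVector node_color,
                                   IntegerVector edge_color,
                                   List lookup, int max_size, int n_orbits,
                                   int k, bool by_edge) {
  int m = edges.nrow();
  std::vector<std::vector<int>> nbr(n), nbrcol(n);
  std::vector<std::pair<int, int>> tmp;
  for (int e = 0; e < m; ++e) {
    int a = edges(e, 0), b = edges(e, 1);
    int cb = by_edge ? (1 << edge_color[e]) : 0;
    nbr[a].push_back(b); nbrcol[a].push_back(cb);
    nbr[b].push_back(a); nbrcol[b].push_back(cb);
  }
  for (int v = 0; v < n; ++v) {
    // co-sort neighbor + color arrays
    std::vector<size_t> idx(nbr[v].size());
    for (size_t i = 0; i < idx.size(); ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(),
              [&](size_t a, size_t b) { return nbr[v][a] < nbr[v][b]; });
    std::vector<int> sn(idx.size()), sc(idx.size());
    for (size_t i = 0; i < idx.size(); ++i) {
      sn[i] = nbr[v][idx[i]];
      sc[i] = nbrcol[v][idx[i]];
    }
    nbr[v] = std::move(sn);
    nbrcol[v] = std::move(sc);
  }
  std::vector<int> ncolbit(n);
  for (int v = 0; v < n; ++v) ncolbit[v] = 1 << node_color[v];

  int ncomb = (1 << k) - 1;
  NumericMatrix out(n, n_orbits * ncomb);

  Counter C;
  C.n = n; C.max_size = max_size; C.ncomb = ncomb; C.norb = n_orbits;
  C.nbr = &nbr; C.nbrcol = &nbrcol; C.ncol = &ncolbit; C.by_edge = by_edge;
  C.lut.assign(max_size + 1, nullptr);
  C.lutrows.assign(max_size + 1, 0);
  std::vector<IntegerMatrix> keep;
  for (int s = 2; s <= max_size; ++s) {
    IntegerMatrix tab = lookup[s - 1];
    keep.push_back(tab);
    C.lut[s] = INTEGER(tab);
    C.lutrows[s] = tab.nrow();
  }
  C.counts = REAL(out);
  C.nbh.assign(n, 0);
  C.run();
  return out;
}
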