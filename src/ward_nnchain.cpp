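#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Ward agglomeration by the nearest-neighbour chain algorithm, computed
// directly on the feature matrix. Working memory is O(N*d): no pairwise
// distance matrix is ever materialized. Heights follow the ward.D2
// convention: h(i,j) = sqrt(2 * ni*nj/(ni+nj)) * ||ci - cj||, so the merge
// of two singletons sits at their Euclidean distance.

struct MergeRec {
  int a, b;        // chain labels of merged clusters
  double height;
  int order;       // emission order (stable tie-break)
};

// Ward merge cost surrogate (monotone in the true SSE increment)
static inline double ward_h2(const std::vector<double>& cent, int d,
                             int i, int j,
                             const std::vector<double>& size) {
  double ss = 0.0;
  const double* ci = &cent[(size_t)i * d];
  const double* cj = &cent[(size_t)j * d];
  for (int k = 0; k < d; ++k) {
    double diff = ci[k] - cj[k];
    ss += diff * diff;
  }
  double ni = size[i], nj = size[j];
  return 2.0 * ni * nj / (ni + nj) * ss;
}

// [[Rcpp::export(name = ".ward_nnchain_cpp")]]
List ward_nnchain_cpp(NumericMatrix x) {
  const int n = x.nrow(), d = x.ncol();
  if (n < 2) stop("need at least 2 observations");

  // centroids for up to 2n-1 clusters (singletons + merges)
  std::vector<double> cent((size_t)(2 * n - 1) * d);
  std::vector<double> size(2 * n - 1, 0.0);
  std::vector<bool> active(2 * n - 1, false);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < d; ++k) cent[(size_t)i * d + k] = x(i, k);
    size[i] = 1.0;
    active[i] = true;
  }

  std::vector<int> act;            // currently active cluster labels
  act.reserve(n);
  for (int i = 0; i < n; ++i) act.push_back(i);

  std::vector<int> chain;
  chain.reserve(n);
  std::vector<MergeRec> merges;
  merges.reserve(n - 1);
  int next_label = n;

  while ((int)act.size() > 1) {
    if (chain.empty()) chain.push_back(act[0]);
    for (;;) {
      int tip = chain.back();
      int prev = chain.size() >= 2 ? chain[chain.size() - 2] : -1;
      // nearest active neighbour of tip; prefer prev on ties (reciprocity)
      double best = R_PosInf;
      int who = -1;
      if (prev >= 0) { best = ward_h2(cent, d, tip, prev, size); who = prev; }
      for (int idx = 0; idx < (int)act.size(); ++idx) {
        int c = act[idx];
        if (c == tip || c == prev) continue;
        double h2 = ward_h2(cent, d, tip, c, size);
        if (h2 < best) { best = h2; who = c; }
      }
      if (who == prev && prev >= 0) {
        // reciprocal nearest neighbours: merge tip and prev
        MergeRec m;
        m.a = prev; m.b = tip;
        m.height = std::sqrt(best);
        m.order = (int)merges.size();
        merges.push_back(m);
        chain.pop_back();
        chain.pop_back();
        // new cluster
        int nl = next_label++;
        double na = size[m.a], nb = size[m.b];
        for (int k = 0; k < d; ++k)
          cent[(size_t)nl * d + k] =
            (na * cent[(size_t)m.a * d + k] + nb * cent[(size_t)m.b * d + k]) /
            (na + nb);
        size[nl] = na + nb;
        active[m.a] = active[m.b] = false;
        active[nl] = true;
        act.erase(std::remove_if(act.begin(), act.end(),
                                 [&](int c) { return c == m.a || c == m.b; }),
                  act.end());
        act.push_back(nl);
        break;
      }
      chain.push_back(who);
    }
  }

  // sort merges by height (stable: children precede parents at ties because
  // they were emitted earlier)
  std::stable_sort(merges.begin(), merges.end(),
                   [](const MergeRec& u, const MergeRec& v) {
                     return u.height < v.height;
                   });

  // relabel into hclust convention: negative = singleton observation (1-based),
  // positive = row index of an earlier merge
  std::vector<int> node_of(2 * n - 1, 0);  // chain label -> hclust code
  for (int i = 0; i < n; ++i) node_of[i] = -(i + 1);
  // chain label of the cluster created by emission-order o is n + o
  std::vector<int> row_of_emission(n - 1, 0);
  IntegerMatrix merge(n - 1, 2);
  NumericVector height(n - 1);
  for (int r = 0; r < n - 1; ++r) {
    const MergeRec& m = merges[r];
    int ca = node_of[m.a], cb = node_of[m.b];
    if (ca > cb) std::swap(ca, cb);  // hclust orders singletons first/neg asc
    merge(r, 0) = ca;
    merge(r, 1) = cb;
    height[r] = m.height;
    node_of[n + m.order] = r + 1;
  }
  return List::create(_["merge"] = merge, _["height"] = height);
}

// 8-connected component labelling of a logical matrix, two-pass union-find.
// [[Rcpp::export(name = ".label8_cpp")]]
IntegerMatrix label8_cpp(LogicalMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);  // parent[0] unused
  auto find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!m(i, j)) continue;
      int best = 0;
      // neighbours already visited in column-major order:
      // (i-1, j), (i-1, j-1), (i, j-1), (i+1, j-1)
      const int di[4] = {-1, -1, 0, 1};
      const int dj[4] = {0, -1, -1, -1};
      for (int t = 0; t < 4; ++t) {
        int ii = i + di[t], jj = j + dj[t];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        int l = lab(ii, jj);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(best, l);
        }
      }
      if (best == 0) {
        best = ++next;
        parent.push_back(best);
      }
      lab(i, j) = best;
    }
  }
  // second pass: flatten and renumber compactly
  std::vector<int> newid(next + 1, 0);
  int k = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) > 0) {
        int r = find(lab(i, j));
        if (newid[r] == 0) newid[r] = ++k;
        lab(i, j) = newid[r];
      }
  return lab;
}
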