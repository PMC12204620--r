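#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Best axis-aligned split for a CART node.
//
// X:     n x p feature matrix (full data; rows addressed through idx)
// y:     response; class in {0,1} when classify = true, else numeric
// idx:   0-based row indices of the samples in this node
// feats: 0-based column indices of the candidate features (mtry subset)
// min_leaf: minimum number of samples allowed in each child
//
// Returns feature = -1 when no split improves the node impurity.
// Classification uses the Gini impurity decrease, regression the decrease in
// the sum of squared errors.  Thresholds are midpoints between consecutive
// distinct values, ties in gain resolved in favour of the first (lowest
// feature index, lowest threshold) candidate so trees are deterministic.
// [[Rcpp::export]]
List cpp_best_split(NumericMatrix X, NumericVector y, IntegerVector idx,
                    IntegerVector feats, int min_leaf, bool classify) {
  const int n = idx.size();
  int best_feat = -1;
  double best_gain = 1e-12, best_thr = NA_REAL;

  std::vector<double> v(n), yy(n);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) yy[i] = y[idx[i]];

  double parent_imp;
  if (classify) {
    double n1 = 0.0;
    for (int i = 0; i < n; ++i) n1 += yy[i];
    const double p1 = n1 / n;
    parent_imp = n * 2.0 * p1 * (1.0 - p1);
  } else {
    double s = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) { s += yy[i]; s2 += yy[i] * yy[i]; }
    parent_imp = s2 - s * s / n;
  }

  for (int fi = 0; fi < feats.size(); ++fi) {
    const int f = feats[fi];
    for (int i = 0; i < n; ++i) { v[i] = X(idx[i], f); ord[i] = i; }
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return v[a] < v[b]; });

    double ls = 0.0, ls2 = 0.0;                 // left sums
    double ts = 0.0, ts2 = 0.0;                 // totals
    for (int i = 0; i < n; ++i) { ts += yy[i]; ts2 += yy[i] * yy[i]; }

    for (int i = 0; i < n - 1; ++i) {
      const double yi = yy[ord[i]];
      ls += yi; ls2 += yi * yi;
      const int nl = i + 1, nr = n - nl;
      if (nl < min_leaf) continue;
      if (nr < min_leaf) break;
      const double vl = v[ord[i]], vr = v[ord[i + 1]];
      if (vr <= vl) continue;                   // tied values: not a cut point

      double child_imp;
      if (classify) {
        const double pl = ls / nl, pr = (ts - ls) / nr;
        child_imp = nl * 2.0 * pl * (1.0 - pl) + nr * 2.0 * pr * (1.0 - pr);
      } else {
        const double rs = ts - ls, rs2 = ts2 - ls2;
        child_imp = (ls2 - ls * ls / nl) + (rs2 - rs * rs / nr);
      }
      const double gain = parent_imp - child_imp;
      if (gain > best_gain) {
        best_gain = gain;
        best_feat = f;
        best_thr = (vl + vr) / 2.0;
      }
    }
  }

  return List::create(_["feature"] = best_feat,
                      _["threshold"] = best_thr,
                      _["gain"] = best_gain);
}

// Label connected components of a binary mask with 8-connectivity.
// Two-pass union-find; labels are dense from 1, background 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);               // parent[0] unused

  auto find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };

  // scan column-major; neighbours already visited under that order
  const int dr[4] = {-1, -1, 0, 1};
  const int dc[4] = {0, -1, -1, -1};
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int lbl = 0;
      for (int k = 0; k < 4; ++k) {
        const int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0) continue;
        const int nl = lab(rr, cc);
        if (nl > 0) {
          if (lbl == 0) lbl = nl;
          else unite(lbl, nl);
        }
      }
      if (lbl == 0) {
        lbl = parent.size();
        parent.push_back(lbl);
      }
      lab(r, c) = lbl;
    }
  }

  // flatten and relabel densely
  std::vector<int> dense(parent.size(), 0);
  int next = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) > 0) {
        const int root = find(lab(r, c));
        if (dense[root] == 0) dense[root] = ++next;
        lab(r, c) = dense[root];
      }
  return lab;
}
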