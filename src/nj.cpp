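#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Canonical neighbor joining on a symmetric distance matrix.
// Ties in the Q criterion are broken by the smallest (i, j) index pair
// (lexicographic over current active-node order); negative branch-length
// estimates are clamped to zero. Joins are reported with node ids
// 1..n for leaves and n+1, n+2, ... for internal nodes in creation order;
// the last row is the final three-way join onto the basal node.
// [[Rcpp::export]]
List nj_joins(NumericMatrix d) {
  const int n = d.nrow();
  if (n < 3) stop("neighbor joining needs at least 3 taxa");
  std::vector<int> id(n);
  std::vector<bool> alive(n, true);
  std::vector<std::vector<double> > D(n, std::vector<double>(n));
  for (int i = 0; i < n; ++i) {
    id[i] = i + 1;
    for (int j = 0; j < n; ++j) D[i][j] = d(i, j);
  }
  int n_act = n, next_id = n + 1;
  const int n_join = n - 3;
  IntegerMatrix joins(n_join, 3);   // child_a, child_b, parent
  NumericMatrix jlen(n_join, 2);
  std::vector<double> r(n);
  for (int step = 0; step < n_join; ++step) {
    for (int i = 0; i < n; ++i) {
      if (!alive[i]) continue;
      double s = 0;
      for (int j = 0; j < n; ++j) if (alive[j]) s += D[i][j];
      r[i] = s;
    }
    double qmin = R_PosInf; int bi = -1, bj = -1;
    for (int i = 0; i < n; ++i) {
      if (!alive[i]) continue;
      for (int j = i + 1; j < n; ++j) {
        if (!alive[j]) continue;
        double q = (n_act - 2) * D[i][j] - r[i] - r[j];
        if (q < qmin) { qmin = q; bi = i; bj = j; }
      }
    }
    double li = 0.5 * D[bi][bj] + (r[bi] - r[bj]) / (2.0 * (n_act - 2));
    double lj = D[bi][bj] - li;
    if (li < 0) li = 0;
    if (lj < 0) lj = 0;
    joins(step, 0) = id[bi]; joins(step, 1) = id[bj]; joins(step, 2) = next_id;
    jlen(step, 0) = li; jlen(step, 1) = lj;
    // new node replaces slot bi
    for (int k = 0; k < n; ++k) {
      if (!alive[k] || k == bi || k == bj) continue;
      D[bi][k] = D[k][bi] = 0.5 * (D[bi][k] + D[bj][k] - D[bi][bj]);
    }
    D[bi][bi] = 0;
    alive[bj] = false;
    id[bi] = next_id++;
    --n_act;
  }
  // final three active nodes join at the basal trifurcation
  std::vector<int> rest;
  for (int i = 0; i < n; ++i) if (alive[i]) rest.push_back(i);
  int a = rest[0], b = rest[1], c = rest[2];
  double la = 0.5 * (D[a][b] + D[a][c] - D[b][c]);
  double lb = 0.5 * (D[a][b] + D[b][c] - D[a][c]);
  double lc = 0.5 * (D[a][c] + D[b][c] - D[a][b]);
  if (la < 0) la = 0;
  if (lb < 0) lb = 0;
  if (lc < 0) lc = 0;
  return List::create(
    _["joins"] = joins, _["lengths"] = jlen,
    _["final_ids"] = IntegerVector::create(id[a], id[b], id[c]),
    _["final_lengths"] = NumericVector::create(la, lb, lc),
    _["basal_id"] = next_id);
}
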