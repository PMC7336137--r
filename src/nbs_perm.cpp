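// Permutation engine for the network-based statistic: pooled-variance
// two-sample t per edge for each group-label permutation, primary
// thresholding, and the maximum connected-component extent (edge count)
// via union-find. Only the per-permutation maxima are returned; the
// observed statistics are computed in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

namespace {

int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// max component extent of the edges listed in `which_edges`
int max_extent(const std::vector<int>& which_edges,
               const arma::imat& pairs, int n_nodes) {
  const int m = static_cast<int>(which_edges.size());
  if (m <= 1) return m;
  std::vector<int> parent(n_nodes);
  for (int i = 0; i < n_nodes; ++i) parent[i] = i;
  for (int e : which_edges) {
    int a = uf_find(parent, pairs(e, 0) - 1);
    int b = uf_find(parent, pairs(e, 1) - 1);
    if (a != b) parent[b] = a;
  }
  std::vector<int> count(n_nodes, 0);
  int best = 0;
  for (int e : which_edges) {
    int r = uf_find(parent, pairs(e, 0) - 1);
    if (++count[r] > best) best = count[r];
  }
  return best;
}

}  // namespace

// [[Rcpp::export(name = ".nbs_null_max_extents")]]
Rcpp::IntegerMatrix nbs_null_max_extents(const arma::mat& x,
                                         const arma::imat& perm_idx,
                                         const arma::imat& pairs,
                                         int n_nodes,
                                         int n_a, int n_b,
                                         double threshold) {
  const int n = x.n_rows;
  const arma::uword n_edges = x.n_cols;
  const int n_perm = perm_idx.n_cols;
  const double inv_na = 1.0 / n_a, inv_nb = 1.0 / n_b;
  const double c_se = inv_na + inv_nb;
  const double df = n_a + n_b - 2.0;

  arma::rowvec tot1 = arma::sum(x, 0);
  arma::rowvec tot2 = arma::sum(arma::square(x), 0);

  Rcpp::IntegerMatrix out(n_perm, 2);  // col 0: t > thr, col 1: -t > thr
  arma::vec g(n);
  std::vector<int> pos_edges, neg_edges;

  for (int p = 0; p < n_perm; ++p) {
    g.zeros();
    for (int k = 0; k < n_a; ++k) g(perm_idx(k, p) - 1) = 1.0;
    arma::rowvec s1 = g.t() * x;  // group-A sums per edge
    pos_edges.clear();
    neg_edges.clear();
    for (arma::uword e = 0; e < n_edges; ++e) {
      const double sa = s1(e);
      const double sb = tot1(e) - sa;
      const double num = sa * inv_na - sb * inv_nb;
      const double ss = tot2(e) - sa * sa * inv_na - sb * sb * inv_nb;
      double t;
      if (ss <= 0.0) {
        t = (num == 0.0) ? 0.0 : (num > 0 ? 1e10 : -1e10);
      } else {
        t = num / std::sqrt(ss / df * c_se);
      }
      if (t > threshold) pos_edges.push_back(static_cast<int>(e));
      else if (-t > threshold) neg_edges.push_back(static_cast<int>(e));
    }
    out(p, 0) = max_extent(pos_edges, pairs, n_nodes);
    out(p, 1) = max_extent(neg_edges, pairs, n_nodes);
  }
  return out;
}
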