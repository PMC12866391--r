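// Dense Markov-clustering kernel: expansion (BLAS matrix square) followed
// by a fused inflation / pruning / column-normalization pass, tracking the
// maximum entry change against the previous and the second-previous
// iterate (period-two limit cycles count as converged).  After each
// iteration a union-find pass over the support detects when pruning has
// cut the block into disconnected sub-blocks, which the caller then
// iterates independently (MCL flow is block diagonal, so this is exact).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>

namespace {

int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[rb] = ra;
}

}  // namespace

// Run up to `steps` MCL iterations on a column-stochastic dense matrix.
// Returns the current matrix, the iterations done, a convergence flag and
// the support-component membership (all 1s while connected).
// [[Rcpp::export(name = ".mcl_dense_steps")]]
Rcpp::List mcl_dense_steps(arma::mat M, double granularity, int steps,
                           double prune_eps, double tol) {
  arma::mat Mp2;
  bool have_p2 = false, converged = false;
  int done = 0;
  const arma::uword n = M.n_cols;
  std::vector<int> parent(n);
  arma::ivec membership(n, arma::fill::ones);
  bool split = false;
  while (done < steps && !split) {
    ++done;
    arma::mat M2 = M * M;  // expansion
    for (arma::uword j = 0; j < n; ++j) {
      double *col = M2.colptr(j);
      double s = 0.0;
      for (arma::uword i = 0; i < n; ++i) {
        double v = col[i];
        if (v > 0.0) {
          v = std::pow(v, granularity);  // inflation
          if (v < prune_eps) v = 0.0;    // pruning
        } else {
          v = 0.0;
        }
        col[i] = v;
        s += v;
      }
      const double inv = 1.0 / s;
      for (arma::uword i = 0; i < n; ++i) col[i] *= inv;
    }
    const double d1 = arma::abs(M2 - M).max();
    const double d2 = have_p2 ? arma::abs(M2 - Mp2).max() : arma::datum::inf;
    Mp2 = std::move(M);
    have_p2 = true;
    M = std::move(M2);
    if (d1 < tol || d2 < tol) {
      converged = true;
      break;
    }
    // weak components of the support via union-find
    for (arma::uword i = 0; i < n; ++i) parent[i] = static_cast<int>(i);
    for (arma::uword j = 0; j < n; ++j) {
      const double *col = M.colptr(j);
      for (arma::uword i = 0; i < n; ++i) {
        if (col[i] != 0.0 && i != j) {
          uf_union(parent, static_cast<int>(j), static_cast<int>(i));
        }
      }
    }
    int n_comp = 0;
    std::vector<int> label(n, -1);
    for (arma::uword i = 0; i < n; ++i) {
      int r = uf_find(parent, static_cast<int>(i));
      if (label[r] < 0) label[r] = n_comp++;
      membership[i] = label[r] + 1;
    }
    split = n_comp > 1;
  }
  return Rcpp::List::create(Rcpp::Named("M") = M,
                            Rcpp::Named("done") = done,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("split") = split,
                            Rcpp::Named("membership") = membership);
}
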