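#include <Rcpp.h>
using namespace Rcpp;

// L1 (city-block) primitives used by the SPADE-style clustering stage.
// Densities and nearest-median assignment are O(n^2) / O(n*k); early
// abandoning on the partial sum keeps the constant small on wide panels.

// [[Rcpp::export]]
NumericVector cpp_l1_density(NumericMatrix X, double radius) {
  const int n = X.nrow(), d = X.ncol();
  NumericVector cnt(n, 1.0); // each cell counts itself
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int m = 0; m < d; ++m) {
        s += std::fabs(X(i, m) - X(j, m));
        if (s > radius) break;
      }
      if (s <= radius) { cnt[i] += 1.0; cnt[j] += 1.0; }
    }
  }
  return cnt;
}

// Nearest-neighbour L1 distance of every row to any other row.
// [[Rcpp::export]]
NumericVector cpp_l1_nn_dist(NumericMatrix X) {
  const int n = X.nrow(), d = X.ncol();
  NumericVector best(n, R_PosInf);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double cap = std::max(best[i], best[j]);
      double s = 0.0;
      for (int m = 0; m < d; ++m) {
        s += std::fabs(X(i, m) - X(j, m));
        if (s > cap) break;
      }
      if (s < best[i]) best[i] = s;
      if (s < best[j]) best[j] = s;
    }
  }
  return best;
}

// Assign each row of X to the nearest row of M under L1 distance.
// Ties resolve to the lower row index of M (strict < keeps the first hit).
// [[Rcpp::export]]
IntegerVector cpp_l1_nn_assign(NumericMatrix X, NumericMatrix M) {
  const int n = X.nrow(), k = M.nrow(), d = X.ncol();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int arg = 0;
    for (int c = 0; c < k; ++c) {
      double s = 0.0;
      for (int m = 0; m < d; ++m) {
        s += std::fabs(X(i, m) - M(c, m));
        if (s >= best) break;
      }
      if (s < best) { best = s; arg = c; }
    }
    out[i] = arg + 1;
  }
  return out;
}
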