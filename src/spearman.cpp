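#include <Rcpp.h>
using namespace Rcpp;

// Exact null distribution of Spearman's S = sum (rank difference)^2 under
// the hypothesis of independence: enumerate all n! rank permutations
// (Heap's algorithm) and tally S. Feasible for n <= 10 (10! = 3,628,800).
// Returns counts[s] = number of permutations with S == s, s = 0..2*binom(n+1,3).

// [[Rcpp::export]]
NumericVector cpp_spearman_s_counts(int n) {
  if (n < 2 || n > 10) stop("exact Spearman null enumerated only for 2 <= n <= 10");
  const int smax = n * (n * n - 1) / 3;
  NumericVector counts(smax + 1, 0.0);
  std::vector<int> p(n), c(n, 0);
  for (int i = 0; i < n; ++i) p[i] = i + 1;
  auto tally = [&]() {
    int s = 0;
    for (int i = 0; i < n; ++i) { int d = p[i] - (i + 1); s += d * d; }
    counts[s] += 1.0;
  };
  tally();
  int i = 0;
  while (i < n) {
    if (c[i] < i) {
      if (i % 2 == 0) std::swap(p[0], p[i]); else std::swap(p[c[i]], p[i]);
      tally();
      c[i]++; i = 0;
    } else { c[i] = 0; ++i; }
  }
  return counts;
}
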