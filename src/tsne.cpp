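#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

// Exact-gradient t-SNE (Gaussian input affinities with per-point perplexity
// calibration, Student-t output kernel, momentum + adaptive gains, early
// exaggeration). O(n^2) per iteration, intended for the moderate per-sample
// subsamples this pipeline embeds.

static void perplexity_calibrate(const std::vector<double>& D2, int n,
                                 double perplexity, std::vector<double>& P) {
  const double logU = std::log(perplexity);
  for (int i = 0; i < n; ++i) {
    double beta = 1.0, betamin = -1e30, betamax = 1e30;
    double sumP = 0.0, H = 0.0;
    for (int it = 0; it < 60; ++it) {
      sumP = 0.0; H = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) { P[(size_t)i * n + j] = 0.0; continue; }
        double pj = std::exp(-beta * D2[(size_t)i * n + j]);
        P[(size_t)i * n + j] = pj;
        sumP += pj;
        H += beta * D2[(size_t)i * n + j] * pj;
      }
      if (sumP <= 0) sumP = 1e-12;
      H = H / sumP + std::log(sumP);
      double diff = H - logU;
      if (std::fabs(diff) < 1e-5) break;
      if (diff > 0) { betamin = beta; beta = (betamax > 1e29) ? beta * 2 : (beta + betamax) / 2; }
      else          { betamax = beta; beta = (betamin < -1e29) ? beta / 2 : (beta + betamin) / 2; }
    }
    for (int j = 0; j < n; ++j) P[(size_t)i * n + j] /= sumP;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_tsne(NumericMatrix X, double perplexity, int max_iter,
                       double eta, int seed) {
  const int n = X.nrow(), d = X.ncol();
  if (n - 1 < 3 * perplexity) stop("perplexity too large for the number of cells");
  std::vector<double> D2((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int m = 0; m < d; ++m) { double df = X(i, m) - X(j, m); s += df * df; }
      D2[(size_t)i * n + j] = s; D2[(size_t)j * n + i] = s;
    }
  std::vector<double> P((size_t)n * n, 0.0);
  perplexity_calibrate(D2, n, perplexity, P);
  // symmetrize
  double psum = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double v = (P[(size_t)i * n + j] + P[(size_t)j * n + i]) / 2.0;
      P[(size_t)i * n + j] = v; P[(size_t)j * n + i] = v; psum += 2.0 * v;
    }
  for (size_t t = 0; t < P.size(); ++t) P[t] = std::max(P[t] / psum, 1e-12);

  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<double> norm(0.0, 1e-4);
  std::vector<double> Y(2 * (size_t)n), dY(2 * (size_t)n, 0.0),
      gains(2 * (size_t)n, 1.0), uY(2 * (size_t)n, 0.0);
  for (size_t t = 0; t < Y.size(); ++t) Y[t] = norm(rng);

  const int lying_end = std::min(250, max_iter / 4);
  const double exaggeration = 12.0;
  for (size_t t = 0; t < P.size(); ++t) P[t] *= exaggeration;

  std::vector<double> Qnum((size_t)n * n, 0.0);
  for (int iter = 0; iter < max_iter; ++iter) {
    double qsum = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = Y[2 * (size_t)i] - Y[2 * (size_t)j];
        double dy = Y[2 * (size_t)i + 1] - Y[2 * (size_t)j + 1];
        double q = 1.0 / (1.0 + dx * dx + dy * dy);
        Qnum[(size_t)i * n + j] = q; Qnum[(size_t)j * n + i] = q;
        qsum += 2.0 * q;
      }
    for (int i = 0; i < n; ++i) {
      double gx = 0.0, gy = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double q = Qnum[(size_t)i * n + j];
        double mult = (P[(size_t)i * n + j] - q / qsum) * q;
        gx += mult * (Y[2 * (size_t)i] - Y[2 * (size_t)j]);
        gy += mult * (Y[2 * (size_t)i + 1] - Y[2 * (size_t)j + 1]);
      }
      dY[2 * (size_t)i] = 4.0 * gx; dY[2 * (size_t)i + 1] = 4.0 * gy;
    }
    double momentum = (iter < 250) ? 0.5 : 0.8;
    for (size_t t = 0; t < Y.size(); ++t) {
      gains[t] = ((dY[t] > 0) != (uY[t] > 0)) ? gains[t] + 0.2 : gains[t] * 0.8;
      if (gains[t] < 0.01) gains[t] = 0.01;
      uY[t] = momentum * uY[t] - eta * gains[t] * dY[t];
      Y[t] += uY[t];
    }
    if (iter == lying_end)
      for (size_t t = 0; t < P.size(); ++t) P[t] /= exaggeration;
  }
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = Y[2 * (size_t)i]; out(i, 1) = Y[2 * (size_t)i + 1]; }
  return out;
}
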