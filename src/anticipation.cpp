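#include <Rcpp.h>
using namespace Rcpp;

// Discounted-count learner along a node sequence.
// Maintains per-node history weights w[a] = sum_{s<=t, x_s=a} exp(-beta (t-s))
// recursively; each observed transition deposits unit mass (weights divided
// by their sum) into the count matrix column of the incoming node.

// [[Rcpp::export]]
NumericVector anticipation_cpp(IntegerVector x, double beta, int n) {
  int T = x.size();
  NumericVector a(T, NA_REAL);
  std::vector<double> counts((size_t)n * n, 0.0);
  std::vector<double> rowsum(n, 0.0);
  std::vector<double> w(n, 0.0);
  double decay = std::exp(-beta), Z = 1.0;
  w[x[0] - 1] = 1.0;
  for (int t = 1; t < T; ++t) {
    int prev = x[t - 1] - 1, cur = x[t] - 1;
    double rs = rowsum[prev];
    a[t] = rs > 0 ? counts[(size_t)prev * n + cur] / rs : 1.0 / n;
    for (int k = 0; k < n; ++k) {
      double inc = w[k] / Z;
      counts[(size_t)k * n + cur] += inc;
      rowsum[k] += inc;
      w[k] *= decay;
    }
    w[cur] += 1.0;
    Z = Z * decay + 1.0;
  }
  return a;
}

// Final discounted-count matrix after the full sequence (row-major fill of
// an R matrix via index arithmetic below).

// [[Rcpp::export]]
NumericMatrix run_counts_cpp(IntegerVector x, double beta, int n) {
  int T = x.size();
  NumericMatrix counts(n, n);
  std::vector<double> w(n, 0.0);
  double decay = std::exp(-beta), Z = 1.0;
  w[x[0] - 1] = 1.0;
  for (int t = 1; t < T; ++t) {
    int cur = x[t] - 1;
    for (int k = 0; k < n; ++k) {
      counts(k, cur) += w[k] / Z;
      w[k] *= decay;
    }
    w[cur] += 1.0;
    Z = Z * decay + 1.0;
  }
  return counts;
}

// Per-trial correlation between the lower triangle of the running
// finite-time estimate and a target lower triangle (the analytic map).

// [[Rcpp::export]]
NumericVector convergence_cpp(IntegerVector x, double beta, int n,
                              NumericVector target_lt) {
  int T = x.size();
  NumericVector out(T, NA_REAL);
  std::vector<double> counts((size_t)n * n, 0.0);
  std::vector<double> rowsum(n, 0.0);
  std::vector<double> w(n, 0.0);
  double decay = std::exp(-beta), Z = 1.0;
  w[x[0] - 1] = 1.0;
  int m = target_lt.size();
  double ty = 0, tyy = 0;
  for (int i = 0; i < m; ++i) { ty += target_lt[i]; tyy += target_lt[i] * target_lt[i]; }
  for (int t = 1; t < T; ++t) {
    int cur = x[t] - 1;
    for (int k = 0; k < n; ++k) {
      double inc = w[k] / Z;
      counts[(size_t)k * n + cur] += inc;
      rowsum[k] += inc;
      w[k] *= decay;
    }
    w[cur] += 1.0;
    Z = Z * decay + 1.0;
    if (t >= 2) {
      // lower triangle, column-major order: (i, j) with i > j
      double sx = 0, sxx = 0, sxy = 0;
      int idx = 0;
      for (int j = 0; j < n; ++j) {
        for (int i = j + 1; i < n; ++i, ++idx) {
          double v = rowsum[i] > 0 ? counts[(size_t)i * n + j] / rowsum[i]
                                   : 1.0 / n;
          sx += v; sxx += v * v; sxy += v * target_lt[idx];
        }
      }
      double vx = sxx - sx * sx / m, vy = tyy - ty * ty / m;
      double cov = sxy - sx * ty / m;
      if (vx > 1e-300 && vy > 1e-300) out[t] = cov / std::sqrt(vx * vy);
    }
  }
  return out;
}
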