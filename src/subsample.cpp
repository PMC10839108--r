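#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive enumeration of all C(n, j) subsamples of a batch, in
// lexicographic order, returning for each the relative difference of its
// mean (col 0) and of its sample SD (col 1) from the full batch, as
// fractions. Values are centered on the full mean before accumulation so
// the exact identities (mean of deltas = 0, mean of subset variances =
// full variance) hold to near machine precision.

// [[Rcpp::export]]
NumericMatrix rel_diff_exact_cpp(NumericVector x, int j) {
  const int n = x.size();
  if (j < 2 || j > n) stop("subsample size j must lie in [2, n]");
  double mu = 0.0;
  for (int i = 0; i < n; ++i) mu += x[i];
  mu /= n;
  if (mu == 0.0) stop("zero batch mean: relative difference undefined");
  std::vector<double> xc(n);
  double ssq = 0.0;
  for (int i = 0; i < n; ++i) {
    xc[i] = x[i] - mu;
    ssq += xc[i] * xc[i];
  }
  const double sigma = std::sqrt(ssq / (n - 1));
  if (sigma == 0.0) stop("zero batch SD: relative difference undefined");

  const double total_d = Rf_choose((double)n, (double)j);
  if (total_d > 2147483647.0)
    stop("C(n, j) exceeds integer range; use Monte Carlo mode");
  const int total = (int)total_d;

  NumericMatrix out(total, 2);
  std::vector<int> idx(j);
  for (int t = 0; t < j; ++t) idx[t] = t;

  for (int s = 0; s < total; ++s) {
    double sum = 0.0, sumsq = 0.0;
    for (int t = 0; t < j; ++t) {
      const double v = xc[idx[t]];
      sum += v;
      sumsq += v * v;
    }
    const double m = sum / j;
    double var = (sumsq - (double)j * m * m) / (j - 1);
    if (var < 0.0) var = 0.0;
    out(s, 0) = m / mu;
    out(s, 1) = (std::sqrt(var) - sigma) / sigma;

    int t = j - 1;
    while (t >= 0 && idx[t] == n - j + t) --t;
    if (t < 0) break;
    ++idx[t];
    for (int u = t + 1; u < j; ++u) idx[u] = idx[u - 1] + 1;
  }
  return out;
}
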