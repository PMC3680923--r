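#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive single-change scan over one arm.
//
// Maximizes |T(i, j)| over all contiguous intervals i..j with
// j - i + 1 >= min_markers and a non-empty complement, where
//   T = (mean_in - mean_out) / sqrt(1/n_in + 1/n_out)
// on unit-noise scale (the caller divides by sigma). Tie-break: the
// interval with the smallest i, then the smallest j, wins (strict ">"
// comparison while scanning in (i, j) lexicographic order).
//
// Returns c(i, j, T) with 1-based indices, or c(NA, NA, NA) when no valid
// interval exists (arm shorter than min_markers + 1).
// [[Rcpp::export(name = ".scan_one_change")]]
NumericVector scan_one_change(NumericVector x, int min_markers) {
  int n = x.size();
  NumericVector out = NumericVector::create(NA_REAL, NA_REAL, NA_REAL);
  if (n < min_markers + 1 || min_markers < 1) return out;
  std::vector<double> S(n + 1, 0.0);
  for (int k = 0; k < n; ++k) S[k + 1] = S[k] + x[k];
  double total = S[n];
  double best = -1.0;
  int bi = 0, bj = 0;
  double bT = 0.0;
  for (int i = 1; i <= n; ++i) {
    // The full arm is handled separately by the caller. A suffix segment
    // (i..n) has exactly the |T| of its complementary prefix (1..i-1)
    // with opposite sign; when that prefix is itself a valid candidate it
    // precedes lexicographically, so the suffix is skipped rather than
    // letting rounding noise decide the tie.
    int jmax = (i == 1 || i - 1 >= min_markers) ? n - 1 : n;
    for (int j = i + min_markers - 1; j <= jmax; ++j) {
      int nin = j - i + 1;
      int nout = n - nin;
      double min_ = (S[j] - S[i - 1]) / nin;
      double mout = (total - (S[j] - S[i - 1])) / nout;
      double T = (min_ - mout) / std::sqrt(1.0 / nin + 1.0 / nout);
      double a = std::fabs(T);
      if (a > best) {
        best = a;
        bi = i; bj = j; bT = T;
      }
    }
  }
  if (bi == 0) return out;
  out[0] = bi; out[1] = bj; out[2] = bT;
  return out;
}
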