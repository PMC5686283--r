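#include <Rcpp.h>
using namespace Rcpp;

// Template-matching counts for regularity statistics on physiological
// series. Chebyshev (max-coordinate) distance throughout; O(n^2) pair
// scans are the honest computation at these record lengths.

// Phi_m of Pincus' approximate entropy: mean over i of log(C_i^m), where
// C_i^m counts templates within r of template i, self-match included.
static double apen_phi(const NumericVector &x, int m, double r) {
  int n = x.size();
  int nt = n - m + 1;
  if (nt <= 0) return NA_REAL;
  double acc = 0.0;
  for (int i = 0; i < nt; ++i) {
    int cnt = 0;
    for (int j = 0; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        double d = x[i + k] - x[j + k];
        if (d < 0) d = -d;
        if (d > r) { match = false; break; }
      }
      if (match) ++cnt;
    }
    acc += std::log((double)cnt / (double)nt);
  }
  return acc / (double)nt;
}

// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  double phi_m = apen_phi(x, m, r);
  double phi_m1 = apen_phi(x, m + 1, r);
  if (NumericVector::is_na(phi_m) || NumericVector::is_na(phi_m1))
    return NA_REAL;
  return phi_m - phi_m1;
}

// Sample-entropy match counts: B pairs matching at length m, A pairs
// matching at length m+1, i < j, self-matches excluded. Templates are
// restricted to i <= n - m - 1 so every counted template also has an
// (m+1)-length extension, the standard Richman-Moorman convention.
// [[Rcpp::export]]
List sampen_counts_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m; // templates with an extension
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        double d = x[i + k] - x[j + k];
        if (d < 0) d = -d;
        if (d > r) { match = false; break; }
      }
      if (match) {
        B += 1.0;
        double d = x[i + m] - x[j + m];
        if (d < 0) d = -d;
        if (d <= r) A += 1.0;
      }
    }
  }
  return List::create(_["A"] = A, _["B"] = B);
}

// Lempel-Ziv (1976) phrase count of an integer symbol sequence, computed
// with the Kaspar-Schuster scan. A final phrase reproducible from the past
// still counts as one phrase.
// [[Rcpp::export]]
int lz76_cpp(IntegerVector s) {
  int n = s.size();
  if (n == 0) return 0;
  if (n == 1) return 1;
  // 1-based indexing to mirror the published recursion
  int c = 1, l = 1, i = 0, k = 1, k_max = 1;
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > k_max) k_max = k;
      ++i;
      if (i == l) {
        ++c;
        l += k_max;
        if (l + 1 > n) break;
        i = 0; k = 1; k_max = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}

// Higuchi curve-length statistic: mean normalized length L(k) for each
// lag k = 1..k_max; the fractal dimension is the slope of log L vs log(1/k).
// [[Rcpp::export]]
NumericVector higuchi_lengths_cpp(NumericVector x, int k_max) {
  int n = x.size();
  NumericVector L(k_max);
  for (int k = 1; k <= k_max; ++k) {
    double Lk = 0.0;
    for (int m0 = 0; m0 < k; ++m0) {
      int np = (n - 1 - m0) / k; // points in the subsampled curve
      if (np < 1) continue;
      double len = 0.0;
      for (int i = 1; i <= np; ++i)
        len += std::fabs(x[m0 + i * k] - x[m0 + (i - 1) * k]);
      // normalization per Higuchi: (n-1)/(np*k) scales to the full record
      len *= (double)(n - 1) / ((double)np * (double)k);
      Lk += len / (double)k;
    }
    L[k - 1] = Lk / (double)k;
  }
  return L;
}
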