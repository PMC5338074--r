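#include <Rcpp.h>
using namespace Rcpp;

// Chebyshev template match: max_k |x[i+k] - x[j+k]| <= r, k = 0..m-1
static inline bool match(const double* x, int i, int j, int m, double r) {
  for (int k = 0; k < m; ++k) {
    double d = x[i + k] - x[j + k];
    if (d < 0) d = -d;
    if (d > r) return false;
  }
  return true;
}

// Sample-entropy pair counts (Richman-Moorman): templates i = 0..N-m-1,
// unordered pairs i < j.  B counts length-m matches, A length-(m+1).
// [[Rcpp::export(name = ".sampenCounts")]]
NumericVector sampenCounts(NumericVector xs, int m, double r) {
  int n = xs.size();
  const double* x = xs.begin();
  int nt = n - m;  // templates for both lengths
  double A = 0, B = 0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      if (match(x, i, j, m, r)) {
        B += 1;
        double d = x[i + m] - x[j + m];
        if (d < 0) d = -d;
        if (d <= r) A += 1;
      }
    }
  }
  return NumericVector::create(A, B);
}

// Phi^d(r) = mean_i log C_i^d(r) with C_i^d the fraction of templates j
// (self included) within r of template i; templates i = 0..N-d.
// [[Rcpp::export(name = ".apenPhi")]]
double apenPhi(NumericVector xs, int d, double r) {
  int n = xs.size();
  const double* x = xs.begin();
  int nt = n - d + 1;
  double acc = 0;
  for (int i = 0; i < nt; ++i) {
    int c = 0;
    for (int j = 0; j < nt; ++j)
      if (match(x, i, j, d, r)) ++c;
    acc += std::log((double)c / nt);
  }
  return acc / nt;
}
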