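#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <numeric>
#include <algorithm>
using namespace Rcpp;

// Sample entropy by exact pairwise template counting.
//
// C_m is the fraction of ordered template pairs (i, j), i != j, whose
// length-m subsequences differ by < r in Chebyshev distance, normalised by
// (N - m + 1)(N - m); C_{m+1} likewise over the N - m longer templates.
// SampEn = -ln(C_{m+1} / C_m); NA when either count is zero.
//
// Template starts are sorted by their first coordinate; only pairs within
// r on that coordinate (a sliding window in sorted order) are compared on
// the remaining coordinates. The counts are identical to the naive double
// loop, at a fraction of the comparisons.
//
// [[Rcpp::export(name = ".sampen_core")]]
double sampen_core(NumericVector y, int m, double r) {
  const int N = y.size();
  if (m < 1) stop("m must be >= 1");
  if (r <= 0) stop("r must be positive");
  if (N <= m + 1) stop("series too short for m = %d", m);
  long long A = 0; // length-m matches among unordered start pairs
  long long B = 0; // length-(m+1) matches
  const int last_m = N - m;      // last 0-based start of an m-template
  const int last_m1 = N - m - 1; // last 0-based start of an (m+1)-template
  const double* yp = REAL(y);
  std::vector<int> ord(last_m + 1);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(),
            [yp](int i, int j) { return yp[i] < yp[j]; });
  for (int ii = 0; ii <= last_m; ++ii) {
    const int i = ord[ii];
    const double yi = yp[i];
    for (int jj = ii + 1; jj <= last_m && yp[ord[jj]] - yi < r; ++jj) {
      const int j = ord[jj];
      bool match = true;
      for (int k = 1; k < m; ++k) {
        if (std::fabs(yp[i + k] - yp[j + k]) >= r) { match = false; break; }
      }
      if (!match) continue;
      ++A;
      if (i <= last_m1 && j <= last_m1 &&
          std::fabs(yp[i + m] - yp[j + m]) < r) ++B;
    }
  }
  if (A == 0 || B == 0) return NA_REAL;
  const double n_m = (double)(N - m + 1);
  const double n_m1 = (double)(N - m);
  const double Cm = 2.0 * A / (n_m * (n_m - 1.0));
  const double Cm1 = 2.0 * B / (n_m1 * (n_m1 - 1.0));
  return -std::log(Cm1 / Cm);
}
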