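#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Sample entropy template-match counts (Richman & Moorman convention):
// N - m templates of length m and m + 1, Chebyshev distance, strict
// inequality d < r, self-matches excluded. Candidate pairs are pruned by
// sorting on the first template element (a pair can only match if its lag-0
// distance is already < r), which changes nothing about the counts but
// avoids the full O(N^2) scan. Returns the counts so the R side decides how
// to handle the undefined (zero-count) case.
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // number of templates
  double B = 0.0, A = 0.0;
  std::vector<int> ord(nt);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  for (int a = 0; a < nt - 1; ++a) {
    const int i = ord[a];
    for (int b = a + 1; b < nt; ++b) {
      const int j = ord[b];
      if (x[j] - x[i] >= r) break;  // sorted: no further lag-0 matches
      bool match_m = true;
      for (int k = 1; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) >= r) { match_m = false; break; }
      }
      if (!match_m) continue;
      B += 1.0;
      if (std::fabs(x[i + m] - x[j + m]) < r) A += 1.0;
    }
  }
  return NumericVector::create(_["A"] = A, _["B"] = B);
}
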