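#include <Rcpp.h>
using namespace Rcpp;

// Sample entropy SampEn(m, r) with Chebyshev distance, self-matches
// excluded. Templates are the N - m windows for which an (m+1)-length
// extension exists, so the m-length and (m+1)-length counts range over the
// same template index set (Richman & Moorman convention). Matching uses
// distance <= r. When either count is zero the value is undefined; the
// caller maps that to a documented cap.
// [[Rcpp::export]]
List sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  long long A = 0, B = 0;
  for (int i = 0; i < n - m; ++i) {
    for (int j = i + 1; j < n - m; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (!match) continue;
      ++B;
      if (std::fabs(x[i + m] - x[j + m]) <= r) ++A;
    }
  }
  return List::create(Named("A") = (double)A, Named("B") = (double)B);
}
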