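#include <Rcpp.h>
#include <cmath>

// Pair counts for sample entropy: B = matching template pairs at dimension m,
// A = pairs still matching at m+1, Chebyshev distance, self-matches excluded.
// Both counts run over the first n-m templates so that A <= B and a constant
// series gives A == B (SampEn 0). Counts are unordered pairs (i < j); the
// factor 2 cancels in A/B.
// [[Rcpp::export]]
Rcpp::NumericVector sampen_counts(Rcpp::NumericVector y, int m, double r) {
    const int n = y.size();
    const int nt = n - m;  // templates with a continuation point
    double A = 0.0, B = 0.0;
    for (int i = 0; i < nt; ++i) {
        for (int j = i + 1; j < nt; ++j) {
            bool ok = true;
            for (int k = 0; k < m; ++k) {
                if (std::fabs(y[i + k] - y[j + k]) > r) { ok = false; break; }
            }
            if (!ok) continue;
            B += 1.0;
            if (std::fabs(y[i + m] - y[j + m]) <= r) A += 1.0;
        }
    }
    return Rcpp::NumericVector::create(B, A);
}
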