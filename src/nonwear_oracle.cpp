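#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive reference for the non-wear rule: enumerate every window with
// zero endpoints, length >= min_window minutes, and at most max_interruptions
// nonzero interior minutes; mark the union nonwear. O(n^2); test oracle only.
// [[Rcpp::export]]
LogicalVector nonwear_oracle_cpp(IntegerVector counts, int min_window,
                                 int max_interruptions) {
  int n = counts.size();
  LogicalVector nonwear(n, false);
  for (int i = 0; i < n; ++i) {
    if (counts[i] != 0) continue;
    int nz_interior = 0;
    int j_best = -1;  // largest qualifying end for this start; nested
                      // qualifying windows are contained in [i, j_best]
    for (int j = i + 1; j < n; ++j) {
      if (counts[j] == 0) {
        if (j - i + 1 >= min_window && nz_interior <= max_interruptions) {
          j_best = j;
        }
      } else {
        ++nz_interior;  // j becomes interior for larger windows
        if (nz_interior > max_interruptions) break;  // monotone in j
      }
    }
    if (j_best >= 0) {
      for (int k = i; k <= j_best; ++k) nonwear[k] = true;
    }
  }
  return nonwear;
}
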