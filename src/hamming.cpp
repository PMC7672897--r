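#include <Rcpp.h>
using namespace Rcpp;

// Bounded Hamming distance between paired strings a[i], b[i].
// Returns max_d + 1 as soon as more than max_d mismatches are seen
// (early exit), so callers must treat any value > max_d as "exceeded".
// [[Rcpp::export]]
IntegerVector hamming_bounded(CharacterVector a, CharacterVector b, int max_d) {
  R_xlen_t n = a.size();
  if (b.size() != n)
    stop("'a' and 'b' must have the same length");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP sa = STRING_ELT(a, i);
    SEXP sb = STRING_ELT(b, i);
    if (sa == NA_STRING || sb == NA_STRING) {
      out[i] = NA_INTEGER;
      continue;
    }
    int la = LENGTH(sa), lb = LENGTH(sb);
    if (la != lb)
      stop("strings at position %d differ in length (%d vs %d)",
           (int)(i + 1), la, lb);
    const char *x = CHAR(sa);
    const char *y = CHAR(sb);
    int d = 0;
    for (int j = 0; j < la; ++j) {
      if (x[j] != y[j] && ++d > max_d) break;
    }
    out[i] = d;
  }
  return out;
}
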