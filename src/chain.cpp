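#include <Rcpp.h>
using namespace Rcpp;

// Stepwise sampling of a finite-state chain whose transition matrix
// switches from `cum_first` to `cum_second` at the night midpoint.
// `cum_*` are row-wise cumulative probability matrices; `u` holds the
// length-1 fewer uniforms drawn in R (so set.seed() governs the draw).
// The transition into 0-based position t uses the first matrix while
// t <= boundary, the second afterwards. States are 1-based row indices.
// [[Rcpp::export]]
IntegerVector sample_chain_cpp(NumericMatrix cum_first,
                               NumericMatrix cum_second,
                               int boundary, int init_state,
                               NumericVector u) {
  int n = u.size() + 1;
  int k = cum_first.ncol();
  IntegerVector s(n);
  s[0] = init_state;
  for (int t = 1; t < n; ++t) {
    NumericMatrix& cum = (t <= boundary) ? cum_first : cum_second;
    double uu = u[t - 1];
    int row = s[t - 1] - 1;
    int j = 0;
    while (j < k - 1 && uu > cum(row, j)) ++j;
    s[t] = j + 1;
  }
  return s;
}
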