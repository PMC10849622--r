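#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Median of each row of a numeric matrix. Used for the per-sample
// common-average reference across channels, where an R-level apply() over
// millions of samples is prohibitively slow.
// [[Rcpp::export]]
NumericVector row_medians_cpp(NumericMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  NumericVector out(nr);
  std::vector<double> buf(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) buf[j] = m(i, j);
    const int h = nc / 2;
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double med = buf[h];
    if (nc % 2 == 0) {
      double lo = *std::max_element(buf.begin(), buf.begin() + h);
      med = 0.5 * (med + lo);
    }
    out[i] = med;
  }
  return out;
}
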