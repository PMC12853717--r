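#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Mean of the `k` nearest donors' values for every query row.
// `query` and `donor` are standardised covariate matrices with matching
// columns; distance is squared Euclidean. Ties in distance resolve in donor
// order (stable sort), matching the R-level contract.
// [[Rcpp::export(name = ".knn_mean_cpp")]]
NumericVector knn_mean_cpp(NumericMatrix query, NumericMatrix donor,
                           NumericVector donor_values, int k) {
  const int nq = query.nrow(), nd = donor.nrow(), p = query.ncol();
  if (donor.ncol() != p) stop("column mismatch between query and donor");
  if (k < 1 || k > nd) stop("k out of range");
  NumericVector out(nq);
  std::vector<double> bestd(k);
  std::vector<int> besti(k);
  for (int i = 0; i < nq; ++i) {
    int filled = 0;
    for (int j = 0; j < nd; ++j) {
      double s = 0.0;
      for (int c = 0; c < p; ++c) {
        const double diff = query(i, c) - donor(j, c);
        s += diff * diff;
      }
      // keep the running top-k, sorted ascending by (distance, donor
      // order); insertion only on strictly smaller distance preserves the
      // earlier donor on ties
      if (filled < k) {
        int pos = filled++;
        while (pos > 0 && bestd[pos - 1] > s) {
          bestd[pos] = bestd[pos - 1];
          besti[pos] = besti[pos - 1];
          --pos;
        }
        bestd[pos] = s;
        besti[pos] = j;
      } else if (s < bestd[k - 1]) {
        int pos = k - 1;
        while (pos > 0 && bestd[pos - 1] > s) {
          bestd[pos] = bestd[pos - 1];
          besti[pos] = besti[pos - 1];
          --pos;
        }
        bestd[pos] = s;
        besti[pos] = j;
      }
    }
    double acc = 0.0;
    for (int j = 0; j < k; ++j) acc += donor_values[besti[j]];
    out[i] = acc / k;
  }
  return out;
}
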