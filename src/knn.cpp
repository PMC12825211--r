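#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exact k-nearest neighbours by brute force with partial selection.
// Distances are Euclidean; the point itself is excluded.

// [[Rcpp::export]]
List knn_brute(NumericMatrix values, int k) {
  const int n = values.nrow(), d = values.ncol();
  if (k >= n) stop("k must be smaller than the number of points");
  IntegerMatrix idx(n, k);
  NumericMatrix dst(n, k);
  std::vector<double> sq(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < d; ++c) sq[i] += values(i, c) * values(i, c);

  std::vector<std::pair<double, int>> row(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double dot = 0.0;
      for (int c = 0; c < d; ++c) dot += values(i, c) * values(j, c);
      double d2 = sq[i] + sq[j] - 2.0 * dot;
      row[j] = {j == i ? R_PosInf : (d2 > 0 ? d2 : 0.0), j};
    }
    std::partial_sort(row.begin(), row.begin() + k, row.end());
    for (int m = 0; m < k; ++m) {
      idx(i, m) = row[m].second + 1;  // 1-based for R
      dst(i, m) = std::sqrt(row[m].first);
    }
  }
  return List::create(_["index"] = idx, _["dist"] = dst);
}
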