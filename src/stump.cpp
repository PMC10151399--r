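#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Exhaustive best-stump search for boosted regression trees.
// Candidate thresholds are midpoints between consecutive distinct sorted
// values of each feature; a split is admissible only if both sides hold at
// least min_node observations.  The criterion is the squared-error
// reduction n_L * mean_L^2 + n_R * mean_R^2 (the parent term is constant).
// Ties keep the first candidate found, i.e. lowest feature index, then
// lowest threshold.
// [[Rcpp::export(name = ".best_stump_cpp", rng = false)]]
List best_stump_cpp(NumericMatrix X, NumericVector r, IntegerVector idx,
                    int min_node) {
  const int n = idx.size();
  const int p = X.ncol();
  double best_gain = -1.0;
  int best_feat = -1;
  double best_thr = 0.0, best_left = 0.0, best_right = 0.0;

  std::vector<std::pair<double, double> > v(n);  // (x, residual)
  for (int j = 0; j < p; ++j) {
    double tot = 0.0;
    for (int k = 0; k < n; ++k) {
      const int i = idx[k] - 1;
      v[k].first = X(i, j);
      v[k].second = r[i];
      tot += r[i];
    }
    std::sort(v.begin(), v.end());
    double left_sum = 0.0;
    for (int k = 0; k < n - 1; ++k) {
      left_sum += v[k].second;
      if (v[k].first == v[k + 1].first) continue;  // not a boundary
      const int nl = k + 1, nr = n - nl;
      if (nl < min_node || nr < min_node) continue;
      const double right_sum = tot - left_sum;
      const double gain = left_sum * left_sum / nl + right_sum * right_sum / nr;
      if (gain > best_gain + 1e-12 * (1.0 + std::abs(best_gain))) {
        best_gain = gain;
        best_feat = j + 1;
        best_thr = 0.5 * (v[k].first + v[k + 1].first);
        best_left = left_sum / nl;
        best_right = right_sum / nr;
      }
    }
  }
  if (best_feat < 0) {
    return List::create(Named("found") = false);
  }
  return List::create(Named("found") = true,
                      Named("feature") = best_feat,
                      Named("threshold") = best_thr,
                      Named("left") = best_left,
                      Named("right") = best_right);
}
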