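#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// SMO for the dual of linear epsilon-insensitive SVR.
// Variables t = 0..2n-1: t < n are alpha_plus (sign +1), t >= n alpha_minus
// (sign -1).  Gradient G_t = s_t (K theta)_i(t) + eps - s_t y_i(t).
// Working set: maximal -sG over the "up" set, second-order choice of the
// partner; stops when the maximal KKT violation drops below tol.
// [[Rcpp::export(name = ".svr_smo_cpp", rng = false)]]
List svr_smo_cpp(NumericMatrix K, NumericVector y, double eps, double C,
                 double tol, int max_iter) {
  const int n = y.size();
  const int m = 2 * n;
  std::vector<double> z(m, 0.0), G(m), msG(m);
  for (int t = 0; t < m; ++t) {
    const double s = t < n ? 1.0 : -1.0;
    G[t] = eps - s * y[t % n];
  }
  double viol = R_PosInf;
  int iter = 0;
  while (true) {
    // msG = -s * G; up/low feasibility masks
    int i = -1; double mi = R_NegInf;
    double lo = R_PosInf;
    for (int t = 0; t < m; ++t) {
      const double s = t < n ? 1.0 : -1.0;
      msG[t] = -s * G[t];
      const bool up = (s > 0 && z[t] < C - 1e-12) || (s < 0 && z[t] > 1e-12);
      const bool low = (s < 0 && z[t] < C - 1e-12) || (s > 0 && z[t] > 1e-12);
      if (up && msG[t] > mi) { mi = msG[t]; i = t; }
      if (low && msG[t] < lo) lo = msG[t];
    }
    if (i < 0 || !R_FINITE(lo)) break;
    viol = mi - lo;
    if (viol < tol) break;
    if (iter >= max_iter) break;

    const int ki = i % n;
    const double si = i < n ? 1.0 : -1.0;
    const double kii = K(ki, ki);
    int j = -1; double best = -1.0;
    for (int t = 0; t < m; ++t) {
      const double s = t < n ? 1.0 : -1.0;
      const bool low = (s < 0 && z[t] < C - 1e-12) || (s > 0 && z[t] > 1e-12);
      if (!low || msG[t] >= mi - 1e-12) continue;
      const double delta = mi - msG[t];
      double eta = kii + K(t % n, t % n) - 2.0 * K(ki, t % n);
      if (eta < 1e-12) eta = 1e-12;
      const double score = delta * delta / eta;
      if (score > best) { best = score; j = t; }
    }
    if (j < 0) break;

    const int kj = j % n;
    const double sj = j < n ? 1.0 : -1.0;
    double eta = kii + K(kj, kj) - 2.0 * K(ki, kj);
    if (eta < 1e-12) eta = 1e-12;
    double step = -(G[i] - si * sj * G[j]) / eta;
    const double same = si * sj;
    const double t_max = std::min(C - z[i], same > 0 ? z[j] : C - z[j]);
    const double t_min = std::max(-z[i], same > 0 ? z[j] - C : -z[j]);
    if (step > t_max) step = t_max;
    if (step < t_min) step = t_min;
    if (std::fabs(step) < 1e-15) break;
    z[i] += step;
    z[j] -= same * step;
    for (int t = 0; t < m; ++t) {
      const double s = t < n ? 1.0 : -1.0;
      G[t] += step * s * si * (K(t % n, ki) - K(t % n, kj));
    }
    ++iter;
  }
  return List::create(Named("z") = NumericVector(z.begin(), z.end()),
                      Named("iterations") = iter,
                      Named("violation") = viol);
}
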