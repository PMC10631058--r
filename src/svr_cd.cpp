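#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for epsilon-SVR with the bias absorbed into the
// kernel. Minimizes over beta in [-C, C]^n:
//   0.5 * beta' K beta - y' beta + eps * ||beta||_1
// where K already includes the +1 bias term. Each coordinate has a
// closed-form soft-threshold update; f = K beta is maintained
// incrementally. Deterministic sweep order.
// [[Rcpp::export]]
List svr_cd(NumericMatrix K, NumericVector y, double C, double eps,
            double tol, int max_sweeps) {
  int n = y.size();
  NumericVector beta(n), f(n);
  int sweeps = 0;
  double delta_max = 0.0;
  for (sweeps = 0; sweeps < max_sweeps; ++sweeps) {
    delta_max = 0.0;
    for (int i = 0; i < n; ++i) {
      double kii = K(i, i);
      if (kii <= 0.0) continue;
      double g = f[i] - kii * beta[i];  // prediction without i's own term
      double num = y[i] - g;
      double b;
      if (num > eps) b = (num - eps) / kii;
      else if (num < -eps) b = (num + eps) / kii;
      else b = 0.0;
      if (b > C) b = C;
      if (b < -C) b = -C;
      double d = b - beta[i];
      if (d != 0.0) {
        beta[i] = b;
        for (int j = 0; j < n; ++j) f[j] += d * K(j, i);
        double ad = d < 0 ? -d : d;
        if (ad > delta_max) delta_max = ad;
      }
    }
    if (delta_max < tol) { ++sweeps; break; }
  }
  return List::create(_["beta"] = beta, _["fitted"] = f,
                      _["sweeps"] = sweeps, _["converged"] = delta_max < tol);
}
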