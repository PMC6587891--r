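#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the non-negative elastic net
//   min_{b >= 0} 0.5 * ||y - F b||^2 + l1 * sum(b) + 0.5 * l2 * ||b||^2
// on the Gram form (FtF = F'F, Fty = F'y). The gradient vector
// g = Fty - FtF b is maintained incrementally; each coordinate update is the
// non-negative soft threshold  b_j = max(0, (g_j + FtF_jj b_j - l1) /
// (FtF_jj + l2)). Columns with zero norm (FtF_jj + l2 == 0) keep b_j = 0.
// [[Rcpp::export]]
List nonneg_enet_cd(NumericMatrix FtF, NumericVector Fty, double l1,
                    double l2, double tol, int max_sweeps) {
  const int p = Fty.size();
  NumericVector b(p);
  std::vector<double> g(p);
  for (int j = 0; j < p; ++j) g[j] = Fty[j];
  double max_change = 0.0;
  int sweep = 0;
  for (sweep = 1; sweep <= max_sweeps; ++sweep) {
    max_change = 0.0;
    for (int j = 0; j < p; ++j) {
      const double denom = FtF(j, j) + l2;
      if (denom <= 0.0) continue;
      const double r = g[j] + FtF(j, j) * b[j];
      double nb = (r - l1) / denom;
      if (nb < 0.0) nb = 0.0;
      const double d = nb - b[j];
      if (d != 0.0) {
        const double* col = &FtF(0, j);
        for (int i = 0; i < p; ++i) g[i] -= col[i] * d;
        b[j] = nb;
        const double ad = std::fabs(d);
        if (ad > max_change) max_change = ad;
      }
    }
    if (max_change < tol) break;
  }
  const bool converged = max_change < tol;
  if (sweep > max_sweeps) sweep = max_sweeps;
  return List::create(_["beta"] = b, _["sweeps"] = sweep,
                      _["max_change"] = max_change,
                      _["converged"] = converged);
}
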