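#include <Rcpp.h>
using namespace Rcpp;

// Debye scattering sum for identical point scatterers (form factor f = 1):
//   I(q) = n + 2 * sum_{i<j} sin(q r_ij) / (q r_ij)
// `d` holds the n*(n-1)/2 unique pairwise distances (Angstrom), `q` the
// momentum-transfer grid (1/Angstrom, q > 0). sinc(0) = 1 is the diagonal.
// [[Rcpp::export(name = ".debye_sum")]]
NumericVector debye_sum(NumericVector d, NumericVector q, double n) {
  const R_xlen_t np = d.size(), nq = q.size();
  NumericVector out(nq);
  for (R_xlen_t k = 0; k < nq; ++k) {
    const double qk = q[k];
    double acc = 0.0;
    for (R_xlen_t p = 0; p < np; ++p) {
      const double x = qk * d[p];
      acc += (x < 1e-12) ? 1.0 : std::sin(x) / x;
    }
    out[k] = n + 2.0 * acc;
  }
  return out;
}

// Minimum distance between beads separated by >= minsep in sequence and not
// belonging to the same rigid segment (segment id 0 = flexible, always checked).
// [[Rcpp::export(name = ".min_cross_dist")]]
double min_cross_dist(NumericMatrix xyz, IntegerVector seg, int minsep) {
  const int n = xyz.nrow();
  double best = R_PosInf;
  for (int i = 0; i < n; ++i) {
    for (int j = i + minsep; j < n; ++j) {
      if (seg[i] != 0 && seg[i] == seg[j]) continue;
      const double dx = xyz(i, 0) - xyz(j, 0);
      const double dy = xyz(i, 1) - xyz(j, 1);
      const double dz = xyz(i, 2) - xyz(j, 2);
      const double dd = dx * dx + dy * dy + dz * dz;
      if (dd < best) best = dd;
    }
  }
  return std::sqrt(best);
}
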