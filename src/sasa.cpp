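// Shrake-Rupley solvent-accessible surface area with a deterministic
// golden-spiral sphere point set (no RNG: results are reproducible to the
// bit for a given sample count).
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix xyz, NumericVector radii,
                       double probe, int n_points) {
  const int n = xyz.nrow();
  // golden-spiral points on the unit sphere
  std::vector<double> sp(3 * n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = golden * k;
    sp[3 * k] = r * std::cos(th);
    sp[3 * k + 1] = r * std::sin(th);
    sp[3 * k + 2] = z;
  }
  NumericVector area(n);
  std::vector<double> R(n);
  for (int i = 0; i < n; ++i) R[i] = radii[i] + probe;
  for (int i = 0; i < n; ++i) {
    // neighbours able to bury points of atom i
    std::vector<int> nbr;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double d2 = 0.0;
      for (int d = 0; d < 3; ++d) {
        double dd = xyz(i, d) - xyz(j, d);
        d2 += dd * dd;
      }
      double lim = R[i] + R[j];
      if (d2 < lim * lim) nbr.push_back(j);
    }
    int accessible = 0;
    for (int k = 0; k < n_points; ++k) {
      double p[3];
      for (int d = 0; d < 3; ++d) p[d] = xyz(i, d) + R[i] * sp[3 * k + d];
      bool buried = false;
      for (int j : nbr) {
        double d2 = 0.0;
        for (int d = 0; d < 3; ++d) {
          double dd = p[d] - xyz(j, d);
          d2 += dd * dd;
        }
        if (d2 < R[j] * R[j]) { buried = true; break; }
      }
      if (!buried) ++accessible;
    }
    area[i] = 4.0 * M_PI * R[i] * R[i] * accessible / n_points;
  }
  return area;
}
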