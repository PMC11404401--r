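// Hexatic bond-orientational order parameter psi6 with minimum-image
// distances and a deterministic (distance, index) tie-break for the
// six-nearest-neighbor set.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <complex>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
ComplexVector cpp_psi6(NumericMatrix pts, double Lx, double Ly) {
  const int n = pts.nrow();
  if (n < 7) stop("psi6 needs at least 7 centers (6 neighbors per cell)");
  ComplexVector out(n);
  std::vector<std::pair<double, int>> d(n);
  for (int k = 0; k < n; ++k) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == k) continue;
      double dx = pts(j, 0) - pts(k, 0);
      double dy = pts(j, 1) - pts(k, 1);
      dx -= Lx * std::round(dx / Lx);
      dy -= Ly * std::round(dy / Ly);
      d[m++] = {dx * dx + dy * dy, j};
    }
    std::partial_sort(d.begin(), d.begin() + 6, d.begin() + m);
    std::complex<double> s(0.0, 0.0);
    for (int t = 0; t < 6; ++t) {
      int j = d[t].second;
      double dx = pts(j, 0) - pts(k, 0);
      double dy = pts(j, 1) - pts(k, 1);
      dx -= Lx * std::round(dx / Lx);
      dy -= Ly * std::round(dy / Ly);
      double th = std::atan2(dy, dx);
      s += std::complex<double>(std::cos(6.0 * th), std::sin(6.0 * th));
    }
    s /= 6.0;
    out[k].r = s.real();
    out[k].i = s.imag();
  }
  return out;
}
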