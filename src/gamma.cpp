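// 3D gamma-index pass rate with global dose normalization.
// For every reference voxel above the low-dose threshold, searches the
// evaluated distribution over a sphere of physical offsets (sorted by
// distance, early exit) with trilinear sub-voxel interpolation.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// trilinear interpolation at continuous 0-based index (ci,cj,ck);
// returns false when outside the grid (no extrapolation)
static bool triInterp(const arma::cube& a, double ci, double cj, double ck,
                      double& out) {
  const int d0 = a.n_rows, d1 = a.n_cols, d2 = a.n_slices;
  if (ci < 0 || cj < 0 || ck < 0 || ci > d0 - 1 || cj > d1 - 1 || ck > d2 - 1)
    return false;
  int i0 = (int)std::floor(ci), j0 = (int)std::floor(cj),
      k0 = (int)std::floor(ck);
  if (i0 == d0 - 1) --i0;
  if (j0 == d1 - 1) --j0;
  if (k0 == d2 - 1) --k0;
  if (d0 == 1) i0 = 0;
  if (d1 == 1) j0 = 0;
  if (d2 == 1) k0 = 0;
  const double fx = ci - i0, fy = cj - j0, fz = ck - k0;
  const int i1 = std::min(i0 + 1, d0 - 1), j1 = std::min(j0 + 1, d1 - 1),
            k1 = std::min(k0 + 1, d2 - 1);
  out =
    a(i0, j0, k0) * (1 - fx) * (1 - fy) * (1 - fz) +
    a(i1, j0, k0) * fx * (1 - fy) * (1 - fz) +
    a(i0, j1, k0) * (1 - fx) * fy * (1 - fz) +
    a(i1, j1, k0) * fx * fy * (1 - fz) +
    a(i0, j0, k1) * (1 - fx) * (1 - fy) * fz +
    a(i1, j0, k1) * fx * (1 - fy) * fz +
    a(i0, j1, k1) * (1 - fx) * fy * fz +
    a(i1, j1, k1) * fx * fy * fz;
  return true;
}

// [[Rcpp::export]]
List cpp_gamma_pass(const arma::cube& ref, const arma::cube& ev,
                    const arma::vec& spacing, double deltaD, double dta,
                    double lowDoseThreshold, double searchRadius,
                    double step) {
  const int d0 = ref.n_rows, d1 = ref.n_cols, d2 = ref.n_slices;
  const double maxRef = ref.max();
  const double thr = lowDoseThreshold * maxRef;

  // offset lattice within the search sphere, sorted by distance
  const int n0 = (int)std::floor(searchRadius / step);
  std::vector<std::array<double, 4>> offs;  // dx,dy,dz,r2
  for (int a = -n0; a <= n0; ++a)
    for (int b = -n0; b <= n0; ++b)
      for (int c = -n0; c <= n0; ++c) {
        const double dx = a * step, dy = b * step, dz = c * step;
        const double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 <= searchRadius * searchRadius + 1e-12)
          offs.push_back({dx, dy, dz, r2});
      }
  std::sort(offs.begin(), offs.end(),
            [](const std::array<double, 4>& x, const std::array<double, 4>& y) {
              return x[3] < y[3];
            });

  long evaluated = 0, passed = 0;
  const double dta2 = dta * dta, dD2 = deltaD * deltaD;
  for (int k = 0; k < d2; ++k)
    for (int j = 0; j < d1; ++j)
      for (int i = 0; i < d0; ++i) {
        const double rv = ref(i, j, k);
        if (rv <= thr) continue;
        ++evaluated;
        bool pass = false;
        for (const auto& o : offs) {
          const double rterm = o[3] / dta2;
          if (rterm > 1.0) break;  // sorted: no later offset can pass
          double evVal;
          if (!triInterp(ev, i + o[0] / spacing(0), j + o[1] / spacing(1),
                         k + o[2] / spacing(2), evVal))
            continue;
          const double dd = evVal - rv;
          if (dd * dd / dD2 + rterm <= 1.0) { pass = true; break; }
        }
        if (pass) ++passed;
      }
  return List::create(_["evaluated"] = (double)evaluated,
                      _["passed"] = (double)passed);
}
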