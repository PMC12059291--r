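#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Bilinear sample at continuous 0-based pixel coords with nearest-edge
// (constant) extension.  Outside the film the plan dose is already at
// background level, so clamping only matters in the outer low-dose region.
static inline double sampleBilinear(const NumericMatrix& m, double iy,
                                    double ix) {
  const int ny = m.nrow(), nx = m.ncol();
  if (ix < 0) ix = 0;
  if (ix > nx - 1) ix = nx - 1;
  if (iy < 0) iy = 0;
  if (iy > ny - 1) iy = ny - 1;
  const int x0 = (int)std::floor(ix), y0 = (int)std::floor(iy);
  const int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1);
  const double fx = ix - x0, fy = iy - y0;
  return m(y0, x0) * (1 - fy) * (1 - fx) + m(y0, x1) * (1 - fy) * fx +
         m(y1, x0) * fy * (1 - fx) + m(y1, x1) * fy * fx;
}

// Time-uniform dose accumulation: out(x) = mean_k plan(x - shift_k), shifts
// in pixel units, bilinear interpolation for fractional shifts.
// [[Rcpp::export(name = ".blurAccumulate")]]
NumericMatrix blurAccumulate(NumericMatrix plan, NumericVector dxPix,
                             NumericVector dyPix) {
  const int ny = plan.nrow(), nx = plan.ncol();
  const int n = dxPix.size();
  if (n == 0) stop("no time samples");
  NumericMatrix out(ny, nx);
  for (int k = 0; k < n; ++k) {
    const double dx = dxPix[k], dy = dyPix[k];
    for (int j = 0; j < nx; ++j)
      for (int i = 0; i < ny; ++i)
        out(i, j) += sampleBilinear(plan, i - dy, j - dx);
  }
  const double inv = 1.0 / n;
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < ny; ++i) out(i, j) *= inv;
  return out;
}

// Gamma index on co-registered grids.  For each evaluable reference pixel,
// minimise (r/dta)^2 + (dDose/ddAbs)^2 over a search disc of the given
// radius, stepping the bilinear-interpolated evaluated grid on a `step`-mm
// lattice.  Offsets are visited in order of increasing radius so the search
// can stop as soon as the pure distance term exceeds the running minimum.
// [[Rcpp::export(name = ".gammaCore")]]
NumericMatrix gammaCore(NumericMatrix refDose, NumericMatrix evalDose,
                        double spacing, double dta, double ddAbs,
                        LogicalMatrix evaluate, double step, double radius) {
  if (refDose.nrow() != evalDose.nrow() || refDose.ncol() != evalDose.ncol())
    stop("reference and evaluated grids must be co-registered");
  const int m = (int)std::floor(radius / step + 1e-9);
  std::vector<double> offx, offy, offr2;
  offx.reserve((2 * m + 1) * (2 * m + 1));
  for (int a = -m; a <= m; ++a)
    for (int b = -m; b <= m; ++b) {
      const double ox = a * step, oy = b * step, r2 = ox * ox + oy * oy;
      if (r2 <= radius * radius + 1e-12) {
        offx.push_back(ox);
        offy.push_back(oy);
        offr2.push_back(r2);
      }
    }
  std::vector<size_t> ord(offx.size());
  std::iota(ord.begin(), ord.end(), (size_t)0);
  std::sort(ord.begin(), ord.end(),
            [&](size_t a, size_t b) { return offr2[a] < offr2[b]; });

  const int ny = refDose.nrow(), nx = refDose.ncol();
  const double dta2 = dta * dta, dd2 = ddAbs * ddAbs;
  NumericMatrix g(ny, nx);
  std::fill(g.begin(), g.end(), NA_REAL);
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < ny; ++i) {
      if (!evaluate(i, j)) continue;
      const double rd = refDose(i, j);
      double best = R_PosInf;
      for (size_t q = 0; q < ord.size(); ++q) {
        const size_t o = ord[q];
        const double distTerm = offr2[o] / dta2;
        if (distTerm >= best) break;  // offsets only get farther
        const double ix = j + offx[o] / spacing;
        const double iy = i + offy[o] / spacing;
        if (ix < 0 || ix > nx - 1 || iy < 0 || iy > ny - 1) continue;
        const double dd = sampleBilinear(evalDose, iy, ix) - rd;
        const double gg = distTerm + dd * dd / dd2;
        if (gg < best) best = gg;
      }
      g(i, j) = std::sqrt(best);
    }
  }
  return g;
}
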