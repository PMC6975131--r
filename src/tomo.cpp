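#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parallel-beam forward projection of one slice.
// slice: n x n matrix (rows = x, cols = y), angles in radians.
// Returns nAngle x ns matrix of line integrals in units of voxel lengths.
// Rays are sampled with unit (voxel) steps and bilinear interpolation.
// [[Rcpp::export(name = ".radonForwardCpp")]]
NumericMatrix radonForwardCpp(NumericMatrix slice, NumericVector angles,
                              int ns) {
  const int n = slice.nrow();
  if (slice.ncol() != n) stop("slice must be square");
  const double c0 = (n - 1) / 2.0;
  const double s0 = (ns - 1) / 2.0;
  const int nA = angles.size();
  NumericMatrix out(nA, ns);
  const int nSteps = (int)std::ceil(n * 1.45) + 1;
  const double t0 = -(nSteps - 1) / 2.0;
  for (int a = 0; a < nA; ++a) {
    const double ca = std::cos(angles[a]);
    const double sa = std::sin(angles[a]);
    for (int is = 0; is < ns; ++is) {
      const double s = is - s0;
      double acc = 0.0;
      for (int it = 0; it < nSteps; ++it) {
        const double t = t0 + it;
        // detector coordinate s along (cos, sin), ray direction (-sin, cos)
        const double x = c0 + s * ca - t * sa;
        const double y = c0 + s * sa + t * ca;
        const int ix = (int)std::floor(x);
        const int iy = (int)std::floor(y);
        if (ix < 0 || ix >= n - 1 || iy < 0 || iy >= n - 1) continue;
        const double fx = x - ix, fy = y - iy;
        acc += (1 - fx) * (1 - fy) * slice(ix, iy)
             + fx * (1 - fy) * slice(ix + 1, iy)
             + (1 - fx) * fy * slice(ix, iy + 1)
             + fx * fy * slice(ix + 1, iy + 1);
      }
      out(a, is) = acc;
    }
  }
  return out;
}

// Backprojection of a filtered sinogram (nAngle x ns) onto an n x n slice.
// Includes the pi/nAngle quadrature weight of the inverse Radon transform.
// [[Rcpp::export(name = ".backprojectCpp")]]
NumericMatrix backprojectCpp(NumericMatrix filtered, NumericVector angles,
                             int n) {
  const int nA = angles.size();
  const int ns = filtered.ncol();
  const double c0 = (n - 1) / 2.0;
  const double s0 = (ns - 1) / 2.0;
  NumericMatrix out(n, n);
  for (int a = 0; a < nA; ++a) {
    const double ca = std::cos(angles[a]);
    const double sa = std::sin(angles[a]);
    for (int iy = 0; iy < n; ++iy) {
      const double yc = iy - c0;
      for (int ix = 0; ix < n; ++ix) {
        const double xc = ix - c0;
        const double s = xc * ca + yc * sa + s0;
        const int is = (int)std::floor(s);
        if (is < 0 || is >= ns - 1) continue;
        const double fs = s - is;
        out(ix, iy) += (1 - fs) * filtered(a, is) + fs * filtered(a, is + 1);
      }
    }
  }
  const double w = M_PI / nA;
  for (int i = 0; i < n * n; ++i) out[i] *= w;
  return out;
}
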