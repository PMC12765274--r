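#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Axis-angle propagation of independent spin-1/2 Bloch vectors through a
// piecewise-constant driving field. Each step rotates every magnetization
// vector right-handedly about its effective field (scale*wx, scale*wy,
// offset) by |field| * dt (generator dM/dt = B x M). Rotations preserve the
// vector norm to machine precision, which is the point of using the exact
// rotation instead of a finite-difference integrator.
//
// M: 3 x nspins, one column per spin; offsets: rad/s, one per spin;
// wx, wy: rad/s, one per time step; dt: s; scale: B1 scale factor.
// [[Rcpp::export(name = ".bloch_propagate_cpp")]]
NumericMatrix bloch_propagate_cpp(NumericMatrix M, NumericVector offsets,
                                  NumericVector wx, NumericVector wy,
                                  double dt, double scale) {
  const int ns = M.ncol();
  const int nt = wx.size();
  if (M.nrow() != 3) stop("M must be a 3 x nspins matrix");
  if (offsets.size() != ns) stop("one offset per spin is required");
  if (wy.size() != nt) stop("wx and wy must have equal length");
  NumericMatrix out = clone(M);
  for (int k = 0; k < nt; ++k) {
    const double bx = scale * wx[k];
    const double by = scale * wy[k];
    for (int i = 0; i < ns; ++i) {
      const double bz = offsets[i];
      const double bnorm = std::sqrt(bx * bx + by * by + bz * bz);
      if (bnorm == 0.0) continue;
      const double theta = bnorm * dt;
      const double nx = bx / bnorm, ny = by / bnorm, nz = bz / bnorm;
      const double c = std::cos(theta), s = std::sin(theta);
      const double mx = out(0, i), my = out(1, i), mz = out(2, i);
      const double dot = nx * mx + ny * my + nz * mz;
      const double cx = ny * mz - nz * my;
      const double cy = nz * mx - nx * mz;
      const double cz = nx * my - ny * mx;
      const double f = (1.0 - c) * dot;
      out(0, i) = mx * c + cx * s + nx * f;
      out(1, i) = my * c + cy * s + ny * f;
      out(2, i) = mz * c + cz * s + nz * f;
    }
  }
  return out;
}
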