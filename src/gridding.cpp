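#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Kaiser-Bessel gridding kernels for the 3D NUFFT. Coordinates arrive in
// oversampled-grid units (u = k * voxel_size * n_oversampled per axis); the
// FFTs themselves are done in R. Kernel support is `width` grid cells.

static inline double kb(double u, double width, double beta) {
  double t = 2.0 * u / width;
  double s = 1.0 - t * t;
  if (s < 0.0) return 0.0;
  return R::bessel_i(beta * std::sqrt(s), 0.0, 1.0);
}

// Per-sample kernel weights along one axis: fills idx (0-based, wrapped) and w.
static inline int axis_weights(double u, int nos, double width, double beta,
                               int *idx, double *w) {
  int lo = (int)std::ceil(u - width / 2.0);
  int hi = (int)std::floor(u + width / 2.0);
  int m = 0;
  for (int g = lo; g <= hi; ++g) {
    double wk = kb(u - g, width, beta);
    if (wk <= 0.0) continue;
    int wrapped = g % nos;
    if (wrapped < 0) wrapped += nos;
    idx[m] = wrapped;
    w[m] = wk;
    ++m;
  }
  return m;
}

// Interpolate oversampled spectrum at nonuniform points (forward direction).
// spec: complex vector of length nos1*nos2*nos3 (column-major, unshifted FFT
// layout); u: n x 3 matrix of grid-unit coordinates.
// [[Rcpp::export(name = ".kb_interp3")]]
ComplexVector kb_interp3(ComplexVector spec, IntegerVector nos,
                         NumericMatrix u, double width, double beta) {
  int n1 = nos[0], n2 = nos[1], n3 = nos[2];
  R_xlen_t n = u.nrow();
  ComplexVector out(n);
  std::vector<int> i1(16), i2(16), i3(16);
  std::vector<double> w1(16), w2(16), w3(16);
  for (R_xlen_t j = 0; j < n; ++j) {
    int m1 = axis_weights(u(j, 0), n1, width, beta, i1.data(), w1.data());
    int m2 = axis_weights(u(j, 1), n2, width, beta, i2.data(), w2.data());
    int m3 = axis_weights(u(j, 2), n3, width, beta, i3.data(), w3.data());
    double sr = 0.0, si = 0.0;
    for (int c = 0; c < m3; ++c) {
      R_xlen_t off3 = (R_xlen_t)i3[c] * n1 * n2;
      for (int b = 0; b < m2; ++b) {
        R_xlen_t off2 = off3 + (R_xlen_t)i2[b] * n1;
        double wbc = w2[b] * w3[c];
        for (int a = 0; a < m1; ++a) {
          Rcomplex v = spec[off2 + i1[a]];
          double wt = w1[a] * wbc;
          sr += wt * v.r;
          si += wt * v.i;
        }
      }
    }
    out[j].r = sr;
    out[j].i = si;
  }
  return out;
}

// Spread nonuniform samples onto the oversampled grid (adjoint direction).
// [[Rcpp::export(name = ".kb_spread3")]]
ComplexVector kb_spread3(ComplexVector vals, IntegerVector nos,
                         NumericMatrix u, double width, double beta) {
  int n1 = nos[0], n2 = nos[1], n3 = nos[2];
  R_xlen_t n = u.nrow();
  ComplexVector grid((R_xlen_t)n1 * n2 * n3);
  std::vector<int> i1(16), i2(16), i3(16);
  std::vector<double> w1(16), w2(16), w3(16);
  for (R_xlen_t j = 0; j < n; ++j) {
    int m1 = axis_weights(u(j, 0), n1, width, beta, i1.data(), w1.data());
    int m2 = axis_weights(u(j, 1), n2, width, beta, i2.data(), w2.data());
    int m3 = axis_weights(u(j, 2), n3, width, beta, i3.data(), w3.data());
    double vr = vals[j].r, vi = vals[j].i;
    for (int c = 0; c < m3; ++c) {
      R_xlen_t off3 = (R_xlen_t)i3[c] * n1 * n2;
      for (int b = 0; b < m2; ++b) {
        R_xlen_t off2 = off3 + (R_xlen_t)i2[b] * n1;
        double wbc = w2[b] * w3[c];
        for (int a = 0; a < m1; ++a) {
          double wt = w1[a] * wbc;
          grid[off2 + i1[a]].r += wt * vr;
          grid[off2 + i1[a]].i += wt * vi;
        }
      }
    }
  }
  return grid;
}

// Flood fill: connected component (6-connectivity) of `candidate` voxels
// containing any seed voxel. Arrays are logical vectors over an n1*n2*n3 grid.
// [[Rcpp::export(name = ".flood_fill3")]]
LogicalVector flood_fill3(LogicalVector candidate, LogicalVector seed,
                          IntegerVector dims) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  LogicalVector out(ntot);
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < ntot; ++i)
    if (seed[i] && candidate[i] && !out[i]) { out[i] = true; stack.push_back(i); }
  while (!stack.empty()) {
    R_xlen_t i = stack.back(); stack.pop_back();
    int z = (int)(i / ((R_xlen_t)n1 * n2));
    int rem = (int)(i % ((R_xlen_t)n1 * n2));
    int y = rem / n1, x = rem % n1;
    const int dx[6] = {-1, 1, 0, 0, 0, 0};
    const int dy[6] = {0, 0, -1, 1, 0, 0};
    const int dz[6] = {0, 0, 0, 0, -1, 1};
    for (int d = 0; d < 6; ++d) {
      int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
      if (xx < 0 || xx >= n1 || yy < 0 || yy >= n2 || zz < 0 || zz >= n3) continue;
      R_xlen_t jj = (R_xlen_t)zz * n1 * n2 + (R_xlen_t)yy * n1 + xx;
      if (candidate[jj] && !out[jj]) { out[jj] = true; stack.push_back(jj); }
    }
  }
  return out;
}
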