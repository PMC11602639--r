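// Inner loops for volume resampling and metric evaluation.
//
// Coordinates are 0-based voxel indices; the R side converts between mm and
// voxel units and builds the affine map (A, b) so that an output voxel at
// index x samples the source volume at A*x + b.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Keys cubic convolution kernel, a = -0.5 (the "bicubic" of Matlab/scikit-image)
static inline double cubic_w(double x) {
  x = std::fabs(x);
  if (x < 1.0) return ((1.5 * x - 2.5) * x) * x + 1.0;
  if (x < 2.0) return ((-0.5 * x + 2.5) * x - 4.0) * x + 2.0;
  return 0.0;
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Sample vol at fractional voxel coordinate (x,y,z). Points outside the grid
// hull [0, d-1] per axis get `fill`; inside, cubic uses edge replication for
// the neighbourhood.
static double sample_one(const double *vol, int d0, int d1, int d2,
                         double x, double y, double z, int interp, double fill) {
  if (x < 0.0 || x > d0 - 1 || y < 0.0 || y > d1 - 1 || z < 0.0 || z > d2 - 1)
    return fill;
  const R_xlen_t s1 = d0, s2 = (R_xlen_t)d0 * d1;
  if (interp == 0) { // trilinear
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 >= d0 - 1) x0 = d0 - 2; if (x0 < 0) x0 = 0;
    if (y0 >= d1 - 1) y0 = d1 - 2; if (y0 < 0) y0 = 0;
    if (z0 >= d2 - 1) z0 = d2 - 2; if (z0 < 0) z0 = 0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    if (d0 == 1) { x0 = 0; fx = 0.0; }
    if (d1 == 1) { y0 = 0; fy = 0.0; }
    if (d2 == 1) { z0 = 0; fz = 0.0; }
    int x1 = clampi(x0 + 1, 0, d0 - 1), y1 = clampi(y0 + 1, 0, d1 - 1),
        z1 = clampi(z0 + 1, 0, d2 - 1);
    const double *p = vol;
    double c00 = p[x0 + s1 * y0 + s2 * z0] * (1 - fx) + p[x1 + s1 * y0 + s2 * z0] * fx;
    double c10 = p[x0 + s1 * y1 + s2 * z0] * (1 - fx) + p[x1 + s1 * y1 + s2 * z0] * fx;
    double c01 = p[x0 + s1 * y0 + s2 * z1] * (1 - fx) + p[x1 + s1 * y0 + s2 * z1] * fx;
    double c11 = p[x0 + s1 * y1 + s2 * z1] * (1 - fx) + p[x1 + s1 * y1 + s2 * z1] * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    return c0 * (1 - fz) + c1 * fz;
  }
  // tricubic (separable Keys)
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double wx[4], wy[4], wz[4];
  int ix[4], iy[4], iz[4];
  for (int m = 0; m < 4; ++m) {
    int o = m - 1;
    wx[m] = cubic_w(x - (x0 + o)); ix[m] = clampi(x0 + o, 0, d0 - 1);
    wy[m] = cubic_w(y - (y0 + o)); iy[m] = clampi(y0 + o, 0, d1 - 1);
    wz[m] = cubic_w(z - (z0 + o)); iz[m] = clampi(z0 + o, 0, d2 - 1);
  }
  double acc = 0.0;
  for (int kz = 0; kz < 4; ++kz) {
    if (wz[kz] == 0.0) continue;
    double accz = 0.0;
    for (int ky = 0; ky < 4; ++ky) {
      if (wy[ky] == 0.0) continue;
      const double *row = vol + s1 * iy[ky] + s2 * iz[kz];
      double accy = 0.0;
      for (int kx = 0; kx < 4; ++kx)
        accy += wx[kx] * row[ix[kx]];
      accz += wy[ky] * accy;
    }
    acc += wz[kz] * accz;
  }
  return acc;
}

// [[Rcpp::export]]
NumericVector cpp_affine_resample(NumericVector vol, IntegerVector dim,
                                  NumericMatrix A, NumericVector b,
                                  int interp, double fill) {
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  NumericVector out((R_xlen_t)d0 * d1 * d2);
  const double *pv = vol.begin();
  double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2),
         a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2),
         a20 = A(2, 0), a21 = A(2, 1), a22 = A(2, 2);
  R_xlen_t idx = 0;
  for (int k = 0; k < d2; ++k)
    for (int j = 0; j < d1; ++j) {
      double cx = a01 * j + a02 * k + b[0];
      double cy = a11 * j + a12 * k + b[1];
      double cz = a21 * j + a22 * k + b[2];
      for (int i = 0; i < d0; ++i, ++idx)
        out[idx] = sample_one(pv, d0, d1, d2,
                              a00 * i + cx, a10 * i + cy, a20 * i + cz,
                              interp, fill);
    }
  return out;
}

// Sample the source volume over a set of index boxes (n x 6 matrix of 0-based
// inclusive bounds i0,i1,j0,j1,k0,k1), mapping each box voxel through A*x + b.
// Values are concatenated box by box, first index fastest.
// [[Rcpp::export]]
NumericVector cpp_sample_boxes(NumericVector vol, IntegerVector dim,
                               IntegerMatrix boxes, NumericMatrix A,
                               NumericVector b, int interp, double fill) {
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  const double *pv = vol.begin();
  R_xlen_t total = 0;
  for (int r = 0; r < boxes.nrow(); ++r)
    total += (R_xlen_t)(boxes(r, 1) - boxes(r, 0) + 1) *
             (boxes(r, 3) - boxes(r, 2) + 1) * (boxes(r, 5) - boxes(r, 4) + 1);
  NumericVector out(total);
  double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2),
         a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2),
         a20 = A(2, 0), a21 = A(2, 1), a22 = A(2, 2);
  R_xlen_t idx = 0;
  for (int r = 0; r < boxes.nrow(); ++r) {
    for (int k = boxes(r, 4); k <= boxes(r, 5); ++k)
      for (int j = boxes(r, 2); j <= boxes(r, 3); ++j) {
        double cx = a01 * j + a02 * k + b[0];
        double cy = a11 * j + a12 * k + b[1];
        double cz = a21 * j + a22 * k + b[2];
        for (int i = boxes(r, 0); i <= boxes(r, 1); ++i, ++idx)
          out[idx] = sample_one(pv, d0, d1, d2,
                                a00 * i + cx, a10 * i + cy, a20 * i + cz,
                                interp, fill);
      }
  }
  return out;
}

// Separable same-size convolution along each axis with zero padding.
// [[Rcpp::export]]
NumericVector cpp_sep_conv3(NumericVector vol, IntegerVector dim,
                            NumericVector kernel) {
  int d[3] = {dim[0], dim[1], dim[2]};
  int klen = kernel.size(), half = klen / 2;
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  NumericVector cur = clone(vol);
  NumericVector nxt(n);
  R_xlen_t stride[3] = {1, (R_xlen_t)d[0], (R_xlen_t)d[0] * d[1]};
  for (int ax = 0; ax < 3; ++ax) {
    if (d[ax] == 1) continue;
    R_xlen_t st = stride[ax];
    int len = d[ax];
    // iterate over all lines along axis `ax`
    for (R_xlen_t base = 0; base < n; ++base) {
      // compute position along axis; only process when at line start
      R_xlen_t pos = (base / st) % len;
      if (pos != 0) continue;
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        for (int m = 0; m < klen; ++m) {
          int src = i + m - half;
          if (src < 0 || src >= len) continue;
          acc += kernel[m] * cur[base + (R_xlen_t)src * st];
        }
        nxt[base + (R_xlen_t)i * st] = acc;
      }
    }
    std::swap(cur, nxt);
  }
  return cur;
}
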