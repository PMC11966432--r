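#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Volumes are stored as R arrays in (x, y, z, channel) order, column-major,
// so voxel (ix,iy,iz,c) lives at ix + X*(iy + Y*(iz + Z*c)).
// Convolution weights are (k, k, k, c_in, c_out).

static inline int idiv_ceil(int a, int b) {  // b > 0
  return (a >= 0) ? (a + b - 1) / b : -((-a) / b);
}
static inline int idiv_floor(int a, int b) {  // b > 0
  return (a >= 0) ? a / b : -((-a + b - 1) / b);
}

// Strided 3D cross-correlation: y[o, co] = b[co] + sum_{ci,k} x[o*s + k - p, ci] w[k, ci, co]
// [[Rcpp::export]]
NumericVector cpp_conv3d(NumericVector x, IntegerVector xd,
                         NumericVector w, int k, int ci, int co,
                         NumericVector b, int s, int p) {
  const int X = xd[0], Y = xd[1], Z = xd[2];
  const int Xo = (X + 2 * p - k) / s + 1;
  const int Yo = (Y + 2 * p - k) / s + 1;
  const int Zo = (Z + 2 * p - k) / s + 1;
  NumericVector y((R_xlen_t)Xo * Yo * Zo * co);
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  double* yp = REAL(y);
  for (int c2 = 0; c2 < co; ++c2) {
    double* y0 = yp + (R_xlen_t)Xo * Yo * Zo * c2;
    const double bv = b[c2];
    for (R_xlen_t i = 0; i < (R_xlen_t)Xo * Yo * Zo; ++i) y0[i] = bv;
    for (int c1 = 0; c1 < ci; ++c1) {
      const double* x0 = xp + (R_xlen_t)X * Y * Z * c1;
      for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
      for (int kx = 0; kx < k; ++kx) {
        const double wv = wp[kx + k * (ky + k * (kz + k * (c1 + (R_xlen_t)ci * c2)))];
        const int qx = p - kx, qy = p - ky, qz = p - kz;
        const int ox0 = std::max(0, idiv_ceil(qx, s));
        const int ox1 = std::min(Xo - 1, idiv_floor(X - 1 + qx, s));
        const int oy0 = std::max(0, idiv_ceil(qy, s));
        const int oy1 = std::min(Yo - 1, idiv_floor(Y - 1 + qy, s));
        const int oz0 = std::max(0, idiv_ceil(qz, s));
        const int oz1 = std::min(Zo - 1, idiv_floor(Z - 1 + qz, s));
        for (int oz = oz0; oz <= oz1; ++oz) {
          const int iz = oz * s - qz;
          for (int oy = oy0; oy <= oy1; ++oy) {
            const int iy = oy * s - qy;
            double* yr = y0 + (R_xlen_t)Xo * (oy + (R_xlen_t)Yo * oz);
            const double* xr = x0 + (R_xlen_t)X * (iy + (R_xlen_t)Y * iz);
            if (s == 1) {
              for (int ox = ox0; ox <= ox1; ++ox) yr[ox] += wv * xr[ox - qx];
            } else {
              for (int ox = ox0; ox <= ox1; ++ox) yr[ox] += wv * xr[ox * s - qx];
            }
          }
        }
      }
    }
  }
  return y;
}

// Gradient of cpp_conv3d w.r.t. its input: scatter gy back through the kernel.
// Also serves as the forward pass of the stride-s transposed convolution.
// [[Rcpp::export]]
NumericVector cpp_conv3d_bwd_x(NumericVector gy, IntegerVector yd,
                               NumericVector w, int k, int ci, int co,
                               IntegerVector xd, int s, int p) {
  const int X = xd[0], Y = xd[1], Z = xd[2];
  const int Xo = yd[0], Yo = yd[1], Zo = yd[2];
  NumericVector gx((R_xlen_t)X * Y * Z * ci);
  const double* gp = REAL(gy);
  const double* wp = REAL(w);
  double* xp = REAL(gx);
  for (int c2 = 0; c2 < co; ++c2) {
    const double* g0 = gp + (R_xlen_t)Xo * Yo * Zo * c2;
    for (int c1 = 0; c1 < ci; ++c1) {
      double* x0 = xp + (R_xlen_t)X * Y * Z * c1;
      for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
      for (int kx = 0; kx < k; ++kx) {
        const double wv = wp[kx + k * (ky + k * (kz + k * (c1 + (R_xlen_t)ci * c2)))];
        const int qx = p - kx, qy = p - ky, qz = p - kz;
        const int ox0 = std::max(0, idiv_ceil(qx, s));
        const int ox1 = std::min(Xo - 1, idiv_floor(X - 1 + qx, s));
        const int oy0 = std::max(0, idiv_ceil(qy, s));
        const int oy1 = std::min(Yo - 1, idiv_floor(Y - 1 + qy, s));
        const int oz0 = std::max(0, idiv_ceil(qz, s));
        const int oz1 = std::min(Zo - 1, idiv_floor(Z - 1 + qz, s));
        for (int oz = oz0; oz <= oz1; ++oz) {
          const int iz = oz * s - qz;
          for (int oy = oy0; oy <= oy1; ++oy) {
            const int iy = oy * s - qy;
            const double* gr = g0 + (R_xlen_t)Xo * (oy + (R_xlen_t)Yo * oz);
            double* xr = x0 + (R_xlen_t)X * (iy + (R_xlen_t)Y * iz);
            for (int ox = ox0; ox <= ox1; ++ox) xr[ox * s - qx] += wv * gr[ox];
          }
        }
      }
    }
  }
  return gx;
}

// Gradient of cpp_conv3d w.r.t. the kernel.
// [[Rcpp::export]]
NumericVector cpp_conv3d_bwd_w(NumericVector x, IntegerVector xd,
                               NumericVector gy, IntegerVector yd,
                               int k, int ci, int co, int s, int p) {
  const int X = xd[0], Y = xd[1], Z = xd[2];
  const int Xo = yd[0], Yo = yd[1], Zo = yd[2];
  NumericVector gw((R_xlen_t)k * k * k * ci * co);
  const double* xp = REAL(x);
  const double* gp = REAL(gy);
  double* wp = REAL(gw);
  for (int c2 = 0; c2 < co; ++c2) {
    const double* g0 = gp + (R_xlen_t)Xo * Yo * Zo * c2;
    for (int c1 = 0; c1 < ci; ++c1) {
      const double* x0 = xp + (R_xlen_t)X * Y * Z * c1;
      for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
      for (int kx = 0; kx < k; ++kx) {
        const int qx = p - kx, qy = p - ky, qz = p - kz;
        const int ox0 = std::max(0, idiv_ceil(qx, s));
        const int ox1 = std::min(Xo - 1, idiv_floor(X - 1 + qx, s));
        const int oy0 = std::max(0, idiv_ceil(qy, s));
        const int oy1 = std::min(Yo - 1, idiv_floor(Y - 1 + qy, s));
        const int oz0 = std::max(0, idiv_ceil(qz, s));
        const int oz1 = std::min(Zo - 1, idiv_floor(Z - 1 + qz, s));
        double acc = 0.0;
        for (int oz = oz0; oz <= oz1; ++oz) {
          const int iz = oz * s - qz;
          for (int oy = oy0; oy <= oy1; ++oy) {
            const int iy = oy * s - qy;
            const double* gr = g0 + (R_xlen_t)Xo * (oy + (R_xlen_t)Yo * oz);
            const double* xr = x0 + (R_xlen_t)X * (iy + (R_xlen_t)Y * iz);
            for (int ox = ox0; ox <= ox1; ++ox) acc += xr[ox * s - qx] * gr[ox];
          }
        }
        wp[kx + k * (ky + k * (kz + k * (c1 + (R_xlen_t)ci * c2)))] = acc;
      }
    }
  }
  return gw;
}

// Trilinear / nearest resampling on the half-voxel-centre convention:
// source coordinate of output index o along an axis is (o + 0.5) * scale - 0.5,
// clamped to the valid index range.  scale = 1 is an exact identity.
// [[Rcpp::export]]
NumericVector cpp_resize3d(NumericVector x, IntegerVector xd,
                           IntegerVector od, NumericVector scale,
                           bool nearest) {
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  const int Xo = od[0], Yo = od[1], Zo = od[2];
  NumericVector y((R_xlen_t)Xo * Yo * Zo * C);
  std::vector<int> i0x(Xo), i1x(Xo), i0y(Yo), i1y(Yo), i0z(Zo), i1z(Zo);
  std::vector<double> tx(Xo), ty(Yo), tz(Zo);
  const int nin[3] = {X, Y, Z};
  const int nout[3] = {Xo, Yo, Zo};
  for (int ax = 0; ax < 3; ++ax) {
    int* i0 = ax == 0 ? i0x.data() : (ax == 1 ? i0y.data() : i0z.data());
    int* i1 = ax == 0 ? i1x.data() : (ax == 1 ? i1y.data() : i1z.data());
    double* t = ax == 0 ? tx.data() : (ax == 1 ? ty.data() : tz.data());
    for (int o = 0; o < nout[ax]; ++o) {
      double src = (o + 0.5) * scale[ax] - 0.5;
      if (nearest) {
        int i = (int)std::floor(src + 0.5);
        i = std::min(std::max(i, 0), nin[ax] - 1);
        i0[o] = i; i1[o] = i; t[o] = 0.0;
      } else {
        if (src < 0) src = 0;
        if (src > nin[ax] - 1) src = nin[ax] - 1;
        int i = (int)std::floor(src);
        if (i > nin[ax] - 2) i = std::max(0, nin[ax] - 2);
        i0[o] = i; i1[o] = std::min(i + 1, nin[ax] - 1);
        t[o] = src - i;
      }
    }
  }
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int c = 0; c < C; ++c) {
    const double* x0 = xp + (R_xlen_t)X * Y * Z * c;
    double* y0 = yp + (R_xlen_t)Xo * Yo * Zo * c;
    for (int oz = 0; oz < Zo; ++oz)
    for (int oy = 0; oy < Yo; ++oy)
    for (int ox = 0; ox < Xo; ++ox) {
      const double wx1 = tx[ox], wy1 = ty[oy], wz1 = tz[oz];
      const double wx0 = 1 - wx1, wy0 = 1 - wy1, wz0 = 1 - wz1;
      double v = 0.0;
      const int xs[2] = {i0x[ox], i1x[ox]}, ys[2] = {i0y[oy], i1y[oy]}, zs[2] = {i0z[oz], i1z[oz]};
      const double wxs[2] = {wx0, wx1}, wys[2] = {wy0, wy1}, wzs[2] = {wz0, wz1};
      for (int a = 0; a < 2; ++a)
      for (int bq = 0; bq < 2; ++bq)
      for (int cc = 0; cc < 2; ++cc) {
        const double ww = wxs[a] * wys[bq] * wzs[cc];
        if (ww != 0.0)
          v += ww * x0[xs[a] + (R_xlen_t)X * (ys[bq] + (R_xlen_t)Y * zs[cc])];
      }
      y0[ox + (R_xlen_t)Xo * (oy + (R_xlen_t)Yo * oz)] = v;
    }
  }
  return y;
}

// Adjoint of trilinear cpp_resize3d (scatter of the same weights); used for
// backpropagation through attention-coefficient upsampling.
// [[Rcpp::export]]
NumericVector cpp_resize3d_adj(NumericVector gy, IntegerVector od,
                               IntegerVector xd, NumericVector scale) {
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  const int Xo = od[0], Yo = od[1], Zo = od[2];
  NumericVector gx((R_xlen_t)X * Y * Z * C);
  std::vector<int> i0x(Xo), i0y(Yo), i0z(Zo);
  std::vector<double> tx(Xo), ty(Yo), tz(Zo);
  const int nin[3] = {X, Y, Z};
  const int nout[3] = {Xo, Yo, Zo};
  for (int ax = 0; ax < 3; ++ax) {
    int* i0 = ax == 0 ? i0x.data() : (ax == 1 ? i0y.data() : i0z.data());
    double* t = ax == 0 ? tx.data() : (ax == 1 ? ty.data() : tz.data());
    for (int o = 0; o < nout[ax]; ++o) {
      double src = (o + 0.5) * scale[ax] - 0.5;
      if (src < 0) src = 0;
      if (src > nin[ax] - 1) src = nin[ax] - 1;
      int i = (int)std::floor(src);
      if (i > nin[ax] - 2) i = std::max(0, nin[ax] - 2);
      i0[o] = i; t[o] = src - i;
    }
  }
  const double* gp = REAL(gy);
  double* xp = REAL(gx);
  for (int c = 0; c < C; ++c) {
    double* x0 = xp + (R_xlen_t)X * Y * Z * c;
    const double* g0 = gp + (R_xlen_t)Xo * Yo * Zo * c;
    for (int oz = 0; oz < Zo; ++oz)
    for (int oy = 0; oy < Yo; ++oy)
    for (int ox = 0; ox < Xo; ++ox) {
      const double g = g0[ox + (R_xlen_t)Xo * (oy + (R_xlen_t)Yo * oz)];
      if (g == 0.0) continue;
      const int x0i = i0x[ox], y0i = i0y[oy], z0i = i0z[oz];
      const int x1i = std::min(x0i + 1, X - 1), y1i = std::min(y0i + 1, Y - 1), z1i = std::min(z0i + 1, Z - 1);
      const double wx1 = tx[ox], wy1 = ty[oy], wz1 = tz[oz];
      const double wx0 = 1 - wx1, wy0 = 1 - wy1, wz0 = 1 - wz1;
      const int xs[2] = {x0i, x1i}, ys[2] = {y0i, y1i}, zs[2] = {z0i, z1i};
      const double wxs[2] = {wx0, wx1}, wys[2] = {wy0, wy1}, wzs[2] = {wz0, wz1};
      for (int a = 0; a < 2; ++a)
      for (int bq = 0; bq < 2; ++bq)
      for (int cc = 0; cc < 2; ++cc) {
        const double ww = wxs[a] * wys[bq] * wzs[cc];
        if (ww != 0.0)
          x0[xs[a] + (R_xlen_t)X * (ys[bq] + (R_xlen_t)Y * zs[cc])] += ww * g;
      }
    }
  }
  return gx;
}

// Exact anisotropic squared Euclidean distance transform
// (Felzenszwalb & Huttenlocher lower-envelope-of-parabolas, one pass per axis).
// Returns for every voxel the squared distance in mm^2 to the nearest
// foreground (mask > 0.5) voxel centre.
static const double EDT_INF = 1e30;

static void edt_1d(const double* f, double* d, int n, double w2,
                   int* v, double* z) {
  const double NINF = -std::numeric_limits<double>::infinity();
  const double PINF = std::numeric_limits<double>::infinity();
  int kk = 0;
  v[0] = 0;
  z[0] = NINF;   // true infinities: intersections of parabolas with 1e30
  z[1] = PINF;   // offsets can exceed any finite sentinel
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[kk]] + w2 * v[kk] * v[kk])) /
          (2.0 * w2 * (q - v[kk]));
      if (s <= z[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    z[kk] = s;
    z[kk + 1] = PINF;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    d[q] = w2 * (double)(q - v[kk]) * (q - v[kk]) + f[v[kk]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_sq_edt(NumericVector mask, IntegerVector d,
                         NumericVector spacing) {
  const int X = d[0], Y = d[1], Z = d[2];
  NumericVector out((R_xlen_t)X * Y * Z);
  double* o = REAL(out);
  const double* m = REAL(mask);
  for (R_xlen_t i = 0; i < (R_xlen_t)X * Y * Z; ++i)
    o[i] = (m[i] > 0.5) ? 0.0 : EDT_INF;
  const int nmax = std::max(X, std::max(Y, Z));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x axis
  double w2 = spacing[0] * spacing[0];
  for (int iz = 0; iz < Z; ++iz)
  for (int iy = 0; iy < Y; ++iy) {
    double* row = o + (R_xlen_t)X * (iy + (R_xlen_t)Y * iz);
    edt_1d(row, dd.data(), X, w2, v.data(), z.data());
    std::copy(dd.begin(), dd.begin() + X, row);
  }
  // y axis
  w2 = spacing[1] * spacing[1];
  for (int iz = 0; iz < Z; ++iz)
  for (int ix = 0; ix < X; ++ix) {
    for (int iy = 0; iy < Y; ++iy) f[iy] = o[ix + (R_xlen_t)X * (iy + (R_xlen_t)Y * iz)];
    edt_1d(f.data(), dd.data(), Y, w2, v.data(), z.data());
    for (int iy = 0; iy < Y; ++iy) o[ix + (R_xlen_t)X * (iy + (R_xlen_t)Y * iz)] = dd[iy];
  }
  // z axis
  w2 = spacing[2] * spacing[2];
  for (int iy = 0; iy < Y; ++iy)
  for (int ix = 0; ix < X; ++ix) {
    for (int iz = 0; iz < Z; ++iz) f[iz] = o[ix + (R_xlen_t)X * (iy + (R_xlen_t)Y * iz)];
    edt_1d(f.data(), dd.data(), Z, w2, v.data(), z.data());
    for (int iz = 0; iz < Z; ++iz) o[ix + (R_xlen_t)X * (iy + (R_xlen_t)Y * iz)] = dd[iz];
  }
  return out;
}
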