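// Numerical kernels for the 3D->2D segmentation network and the synthetic
// generator: im2col/GEMM convolutions (forward + backward), max pooling with
// argmax bookkeeping, trilinear and area-weighted resampling, an anisotropic
// exact Euclidean distance transform, and 8-connectivity labelling.
//
// Array layout follows R column-major order throughout:
//   3D feature maps: (nz, nx, ny, c)  -> linear index z + nz*(x + nx*(y + ny*ch))
//   2D feature maps: (nx, ny, c)      -> linear index x + nx*(y + ny*ch)

#define USE_FC_LEN_T
#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline IntegerVector dims_of(const NumericVector& x) {
  SEXP d = x.attr("dim");
  if (Rf_isNull(d)) stop("array input must carry a dim attribute");
  return IntegerVector(d);
}

// ---------------------------------------------------------------------------
// 3D convolution, kernel 3x3x3 (pad 1) or 1x1x1.
//
// The 3x3x3 path avoids materializing an im2col patch matrix: the input is
// copied once into a zero-padded buffer in which every kernel offset is a
// plain linear pointer shift, and the 27 per-offset GEMMs are cache-blocked
// over slabs of the slow (y) axis so the accumulator stays resident.
// Weight matrix W: (27 * c_in) x c_out, row index = o + 27*c with
// o = (dz+1) + 3*(dx+1) + 9*(dy+1).

struct Pad3 {
  int nz, nx, ny, nzp, nxp, nyp;
  size_t npad;
};

static Pad3 pad_geom(int nz, int nx, int ny) {
  Pad3 g;
  g.nz = nz; g.nx = nx; g.ny = ny;
  g.nzp = nz + 2; g.nxp = nx + 2; g.nyp = ny + 2;
  g.npad = (size_t)g.nzp * g.nxp * g.nyp;
  return g;
}

// copy (nz,nx,ny,c) interior into the zero-padded buffer
static void pack_pad(const double* x, double* xp, const Pad3& g, int nc) {
  std::fill(xp, xp + g.npad * nc, 0.0);
  for (int c = 0; c < nc; ++c) {
    const double* src = x + (size_t)c * g.nz * g.nx * g.ny;
    double* dst = xp + (size_t)c * g.npad;
    for (int y = 0; y < g.ny; ++y)
      for (int xx = 0; xx < g.nx; ++xx) {
        const double* s = src + (size_t)g.nz * (xx + (size_t)g.nx * y);
        double* t = dst + 1 + (size_t)g.nzp * (xx + 1) +
                    (size_t)g.nzp * g.nxp * (y + 1);
        std::copy(s, s + g.nz, t);
      }
  }
}

// harvest padded-buffer interior back into an (nz,nx,ny,c) array
static void unpack_pad(const double* yp, double* y, const Pad3& g, int nc) {
  for (int c = 0; c < nc; ++c) {
    const double* src = yp + (size_t)c * g.npad;
    double* dst = y + (size_t)c * g.nz * g.nx * g.ny;
    for (int yy = 0; yy < g.ny; ++yy)
      for (int xx = 0; xx < g.nx; ++xx) {
        const double* s = src + 1 + (size_t)g.nzp * (xx + 1) +
                          (size_t)g.nzp * g.nxp * (yy + 1);
        double* t = dst + (size_t)g.nz * (xx + (size_t)g.nx * yy);
        std::copy(s, s + g.nz, t);
      }
  }
}

// repack W into 27 dense (ci x co) blocks
static void split_w(const double* W, double* Wo, int ci, int co) {
  for (int o = 0; o < 27; ++o)
    for (int j = 0; j < co; ++j)
      for (int c = 0; c < ci; ++c)
        Wo[(size_t)o * ci * co + c + (size_t)ci * j] =
            W[o + 27 * c + (size_t)27 * ci * j];
}

static int slab_planes(const Pad3& g, int ci, int co) {
  const double budget = 1.4e6 / 8.0;  // ~1.4 MB of doubles in cache
  int B = (int)(budget / ((double)g.nzp * g.nxp * (ci + co)));
  return std::max(1, std::min(B, g.nyp));
}

static void dgemm_(char ta, char tb, int m, int n, int kk, double alpha,
                   const double* A, int lda, const double* B, int ldb,
                   double beta, double* C, int ldc) {
  F77_CALL(dgemm)(&ta, &tb, &m, &n, &kk, &alpha, A, &lda, B, &ldb, &beta,
                  C, &ldc FCONE FCONE);
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, NumericMatrix W, NumericVector b,
                            int k) {
  IntegerVector d = dims_of(x);
  const int nz = d[0], nx = d[1], ny = d[2], ci = d.size() > 3 ? d[3] : 1;
  const int co = W.ncol();
  const size_t nvox = (size_t)nz * nx * ny;
  NumericVector y(nvox * co);
  y.attr("dim") = IntegerVector::create(nz, nx, ny, co);
  if (k == 1) {
    arma::mat Wm(W.begin(), W.nrow(), co, false);
    arma::mat Xm(x.begin(), nvox, ci, false);
    arma::mat Ym(y.begin(), nvox, co, false);
    Ym = Xm * Wm;
  } else {
    const Pad3 g = pad_geom(nz, nx, ny);
    static std::vector<double> xp, yp, Wo;
    xp.resize(g.npad * ci);
    yp.resize(g.npad * co);
    Wo.resize(27 * (size_t)ci * co);
    pack_pad(x.begin(), xp.data(), g, ci);
    std::fill(yp.begin(), yp.end(), 0.0);
    split_w(W.begin(), Wo.data(), ci, co);
    const size_t plane = (size_t)g.nzp * g.nxp;
    const int B = slab_planes(g, ci, co);
    for (int y0 = 0; y0 < g.nyp; y0 += B) {
      const size_t r0 = plane * y0;
      const size_t r1 = plane * std::min(g.nyp, y0 + B);
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          for (int dz = -1; dz <= 1; ++dz) {
            const int o = (dz + 1) + 3 * (dx + 1) + 9 * (dy + 1);
            const long off = dz + (long)g.nzp * dx + (long)plane * dy;
            const size_t lo = std::max((long)r0, -off < 0 ? 0L : -off);
            const size_t hi =
                std::min((long)r1, (long)g.npad - (off > 0 ? off : 0L));
            if (hi <= lo) continue;
            dgemm_('N', 'N', (int)(hi - lo), co, ci, 1.0,
                   xp.data() + lo + off, (int)g.npad,
                   Wo.data() + (size_t)o * ci * co, ci, 1.0,
                   yp.data() + lo, (int)g.npad);
          }
    }
    unpack_pad(yp.data(), y.begin(), g, co);
  }
  for (int c = 0; c < co; ++c) {
    double* yc = y.begin() + (size_t)c * nvox;
    const double bc = b[c];
    for (size_t i = 0; i < nvox; ++i) yc[i] += bc;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, NumericMatrix W, NumericVector dy, int k) {
  IntegerVector d = dims_of(x);
  const int nz = d[0], nx = d[1], ny = d[2], ci = d.size() > 3 ? d[3] : 1;
  const int co = W.ncol();
  const size_t nvox = (size_t)nz * nx * ny;
  arma::mat Wm(W.begin(), W.nrow(), co, false);
  arma::mat dYm(dy.begin(), nvox, co, false);
  NumericMatrix dW(W.nrow(), co);
  NumericVector db(co);
  for (int c = 0; c < co; ++c) db[c] = arma::accu(dYm.col(c));
  NumericVector dx(x.size());
  dx.attr("dim") = d;
  if (k == 1) {
    arma::mat dWm(dW.begin(), W.nrow(), co, false);
    arma::mat Xm(x.begin(), nvox, ci, false);
    arma::mat dXm(dx.begin(), nvox, ci, false);
    dWm = Xm.t() * dYm;
    dXm = dYm * Wm.t();
    return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
  }
  const Pad3 g = pad_geom(nz, nx, ny);
  static std::vector<double> xp, dyp, dxp, Wo, dWo;
  xp.resize(g.npad * ci);
  dyp.resize(g.npad * co);
  dxp.resize(g.npad * ci);
  Wo.resize(27 * (size_t)ci * co);
  dWo.assign(27 * (size_t)ci * co, 0.0);
  pack_pad(x.begin(), xp.data(), g, ci);
  pack_pad(dy.begin(), dyp.data(), g, co);
  std::fill(dxp.begin(), dxp.end(), 0.0);
  split_w(W.begin(), Wo.data(), ci, co);
  const size_t plane = (size_t)g.nzp * g.nxp;
  const int B = slab_planes(g, ci, co);
  for (int y0 = 0; y0 < g.nyp; y0 += B) {
    const size_t r0 = plane * y0;
    const size_t r1 = plane * std::min(g.nyp, y0 + B);
    for (int dyy = -1; dyy <= 1; ++dyy)
      for (int dxx = -1; dxx <= 1; ++dxx)
        for (int dzz = -1; dzz <= 1; ++dzz) {
          const int o = (dzz + 1) + 3 * (dxx + 1) + 9 * (dyy + 1);
          const long off = dzz + (long)g.nzp * dxx + (long)plane * dyy;
          const size_t lo = std::max((long)r0, -off < 0 ? 0L : -off);
          const size_t hi =
              std::min((long)r1, (long)g.npad - (off > 0 ? off : 0L));
          if (hi <= lo) continue;
          const int m = (int)(hi - lo);
          // dW_o += x_shifted^T * dy   (ci x co)
          dgemm_('T', 'N', ci, co, m, 1.0, xp.data() + lo + off, (int)g.npad,
                 dyp.data() + lo, (int)g.npad, 1.0,
                 dWo.data() + (size_t)o * ci * co, ci);
          // dx_shifted += dy * W_o^T
          dgemm_('N', 'T', m, ci, co, 1.0, dyp.data() + lo, (int)g.npad,
                 Wo.data() + (size_t)o * ci * co, ci, 1.0,
                 dxp.data() + lo + off, (int)g.npad);
        }
  }
  unpack_pad(dxp.data(), dx.begin(), g, ci);
  // fold dW_o blocks back into the (27*ci) x co layout
  for (int o = 0; o < 27; ++o)
    for (int j = 0; j < co; ++j)
      for (int c = 0; c < ci; ++c)
        dW(o + 27 * c, j) = dWo[(size_t)o * ci * co + c + (size_t)ci * j];
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// ---------------------------------------------------------------------------
// 2D convolution, kernel 3x3 (pad 1) or 1x1. Images are small; single im2col.

static void im2col2(const double* x, int nx, int ny, int ci, int k,
                    arma::mat& P) {
  const int p = (k - 1) / 2, k2 = k * k;
  const size_t m = (size_t)nx * ny;
  P.set_size(m, k2 * ci);
  for (int c = 0; c < ci; ++c) {
    const double* xc = x + (size_t)c * m;
    for (int dy = -p; dy <= p; ++dy)
      for (int dx = -p; dx <= p; ++dx) {
        const int o = (dx + p) + k * (dy + p);
        double* col = P.colptr(o + k2 * c);
        size_t r = 0;
        for (int y = 0; y < ny; ++y) {
          const int sy = y + dy;
          const bool yok = sy >= 0 && sy < ny;
          for (int xx = 0; xx < nx; ++xx, ++r) {
            const int sx = xx + dx;
            col[r] = (yok && sx >= 0 && sx < nx) ? xc[(size_t)nx * sy + sx]
                                                 : 0.0;
          }
        }
      }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericMatrix W, NumericVector b,
                            int k) {
  IntegerVector d = dims_of(x);
  const int nx = d[0], ny = d[1], ci = d.size() > 2 ? d[2] : 1;
  const int co = W.ncol();
  const size_t m = (size_t)nx * ny;
  NumericVector y(m * co);
  y.attr("dim") = IntegerVector::create(nx, ny, co);
  arma::mat Wm(W.begin(), W.nrow(), co, false);
  arma::mat Ym(y.begin(), m, co, false);
  if (k == 1) {
    arma::mat Xm(x.begin(), m, ci, false);
    Ym = Xm * Wm;
  } else {
    arma::mat P;
    im2col2(x.begin(), nx, ny, ci, k, P);
    Ym = P * Wm;
  }
  for (int c = 0; c < co; ++c) Ym.col(c) += b[c];
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericMatrix W, NumericVector dy, int k) {
  IntegerVector d = dims_of(x);
  const int nx = d[0], ny = d[1], ci = d.size() > 2 ? d[2] : 1;
  const int co = W.ncol();
  const size_t m = (size_t)nx * ny;
  arma::mat Wm(W.begin(), W.nrow(), co, false);
  arma::mat dYm(dy.begin(), m, co, false);
  NumericMatrix dW(W.nrow(), co);
  arma::mat dWm(dW.begin(), W.nrow(), co, false);
  NumericVector db(co);
  for (int c = 0; c < co; ++c) db[c] = arma::accu(dYm.col(c));
  NumericVector dx(x.size());
  dx.attr("dim") = d;
  if (k == 1) {
    arma::mat Xm(x.begin(), m, ci, false);
    arma::mat dXm(dx.begin(), m, ci, false);
    dWm = Xm.t() * dYm;
    dXm = dYm * Wm.t();
    return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
  }
  const int p = (k - 1) / 2, k2 = k * k;
  arma::mat P;
  im2col2(x.begin(), nx, ny, ci, k, P);
  dWm = P.t() * dYm;
  arma::mat dP = dYm * Wm.t();
  for (int c = 0; c < ci; ++c) {
    double* xc = dx.begin() + (size_t)c * m;
    for (int dyy = -p; dyy <= p; ++dyy)
      for (int dxx = -p; dxx <= p; ++dxx) {
        const int o = (dxx + p) + k * (dyy + p);
        const double* col = dP.colptr(o + k2 * c);
        size_t r = 0;
        for (int y = 0; y < ny; ++y) {
          const int sy = y + dyy;
          if (sy < 0 || sy >= ny) { r += nx; continue; }
          for (int xx = 0; xx < nx; ++xx, ++r) {
            const int sx = xx + dxx;
            if (sx >= 0 && sx < nx) xc[(size_t)nx * sy + sx] += col[r];
          }
        }
      }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// ---------------------------------------------------------------------------
// Max pooling over (z,x,y) with per-axis factor 1 or 2 (ceiling semantics on
// odd extents). Returns pooled array and 1-based argmax indices into input.

// [[Rcpp::export]]
List cpp_maxpool3d(NumericVector x, int fz, int fx, int fy) {
  IntegerVector d = dims_of(x);
  const int nz = d[0], nx = d[1], ny = d[2], nc = d.size() > 3 ? d[3] : 1;
  const int oz = (nz + fz - 1) / fz, ox = (nx + fx - 1) / fx,
            oy = (ny + fy - 1) / fy;
  NumericVector y((size_t)oz * ox * oy * nc);
  y.attr("dim") = IntegerVector::create(oz, ox, oy, nc);
  IntegerVector idx(y.size());
  const size_t plane = (size_t)nz * nx;
  size_t r = 0;
  for (int c = 0; c < nc; ++c) {
    const double* xc = x.begin() + (size_t)c * plane * ny;
    for (int y0 = 0; y0 < oy; ++y0)
      for (int x0 = 0; x0 < ox; ++x0)
        for (int z0 = 0; z0 < oz; ++z0, ++r) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bi = 0;
          for (int yy = y0 * fy; yy < std::min(ny, y0 * fy + fy); ++yy)
            for (int xx = x0 * fx; xx < std::min(nx, x0 * fx + fx); ++xx)
              for (int zz = z0 * fz; zz < std::min(nz, z0 * fz + fz); ++zz) {
                const size_t li = plane * yy + (size_t)nz * xx + zz;
                if (xc[li] > best) { best = xc[li]; bi = li; }
              }
          y[r] = best;
          idx[r] = (int)(bi + (size_t)c * plane * ny) + 1;
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bw(IntegerVector idx, NumericVector dy,
                               IntegerVector in_dim) {
  size_t n = 1;
  for (int i = 0; i < in_dim.size(); ++i) n *= in_dim[i];
  NumericVector dx(n);
  dx.attr("dim") = in_dim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i] - 1] += dy[i];
  return dx;
}

// ---------------------------------------------------------------------------
// Trilinear resampling of a 3D grid, cell-center alignment, edge clamping.

// [[Rcpp::export]]
NumericVector cpp_resample3d(NumericVector x, IntegerVector out_dim) {
  IntegerVector d = dims_of(x);
  const int nz = d[0], nx = d[1], ny = d[2];
  const int oz = out_dim[0], ox = out_dim[1], oy = out_dim[2];
  NumericVector y((size_t)oz * ox * oy);
  y.attr("dim") = IntegerVector::create(oz, ox, oy);
  std::vector<int> z0v(oz), x0v(ox), y0v(oy);
  std::vector<double> zfv(oz), xfv(ox), yfv(oy);
  auto prep = [](int n_in, int n_out, std::vector<int>& i0,
                 std::vector<double>& fr) {
    for (int i = 0; i < n_out; ++i) {
      double s = (i + 0.5) * (double)n_in / n_out - 0.5;
      if (s < 0) s = 0;
      if (s > n_in - 1) s = n_in - 1;
      int lo = (int)std::floor(s);
      if (lo > n_in - 2) lo = std::max(0, n_in - 2);
      i0[i] = lo;
      fr[i] = n_in == 1 ? 0.0 : s - lo;
    }
  };
  prep(nz, oz, z0v, zfv);
  prep(nx, ox, x0v, xfv);
  prep(ny, oy, y0v, yfv);
  const size_t plane = (size_t)nz * nx;
  size_t r = 0;
  for (int j = 0; j < oy; ++j) {
    const int yy = y0v[j];
    const int y1 = std::min(ny - 1, yy + 1);
    const double fy = yfv[j];
    for (int i = 0; i < ox; ++i) {
      const int xx = x0v[i];
      const int x1 = std::min(nx - 1, xx + 1);
      const double fx = xfv[i];
      for (int kz = 0; kz < oz; ++kz, ++r) {
        const int zz = z0v[kz];
        const int z1 = std::min(nz - 1, zz + 1);
        const double fz = zfv[kz];
        auto at = [&](int a, int b, int cc) {
          return x[plane * cc + (size_t)nz * b + a];
        };
        double c00 = at(zz, xx, yy) * (1 - fz) + at(z1, xx, yy) * fz;
        double c10 = at(zz, x1, yy) * (1 - fz) + at(z1, x1, yy) * fz;
        double c01 = at(zz, xx, y1) * (1 - fz) + at(z1, xx, y1) * fz;
        double c11 = at(zz, x1, y1) * (1 - fz) + at(z1, x1, y1) * fz;
        double c0 = c00 * (1 - fx) + c10 * fx;
        double c1 = c01 * (1 - fx) + c11 * fx;
        y[r] = c0 * (1 - fy) + c1 * fy;
      }
    }
  }
  return y;
}

// ---------------------------------------------------------------------------
// Exact area-weighted resampling of a 2D grid: each output cell is the
// average of the input weighted by geometric overlap (conserves the mean).

// [[Rcpp::export]]
NumericMatrix cpp_resample2d_area(NumericMatrix x, int ox, int oy) {
  const int nx = x.nrow(), ny = x.ncol();
  NumericMatrix y(ox, oy);
  const double sx = (double)nx / ox, sy = (double)ny / oy;
  for (int j = 0; j < oy; ++j) {
    const double ylo = j * sy, yhi = (j + 1) * sy;
    const int jy0 = (int)std::floor(ylo), jy1 = std::min(ny, (int)std::ceil(yhi));
    for (int i = 0; i < ox; ++i) {
      const double xlo = i * sx, xhi = (i + 1) * sx;
      const int ix0 = (int)std::floor(xlo), ix1 = std::min(nx, (int)std::ceil(xhi));
      double acc = 0.0, wtot = 0.0;
      for (int jj = jy0; jj < jy1; ++jj) {
        const double wy = std::min(yhi, (double)jj + 1) - std::max(ylo, (double)jj);
        for (int ii = ix0; ii < ix1; ++ii) {
          const double wx =
              std::min(xhi, (double)ii + 1) - std::max(xlo, (double)ii);
          const double w = wx * wy;
          acc += w * x(ii, jj);
          wtot += w;
        }
      }
      y(i, j) = wtot > 0 ? acc / wtot : 0.0;
    }
  }
  return y;
}

// ---------------------------------------------------------------------------
// Anisotropic exact Euclidean distance transform (Felzenszwalb-Huttenlocher):
// distance in mm from every pixel to the nearest foreground pixel.

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double s) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  const double s2 = s * s;
  for (int q = 1; q < n; ++q) {
    double num, den, sp;
    while (true) {
      num = (f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k]);
      den = 2.0 * s2 * (q - v[k]);
      sp = num / den;
      if (sp <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = sp;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = (double)(q - v[k]);
    d[q] = s2 * dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt2d(LogicalMatrix mask, double dx, double dy) {
  const int nx = mask.nrow(), ny = mask.ncol();
  const double INF = 1e30;
  NumericMatrix d2(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) d2(i, j) = mask(i, j) ? 0.0 : INF;
  std::vector<double> f(std::max(nx, ny)), out(std::max(nx, ny));
  for (int j = 0; j < ny; ++j) {  // pass along x
    for (int i = 0; i < nx; ++i) f[i] = d2(i, j);
    dt1d(f, out, nx, dx);
    for (int i = 0; i < nx; ++i) d2(i, j) = out[i];
  }
  for (int i = 0; i < nx; ++i) {  // pass along y
    for (int j = 0; j < ny; ++j) f[j] = d2(i, j);
    dt1d(f, out, ny, dy);
    for (int j = 0; j < ny; ++j) d2(i, j) = std::sqrt(out[j]);
  }
  return d2;
}

// ---------------------------------------------------------------------------
// 8-connectivity component labelling of a binary en face mask.

// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  const int nx = mask.nrow(), ny = mask.ncol();
  IntegerMatrix lab(nx, ny);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back({i, j});
      lab(i, j) = next;
      while (!stack.empty()) {
        auto [ci, cj] = stack.back();
        stack.pop_back();
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            const int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= nx || nj < 0 || nj >= ny) continue;
            if (mask(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              stack.push_back({ni, nj});
            }
          }
      }
    }
  return lab;
}

// ---------------------------------------------------------------------------
// axial collapse: per-(x,y,channel) softmax over z with learned per-channel
// logit scale/offset, then 1x1 channel mixing. Forward returns the softmax
// weights and pre-mix collapsed features for the backward pass.

// [[Rcpp::export]]
List cpp_collapse_fw(NumericVector f, NumericVector a, NumericVector b,
                     NumericMatrix mixW, NumericVector mixb) {
  IntegerVector d = dims_of(f);
  const int nz = d[0];
  const size_t m = (size_t)d[1] * d[2];
  const int nc = d[3];
  NumericVector wm((size_t)nz * m * nc);
  NumericMatrix S1((int)m, nc);
  for (int c = 0; c < nc; ++c) {
    const double ac = a[c], bc = b[c];
    const double* fc = f.begin() + (size_t)c * nz * m;
    double* wc = wm.begin() + (size_t)c * nz * m;
    double* s1 = S1.begin() + (size_t)c * m;
    for (size_t col = 0; col < m; ++col) {
      const double* fz = fc + col * nz;
      double* wz = wc + col * nz;
      double mx = -INFINITY;
      for (int z = 0; z < nz; ++z) {
        wz[z] = ac * fz[z] + bc;
        if (wz[z] > mx) mx = wz[z];
      }
      double s = 0.0;
      for (int z = 0; z < nz; ++z) { wz[z] = std::exp(wz[z] - mx); s += wz[z]; }
      double acc = 0.0;
      for (int z = 0; z < nz; ++z) { wz[z] /= s; acc += wz[z] * fz[z]; }
      s1[col] = acc;
    }
  }
  NumericVector out(m * nc);
  out.attr("dim") = IntegerVector::create(d[1], d[2], nc);
  arma::mat S1m(S1.begin(), m, nc, false);
  arma::mat Wm(mixW.begin(), nc, nc, false);
  arma::mat Om(out.begin(), m, nc, false);
  Om = S1m * Wm;
  for (int c = 0; c < nc; ++c) Om.col(c) += mixb[c];
  return List::create(_["out"] = out, _["wm"] = wm, _["S1"] = S1);
}

// [[Rcpp::export]]
List cpp_collapse_bw(NumericVector f, NumericVector wm, NumericMatrix S1,
                     NumericVector a, NumericMatrix mixW, NumericVector dOut) {
  IntegerVector d = dims_of(f);
  const int nz = d[0];
  const size_t m = (size_t)d[1] * d[2];
  const int nc = d[3];
  arma::mat dOm(dOut.begin(), m, nc, false);
  arma::mat S1m(S1.begin(), m, nc, false);
  arma::mat Wm(mixW.begin(), nc, nc, false);
  NumericMatrix dmixW(nc, nc);
  arma::mat dmixWm(dmixW.begin(), nc, nc, false);
  dmixWm = S1m.t() * dOm;
  NumericVector dmixb(nc);
  for (int c = 0; c < nc; ++c) dmixb[c] = arma::accu(dOm.col(c));
  arma::mat dS1 = dOm * Wm.t();
  NumericVector dF(f.size());
  dF.attr("dim") = d;
  NumericVector da(nc), db(nc);
  for (int c = 0; c < nc; ++c) {
    const double ac = a[c];
    const double* fc = f.begin() + (size_t)c * nz * m;
    const double* wc = wm.begin() + (size_t)c * nz * m;
    double* dfc = dF.begin() + (size_t)c * nz * m;
    double dac = 0.0, dbc = 0.0;
    for (size_t col = 0; col < m; ++col) {
      const double g = dS1(col, c);
      const double* fz = fc + col * nz;
      const double* wz = wc + col * nz;
      double* dfz = dfc + col * nz;
      double dot = 0.0;
      for (int z = 0; z < nz; ++z) dot += wz[z] * fz[z];
      for (int z = 0; z < nz; ++z) {
        const double dl = (nz > 1) ? wz[z] * g * (fz[z] - dot) : 0.0;
        dfz[z] = wz[z] * g + dl * ac;
        dac += dl * fz[z];
        dbc += dl;
      }
    }
    da[c] = dac;
    db[c] = dbc;
  }
  return List::create(_["dF"] = dF, _["da"] = da, _["db"] = db,
                      _["dmixW"] = dmixW, _["dmixb"] = dmixb);
}
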