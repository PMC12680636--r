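#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Linear index into a column-major (X,Y,Z) array, 0-based.
static inline R_xlen_t lin3(int i, int j, int k, int X, int Y) {
  return (R_xlen_t)i + (R_xlen_t)X * ((R_xlen_t)j + (R_xlen_t)Y * (R_xlen_t)k);
}

// ---------------------------------------------------------------------------
// Trilinear resampling through an affine voxel-to-voxel map.
// M (4x4) sends 0-based output voxel indices to 0-based input voxel
// coordinates. Out-of-field samples take `pad`.
// [[Rcpp::export(name = ".resample_affine_cpp")]]
NumericVector resample_affine_cpp(NumericVector src, IntegerVector src_dim,
                                  IntegerVector out_dim, NumericMatrix M,
                                  double pad) {
  const int Xs = src_dim[0], Ys = src_dim[1], Zs = src_dim[2];
  const int Xo = out_dim[0], Yo = out_dim[1], Zo = out_dim[2];
  NumericVector out((R_xlen_t)Xo * Yo * Zo);
  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  R_xlen_t q = 0;
  for (int k = 0; k < Zo; ++k) {
    for (int j = 0; j < Yo; ++j) {
      double bx = m01 * j + m02 * k + m03;
      double by = m11 * j + m12 * k + m13;
      double bz = m21 * j + m22 * k + m23;
      for (int i = 0; i < Xo; ++i, ++q) {
        double sx = m00 * i + bx, sy = m10 * i + by, sz = m20 * i + bz;
        int ix = (int)std::floor(sx), iy = (int)std::floor(sy),
            iz = (int)std::floor(sz);
        if (ix < -1 || iy < -1 || iz < -1 || ix >= Xs || iy >= Ys || iz >= Zs) {
          out[q] = pad;
          continue;
        }
        double fx = sx - ix, fy = sy - iy, fz = sz - iz;
        double acc = 0.0;
        for (int dz = 0; dz < 2; ++dz) {
          int z = iz + dz;
          double wz = dz ? fz : 1.0 - fz;
          if (wz == 0.0) continue;
          for (int dy = 0; dy < 2; ++dy) {
            int y = iy + dy;
            double wy = dy ? fy : 1.0 - fy;
            if (wy == 0.0) continue;
            for (int dx = 0; dx < 2; ++dx) {
              int x = ix + dx;
              double wx = dx ? fx : 1.0 - fx;
              if (wx == 0.0) continue;
              double v = (x < 0 || y < 0 || z < 0 || x >= Xs || y >= Ys ||
                          z >= Zs)
                             ? pad
                             : src[lin3(x, y, z, Xs, Ys)];
              acc += wx * wy * wz * v;
            }
          }
        }
        out[q] = acc;
      }
    }
  }
  out.attr("dim") = out_dim;
  return out;
}

// ---------------------------------------------------------------------------
// Trilinear sampling at a set of output-voxel points (n x 3, 0-based) mapped
// through M into the source voxel grid. Used by the registration objective so
// a full-grid resample is not needed per function evaluation.
// [[Rcpp::export(name = ".sample_affine_points_cpp")]]
NumericVector sample_affine_points_cpp(NumericVector src, IntegerVector src_dim,
                                       NumericMatrix pts, NumericMatrix M,
                                       double pad) {
  const int Xs = src_dim[0], Ys = src_dim[1], Zs = src_dim[2];
  const int n = pts.nrow();
  NumericVector out(n);
  for (int r = 0; r < n; ++r) {
    double i = pts(r, 0), j = pts(r, 1), k = pts(r, 2);
    double sx = M(0,0) * i + M(0,1) * j + M(0,2) * k + M(0,3);
    double sy = M(1,0) * i + M(1,1) * j + M(1,2) * k + M(1,3);
    double sz = M(2,0) * i + M(2,1) * j + M(2,2) * k + M(2,3);
    int ix = (int)std::floor(sx), iy = (int)std::floor(sy),
        iz = (int)std::floor(sz);
    if (ix < -1 || iy < -1 || iz < -1 || ix >= Xs || iy >= Ys || iz >= Zs) {
      out[r] = pad;
      continue;
    }
    double fx = sx - ix, fy = sy - iy, fz = sz - iz;
    double acc = 0.0;
    for (int dz = 0; dz < 2; ++dz) {
      int z = iz + dz;
      double wz = dz ? fz : 1.0 - fz;
      if (wz == 0.0) continue;
      for (int dy = 0; dy < 2; ++dy) {
        int y = iy + dy;
        double wy = dy ? fy : 1.0 - fy;
        if (wy == 0.0) continue;
        for (int dx = 0; dx < 2; ++dx) {
          int x = ix + dx;
          double wx = dx ? fx : 1.0 - fx;
          if (wx == 0.0) continue;
          double v = (x < 0 || y < 0 || z < 0 || x >= Xs || y >= Ys || z >= Zs)
                         ? pad
                         : src[lin3(x, y, z, Xs, Ys)];
          acc += wx * wy * wz * v;
        }
      }
    }
    out[r] = acc;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing, sigma in voxel units per axis, replicate
// padding at the edges (keeps constant volumes exactly constant).
static void smooth_axis(std::vector<double>& a, std::vector<double>& b, int X,
                        int Y, int Z, int axis, double sigma) {
  if (sigma <= 0) return;
  int R = (int)std::ceil(4.0 * sigma);
  std::vector<double> ker(2 * R + 1);
  double s = 0;
  for (int t = -R; t <= R; ++t) {
    ker[t + R] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += ker[t + R];
  }
  for (auto& v : ker) v /= s;
  int n[3] = {X, Y, Z};
  int L = n[axis];
  for (int k = 0; k < Z; ++k)
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i) {
        int idx[3] = {i, j, k};
        double acc = 0;
        for (int t = -R; t <= R; ++t) {
          int p = idx[axis] + t;
          if (p < 0) p = 0;
          if (p >= L) p = L - 1;
          int c[3] = {i, j, k};
          c[axis] = p;
          acc += ker[t + R] * a[lin3(c[0], c[1], c[2], X, Y)];
        }
        b[lin3(i, j, k, X, Y)] = acc;
      }
  a.swap(b);
}

// [[Rcpp::export(name = ".gauss_smooth_cpp")]]
NumericVector gauss_smooth_cpp(NumericVector vol, IntegerVector dim,
                               NumericVector sigma_vox) {
  const int X = dim[0], Y = dim[1], Z = dim[2];
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  for (int ax = 0; ax < 3; ++ax) smooth_axis(a, b, X, Y, Z, ax, sigma_vox[ax]);
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// 3D cross-correlation with bias (the CNN convolution contract).
// x: (X,Y,Z,Ci); w: (kx,ky,kz,Ci,Co); b: (Co). padding: 0 = valid, 1 = same.
// [[Rcpp::export(name = ".conv3d_fwd_cpp")]]
NumericVector conv3d_fwd_cpp(NumericVector x, IntegerVector xd,
                             NumericVector w, IntegerVector wd,
                             NumericVector bias, int same) {
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3];
  const int Kx = wd[0], Ky = wd[1], Kz = wd[2], Co = wd[4];
  const int px = same ? (Kx - 1) / 2 : 0, py = same ? (Ky - 1) / 2 : 0,
            pz = same ? (Kz - 1) / 2 : 0;
  const int Xo = same ? X : X - Kx + 1, Yo = same ? Y : Y - Ky + 1,
            Zo = same ? Z : Z - Kz + 1;
  if (Xo < 1 || Yo < 1 || Zo < 1) stop("kernel larger than padded input");
  const R_xlen_t npx = (R_xlen_t)X * Y * Z;
  const R_xlen_t npo = (R_xlen_t)Xo * Yo * Zo;
  NumericVector out(npo * Co);
  for (int co = 0; co < Co; ++co) {
    double bcs = bias[co];
    for (int zo = 0; zo < Zo; ++zo)
      for (int yo = 0; yo < Yo; ++yo)
        for (int xo = 0; xo < Xo; ++xo) {
          double acc = bcs;
          for (int ci = 0; ci < Ci; ++ci) {
            const double* xs = &x[0] + npx * ci;
            const double* ws =
                &w[0] + (R_xlen_t)Kx * Ky * Kz * (ci + (R_xlen_t)Ci * co);
            for (int dz = 0; dz < Kz; ++dz) {
              int z = zo + dz - pz;
              if (z < 0 || z >= Z) continue;
              for (int dy = 0; dy < Ky; ++dy) {
                int y = yo + dy - py;
                if (y < 0 || y >= Y) continue;
                int xlo = std::max(0, px - xo), xhi = std::min(Kx, X + px - xo);
                const double* xrow = xs + lin3(0, y, z, X, Y) + xo - px;
                const double* wrow = ws + lin3(0, dy, dz, Kx, Ky);
                for (int dx = xlo; dx < xhi; ++dx)
                  acc += xrow[dx] * wrow[dx];
              }
            }
          }
          out[lin3(xo, yo, zo, Xo, Yo) + npo * co] = acc;
        }
  }
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, Co);
  return out;
}

// Gradients of the cross-correlation wrt input, weights and bias.
// [[Rcpp::export(name = ".conv3d_bwd_cpp")]]
List conv3d_bwd_cpp(NumericVector x, IntegerVector xd, NumericVector w,
                    IntegerVector wd, NumericVector gy, int same) {
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3];
  const int Kx = wd[0], Ky = wd[1], Kz = wd[2], Co = wd[4];
  const int px = same ? (Kx - 1) / 2 : 0, py = same ? (Ky - 1) / 2 : 0,
            pz = same ? (Kz - 1) / 2 : 0;
  const int Xo = same ? X : X - Kx + 1, Yo = same ? Y : Y - Ky + 1,
            Zo = same ? Z : Z - Kz + 1;
  const R_xlen_t npx = (R_xlen_t)X * Y * Z;
  const R_xlen_t npo = (R_xlen_t)Xo * Yo * Zo;
  NumericVector gx(npx * Ci), gw(w.size()), gb(Co);
  for (int co = 0; co < Co; ++co) {
    const double* gys = &gy[0] + npo * co;
    double bacc = 0;
    for (R_xlen_t q = 0; q < npo; ++q) bacc += gys[q];
    gb[co] = bacc;
    for (int ci = 0; ci < Ci; ++ci) {
      const double* xs = &x[0] + npx * ci;
      double* gxs = &gx[0] + npx * ci;
      const double* ws =
          &w[0] + (R_xlen_t)Kx * Ky * Kz * (ci + (R_xlen_t)Ci * co);
      double* gws = &gw[0] + (R_xlen_t)Kx * Ky * Kz * (ci + (R_xlen_t)Ci * co);
      for (int zo = 0; zo < Zo; ++zo)
        for (int yo = 0; yo < Yo; ++yo)
          for (int xo = 0; xo < Xo; ++xo) {
            double g = gys[lin3(xo, yo, zo, Xo, Yo)];
            if (g == 0.0) continue;
            for (int dz = 0; dz < Kz; ++dz) {
              int z = zo + dz - pz;
              if (z < 0 || z >= Z) continue;
              for (int dy = 0; dy < Ky; ++dy) {
                int y = yo + dy - py;
                if (y < 0 || y >= Y) continue;
                for (int dx = 0; dx < Kx; ++dx) {
                  int xx = xo + dx - px;
                  if (xx < 0 || xx >= X) continue;
                  R_xlen_t xi = lin3(xx, y, z, X, Y);
                  R_xlen_t wi = lin3(dx, dy, dz, Kx, Ky);
                  gxs[xi] += g * ws[wi];
                  gws[wi] += g * xs[xi];
                }
              }
            }
          }
    }
  }
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// 2x2x2 max pooling, stride 2, no padding (floor division of each side).
// Returns pooled values plus 0-based argmax linear indices into the input
// channel-stacked array, for the backward pass.
// [[Rcpp::export(name = ".maxpool3d_fwd_cpp")]]
List maxpool3d_fwd_cpp(NumericVector x, IntegerVector xd) {
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  if (Xo < 1 || Yo < 1 || Zo < 1) stop("input too small to pool");
  const R_xlen_t npx = (R_xlen_t)X * Y * Z;
  const R_xlen_t npo = (R_xlen_t)Xo * Yo * Zo;
  NumericVector out(npo * C);
  NumericVector arg(npo * C);  // stored as doubles: may exceed INT_MAX
  for (int c = 0; c < C; ++c) {
    const double* xs = &x[0] + npx * c;
    for (int k = 0; k < Zo; ++k)
      for (int j = 0; j < Yo; ++j)
        for (int i = 0; i < Xo; ++i) {
          double best = -HUGE_VAL;
          R_xlen_t bidx = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                R_xlen_t q = lin3(2 * i + dx, 2 * j + dy, 2 * k + dz, X, Y);
                if (xs[q] > best) {
                  best = xs[q];
                  bidx = q;
                }
              }
          R_xlen_t o = lin3(i, j, k, Xo, Yo) + npo * c;
          out[o] = best;
          arg[o] = (double)(bidx + npx * c);
        }
  }
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool3d_bwd_cpp")]]
NumericVector maxpool3d_bwd_cpp(NumericVector gy, NumericVector argmax,
                                IntegerVector xd) {
  NumericVector gx((R_xlen_t)xd[0] * xd[1] * xd[2] * xd[3]);
  for (R_xlen_t q = 0; q < gy.size(); ++q)
    gx[(R_xlen_t)argmax[q]] += gy[q];
  gx.attr("dim") = xd;
  return gx;
}

// ---------------------------------------------------------------------------
// Strict-by-tie-break local maxima over the 26-neighborhood.
// A voxel is a peak if it exceeds every in-bounds neighbor, with exact ties
// resolved in favor of the lowest linear index. Returns 0-based (i,j,k) rows.
// [[Rcpp::export(name = ".local_maxima_cpp")]]
IntegerMatrix local_maxima_cpp(NumericVector vol, IntegerVector dim,
                               LogicalVector mask, double threshold) {
  const int X = dim[0], Y = dim[1], Z = dim[2];
  std::vector<int> hits;
  for (int k = 0; k < Z; ++k)
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i) {
        R_xlen_t q = lin3(i, j, k, X, Y);
        if (!mask[q]) continue;
        double v = vol[q];
        if (!(v > threshold)) continue;
        bool ok = true;
        for (int dz = -1; dz <= 1 && ok; ++dz)
          for (int dy = -1; dy <= 1 && ok; ++dy)
            for (int dx = -1; dx <= 1 && ok; ++dx) {
              if (!dx && !dy && !dz) continue;
              int x = i + dx, y = j + dy, z = k + dz;
              if (x < 0 || y < 0 || z < 0 || x >= X || y >= Y || z >= Z)
                continue;
              R_xlen_t n = lin3(x, y, z, X, Y);
              double u = vol[n];
              if (u > v || (u == v && n < q)) ok = false;
            }
        if (ok) {
          hits.push_back(i);
          hits.push_back(j);
          hits.push_back(k);
        }
      }
  int n = hits.size() / 3;
  IntegerMatrix out(n, 3);
  for (int r = 0; r < n; ++r)
    for (int c = 0; c < 3; ++c) out(r, c) = hits[3 * r + c];
  return out;
}
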