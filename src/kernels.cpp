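// Numerical kernels: 3D convolution (im2col + GEMM), 2x max-pooling,
// 2x2x2/stride-2 transpose convolution, affine grid resampling
// (nearest / trilinear / Catmull-Rom tricubic), all-pairs surface
// distances, and the joint-histogram NMI objective for registration.
//
// Volumes are passed as matrices with one row per voxel (column-major
// voxel order: ix + nx*(iy + ny*iz), matching R's array flattening) and
// one column per channel.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::uword vidx(int x, int y, int z, int nx, int ny) {
  return (arma::uword)x + (arma::uword)nx * ((arma::uword)y + (arma::uword)ny * (arma::uword)z);
}

// Build the im2col matrix for same-padded k^3 convolution.
// Column order matches R's flattening of a (k,k,k,cin) array:
// col = kx + k*(ky + k*(kz + k*c)).
static arma::mat im2col3(const arma::mat& x, int nx, int ny, int nz, int k) {
  const int cin = x.n_cols;
  const int p = (k - 1) / 2;
  const arma::uword nvox = (arma::uword)nx * ny * nz;
  arma::mat cols(nvox, (arma::uword)k * k * k * cin, arma::fill::zeros);
  for (int c = 0; c < cin; ++c) {
    for (int kz = 0; kz < k; ++kz) {
      for (int ky = 0; ky < k; ++ky) {
        for (int kx = 0; kx < k; ++kx) {
          const arma::uword col =
            (arma::uword)kx + (arma::uword)k * (ky + k * (kz + k * c));
          const int ox = kx - p, oy = ky - p, oz = kz - p;
          const int z0 = std::max(0, -oz), z1 = std::min(nz, nz - oz);
          const int y0 = std::max(0, -oy), y1 = std::min(ny, ny - oy);
          const int x0 = std::max(0, -ox), x1 = std::min(nx, nx - ox);
          for (int z = z0; z < z1; ++z) {
            for (int y = y0; y < y1; ++y) {
              const double* src = x.colptr(c) + vidx(x0 + ox, y + oy, z + oz, nx, ny);
              double* dst = cols.colptr(col) + vidx(x0, y, z, nx, ny);
              std::copy(src, src + (x1 - x0), dst);
            }
          }
        }
      }
    }
  }
  return cols;
}

// Scatter-add the im2col adjoint (col2im).
static arma::mat col2im3(const arma::mat& dcols, int nx, int ny, int nz,
                         int k, int cin) {
  const int p = (k - 1) / 2;
  const arma::uword nvox = (arma::uword)nx * ny * nz;
  arma::mat dx(nvox, cin, arma::fill::zeros);
  for (int c = 0; c < cin; ++c) {
    for (int kz = 0; kz < k; ++kz) {
      for (int ky = 0; ky < k; ++ky) {
        for (int kx = 0; kx < k; ++kx) {
          const arma::uword col =
            (arma::uword)kx + (arma::uword)k * (ky + k * (kz + k * c));
          const int ox = kx - p, oy = ky - p, oz = kz - p;
          const int z0 = std::max(0, -oz), z1 = std::min(nz, nz - oz);
          const int y0 = std::max(0, -oy), y1 = std::min(ny, ny - oy);
          const int x0 = std::max(0, -ox), x1 = std::min(nx, nx - ox);
          for (int z = z0; z < z1; ++z) {
            for (int y = y0; y < y1; ++y) {
              const double* src = dcols.colptr(col) + vidx(x0, y, z, nx, ny);
              double* dst = dx.colptr(c) + vidx(x0 + ox, y + oy, z + oz, nx, ny);
              for (int i = 0; i < x1 - x0; ++i) dst[i] += src[i];
            }
          }
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
arma::mat cpp_conv3d_forward(const arma::mat& x, const arma::mat& w,
                             const arma::vec& b, const arma::ivec& dims,
                             int k) {
  arma::mat y = im2col3(x, dims[0], dims[1], dims[2], k) * w;
  y.each_row() += b.t();
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_backward(const arma::mat& x, const arma::mat& w,
                         const arma::mat& dy, const arma::ivec& dims, int k) {
  arma::mat cols = im2col3(x, dims[0], dims[1], dims[2], k);
  arma::mat dw = cols.t() * dy;
  arma::vec db = arma::sum(dy, 0).t();
  arma::mat dcols = dy * w.t();
  arma::mat dx = col2im3(dcols, dims[0], dims[1], dims[2], k, x.n_cols);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2x2 max pooling, stride 2. Returns pooled values and the 1-based
// row index of each max for the backward pass. Ties go to the first
// (lowest-index) voxel.
// [[Rcpp::export]]
List cpp_maxpool2_forward(const arma::mat& x, const arma::ivec& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int mx = nx / 2, my = ny / 2, mz = nz / 2;
  const arma::uword c = x.n_cols;
  const arma::uword nout = (arma::uword)mx * my * mz;
  arma::mat y(nout, c);
  arma::umat idx(nout, c);
  for (arma::uword ch = 0; ch < c; ++ch) {
    const double* xc = x.colptr(ch);
    for (int z = 0; z < mz; ++z) {
      for (int yy = 0; yy < my; ++yy) {
        for (int xx = 0; xx < mx; ++xx) {
          double best = -std::numeric_limits<double>::infinity();
          arma::uword bi = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                arma::uword i = vidx(2 * xx + dx, 2 * yy + dy, 2 * z + dz, nx, ny);
                if (xc[i] > best) { best = xc[i]; bi = i; }
              }
          arma::uword o = vidx(xx, yy, z, mx, my);
          y(o, ch) = best;
          idx(o, ch) = bi + 1;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool2_backward(const arma::mat& dy, const arma::umat& idx,
                                arma::uword nvox_in) {
  arma::mat dx(nvox_in, dy.n_cols, arma::fill::zeros);
  for (arma::uword ch = 0; ch < dy.n_cols; ++ch)
    for (arma::uword i = 0; i < dy.n_rows; ++i)
      dx(idx(i, ch) - 1, ch) += dy(i, ch);
  return dx;
}

// Transpose convolution, kernel 2x2x2, stride 2 (non-overlapping).
// Weights as matrix (8*cin, cout), row = o + 8*ci with
// o = dx + 2*dy + 4*dz (R flattening of a (2,2,2) block per input chan).
// [[Rcpp::export]]
arma::mat cpp_tconv2_forward(const arma::mat& x, const arma::mat& w,
                             const arma::vec& b, const arma::ivec& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox_ = 2 * nx, oy_ = 2 * ny;
  const arma::uword cin = x.n_cols, cout = w.n_cols;
  const arma::uword nout = (arma::uword)8 * nx * ny * nz;
  arma::mat y(nout, cout);
  y.each_row() = b.t();
  for (int o = 0; o < 8; ++o) {
    const int dx = o & 1, dy = (o >> 1) & 1, dz = (o >> 2) & 1;
    arma::mat wo(cin, cout);
    for (arma::uword ci = 0; ci < cin; ++ci) wo.row(ci) = w.row(o + 8 * ci);
    arma::mat yo = x * wo;  // (nvox_in, cout)
    for (int z = 0; z < nz; ++z)
      for (int yy = 0; yy < ny; ++yy)
        for (int xx = 0; xx < nx; ++xx) {
          arma::uword src = vidx(xx, yy, z, nx, ny);
          arma::uword dst = vidx(2 * xx + dx, 2 * yy + dy, 2 * z + dz, ox_, oy_);
          y.row(dst) += yo.row(src);
        }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_tconv2_backward(const arma::mat& x, const arma::mat& w,
                         const arma::mat& dy, const arma::ivec& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox_ = 2 * nx, oy_ = 2 * ny;
  const arma::uword cin = x.n_cols, cout = w.n_cols;
  arma::mat dx_(x.n_rows, cin, arma::fill::zeros);
  arma::mat dw(w.n_rows, cout, arma::fill::zeros);
  arma::vec db = arma::sum(dy, 0).t();
  for (int o = 0; o < 8; ++o) {
    const int dxo = o & 1, dyo = (o >> 1) & 1, dzo = (o >> 2) & 1;
    arma::mat wo(cin, cout);
    for (arma::uword ci = 0; ci < cin; ++ci) wo.row(ci) = w.row(o + 8 * ci);
    arma::mat dyo_(x.n_rows, cout);
    for (int z = 0; z < nz; ++z)
      for (int yy = 0; yy < ny; ++yy)
        for (int xx = 0; xx < nx; ++xx) {
          arma::uword src = vidx(2 * xx + dxo, 2 * yy + dyo, 2 * z + dzo, ox_, oy_);
          dyo_.row(vidx(xx, yy, z, nx, ny)) = dy.row(src);
        }
    dx_ += dyo_ * wo.t();
    arma::mat dwo = x.t() * dyo_;  // (cin, cout)
    for (arma::uword ci = 0; ci < cin; ++ci) dw.row(o + 8 * ci) += dwo.row(ci);
  }
  return List::create(_["dx"] = dx_, _["dw"] = dw, _["db"] = db);
}

static inline double catmull_rom(double p0, double p1, double p2, double p3,
                                 double t) {
  return p1 + 0.5 * t * (p2 - p0 +
         t * (2.0 * p0 - 5.0 * p1 + 4.0 * p2 - p3 +
         t * (3.0 * (p1 - p2) + p3 - p0)));
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Resample a volume onto a new grid. M is a 4x4 matrix mapping 0-based
// output voxel indices to 0-based input voxel coordinates. mode: 0 =
// nearest, 1 = trilinear, 3 = tricubic (Catmull-Rom). Out-of-field -> 0.
// [[Rcpp::export]]
arma::vec cpp_resample_affine(const arma::vec& src, const arma::ivec& sdims,
                              const arma::mat& M, const arma::ivec& odims,
                              int mode) {
  const int nx = sdims[0], ny = sdims[1], nz = sdims[2];
  const int ox = odims[0], oy = odims[1], oz = odims[2];
  arma::vec out((arma::uword)ox * oy * oz, arma::fill::zeros);
  for (int z = 0; z < oz; ++z) {
    for (int y = 0; y < oy; ++y) {
      for (int x = 0; x < ox; ++x) {
        const double sx = M(0,0)*x + M(0,1)*y + M(0,2)*z + M(0,3);
        const double sy = M(1,0)*x + M(1,1)*y + M(1,2)*z + M(1,3);
        const double sz = M(2,0)*x + M(2,1)*y + M(2,2)*z + M(2,3);
        const arma::uword o = vidx(x, y, z, ox, oy);
        if (sx < -0.5 || sy < -0.5 || sz < -0.5 ||
            sx > nx - 0.5 || sy > ny - 0.5 || sz > nz - 0.5)
          continue;  // outside field of view -> background 0
        if (mode == 0) {
          int ix = clampi((int)std::lround(sx), 0, nx - 1);
          int iy = clampi((int)std::lround(sy), 0, ny - 1);
          int iz = clampi((int)std::lround(sz), 0, nz - 1);
          out[o] = src[vidx(ix, iy, iz, nx, ny)];
        } else if (mode == 1) {
          int ix = (int)std::floor(sx), iy = (int)std::floor(sy), iz = (int)std::floor(sz);
          double fx = sx - ix, fy = sy - iy, fz = sz - iz;
          double acc = 0.0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                double wgt = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
                if (wgt == 0.0) continue;
                int jx = clampi(ix + dx, 0, nx - 1);
                int jy = clampi(iy + dy, 0, ny - 1);
                int jz = clampi(iz + dz, 0, nz - 1);
                acc += wgt * src[vidx(jx, jy, jz, nx, ny)];
              }
          out[o] = acc;
        } else {
          int ix = (int)std::floor(sx), iy = (int)std::floor(sy), iz = (int)std::floor(sz);
          double fx = sx - ix, fy = sy - iy, fz = sz - iz;
          double cz[4];
          for (int dz = -1; dz <= 2; ++dz) {
            int jz = clampi(iz + dz, 0, nz - 1);
            double cy[4];
            for (int dy = -1; dy <= 2; ++dy) {
              int jy = clampi(iy + dy, 0, ny - 1);
              double cx[4];
              for (int dx = -1; dx <= 2; ++dx) {
                int jx = clampi(ix + dx, 0, nx - 1);
                cx[dx + 1] = src[vidx(jx, jy, jz, nx, ny)];
              }
              cy[dy + 1] = catmull_rom(cx[0], cx[1], cx[2], cx[3], fx);
            }
            cz[dz + 1] = catmull_rom(cy[0], cy[1], cy[2], cy[3], fy);
          }
          out[o] = catmull_rom(cz[0], cz[1], cz[2], cz[3], fz);
        }
      }
    }
  }
  return out;
}

// Sums of minimal Euclidean distances between two point sets (mm
// coordinates), for the average symmetric surface distance.
// [[Rcpp::export]]
List cpp_min_dist_sums(const arma::mat& A, const arma::mat& B) {
  const arma::uword m = A.n_rows, n = B.n_rows;
  double sumA = 0.0, sumB = 0.0;
  arma::vec minB(n);
  minB.fill(std::numeric_limits<double>::infinity());
  for (arma::uword i = 0; i < m; ++i) {
    double best = std::numeric_limits<double>::infinity();
    const double ax = A(i,0), ay = A(i,1), az = A(i,2);
    for (arma::uword j = 0; j < n; ++j) {
      const double dx = ax - B(j,0), dy = ay - B(j,1), dz = az - B(j,2);
      const double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) best = d2;
      if (d2 < minB[j]) minB[j] = d2;
    }
    sumA += std::sqrt(best);
  }
  for (arma::uword j = 0; j < n; ++j) sumB += std::sqrt(minB[j]);
  return List::create(_["sum_a_to_b"] = sumA, _["sum_b_to_a"] = sumB,
                      _["n_a"] = (double)m, _["n_b"] = (double)n);
}

// Normalized mutual information between a reference volume and a moving
// volume sampled (trilinear) through M (reference voxel -> moving voxel).
// Intensities are binned on fixed ranges so the objective is smooth in M.
// [[Rcpp::export]]
double cpp_nmi(const arma::vec& ref, const arma::ivec& rdims,
               const arma::vec& mov, const arma::ivec& mdims,
               const arma::mat& M, int bins,
               double rmin, double rmax, double mmin, double mmax) {
  const int nx = rdims[0], ny = rdims[1], nz = rdims[2];
  const int mx = mdims[0], my = mdims[1], mz = mdims[2];
  arma::mat hist(bins, bins, arma::fill::zeros);
  const double rscale = (bins - 1) / std::max(rmax - rmin, 1e-12);
  const double mscale = (bins - 1) / std::max(mmax - mmin, 1e-12);
  double nsamp = 0.0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const double sx = M(0,0)*x + M(0,1)*y + M(0,2)*z + M(0,3);
        const double sy = M(1,0)*x + M(1,1)*y + M(1,2)*z + M(1,3);
        const double sz = M(2,0)*x + M(2,1)*y + M(2,2)*z + M(2,3);
        if (sx < 0 || sy < 0 || sz < 0 || sx > mx - 1 || sy > my - 1 || sz > mz - 1)
          continue;
        int ix = (int)std::floor(sx), iy = (int)std::floor(sy), iz = (int)std::floor(sz);
        double fx = sx - ix, fy = sy - iy, fz = sz - iz;
        double mval = 0.0;
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              double wgt = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
              if (wgt == 0.0) continue;
              int jx = clampi(ix + dx, 0, mx - 1);
              int jy = clampi(iy + dy, 0, my - 1);
              int jz = clampi(iz + dz, 0, mz - 1);
              mval += wgt * mov[vidx(jx, jy, jz, mx, my)];
            }
        double rval = ref[vidx(x, y, z, nx, ny)];
        int bi = clampi((int)((rval - rmin) * rscale + 0.5), 0, bins - 1);
        int bj = clampi((int)((mval - mmin) * mscale + 0.5), 0, bins - 1);
        hist(bi, bj) += 1.0;
        nsamp += 1.0;
      }
  const arma::uword nref = (arma::uword)nx * ny * nz;
  if (nsamp < 0.05 * nref || nsamp < 32) return 0.0;  // degenerate overlap
  hist /= nsamp;
  arma::vec pr = arma::sum(hist, 1);
  arma::rowvec pm = arma::sum(hist, 0);
  double hr = 0.0, hm = 0.0, hrm = 0.0;
  for (int i = 0; i < bins; ++i) {
    if (pr[i] > 0) hr -= pr[i] * std::log(pr[i]);
    if (pm[i] > 0) hm -= pm[i] * std::log(pm[i]);
  }
  for (int i = 0; i < bins; ++i)
    for (int j = 0; j < bins; ++j)
      if (hist(i,j) > 0) hrm -= hist(i,j) * std::log(hist(i,j));
  if (hrm <= 0) return 2.0;  // perfectly dependent (single joint bin)
  // penalize sub-50% overlap so translating off the grid cannot win;
  // above that the objective is pure NMI
  double overlap = nsamp / (double)nref;
  double penalty = overlap >= 0.5 ? 1.0 : overlap / 0.5;
  return (hr + hm) / hrm * penalty;
}
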