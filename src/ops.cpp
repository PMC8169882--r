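// Low-level numerical kernels: 3D convolution (via per-slice im2col + GEMM),
// anisotropic max-pooling / nearest-neighbour upsampling with exact adjoints,
// trilinear/nearest resampling, axis warps, separable Gaussian smoothing,
// connected-component labelling and boundary-distance sums.
// Volumes are passed as flat arrays in R's column-major order with x fastest:
// linear index v = x + W*(y + H*z), feature maps as (channels x voxels)
// matrices sharing that voxel order.

#include <RcppArmadillo.h>
#include <queue>

using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Fill the im2col patch matrix for one z-slice. P is (cin*K) x (W*H) with
// patch row r = c + cin * k_idx, k_idx = i + kx*(j + ky*l) over kernel offsets.
static void fill_patches(const arma::mat& X, arma::mat& P,
                         int W, int H, int D, int z0,
                         int kx, int ky, int kz) {
  const int cin = X.n_rows;
  const int ox = kx / 2, oy = ky / 2, oz = kz / 2;
  P.zeros();
  for (int l = 0; l < kz; ++l) {
    const int z = z0 + l - oz;
    if (z < 0 || z >= D) continue;
    for (int j = 0; j < ky; ++j) {
      for (int i = 0; i < kx; ++i) {
        const int kidx = i + kx * (j + ky * l);
        const int rbase = cin * kidx;
        for (int y = 0; y < H; ++y) {
          const int ys = y + j - oy;
          if (ys < 0 || ys >= H) continue;
          const int x_lo = std::max(0, ox - i);
          const int x_hi = std::min(W, W + ox - i);
          for (int x = x_lo; x < x_hi; ++x) {
            const int xs = x + i - ox;
            const arma::uword src = (arma::uword)(xs + W * (ys + (arma::uword)H * z));
            const arma::uword dst = (arma::uword)(x + W * y);
            std::memcpy(P.colptr(dst) + rbase, X.colptr(src),
                        cin * sizeof(double));
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_conv3d_forward(const arma::mat& X, int W, int H, int D,
                             const arma::mat& Wt, const arma::vec& bias,
                             int kx, int ky, int kz) {
  const int cin = X.n_rows, cout = Wt.n_rows;
  const arma::uword nslice = (arma::uword)W * H;
  arma::mat Y(cout, X.n_cols);
  arma::mat P(cin * kx * ky * kz, nslice);
  for (int z = 0; z < D; ++z) {
    fill_patches(X, P, W, H, D, z, kx, ky, kz);
    Y.cols(z * nslice, (z + 1) * nslice - 1) = Wt * P;
  }
  Y.each_col() += bias;
  return Y;
}

// [[Rcpp::export]]
List cpp_conv3d_backward(const arma::mat& X, const arma::mat& dY,
                         int W, int H, int D,
                         const arma::mat& Wt,
                         int kx, int ky, int kz, bool need_dx) {
  const int cin = X.n_rows;
  const arma::uword nslice = (arma::uword)W * H;
  arma::mat dW(Wt.n_rows, Wt.n_cols, arma::fill::zeros);
  arma::vec db = arma::sum(dY, 1);
  arma::mat dX(cin, X.n_cols, arma::fill::zeros);
  arma::mat P(cin * kx * ky * kz, nslice);
  const int ox = kx / 2, oy = ky / 2, oz = kz / 2;
  for (int z = 0; z < D; ++z) {
    fill_patches(X, P, W, H, D, z, kx, ky, kz);
    const arma::mat dYs = dY.cols(z * nslice, (z + 1) * nslice - 1);
    dW += dYs * P.t();
    if (need_dx) {
      // scatter-add of G = Wt' * dYs back through the patch map (col2im)
      const arma::mat G = Wt.t() * dYs;
      for (int l = 0; l < kz; ++l) {
        const int zs = z + l - oz;
        if (zs < 0 || zs >= D) continue;
        for (int j = 0; j < ky; ++j) {
          for (int i = 0; i < kx; ++i) {
            const int kidx = i + kx * (j + ky * l);
            const int rbase = cin * kidx;
            for (int y = 0; y < H; ++y) {
              const int ys = y + j - oy;
              if (ys < 0 || ys >= H) continue;
              const int x_lo = std::max(0, ox - i);
              const int x_hi = std::min(W, W + ox - i);
              for (int x = x_lo; x < x_hi; ++x) {
                const int xs = x + i - ox;
                const arma::uword src = (arma::uword)(xs + W * (ys + (arma::uword)H * zs));
                const arma::uword dst = (arma::uword)(x + W * y);
                double* dxp = dX.colptr(src);
                const double* gp = G.colptr(dst) + rbase;
                for (int c = 0; c < cin; ++c) dxp[c] += gp[c];
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool3d_forward(const arma::mat& X, int W, int H, int D,
                           int px, int py, int pz) {
  const int C = X.n_rows;
  const int Wo = W / px, Ho = H / py, Do = D / pz;
  const arma::uword No = (arma::uword)Wo * Ho * Do;
  arma::mat Y(C, No);
  arma::umat amax(C, No);
  for (int zo = 0; zo < Do; ++zo)
    for (int yo = 0; yo < Ho; ++yo)
      for (int xo = 0; xo < Wo; ++xo) {
        const arma::uword vo = xo + (arma::uword)Wo * (yo + (arma::uword)Ho * zo);
        for (int c = 0; c < C; ++c) {
          double best = -std::numeric_limits<double>::infinity();
          arma::uword bidx = 0;
          for (int dz = 0; dz < pz; ++dz)
            for (int dy = 0; dy < py; ++dy)
              for (int dx = 0; dx < px; ++dx) {
                const arma::uword v = (xo * px + dx) +
                  (arma::uword)W * ((yo * py + dy) + (arma::uword)H * (zo * pz + dz));
                const double val = X(c, v);
                if (val > best) { best = val; bidx = v; }
              }
          Y(c, vo) = best;
          amax(c, vo) = bidx;
        }
      }
  return List::create(_["Y"] = Y, _["argmax"] = amax);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool3d_backward(const arma::mat& dY, const arma::umat& amax,
                                 arma::uword n_in) {
  const int C = dY.n_rows;
  arma::mat dX(C, n_in, arma::fill::zeros);
  for (arma::uword v = 0; v < dY.n_cols; ++v)
    for (int c = 0; c < C; ++c)
      dX(c, amax(c, v)) += dY(c, v);
  return dX;
}

// [[Rcpp::export]]
arma::mat cpp_upsample3d_forward(const arma::mat& X, int W, int H, int D,
                                 int fx, int fy, int fz) {
  const int C = X.n_rows;
  const int Wo = W * fx, Ho = H * fy, Do = D * fz;
  arma::mat Y(C, (arma::uword)Wo * Ho * Do);
  for (int z = 0; z < Do; ++z)
    for (int y = 0; y < Ho; ++y)
      for (int x = 0; x < Wo; ++x) {
        const arma::uword vo = x + (arma::uword)Wo * (y + (arma::uword)Ho * z);
        const arma::uword vi = (x / fx) + (arma::uword)W * ((y / fy) + (arma::uword)H * (z / fz));
        Y.col(vo) = X.col(vi);
      }
  return Y;
}

// [[Rcpp::export]]
arma::mat cpp_upsample3d_backward(const arma::mat& dY, int W, int H, int D,
                                  int fx, int fy, int fz) {
  // W,H,D are the *input* (coarse) dims; dY lives on the upsampled grid.
  const int C = dY.n_rows;
  const int Wo = W * fx, Ho = H * fy, Do = D * fz;
  arma::mat dX(C, (arma::uword)W * H * D, arma::fill::zeros);
  for (int z = 0; z < Do; ++z)
    for (int y = 0; y < Ho; ++y)
      for (int x = 0; x < Wo; ++x) {
        const arma::uword vo = x + (arma::uword)Wo * (y + (arma::uword)Ho * z);
        const arma::uword vi = (x / fx) + (arma::uword)W * ((y / fy) + (arma::uword)H * (z / fz));
        dX.col(vi) += dY.col(vo);
      }
  return dX;
}

// Generic affine resampler: output voxel (i,j,k) samples the input at
// continuous index (ax*i+bx, ay*j+by, az*k+bz).  mode 0 = trilinear,
// 1 = nearest.  border 0 = fill value, 1 = clamp to edge.
// [[Rcpp::export]]
NumericVector cpp_affine_sample3d(const NumericVector& vol,
                                  IntegerVector in_dim, IntegerVector out_dim,
                                  NumericVector scale, NumericVector offset,
                                  int mode, int border, double fill) {
  const int W = in_dim[0], H = in_dim[1], D = in_dim[2];
  const int Wo = out_dim[0], Ho = out_dim[1], Do = out_dim[2];
  NumericVector out((R_xlen_t)Wo * Ho * Do);
  const double* v = vol.begin();
  double* o = out.begin();
  auto at = [&](int x, int y, int z) -> double {
    if (x < 0 || x >= W || y < 0 || y >= H || z < 0 || z >= D) {
      if (border == 1) { x = clampi(x, 0, W - 1); y = clampi(y, 0, H - 1); z = clampi(z, 0, D - 1); }
      else return fill;
    }
    return v[x + (R_xlen_t)W * (y + (R_xlen_t)H * z)];
  };
  R_xlen_t idx = 0;
  for (int k = 0; k < Do; ++k) {
    const double zc = scale[2] * k + offset[2];
    for (int j = 0; j < Ho; ++j) {
      const double yc = scale[1] * j + offset[1];
      for (int i = 0; i < Wo; ++i, ++idx) {
        const double xc = scale[0] * i + offset[0];
        if (mode == 1) {
          o[idx] = at((int)std::lround(xc), (int)std::lround(yc), (int)std::lround(zc));
        } else {
          const int x0 = (int)std::floor(xc), y0 = (int)std::floor(yc), z0 = (int)std::floor(zc);
          const double fxr = xc - x0, fyr = yc - y0, fzr = zc - z0;
          double acc = 0.0;
          for (int dz = 0; dz <= 1; ++dz)
            for (int dy = 0; dy <= 1; ++dy)
              for (int dx = 0; dx <= 1; ++dx) {
                const double wgt = (dx ? fxr : 1 - fxr) * (dy ? fyr : 1 - fyr) * (dz ? fzr : 1 - fzr);
                if (wgt != 0.0) acc += wgt * at(x0 + dx, y0 + dy, z0 + dz);
              }
          o[idx] = acc;
        }
      }
    }
  }
  return out;
}

// Warp along the y axis: output (x,y,z) samples input at (x, y + disp[x,y,z], z).
// [[Rcpp::export]]
NumericVector cpp_warp_y(const NumericVector& vol, IntegerVector dim,
                         const NumericVector& disp, int mode, int border,
                         double fill) {
  const int W = dim[0], H = dim[1], D = dim[2];
  NumericVector out((R_xlen_t)W * H * D);
  const double* v = vol.begin();
  const double* dpp = disp.begin();
  double* o = out.begin();
  auto at = [&](int x, int y, int z) -> double {
    if (y < 0 || y >= H) {
      if (border == 1) y = clampi(y, 0, H - 1); else return fill;
    }
    return v[x + (R_xlen_t)W * (y + (R_xlen_t)H * z)];
  };
  R_xlen_t idx = 0;
  for (int z = 0; z < D; ++z)
    for (int y = 0; y < H; ++y)
      for (int x = 0; x < W; ++x, ++idx) {
        const double ys = y + dpp[idx];
        if (mode == 1) {
          o[idx] = at(x, (int)std::lround(ys), z);
        } else {
          const int y0 = (int)std::floor(ys);
          const double f = ys - y0;
          o[idx] = (1 - f) * at(x, y0, z) + f * at(x, y0 + 1, z);
        }
      }
  return out;
}

// Separable Gaussian smoothing with reflected borders; sigma in voxels.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur3d(const NumericVector& vol, IntegerVector dim,
                                  NumericVector sigma) {
  const int W = dim[0], H = dim[1], D = dim[2];
  std::vector<double> buf(vol.begin(), vol.end()), tmp(buf.size());
  const int dims[3] = {W, H, D};
  const R_xlen_t strides[3] = {1, (R_xlen_t)W, (R_xlen_t)W * H};
  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma[ax];
    if (s <= 0) continue;
    const int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> k(2 * r + 1);
    double ksum = 0;
    for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (s * s)); ksum += k[i + r]; }
    for (double& kv : k) kv /= ksum;
    const int n = dims[ax];
    const R_xlen_t st = strides[ax];
    // iterate over all lines along axis ax
    for (int z = 0; z < (ax == 2 ? 1 : D); ++z)
      for (int y = 0; y < (ax == 1 ? 1 : H); ++y)
        for (int x = 0; x < (ax == 0 ? 1 : W); ++x) {
          const R_xlen_t base = x + (R_xlen_t)W * (y + (R_xlen_t)H * z);
          for (int i = 0; i < n; ++i) {
            double acc = 0;
            for (int q = -r; q <= r; ++q) {
              int p = i + q;
              if (p < 0) p = -p - 1;
              if (p >= n) p = 2 * n - p - 1;
              acc += k[q + r] * buf[base + st * p];
            }
            tmp[base + st * i] = acc;
          }
        }
    std::swap(buf, tmp);
  }
  return NumericVector(buf.begin(), buf.end());
}

// Connected-component labelling of a binary mask (BFS, deterministic:
// components numbered in raster-scan order of their first voxel).
// connectivity: 6, 18 or 26.
// [[Rcpp::export]]
IntegerVector cpp_label_components(const IntegerVector& mask, IntegerVector dim,
                                   int connectivity) {
  const int W = dim[0], H = dim[1], D = dim[2];
  const R_xlen_t N = (R_xlen_t)W * H * D;
  IntegerVector lab(N, 0);
  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        nb.push_back({dx, dy, dz});
      }
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t v = 0; v < N; ++v) {
    if (!mask[v] || lab[v]) continue;
    lab[v] = ++next;
    q.push(v);
    while (!q.empty()) {
      const R_xlen_t u = q.front(); q.pop();
      const int x = u % W, y = (u / W) % H, z = u / ((R_xlen_t)W * H);
      for (const auto& d : nb) {
        const int nx = x + d[0], ny = y + d[1], nz = z + d[2];
        if (nx < 0 || nx >= W || ny < 0 || ny >= H || nz < 0 || nz >= D) continue;
        const R_xlen_t w = nx + (R_xlen_t)W * (ny + (R_xlen_t)H * nz);
        if (mask[w] && !lab[w]) { lab[w] = next; q.push(w); }
      }
    }
  }
  return lab;
}

// Surface voxels: foreground voxels with at least one face-adjacent
// background neighbour; voxels outside the grid count as background.
// Returns 0-based (x,y,z) coordinates, one row per surface voxel.
// [[Rcpp::export]]
IntegerMatrix cpp_surface_voxels(const IntegerVector& mask, IntegerVector dim) {
  const int W = dim[0], H = dim[1], D = dim[2];
  std::vector<std::array<int, 3>> pts;
  const int face[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  R_xlen_t v = 0;
  for (int z = 0; z < D; ++z)
    for (int y = 0; y < H; ++y)
      for (int x = 0; x < W; ++x, ++v) {
        if (!mask[v]) continue;
        bool surf = false;
        for (int f = 0; f < 6 && !surf; ++f) {
          const int nx = x + face[f][0], ny = y + face[f][1], nz = z + face[f][2];
          if (nx < 0 || nx >= W || ny < 0 || ny >= H || nz < 0 || nz >= D) { surf = true; break; }
          if (!mask[nx + (R_xlen_t)W * (ny + (R_xlen_t)H * nz)]) surf = true;
        }
        if (surf) pts.push_back({x, y, z});
      }
  IntegerMatrix out(pts.size(), 3);
  for (size_t i = 0; i < pts.size(); ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = pts[i][j];
  return out;
}

// Sum over rows of A of the minimum Euclidean distance (in mm) to any row
// of B, with per-axis spacings.
// [[Rcpp::export]]
double cpp_sum_min_dists(const IntegerMatrix& A, const IntegerMatrix& B,
                         NumericVector spacing) {
  const int n = A.nrow(), m = B.nrow();
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double total = 0;
  for (int i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    const double ax = A(i, 0) * sx, ay = A(i, 1) * sy, az = A(i, 2) * sz;
    for (int j = 0; j < m; ++j) {
      const double dx = ax - B(j, 0) * sx, dy = ay - B(j, 1) * sy, dz = az - B(j, 2) * sz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    total += std::sqrt(best);
  }
  return total;
}
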