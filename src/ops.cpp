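// Low-level numerical kernels: same-padded 3D convolution (via im2col + BLAS
// gemm) with its adjoint, and 26-connectivity component labeling.
// Feature maps are (n_voxel x n_channel) matrices in R array (column-major,
// x fastest) voxel order; spatial dims travel alongside as an integer triple.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col3(const arma::mat& x, const arma::ivec& dims,
                         const arma::ivec& ksz) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int kx = ksz[0], ky = ksz[1], kz = ksz[2];
  const int px = kx / 2, py = ky / 2, pz = kz / 2;
  const int K = kx * ky * kz, C = x.n_cols;
  const arma::uword n = x.n_rows;
  arma::mat out(n, (arma::uword)C * K, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.colptr(c);
    for (int dz = -pz; dz <= pz; ++dz)
      for (int dy = -py; dy <= py; ++dy)
        for (int dx = -px; dx <= px; ++dx) {
          const int kidx = (dz + pz) * ky * kx + (dy + py) * kx + (dx + px);
          double* oc = out.colptr((arma::uword)c * K + kidx);
          const int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
          if (x1 <= x0) continue;
          for (int z = 0; z < nz; ++z) {
            const int zs = z + dz;
            if (zs < 0 || zs >= nz) continue;
            for (int y = 0; y < ny; ++y) {
              const int ys = y + dy;
              if (ys < 0 || ys >= ny) continue;
              const double* src = xc + ((size_t)zs * ny + ys) * nx + dx;
              double* dst = oc + ((size_t)z * ny + y) * nx;
              std::memcpy(dst + x0, src + x0, (size_t)(x1 - x0) * sizeof(double));
            }
          }
        }
  }
  return out;
}

// adjoint of im2col3: scatter-add columns back onto the padded grid
static arma::mat col2im3(const arma::mat& cols, const arma::ivec& dims,
                         const arma::ivec& ksz, int C) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int kx = ksz[0], ky = ksz[1], kz = ksz[2];
  const int px = kx / 2, py = ky / 2, pz = kz / 2;
  const int K = kx * ky * kz;
  arma::mat out((arma::uword)nx * ny * nz, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* oc = out.colptr(c);
    for (int dz = -pz; dz <= pz; ++dz)
      for (int dy = -py; dy <= py; ++dy)
        for (int dx = -px; dx <= px; ++dx) {
          const int kidx = (dz + pz) * ky * kx + (dy + py) * kx + (dx + px);
          const double* cc = cols.colptr((arma::uword)c * K + kidx);
          const int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
          if (x1 <= x0) continue;
          for (int z = 0; z < nz; ++z) {
            const int zs = z + dz;
            if (zs < 0 || zs >= nz) continue;
            for (int y = 0; y < ny; ++y) {
              const int ys = y + dy;
              if (ys < 0 || ys >= ny) continue;
              double* dst = oc + ((size_t)zs * ny + ys) * nx + dx;
              const double* src = cc + ((size_t)z * ny + y) * nx;
              for (int xi = x0; xi < x1; ++xi) dst[xi] += src[xi];
            }
          }
        }
  }
  return out;
}

// y = im2col(x) %*% W + b ; W is (C_in*K) x C_out, kernel offsets ordered
// z-major / x-fastest within each input channel block.
// [[Rcpp::export]]
arma::mat cs_conv_fwd(const arma::mat& x, const arma::ivec& dims,
                      const arma::mat& W, const arma::vec& b,
                      const arma::ivec& ksz) {
  arma::mat out = im2col3(x, dims, ksz) * W;
  out.each_row() += b.t();
  return out;
}

// [[Rcpp::export]]
List cs_conv_bwd(const arma::mat& x, const arma::ivec& dims,
                 const arma::mat& W, const arma::ivec& ksz,
                 const arma::mat& dout) {
  arma::mat cols = im2col3(x, dims, ksz);
  arma::mat dW = cols.t() * dout;
  arma::vec db = arma::sum(dout, 0).t();
  arma::mat dx = col2im3(dout * W.t(), dims, ksz, x.n_cols);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 26-connectivity labeling of a binary mask given as an integer vector in R
// array order; returns 0 for background, 1..n_components otherwise.
// [[Rcpp::export]]
IntegerVector cs_label_components(const IntegerVector& mask,
                                  const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t v = stack.back();
      stack.pop_back();
      const int vx = (int)(v % nx);
      const int vy = (int)((v / nx) % ny);
      const int vz = (int)(v / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz) {
        const int z2 = vz + dz;
        if (z2 < 0 || z2 >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int y2 = vy + dy;
          if (y2 < 0 || y2 >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            const int x2 = vx + dx;
            if (x2 < 0 || x2 >= nx || (dx == 0 && dy == 0 && dz == 0)) continue;
            const R_xlen_t w = x2 + (R_xlen_t)nx * (y2 + (R_xlen_t)ny * z2);
            if (mask[w] != 0 && lab[w] == 0) {
              lab[w] = cur;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  return lab;
}
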