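// 3D convolution / pooling / upsampling primitives for the Dense-U-Net.
//
// Feature maps are stored as V x C matrices (voxels x channels), voxels
// flattened x-fastest (R array column-major order for dim = c(nx, ny, nz)),
// so each channel is one contiguous column and voxel-shift operations are
// contiguous run copies. Convolutions use odd isotropic kernels with zero
// ("same") padding and are evaluated as one large GEMM plus cheap shifted
// scatter/gather passes:
//  - forward:  T = X * Wperm  (V x (k^3*Cout)), then column block t of T is
//    scatter-added into the output at kernel offset t;
//  - backward: the output gradient is gathered shifted into D
//    (V x (k^3*Cout)), after which dX = D * Wperm' and dW = X' * D are
//    each a single GEMM.
//
// Weights keep the layout W[co, ci + C*t] (Cout x C*k^3), offsets t
// enumerated x-fastest over (-p..p)^3, p = (k-1)/2.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// dst[v] (+)= src[v + d] over the valid region of the grid.
template <bool Accumulate>
static void shift_vec(const double* src, double* dst,
                      int nx, int ny, int nz, int dx, int dy, int dz) {
  for (int z = 0; z < nz; ++z) {
    const int sz = z + dz;
    if (sz < 0 || sz >= nz) continue;
    for (int y = 0; y < ny; ++y) {
      const int sy = y + dy;
      if (sy < 0 || sy >= ny) continue;
      const int x0 = std::max(0, -dx);
      const int x1 = std::min(nx, nx - dx);
      if (x1 <= x0) continue;
      const double* s = src + (arma::uword)(x0 + dx)
        + (arma::uword)nx * (sy + (arma::uword)ny * sz);
      double* d = dst + (arma::uword)x0
        + (arma::uword)nx * (y + (arma::uword)ny * z);
      const int n = x1 - x0;
      if (Accumulate) for (int i = 0; i < n; ++i) d[i] += s[i];
      else            std::memcpy(d, s, sizeof(double) * n);
    }
  }
}

// Wperm[ci, t*Cout + co] = W[co, ci + C*t]  (C x K*Cout)
static arma::mat permute_weights(const arma::mat& W, arma::uword C, arma::uword K) {
  const arma::uword Cout = W.n_rows;
  arma::mat Wperm(C, K * Cout);
  for (arma::uword t = 0; t < K; ++t)
    for (arma::uword ci = 0; ci < C; ++ci)
      for (arma::uword co = 0; co < Cout; ++co)
        Wperm(ci, t * Cout + co) = W(co, ci + C * t);
  return Wperm;
}

// Y[v, co] = b[co] + sum_{ci, t} W[co, ci + C*t] * X[v + offset(t), ci]
// [[Rcpp::export]]
arma::mat conv3d_fw(const arma::mat& X, const IntegerVector& dims,
                    const arma::mat& W, const arma::vec& b, int k) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const arma::uword V = X.n_rows, C = X.n_cols;
  const arma::uword Cout = W.n_rows;
  const arma::uword K = (arma::uword)(k * k * k);
  const int p = (k - 1) / 2;
  if (W.n_cols != C * K)
    stop("conv3d_fw: weight columns do not match channels * k^3");
  if (V != (arma::uword)nx * ny * nz)
    stop("conv3d_fw: dims do not match voxel count");
  const arma::mat Wperm = permute_weights(W, C, K);
  if (k == 1) {
    arma::mat Y = X * Wperm;
    Y.each_row() += b.t();
    return Y;
  }
  const arma::mat T = X * Wperm;  // V x (K*Cout)
  arma::mat Y(V, Cout);
  Y.each_row() = b.t();
  int t = 0;
  for (int dz = -p; dz <= p; ++dz)
    for (int dy = -p; dy <= p; ++dy)
      for (int dx = -p; dx <= p; ++dx, ++t)
        for (arma::uword co = 0; co < Cout; ++co)
          shift_vec<true>(T.colptr((arma::uword)t * Cout + co), Y.colptr(co),
                          nx, ny, nz, dx, dy, dz);
  return Y;
}

// Gradients of conv3d_fw wrt input, weights and bias.
// [[Rcpp::export]]
List conv3d_bw(const arma::mat& X, const IntegerVector& dims,
               const arma::mat& W, const arma::mat& dY, int k) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const arma::uword C = X.n_cols;
  const arma::uword Cout = W.n_rows;
  const arma::uword K = (arma::uword)(k * k * k);
  const int p = (k - 1) / 2;
  arma::vec db = arma::sum(dY, 0).t();
  const arma::mat Wperm = permute_weights(W, C, K);
  if (k == 1) {
    arma::mat dX = dY * Wperm.t();
    arma::mat dWp = X.t() * dY;      // C x Cout
    arma::mat dW(Cout, C);
    for (arma::uword ci = 0; ci < C; ++ci)
      for (arma::uword co = 0; co < Cout; ++co)
        dW(co, ci) = dWp(ci, co);
    return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
  }
  // D[v, t*Cout + co] = dY[v - d_t, co] (zero where the shift leaves the grid)
  arma::mat D(dY.n_rows, K * Cout, arma::fill::zeros);
  int t = 0;
  for (int dz = -p; dz <= p; ++dz)
    for (int dy = -p; dy <= p; ++dy)
      for (int dx = -p; dx <= p; ++dx, ++t)
        for (arma::uword co = 0; co < Cout; ++co)
          shift_vec<false>(dY.colptr(co), D.colptr((arma::uword)t * Cout + co),
                           nx, ny, nz, -dx, -dy, -dz);
  arma::mat dX = D * Wperm.t();   // V x C
  arma::mat dWp = X.t() * D;      // C x (K*Cout)
  arma::mat dW(Cout, C * K);
  for (arma::uword tt = 0; tt < K; ++tt)
    for (arma::uword ci = 0; ci < C; ++ci)
      for (arma::uword co = 0; co < Cout; ++co)
        dW(co, ci + C * tt) = dWp(ci, tt * Cout + co);
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// 2x2x2 max pooling. Returns pooled map (Vo x C) and 1-based argmax voxel
// indices (into the input voxel axis) for the backward pass.
// [[Rcpp::export]]
List maxpool3d_fw(const arma::mat& X, const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (nx % 2 || ny % 2 || nz % 2) stop("maxpool3d_fw: dims must be even");
  const arma::uword C = X.n_cols;
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  const arma::uword Vo = (arma::uword)ox * oy * oz;
  arma::mat Y(Vo, C);
  arma::umat idx(Vo, C);
  for (arma::uword c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    double* yc = Y.colptr(c);
    arma::uword* ic = idx.colptr(c);
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int x = 0; x < ox; ++x) {
          const arma::uword vo = (arma::uword)x + (arma::uword)ox * (y + (arma::uword)oy * z);
          double best = -std::numeric_limits<double>::infinity();
          arma::uword bi = 0;
          for (int ddz = 0; ddz < 2; ++ddz)
            for (int ddy = 0; ddy < 2; ++ddy)
              for (int ddx = 0; ddx < 2; ++ddx) {
                const arma::uword vi = (arma::uword)(2 * x + ddx)
                  + (arma::uword)nx * ((2 * y + ddy) + (arma::uword)ny * (2 * z + ddz));
                if (xc[vi] > best) { best = xc[vi]; bi = vi; }
              }
          yc[vo] = best;
          ic[vo] = bi + 1;
        }
  }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::mat maxpool3d_bw(const arma::mat& dY, const arma::umat& idx, int V_in) {
  const arma::uword C = dY.n_cols, Vo = dY.n_rows;
  arma::mat dX((arma::uword)V_in, C, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c) {
    const double* gc = dY.colptr(c);
    const arma::uword* ic = idx.colptr(c);
    double* dc = dX.colptr(c);
    for (arma::uword v = 0; v < Vo; ++v) dc[ic[v] - 1] += gc[v];
  }
  return dX;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
arma::mat upsample3d_fw(const arma::mat& X, const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const arma::uword C = X.n_cols;
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  arma::mat Y((arma::uword)ox * oy * oz, C);
  for (arma::uword c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    double* yc = Y.colptr(c);
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y) {
        const double* row = xc + (arma::uword)nx * ((y / 2) + (arma::uword)ny * (z / 2));
        double* out = yc + (arma::uword)ox * (y + (arma::uword)oy * z);
        for (int x = 0; x < nx; ++x) { out[2 * x] = row[x]; out[2 * x + 1] = row[x]; }
      }
  }
  return Y;
}

// Adjoint of nearest-neighbour upsampling: sum gradients over each 2x2x2 cell.
// [[Rcpp::export]]
arma::mat upsample3d_bw(const arma::mat& dY, const IntegerVector& dims_in) {
  const int nx = dims_in[0], ny = dims_in[1], nz = dims_in[2];
  const arma::uword C = dY.n_cols;
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  arma::mat dX((arma::uword)nx * ny * nz, C, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c) {
    const double* gc = dY.colptr(c);
    double* dc = dX.colptr(c);
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y) {
        const double* in = gc + (arma::uword)ox * (y + (arma::uword)oy * z);
        double* row = dc + (arma::uword)nx * ((y / 2) + (arma::uword)ny * (z / 2));
        for (int x = 0; x < nx; ++x) row[x] += in[2 * x] + in[2 * x + 1];
      }
  }
  return dX;
}
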