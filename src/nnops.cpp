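// Low-level tensor primitives for the 3D U-Net: same-padded 3x3x3 / 1x1x1
// convolution (im2col + GEMM, float32 accumulation), 2x max-pooling and
// nearest-neighbour upsampling, with the matching backward passes.
//
// Tensor layout: R arrays of dim (X, Y, Z, C), column-major, so the linear
// index of voxel (x, y, z) in channel c is x + X*(y + Y*(z + Z*c)).
// Weight layout: (Cout x Cin*k^3) matrix; column cin*k^3 + kk where
// kk = (dz+1)*k^2 + (dy+1)*k + (dx+1) for kernel offsets in {-1,0,1}.
//
// The im2col block is stored voxel-major (rows = voxels of a z-slab,
// columns = channel/kernel-offset), which keeps every copy loop contiguous;
// the GEMMs absorb the transposes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Fill Kt (X*Y*(z1-z0) rows, Cin*k3 cols) for z-slices [z0, z1).
void im2col_slab(const arma::fvec &x, int X, int Y, int Z, int Cin, int k,
                 int z0, int z1, arma::fmat &Kt) {
  const int k3 = k * k * k, half = k / 2;
  const long planeXY = (long)X * Y;
  const long ncol = planeXY * (z1 - z0);
  Kt.zeros(ncol, (arma::uword)Cin * k3);
  for (int c = 0; c < Cin; ++c) {
    const long cbase = (long)c * X * Y * Z;
    for (int dz = -half; dz <= half; ++dz)
      for (int dy = -half; dy <= half; ++dy)
        for (int dx = -half; dx <= half; ++dx) {
          const int kk = (dz + half) * k * k + (dy + half) * k + (dx + half);
          float *col = Kt.colptr(c * k3 + kk);
          for (int z = z0; z < z1; ++z) {
            const int zs = z + dz;
            if (zs < 0 || zs >= Z) continue;
            const long rowz = (long)(z - z0) * planeXY;
            const long srcz = cbase + (long)zs * planeXY;
            for (int y = 0; y < Y; ++y) {
              const int ys = y + dy;
              if (ys < 0 || ys >= Y) continue;
              float *dst = col + rowz + (long)y * X;
              const float *src = x.memptr() + srcz + (long)ys * X + dx;
              const int xlo = std::max(0, -dx), xhi = std::min(X, X - dx);
              for (int xx = xlo; xx < xhi; ++xx) dst[xx] = src[xx];
            }
          }
        }
  }
}

int slab_nz(int X, int Y, int rows) {
  // keep each im2col block around <= 64 MB of float32
  long per_z = (long)rows * X * Y * 4L;
  return (int)std::max(1L, 64L * 1000L * 1000L / std::max(per_z, 1L));
}

} // namespace

// [[Rcpp::export(name = ".cpp_conv3d_fwd")]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector dims,
                             NumericMatrix W, NumericVector b, int k) {
  const int X = dims[0], Y = dims[1], Z = dims[2], Cin = dims[3];
  const int k3 = k * k * k;
  const int Cout = W.nrow();
  if (W.ncol() != Cin * k3) stop("weight shape mismatch");
  arma::fvec xf = arma::conv_to<arma::fvec>::from(
      arma::vec(x.begin(), x.size(), false));
  arma::fmat Wt(Cin * k3, Cout);  // transposed weights
  for (int j = 0; j < Cin * k3; ++j)
    for (int i = 0; i < Cout; ++i) Wt(j, i) = (float)W(i, j);

  NumericVector out((R_xlen_t)X * Y * Z * Cout);
  const long planeXY = (long)X * Y, vol = (long)X * Y * Z;
  arma::fmat Kt;
  const int nz = slab_nz(X, Y, Cin * k3);
  for (int z0 = 0; z0 < Z; z0 += nz) {
    const int z1 = std::min(Z, z0 + nz);
    im2col_slab(xf, X, Y, Z, Cin, k, z0, z1, Kt);
    arma::fmat Yt = Kt * Wt;  // nvox x Cout
    const long base = (long)z0 * planeXY, nvox = Kt.n_rows;
    for (int c = 0; c < Cout; ++c) {
      const float *src = Yt.colptr(c);
      const double bc = b[c];
      double *dst = REAL(out) + (long)c * vol + base;
      for (long j = 0; j < nvox; ++j) dst[j] = (double)src[j] + bc;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_conv3d_bwd")]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector dims, NumericMatrix W,
                    NumericVector dy, int k) {
  const int X = dims[0], Y = dims[1], Z = dims[2], Cin = dims[3];
  const int k3 = k * k * k, half = k / 2;
  const int Cout = W.nrow();
  arma::fvec xf = arma::conv_to<arma::fvec>::from(
      arma::vec(x.begin(), x.size(), false));
  arma::fmat Wf(Cout, Cin * k3);
  for (int j = 0; j < Cin * k3; ++j)
    for (int i = 0; i < Cout; ++i) Wf(i, j) = (float)W(i, j);

  arma::fmat dWt(Cin * k3, Cout, arma::fill::zeros);
  arma::fvec dbf(Cout, arma::fill::zeros);
  arma::fvec dxf((arma::uword)X * Y * Z * Cin, arma::fill::zeros);
  const long planeXY = (long)X * Y, vol = (long)X * Y * Z;

  arma::fmat Kt;
  const int nz = slab_nz(X, Y, Cin * k3);
  for (int z0 = 0; z0 < Z; z0 += nz) {
    const int z1 = std::min(Z, z0 + nz);
    const long nvox = planeXY * (z1 - z0);
    arma::fmat dYt(nvox, Cout);
    const long base = (long)z0 * planeXY;
    for (int c = 0; c < Cout; ++c) {
      const double *src = REAL(dy) + (long)c * vol + base;
      float *dst = dYt.colptr(c);
      for (long j = 0; j < nvox; ++j) dst[j] = (float)src[j];
    }
    dbf += arma::sum(dYt, 0).t();
    im2col_slab(xf, X, Y, Z, Cin, k, z0, z1, Kt);
    dWt += Kt.t() * dYt;           // BLAS handles the transpose flag
    arma::fmat dKt = dYt * Wf;     // nvox x Cin*k3
    // col2im scatter-add
    for (int c = 0; c < Cin; ++c) {
      const long cbase = (long)c * vol;
      for (int dz = -half; dz <= half; ++dz)
        for (int dyo = -half; dyo <= half; ++dyo)
          for (int dxo = -half; dxo <= half; ++dxo) {
            const int kk = (dz + half) * k * k + (dyo + half) * k +
                           (dxo + half);
            const float *col = dKt.colptr(c * k3 + kk);
            for (int z = z0; z < z1; ++z) {
              const int zs = z + dz;
              if (zs < 0 || zs >= Z) continue;
              const long rowz = (long)(z - z0) * planeXY;
              const long dstz = cbase + (long)zs * planeXY;
              for (int y = 0; y < Y; ++y) {
                const int ys = y + dyo;
                if (ys < 0 || ys >= Y) continue;
                const float *src = col + rowz + (long)y * X;
                float *dst = dxf.memptr() + dstz + (long)ys * X + dxo;
                const int xlo = std::max(0, -dxo), xhi = std::min(X, X - dxo);
                for (int xx = xlo; xx < xhi; ++xx) dst[xx] += src[xx];
              }
            }
          }
    }
  }
  NumericVector dx((R_xlen_t)dxf.n_elem);
  for (long i = 0; i < (long)dxf.n_elem; ++i) dx[i] = (double)dxf[i];
  NumericMatrix dW(Cout, Cin * k3);
  for (int j = 0; j < Cin * k3; ++j)
    for (int i = 0; i < Cout; ++i) dW(i, j) = (double)dWt(j, i);
  NumericVector db(Cout);
  for (int i = 0; i < Cout; ++i) db[i] = (double)dbf[i];
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export(name = ".cpp_maxpool2_fwd")]]
List cpp_maxpool2_fwd(NumericVector x, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  if (X % 2 || Y % 2 || Z % 2) stop("maxpool2 needs even spatial dims");
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  const long vol = (long)X * Y * Z, volo = (long)Xo * Yo * Zo;
  NumericVector out((R_xlen_t)volo * C);
  IntegerVector idx((R_xlen_t)volo * C);
  for (int c = 0; c < C; ++c) {
    const long ib = (long)c * vol, ob = (long)c * volo;
    for (int z = 0; z < Zo; ++z)
      for (int y = 0; y < Yo; ++y)
        for (int xx = 0; xx < Xo; ++xx) {
          double best = -1e300; long bi = -1;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const long li = ib + (2 * xx + dx) +
                                (long)X * ((2 * y + dy) + (long)Y * (2 * z + dz));
                if (x[li] > best) { best = x[li]; bi = li; }
              }
          const long lo = ob + xx + (long)Xo * (y + (long)Yo * z);
          out[lo] = best;
          idx[lo] = (int)bi;
        }
  }
  return List::create(_["y"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool2_bwd")]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector idx,
                               R_xlen_t n_in) {
  NumericVector dx(n_in);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}

// [[Rcpp::export(name = ".cpp_upsample2_fwd")]]
NumericVector cpp_upsample2_fwd(NumericVector x, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  const long vol = (long)X * Y * Z, volo = (long)Xo * Yo * Zo;
  NumericVector out((R_xlen_t)volo * C);
  for (int c = 0; c < C; ++c) {
    const long ib = (long)c * vol, ob = (long)c * volo;
    for (int z = 0; z < Zo; ++z)
      for (int y = 0; y < Yo; ++y) {
        const long srow = ib + (long)X * ((y / 2) + (long)Y * (z / 2));
        const long orow = ob + (long)Xo * (y + (long)Yo * z);
        for (int xx = 0; xx < Xo; ++xx) out[orow + xx] = x[srow + xx / 2];
      }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_upsample2_bwd")]]
NumericVector cpp_upsample2_bwd(NumericVector dy, IntegerVector out_dims) {
  const int Xo = out_dims[0], Yo = out_dims[1], Zo = out_dims[2],
            C = out_dims[3];
  const int X = Xo / 2, Y = Yo / 2, Z = Zo / 2;
  const long vol = (long)X * Y * Z, volo = (long)Xo * Yo * Zo;
  NumericVector dx((R_xlen_t)vol * C);
  for (int c = 0; c < C; ++c) {
    const long ib = (long)c * vol, ob = (long)c * volo;
    for (int z = 0; z < Zo; ++z)
      for (int y = 0; y < Yo; ++y) {
        const long drow = ib + (long)X * ((y / 2) + (long)Y * (z / 2));
        const long orow = ob + (long)Xo * (y + (long)Yo * z);
        for (int xx = 0; xx < Xo; ++xx) dx[drow + xx / 2] += dy[orow + xx];
      }
  }
  return dx;
}
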