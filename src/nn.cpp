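// Dense 3D convolution and resampling primitives for the searchable
// encoder-decoder backbone.  Convolution is im2col + BLAS gemm,
// processed in voxel chunks to bound memory on whole-volume inputs.
// The patch matrix is stored transposed -- (kernel*Cin) x voxels -- so
// both the gather and the scatter walk memory contiguously; the gemm
// calls absorb the transpositions.
//
// Feature maps are R arrays with dim = (nz, ny, nx, C), column-major:
// linear index = z + nz*(y + ny*(x + nx*c)).
// Kernels are arrays with dim = (kz, ky, kx, Cin, Cout); padding is
// zero "same" padding so spatial shape is preserved.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const int CHUNK = 8192;

struct ConvGeom {
  int nz, ny, nx, kz, ky, kx, cin, cout, pz, py, px;
  R_xlen_t nvox, sp;  // spatial voxels, spatial stride per channel
};

static ConvGeom geom_of(IntegerVector xdim, IntegerVector wdim) {
  ConvGeom g;
  g.nz = xdim[0]; g.ny = xdim[1]; g.nx = xdim[2];
  g.kz = wdim[0]; g.ky = wdim[1]; g.kx = wdim[2];
  g.cin = wdim[3]; g.cout = wdim[4];
  g.pz = (g.kz - 1) / 2; g.py = (g.ky - 1) / 2; g.px = (g.kx - 1) / 2;
  g.nvox = (R_xlen_t)g.nz * g.ny * g.nx;
  g.sp = g.nvox;
  return g;
}

// Transposed im2col: Mt(col, r) for voxels [v0, v0+ncol); writes are
// contiguous down each voxel's column.
static void im2col_chunk(const double* x, const ConvGeom& g, R_xlen_t v0,
                         int ncol, arma::mat& Mt) {
  const int K = g.kz * g.ky * g.kx;
  for (int r = 0; r < ncol; ++r) {
    R_xlen_t v = v0 + r;
    const int z = (int)(v % g.nz);
    const int y = (int)((v / g.nz) % g.ny);
    const int xx = (int)(v / ((R_xlen_t)g.nz * g.ny));
    double* col = Mt.colptr(r);
    for (int ci = 0; ci < g.cin; ++ci) {
      const double* xc = x + g.sp * ci;
      for (int dx = 0; dx < g.kx; ++dx) {
        const int xs = xx + dx - g.px;
        const bool okx = xs >= 0 && xs < g.nx;
        for (int dy = 0; dy < g.ky; ++dy) {
          const int ys = y + dy - g.py;
          double* dst = col + K * ci + g.kz * (dy + g.ky * dx);
          if (!okx || ys < 0 || ys >= g.ny) {
            for (int dz = 0; dz < g.kz; ++dz) dst[dz] = 0.0;
            continue;
          }
          const double* src =
              xc + (R_xlen_t)g.nz * (ys + (R_xlen_t)g.ny * xs) + z - g.pz;
          for (int dz = 0; dz < g.kz; ++dz) {
            const int zs = z + dz - g.pz;
            dst[dz] = (zs >= 0 && zs < g.nz) ? src[dz] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add the transposed column gradient Ct(col, r) back onto dx.
static void col2im_chunk(double* dx, const ConvGeom& g, R_xlen_t v0,
                         int ncol, const arma::mat& Ct) {
  const int K = g.kz * g.ky * g.kx;
  for (int r = 0; r < ncol; ++r) {
    R_xlen_t v = v0 + r;
    const int z = (int)(v % g.nz);
    const int y = (int)((v / g.nz) % g.ny);
    const int xx = (int)(v / ((R_xlen_t)g.nz * g.ny));
    const double* col = Ct.colptr(r);
    for (int ci = 0; ci < g.cin; ++ci) {
      double* dxc = dx + g.sp * ci;
      for (int dx_ = 0; dx_ < g.kx; ++dx_) {
        const int xs = xx + dx_ - g.px;
        if (xs < 0 || xs >= g.nx) continue;
        for (int dy = 0; dy < g.ky; ++dy) {
          const int ys = y + dy - g.py;
          if (ys < 0 || ys >= g.ny) continue;
          const double* src = col + K * ci + g.kz * (dy + g.ky * dx_);
          double* dst =
              dxc + (R_xlen_t)g.nz * (ys + (R_xlen_t)g.ny * xs) + z - g.pz;
          for (int dz = 0; dz < g.kz; ++dz) {
            const int zs = z + dz - g.pz;
            if (zs >= 0 && zs < g.nz) dst[dz] += src[dz];
          }
        }
      }
    }
  }
}

// Kernel as a (K*Cin) x Cout matrix whose row ordering matches the
// im2col column layout (identical linear order, so a straight copy).
static arma::mat weight_mat(const NumericVector& w, const ConvGeom& g) {
  const int K = g.kz * g.ky * g.kx;
  arma::mat W(K * g.cin, g.cout);
  std::copy(w.begin(), w.end(), W.memptr());
  return W;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             NumericVector b) {
  ConvGeom g = geom_of(xdim, wdim);
  NumericVector y((R_xlen_t)g.nvox * g.cout);
  arma::mat W = weight_mat(w, g);
  const int K = g.kz * g.ky * g.kx;
  arma::mat Mt(K * g.cin, std::min((R_xlen_t)CHUNK, g.nvox));
  for (R_xlen_t v0 = 0; v0 < g.nvox; v0 += CHUNK) {
    int ncol = (int)std::min((R_xlen_t)CHUNK, g.nvox - v0);
    if (ncol != (int)Mt.n_cols) Mt.set_size(K * g.cin, ncol);
    im2col_chunk(x.begin(), g, v0, ncol, Mt);
    arma::mat Y = Mt.t() * W;  // ncol x cout
    for (int co = 0; co < g.cout; ++co) {
      double* yc = y.begin() + g.sp * co;
      const double bc = b[co];
      const double* src = Y.colptr(co);
      for (int r = 0; r < ncol; ++r) yc[v0 + r] = src[r] + bc;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector xdim, NumericVector w,
                    IntegerVector wdim, NumericVector dy) {
  ConvGeom g = geom_of(xdim, wdim);
  const int K = g.kz * g.ky * g.kx;
  arma::mat W = weight_mat(w, g);
  NumericVector dx((R_xlen_t)g.nvox * g.cin);
  arma::mat dW(K * g.cin, g.cout, arma::fill::zeros);
  NumericVector db(g.cout);

  int first = (int)std::min((R_xlen_t)CHUNK, g.nvox);
  arma::mat Mt(K * g.cin, first), G(first, g.cout);
  for (R_xlen_t v0 = 0; v0 < g.nvox; v0 += CHUNK) {
    int ncol = (int)std::min((R_xlen_t)CHUNK, g.nvox - v0);
    if (ncol != (int)Mt.n_cols) {
      Mt.set_size(K * g.cin, ncol);
      G.set_size(ncol, g.cout);
    }
    for (int co = 0; co < g.cout; ++co) {
      const double* dyc = dy.begin() + g.sp * co;
      double s = 0.0;
      double* gc = G.colptr(co);
      for (int r = 0; r < ncol; ++r) {
        gc[r] = dyc[v0 + r];
        s += gc[r];
      }
      db[co] += s;
    }
    im2col_chunk(x.begin(), g, v0, ncol, Mt);
    dW += Mt * G;                    // (K*Cin) x Cout
    arma::mat Ct = W * G.t();        // (K*Cin) x ncol
    col2im_chunk(dx.begin(), g, v0, ncol, Ct);
  }

  NumericVector dwv((R_xlen_t)K * g.cin * g.cout);
  std::copy(dW.memptr(), dW.memptr() + dW.n_elem, dwv.begin());
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = db);
}

// 2x2x2 max pooling; input spatial dims must be even.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x, IntegerVector xdim) {
  int nz = xdim[0], ny = xdim[1], nx = xdim[2], nc = xdim[3];
  int oz = nz / 2, oy = ny / 2, ox = nx / 2;
  R_xlen_t osp = (R_xlen_t)oz * oy * ox, isp = (R_xlen_t)nz * ny * nx;
  NumericVector y(osp * nc);
  IntegerVector idx(osp * nc);  // 0-based linear index into x
  for (int c = 0; c < nc; ++c) {
    const double* xc = x.begin() + isp * c;
    for (int X = 0; X < ox; ++X)
      for (int Y = 0; Y < oy; ++Y)
        for (int Z = 0; Z < oz; ++Z) {
          double best = -1e300;
          R_xlen_t bi = 0;
          for (int dx = 0; dx < 2; ++dx)
            for (int dy = 0; dy < 2; ++dy)
              for (int dz = 0; dz < 2; ++dz) {
                R_xlen_t i = (2 * Z + dz) +
                             (R_xlen_t)nz * ((2 * Y + dy) +
                                             (R_xlen_t)ny * (2 * X + dx));
                if (xc[i] > best) {
                  best = xc[i];
                  bi = i;
                }
              }
          R_xlen_t o = Z + (R_xlen_t)oz * (Y + (R_xlen_t)oy * X);
          y[o + osp * c] = best;
          idx[o + osp * c] = (int)(bi + isp * c);
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector idx,
                               IntegerVector xdim) {
  R_xlen_t n = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x, IntegerVector xdim) {
  int nz = xdim[0], ny = xdim[1], nx = xdim[2], nc = xdim[3];
  int oz = 2 * nz, oy = 2 * ny, ox = 2 * nx;
  R_xlen_t isp = (R_xlen_t)nz * ny * nx, osp = (R_xlen_t)oz * oy * ox;
  NumericVector y(osp * nc);
  for (int c = 0; c < nc; ++c) {
    const double* xc = x.begin() + isp * c;
    double* yc = y.begin() + osp * c;
    for (int X = 0; X < ox; ++X)
      for (int Y = 0; Y < oy; ++Y)
        for (int Z = 0; Z < oz; ++Z)
          yc[Z + (R_xlen_t)oz * (Y + (R_xlen_t)oy * X)] =
              xc[(Z / 2) + (R_xlen_t)nz * ((Y / 2) + (R_xlen_t)ny * (X / 2))];
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector dy, IntegerVector ydim) {
  int oz = ydim[0], oy = ydim[1], ox = ydim[2], nc = ydim[3];
  int nz = oz / 2, ny = oy / 2, nx = ox / 2;
  R_xlen_t isp = (R_xlen_t)nz * ny * nx, osp = (R_xlen_t)oz * oy * ox;
  NumericVector dx(isp * nc);
  for (int c = 0; c < nc; ++c) {
    const double* dyc = dy.begin() + osp * c;
    double* dxc = dx.begin() + isp * c;
    for (int X = 0; X < ox; ++X)
      for (int Y = 0; Y < oy; ++Y)
        for (int Z = 0; Z < oz; ++Z)
          dxc[(Z / 2) + (R_xlen_t)nz * ((Y / 2) + (R_xlen_t)ny * (X / 2))] +=
              dyc[Z + (R_xlen_t)oz * (Y + (R_xlen_t)oy * X)];
  }
  return dx;
}
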