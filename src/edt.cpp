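// Exact anisotropic squared Euclidean distance transform
// (separable lower-envelope algorithm, one pass per axis) and
// 6-connected surface extraction for binary masks.
//
// Arrays follow the package convention: dim = (nz, ny, nx), R
// column-major, so linear index = z + nz*(y + ny*x).

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const double EDT_INF = 1e20;

// 1-D squared distance transform under d(p) = min_q f(q) + w*(p-q)^2.
// f: input/output line of length n (stride handled by caller through
// gather/scatter buffers), w: squared spacing for this axis.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n,
                 double w) {
  int k = 0;
  v[0] = 0;
  z[0] = -EDT_INF;
  z[1] = EDT_INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w * q * q) - (f[p] + w * p * p)) / (2.0 * w * (q - p));
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = EDT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = w * (q - p) * (q - p) + f[p];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector feature, IntegerVector dim,
                         NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t ntot = (R_xlen_t)nz * ny * nx;
  NumericVector d(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i)
    d[i] = feature[i] ? 0.0 : EDT_INF;

  const int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), out(nmax), zbuf(nmax + 1);
  std::vector<int> vbuf(nmax);

  // axis z (stride 1)
  double w = spacing[0] * spacing[0];
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      for (int z = 0; z < nz; ++z) f[z] = d[base + z];
      dt1d(f, out, vbuf, zbuf, nz, w);
      for (int z = 0; z < nz; ++z) d[base + z] = out[z];
    }

  // axis y (stride nz)
  w = spacing[1] * spacing[1];
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      R_xlen_t base = z + (R_xlen_t)nz * ny * x;
      for (int y = 0; y < ny; ++y) f[y] = d[base + (R_xlen_t)nz * y];
      dt1d(f, out, vbuf, zbuf, ny, w);
      for (int y = 0; y < ny; ++y) d[base + (R_xlen_t)nz * y] = out[y];
    }

  // axis x (stride nz*ny)
  w = spacing[2] * spacing[2];
  const R_xlen_t sx = (R_xlen_t)nz * ny;
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      R_xlen_t base = z + (R_xlen_t)nz * y;
      for (int x = 0; x < nx; ++x) f[x] = d[base + sx * x];
      dt1d(f, out, vbuf, zbuf, nx, w);
      for (int x = 0; x < nx; ++x) d[base + sx * x] = out[x];
    }

  return d;
}

// [[Rcpp::export]]
LogicalVector cpp_surface(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  LogicalVector s((R_xlen_t)nz * ny * nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        if (!mask[i]) continue;
        bool border =
            z == 0 || z == nz - 1 || y == 0 || y == ny - 1 || x == 0 ||
            x == nx - 1;
        if (border) {
          s[i] = true;
          continue;
        }
        R_xlen_t dz = 1, dy = nz, dx = (R_xlen_t)nz * ny;
        if (!mask[i - dz] || !mask[i + dz] || !mask[i - dy] ||
            !mask[i + dy] || !mask[i - dx] || !mask[i + dx])
          s[i] = true;
      }
  return s;
}

// Largest 6-connected component of a binary mask (BFS flood fill);
// returns the component mask, or all-false for an empty input.
// [[Rcpp::export]]
LogicalVector cpp_largest_component(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<int> label(n, 0);
  int best_label = 0;
  R_xlen_t best_size = 0;
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || label[s]) continue;
    ++cur;
    R_xlen_t size = 0;
    stack.push_back(s);
    label[s] = cur;
    while (!stack.empty()) {
      R_xlen_t i = stack.back();
      stack.pop_back();
      ++size;
      int z = (int)(i % nz), y = (int)((i / nz) % ny),
          x = (int)(i / ((R_xlen_t)nz * ny));
      const int dz[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dx[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 ||
            xx >= nx)
          continue;
        R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[j] && !label[j]) {
          label[j] = cur;
          stack.push_back(j);
        }
      }
    }
    if (size > best_size) {
      best_size = size;
      best_label = cur;
    }
  }
  LogicalVector out(n);
  if (best_label)
    for (R_xlen_t i = 0; i < n; ++i) out[i] = label[i] == best_label;
  return out;
}
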