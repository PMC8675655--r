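#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Voxel grids arrive as R arrays with dim = (nz, ny, nx), column-major:
// linear index = z + nz*y + nz*ny*x (0-based here).

// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int z = (int)(cur % nz);
      int y = (int)((cur / nz) % ny);
      int x = (int)(cur / ((R_xlen_t)nz * ny));
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx; if (xx < 0 || xx >= nx) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy; if (yy < 0 || yy >= ny) continue;
          for (int dz = -1; dz <= 1; ++dz) {
            int zz = z + dz; if (zz < 0 || zz >= nz) continue;
            if (!dx && !dy && !dz) continue;
            R_xlen_t j = zz + (R_xlen_t)nz * yy + (R_xlen_t)nz * ny * xx;
            if (mask[j] && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// One-dimensional squared-distance lower envelope (Felzenszwalb & Huttenlocher),
// with physical sample spacing h so anisotropic grids are handled exactly.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &zb,
                 int n, double h) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  zb[0] = -INF; zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF && k == 0) { v[0] = q; continue; }
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + q * (double)q * h * h) - (f[p] + p * (double)p * h * h)) /
          (2.0 * h * h * (q - p));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = (q - v[k]) * h;
    d[q] = (f[v[k]] == INF) ? INF : dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance from every voxel to the nearest background
// (mask == FALSE) voxel centre. per_slice = TRUE restricts to in-plane
// (y, x) passes within each z section.
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dims,
                     NumericVector spacing, bool per_slice) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double dz = spacing[0], dy = spacing[1], dxs = spacing[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? INF : 0.0;

  int m = std::max(nz, std::max(ny, nx));
  std::vector<double> f(m), d(m), zb(m + 1);
  std::vector<int> v(m);

  if (!per_slice) {
    // pass along z
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        R_xlen_t base = (R_xlen_t)nz * y + (R_xlen_t)nz * ny * x;
        for (int z = 0; z < nz; ++z) f[z] = out[base + z];
        dt1d(f, d, v, zb, nz, dz);
        for (int z = 0; z < nz; ++z) out[base + z] = d[z];
      }
  }
  // pass along y
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      R_xlen_t base = z + (R_xlen_t)nz * ny * x;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)nz * y];
      dt1d(f, d, v, zb, ny, dy);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)nz * y] = d[y];
    }
  // pass along x
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      R_xlen_t base = z + (R_xlen_t)nz * y;
      for (int x = 0; x < nx; ++x) f[x] = out[base + (R_xlen_t)nz * ny * x];
      dt1d(f, d, v, zb, nx, dxs);
      for (int x = 0; x < nx; ++x) out[base + (R_xlen_t)nz * ny * x] = d[x];
    }
  out.attr("dim") = dims;
  return out;
}

// Separable convolution along one axis (1 = z, 2 = y, 3 = x) with
// replicate (nearest) boundary padding.
// [[Rcpp::export(name = ".conv_axis_cpp")]]
NumericVector conv_axis_cpp(NumericVector a, IntegerVector dims,
                            NumericVector kernel, int axis) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (a.size() != n) stop("array length does not match dims");
  const int klen = kernel.size();
  const int r = (klen - 1) / 2;
  NumericVector out(n);
  const int alen = axis == 1 ? nz : (axis == 2 ? ny : nx);
  const R_xlen_t stride = axis == 1 ? 1 :
    (axis == 2 ? (R_xlen_t)nz : (R_xlen_t)nz * ny);
  const R_xlen_t nlines = n / alen;
  // iterate over all lines along `axis`
  for (R_xlen_t line = 0; line < nlines; ++line) {
    R_xlen_t base;
    if (axis == 1) base = line * nz;
    else if (axis == 2) {
      R_xlen_t z = line % nz, x = line / nz;
      base = z + (R_xlen_t)nz * ny * x;
    } else {
      base = line; // (z, y) pairs are contiguous for the x axis
    }
    for (int i = 0; i < alen; ++i) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t) {
        int j = i + t;
        if (j < 0) j = 0; else if (j >= alen) j = alen - 1;
        acc += kernel[t + r] * a[base + (R_xlen_t)j * stride];
      }
      out[base + (R_xlen_t)i * stride] = acc;
    }
  }
  out.attr("dim") = dims;
  return out;
}
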