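#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sample a 3D scalar grid at arbitrary world points.
// Grid convention: value (i,j,k) sits at world = origin + c(i,j,k) * spacing,
// 0-based indices, R column-major storage.
// method: 0 = nearest neighbour, 1 = trilinear. Points outside the grid
// support return NA (callers decide how to treat them).
// [[Rcpp::export]]
NumericVector cpp_sample_volume(NumericVector data, IntegerVector dim,
                                NumericVector spacing, NumericVector origin,
                                NumericMatrix pts, int method) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  const double *d = data.begin();
  for (R_xlen_t q = 0; q < n; ++q) {
    double fx = (pts(q, 0) - origin[0]) / spacing[0];
    double fy = (pts(q, 1) - origin[1]) / spacing[1];
    double fz = (pts(q, 2) - origin[2]) / spacing[2];
    if (method == 0) {
      long i = std::lround(fx), j = std::lround(fy), k = std::lround(fz);
      if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) {
        out[q] = NA_REAL;
        continue;
      }
      out[q] = d[i + (size_t)nx * (j + (size_t)ny * k)];
    } else {
      if (!(fx >= 0 && fy >= 0 && fz >= 0 &&
            fx <= nx - 1 && fy <= ny - 1 && fz <= nz - 1)) {
        out[q] = NA_REAL;
        continue;
      }
      int i = (int)std::floor(fx), j = (int)std::floor(fy), k = (int)std::floor(fz);
      if (i > nx - 2) i = nx - 2;
      if (j > ny - 2) j = ny - 2;
      if (k > nz - 2) k = nz - 2;
      if (i < 0) i = 0;
      if (j < 0) j = 0;
      if (k < 0) k = 0;
      double dx = fx - i, dy = fy - j, dz = fz - k;
      size_t base = i + (size_t)nx * (j + (size_t)ny * k);
      size_t sx = 1, sy = nx, sz = (size_t)nx * ny;
      double c000 = d[base],            c100 = d[base + sx];
      double c010 = d[base + sy],       c110 = d[base + sx + sy];
      double c001 = d[base + sz],       c101 = d[base + sx + sz];
      double c011 = d[base + sy + sz],  c111 = d[base + sx + sy + sz];
      double c00 = c000 * (1 - dx) + c100 * dx;
      double c10 = c010 * (1 - dx) + c110 * dx;
      double c01 = c001 * (1 - dx) + c101 * dx;
      double c11 = c011 * (1 - dx) + c111 * dx;
      double c0 = c00 * (1 - dy) + c10 * dy;
      double c1 = c01 * (1 - dy) + c11 * dy;
      out[q] = c0 * (1 - dz) + c1 * dz;
    }
  }
  return out;
}

// Separable convolution of a 3D grid with the same symmetric 1D kernel
// along all three axes, zero boundary condition.
// [[Rcpp::export]]
NumericVector cpp_convolve_axes(NumericVector data, IntegerVector dim,
                                NumericVector kernel) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int kl = kernel.size();
  const int r = (kl - 1) / 2;
  std::vector<double> a(data.begin(), data.end()), b(a.size());
  const size_t sx = 1, sy = nx, sz = (size_t)nx * ny;
  const int n[3] = {nx, ny, nz};
  const size_t st[3] = {sx, sy, sz};
  for (int axis = 0; axis < 3; ++axis) {
    const int na = n[axis];
    const size_t sa = st[axis];
    // iterate over all lines along `axis`
    const int nu = n[(axis + 1) % 3], nv = n[(axis + 2) % 3];
    const size_t su = st[(axis + 1) % 3], sv = st[(axis + 2) % 3];
    for (int v = 0; v < nv; ++v) {
      for (int u = 0; u < nu; ++u) {
        size_t base = (size_t)u * su + (size_t)v * sv;
        for (int t = 0; t < na; ++t) {
          double acc = 0.0;
          int lo = t - r < 0 ? 0 : t - r;
          int hi = t + r >= na ? na - 1 : t + r;
          for (int s = lo; s <= hi; ++s)
            acc += kernel[s - t + r] * a[base + (size_t)s * sa];
          b[base + (size_t)t * sa] = acc;
        }
      }
    }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// Joint histogram with hard binning (exactly symmetric use) —
// fa, fb are 0-based bin indices of equal length.
// [[Rcpp::export]]
NumericVector cpp_joint_hist(IntegerVector fa, IntegerVector fb, int bins) {
  NumericVector h(bins * bins);
  R_xlen_t n = fa.size();
  for (R_xlen_t q = 0; q < n; ++q) {
    int i = fa[q], j = fb[q];
    if (i < 0 || j < 0 || i >= bins || j >= bins) continue;
    h[i + (size_t)bins * j] += 1.0;
  }
  return h;
}

// Joint histogram with partial-volume (linear) weighting on the second
// image: mb is a continuous bin coordinate in [0, bins-1]; each sample
// spreads between the two neighbouring bins. Keeps the registration
// objective continuous in the pose parameters.
// [[Rcpp::export]]
NumericVector cpp_joint_hist_pv(IntegerVector fa, NumericVector mb, int bins) {
  NumericVector h(bins * bins);
  R_xlen_t n = fa.size();
  for (R_xlen_t q = 0; q < n; ++q) {
    int i = fa[q];
    double y = mb[q];
    if (i < 0 || i >= bins || !(y >= 0)) continue;
    if (y > bins - 1) y = bins - 1;
    int j = (int)std::floor(y);
    if (j > bins - 2) j = bins - 2;
    if (j < 0) j = 0;
    double w = y - j;
    h[i + (size_t)bins * j] += 1.0 - w;
    h[i + (size_t)bins * (j + 1)] += w;
  }
  return h;
}
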