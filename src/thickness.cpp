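#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb-Huttenlocher,
// separable lower-envelope of parabolas) and Hildebrand-Ruegsegger local
// thickness by sphere painting. Distances are measured between voxel
// centers, in voxel units; voxels outside the image belong to neither
// phase (the structure is treated as extending past the border).

static const double INF = 1e18;

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared distance from each voxel of `phase` to the nearest voxel of the
// opposite phase (voxel-center to voxel-center, voxel units). Voxels not in
// `phase` get 0. All-one-phase images get +Inf on the phase.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector phase, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  std::vector<double> d(n);
  for (int i = 0; i < n; ++i) d[i] = phase[i] ? INF : 0.0;

  std::vector<double> f(std::max(nx, std::max(ny, nz))), g(f.size());
  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      int base = nx * (y + ny * z);
      for (int x = 0; x < nx; ++x) f[x] = d[base + x];
      dt1d(f, g, nx);
      for (int x = 0; x < nx; ++x) d[base + x] = g[x];
    }
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = d[x + nx * (y + ny * z)];
      dt1d(f, g, ny);
      for (int y = 0; y < ny; ++y) d[x + nx * (y + ny * z)] = g[y];
    }
  // pass along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = d[x + nx * (y + ny * z)];
      dt1d(f, g, nz);
      for (int z = 0; z < nz; ++z) d[x + nx * (y + ny * z)] = g[z];
    }

  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = phase[i] ? (d[i] >= INF ? R_PosInf : d[i]) : 0.0;
  out.attr("dim") = dim;
  return out;
}

// Local thickness map: for each phase voxel p, the diameter (voxel units)
// of the largest sphere that contains p and no opposite-phase voxel center.
// Returned value is 2*sqrt(max covering r^2) - 1 (half-voxel surface
// correction on each side); 0 outside the phase.
// [[Rcpp::export]]
NumericVector cpp_thickness_map(LogicalVector phase, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  NumericVector r2 = cpp_edt_sq(phase, dim);
  for (int i = 0; i < n; ++i)
    if (phase[i] && !R_finite(r2[i]))
      stop("thickness undefined: image contains a single phase");

  // paint spheres in descending radius order so each voxel keeps the max
  std::vector<int> order;
  order.reserve(n);
  for (int i = 0; i < n; ++i) if (phase[i]) order.push_back(i);
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return r2[a] > r2[b]; });

  std::vector<double> best(n, 0.0);
  for (int ci : order) {
    double rc2 = r2[ci];
    int z = ci / (nx * ny), r = ci % (nx * ny);
    int y = r / nx, x = r % nx;
    int rad = (int)std::ceil(std::sqrt(rc2)) - 1;  // ||p-c||^2 < rc2 strictly
    for (int dz = -rad; dz <= rad; ++dz) {
      int zz = z + dz; if (zz < 0 || zz >= nz) continue;
      for (int dy = -rad; dy <= rad; ++dy) {
        int yy = y + dy; if (yy < 0 || yy >= ny) continue;
        double dd = (double)dz * dz + (double)dy * dy;
        if (dd >= rc2) continue;
        int base = nx * (yy + ny * zz);
        for (int dx = -rad; dx <= rad; ++dx) {
          int xx = x + dx; if (xx < 0 || xx >= nx) continue;
          if (dd + (double)dx * dx >= rc2) continue;
          int p = base + xx;
          if (best[p] < rc2) best[p] = rc2;
        }
      }
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = phase[i] ? 2.0 * std::sqrt(best[i]) - 1.0 : 0.0;
  out.attr("dim") = dim;
  return out;
}
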