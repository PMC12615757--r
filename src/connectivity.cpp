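#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Column-major voxel index helpers shared by the 3-D image routines.
// Connectivity: 26 for the bone phase, 6 for pores (prevents checkerboard
// ambiguity between the two phases).

static inline int vox(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Label connected components of `mask` (true voxels) with the given
// connectivity (6 or 26). Returns integer labels, 0 = background.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int seed = 0; seed < n; ++seed) {
    if (!mask[seed] || lab[seed]) continue;
    ++next;
    lab[seed] = next;
    stack.push_back(seed);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int z = cur / (nx * ny), r = cur % (nx * ny);
      int y = r / nx, x = r % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1)
              continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            int nb = vox(xx, yy, zz, nx, ny);
            if (mask[nb] && !lab[nb]) { lab[nb] = next; stack.push_back(nb); }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Keep only the largest 26-connected foreground component.
// [[Rcpp::export]]
LogicalVector cpp_largest_component(LogicalVector mask, IntegerVector dim) {
  IntegerVector lab = cpp_label_components(mask, dim, 26);
  int n = mask.size(), maxlab = 0;
  for (int i = 0; i < n; ++i) maxlab = std::max(maxlab, lab[i]);
  if (maxlab == 0) stop("mask has no foreground voxels");
  std::vector<long> count(maxlab + 1, 0);
  for (int i = 0; i < n; ++i) if (lab[i]) ++count[lab[i]];
  int best = 1;
  for (int l = 2; l <= maxlab; ++l) if (count[l] > count[best]) best = l;
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = (lab[i] == best);
  out.attr("dim") = dim;
  return out;
}

// Fill 6-connected background pockets fully enclosed by foreground: any
// background component not reaching the image border is set to foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_enclosed_pores(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  LogicalVector inv(n);
  for (int i = 0; i < n; ++i) inv[i] = !mask[i];
  IntegerVector lab = cpp_label_components(inv, dim, 6);
  int maxlab = 0;
  for (int i = 0; i < n; ++i) maxlab = std::max(maxlab, lab[i]);
  std::vector<bool> touches(maxlab + 1, false);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (x == 0 || y == 0 || z == 0 || x == nx - 1 || y == ny - 1 || z == nz - 1) {
          int l = lab[vox(x, y, z, nx, ny)];
          if (l) touches[l] = true;
        }
      }
  LogicalVector out = clone(mask);
  for (int i = 0; i < n; ++i)
    if (lab[i] && !touches[lab[i]]) out[i] = true;
  out.attr("dim") = dim;
  return out;
}
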