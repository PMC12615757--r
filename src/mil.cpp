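#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Mean intercept length sampling: for each test direction a parallel grid
// of lines is marched through the voxel volume at sub-voxel steps; bone
// length accumulates per sample and an intercept is counted whenever a
// line enters the bone phase from void (or from outside the volume).

// [[Rcpp::export]]
NumericMatrix cpp_mil_scan(LogicalVector mask, IntegerVector dim,
                           NumericMatrix dirs, double step,
                           double line_spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ndir = dirs.nrow();
  NumericMatrix out(ndir, 2);  // col 0: bone length (voxels), col 1: intercepts

  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  const double rb = 0.5 * std::sqrt((double)nx * nx + (double)ny * ny + (double)nz * nz);

  for (int k = 0; k < ndir; ++k) {
    double dx = dirs(k, 0), dy = dirs(k, 1), dz = dirs(k, 2);
    double nrm = std::sqrt(dx * dx + dy * dy + dz * dz);
    dx /= nrm; dy /= nrm; dz /= nrm;
    // orthonormal in-plane basis
    double ax = 0, ay = 0, az = 1;
    if (std::fabs(dz) > 0.9) { ax = 1; az = 0; }
    double e1x = dy * az - dz * ay, e1y = dz * ax - dx * az, e1z = dx * ay - dy * ax;
    double n1 = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
    e1x /= n1; e1y /= n1; e1z /= n1;
    double e2x = dy * e1z - dz * e1y, e2y = dz * e1x - dx * e1z, e2z = dx * e1y - dy * e1x;

    double blen = 0; long icpt = 0;
    for (double a = -rb; a <= rb; a += line_spacing) {
      for (double b = -rb; b <= rb; b += line_spacing) {
        double ox = cx + a * e1x + b * e2x;
        double oy = cy + a * e1y + b * e2y;
        double oz = cz + a * e1z + b * e2z;
        bool prev_bone = false;
        long nbone = 0;
        for (double t = -rb; t <= rb; t += step) {
          long xi = std::llround(ox + t * dx);
          long yi = std::llround(oy + t * dy);
          long zi = std::llround(oz + t * dz);
          bool bone = false;
          if (xi >= 0 && yi >= 0 && zi >= 0 && xi < nx && yi < ny && zi < nz)
            bone = mask[xi + (long)nx * (yi + (long)ny * zi)];
          if (bone) {
            ++nbone;
            if (!prev_bone) ++icpt;
          }
          prev_bone = bone;
        }
        blen += nbone * step;
      }
    }
    out(k, 0) = blen;
    out(k, 1) = (double)icpt;
  }
  return out;
}
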