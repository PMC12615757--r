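#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel micro-FE homogenization under kinematic uniform boundary
// conditions (KUBC). Each foreground voxel becomes a fully integrated
// trilinear hexahedron (2x2x2 Gauss); all tensors use Mandel notation
// (strain = [e11,e22,e33,sqrt2*e23,sqrt2*e13,sqrt2*e12]) so the 6x6
// apparent matrix carries the fourth-order tensor norm.
//
// Node numbering: node (x,y,z) -> x + (nx+1)*(y + (ny+1)*z), 0-based;
// voxel (i,j,k) owns the 8 nodes (i+di, j+dj, k+dk), local node index
// di + 2*dj + 4*dk, with 3 dofs per node (ux,uy,uz) node-major.

static const double GP = 0.577350269189625764509148780502;  // 1/sqrt(3)

static void mandel_D(double E, double nu, double D[6][6]) {
  double lam = E * nu / ((1 + nu) * (1 - 2 * nu));
  double mu = E / (2 * (1 + nu));
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) D[i][j] = 0;
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) D[i][j] = lam;
    D[i][i] = lam + 2 * mu;
    D[i + 3][i + 3] = 2 * mu;
  }
}

// B matrix (6x24, Mandel) at local coords (xi,eta,zeta) for cube side h.
static void bmat(double xi, double eta, double zeta, double h, double B[6][24]) {
  const double s2 = std::sqrt(0.5);  // 1/sqrt(2)
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 24; ++j) B[i][j] = 0;
  for (int a = 0; a < 8; ++a) {
    double sx = (a & 1) ? 1.0 : -1.0;
    double sy = (a & 2) ? 1.0 : -1.0;
    double sz = (a & 4) ? 1.0 : -1.0;
    // dN/dx = (2/h) * dN/dxi etc.
    double dNx = 0.125 * sx * (1 + sy * eta) * (1 + sz * zeta) * 2.0 / h;
    double dNy = 0.125 * (1 + sx * xi) * sy * (1 + sz * zeta) * 2.0 / h;
    double dNz = 0.125 * (1 + sx * xi) * (1 + sy * eta) * sz * 2.0 / h;
    int c = 3 * a;
    B[0][c] = dNx;
    B[1][c + 1] = dNy;
    B[2][c + 2] = dNz;
    B[3][c + 1] = s2 * dNz; B[3][c + 2] = s2 * dNy;  // sqrt2*e23
    B[4][c] = s2 * dNz;     B[4][c + 2] = s2 * dNx;  // sqrt2*e13
    B[5][c] = s2 * dNy;     B[5][c + 1] = s2 * dNx;  // sqrt2*e12
  }
}

static void hex8_ke(double E, double nu, double h, double Ke[24][24]) {
  double D[6][6], B[6][24];
  mandel_D(E, nu, D);
  for (int i = 0; i < 24; ++i)
    for (int j = 0; j < 24; ++j) Ke[i][j] = 0;
  double detJ = (h / 2) * (h / 2) * (h / 2);
  for (int g = 0; g < 8; ++g) {
    double xi = (g & 1) ? GP : -GP;
    double eta = (g & 2) ? GP : -GP;
    double zeta = (g & 4) ? GP : -GP;
    bmat(xi, eta, zeta, h, B);
    double DB[6][24];
    for (int i = 0; i < 6; ++i)
      for (int j = 0; j < 24; ++j) {
        double s = 0;
        for (int k = 0; k < 6; ++k) s += D[i][k] * B[k][j];
        DB[i][j] = s;
      }
    for (int i = 0; i < 24; ++i)
      for (int j = 0; j < 24; ++j) {
        double s = 0;
        for (int k = 0; k < 6; ++k) s += B[k][i] * DB[k][j];
        Ke[i][j] += s * detJ;
      }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_hex8_ke(double E, double nu, double h) {
  double Ke[24][24];
  hex8_ke(E, nu, h, Ke);
  NumericMatrix out(24, 24);
  for (int i = 0; i < 24; ++i)
    for (int j = 0; j < 24; ++j) out(i, j) = Ke[i][j];
  return out;
}

struct Mesh {
  int nx, ny, nz, nnx, nny, nnz;
  long nnode, ndof;
  std::vector<long> enodes;   // 8 node ids per element
  std::vector<long> elems;    // voxel ids of foreground
};

static void build_mesh(const LogicalVector& mask, const IntegerVector& dim, Mesh& m) {
  m.nx = dim[0]; m.ny = dim[1]; m.nz = dim[2];
  m.nnx = m.nx + 1; m.nny = m.ny + 1; m.nnz = m.nz + 1;
  m.nnode = (long)m.nnx * m.nny * m.nnz;
  m.ndof = 3 * m.nnode;
  for (int k = 0; k < m.nz; ++k)
    for (int j = 0; j < m.ny; ++j)
      for (int i = 0; i < m.nx; ++i) {
        long v = i + (long)m.nx * (j + (long)m.ny * k);
        if (!mask[v]) continue;
        m.elems.push_back(v);
        for (int dk = 0; dk < 2; ++dk)
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di)
              m.enodes.push_back((i + di) + (long)m.nnx * ((j + dj) + (long)m.nny * (k + dk)));
      }
}

// y += K*u over foreground elements (full dof vectors)
static void applyK(const Mesh& m, const double Ke[24][24],
                   const std::vector<double>& u, std::vector<double>& y) {
  std::fill(y.begin(), y.end(), 0.0);
  double ue[24], fe[24];
  const long ne = (long)m.elems.size();
  for (long e = 0; e < ne; ++e) {
    const long* nd = &m.enodes[8 * e];
    for (int a = 0; a < 8; ++a) {
      long d = 3 * nd[a];
      ue[3 * a] = u[d]; ue[3 * a + 1] = u[d + 1]; ue[3 * a + 2] = u[d + 2];
    }
    for (int i = 0; i < 24; ++i) {
      double s = 0;
      for (int j = 0; j < 24; ++j) s += Ke[i][j] * ue[j];
      fe[i] = s;
    }
    for (int a = 0; a < 8; ++a) {
      long d = 3 * nd[a];
      y[d] += fe[3 * a]; y[d + 1] += fe[3 * a + 1]; y[d + 2] += fe[3 * a + 2];
    }
  }
}

// [[Rcpp::export]]
List cpp_homogenize(LogicalVector mask, IntegerVector dim, double h,
                    double E, double nu, double tol, int maxit) {
  Mesh m;
  build_mesh(mask, dim, m);
  if (m.elems.empty()) stop("empty structure: no foreground voxels");

  double Ke[24][24], D[6][6], B0[6][24];
  hex8_ke(E, nu, h, Ke);
  mandel_D(E, nu, D);
  bmat(0, 0, 0, h, B0);  // centroid B = Gauss average for trilinear bricks

  // dof classification: boundary nodes prescribed, attached interior free
  std::vector<char> attached(m.nnode, 0);
  for (long q = 0; q < (long)m.enodes.size(); ++q) attached[m.enodes[q]] = 1;
  std::vector<char> fixed(m.nnode, 1);
  long nfree_nodes = 0;
  for (int z = 1; z < m.nnz - 1; ++z)
    for (int y = 1; y < m.nny - 1; ++y)
      for (int x = 1; x < m.nnx - 1; ++x) {
        long nid = x + (long)m.nnx * (y + (long)m.nny * z);
        if (attached[nid]) { fixed[nid] = 0; ++nfree_nodes; }
      }
  std::vector<long> free_dofs;
  free_dofs.reserve(3 * nfree_nodes);
  for (long nid = 0; nid < m.nnode; ++nid)
    if (!fixed[nid])
      for (int c = 0; c < 3; ++c) free_dofs.push_back(3 * nid + c);
  const long nf = (long)free_dofs.size();

  // Jacobi preconditioner from the assembled diagonal
  std::vector<double> diag(m.ndof, 0.0);
  for (long e = 0; e < (long)m.elems.size(); ++e) {
    const long* nd = &m.enodes[8 * e];
    for (int a = 0; a < 8; ++a)
      for (int c = 0; c < 3; ++c)
        diag[3 * nd[a] + c] += Ke[3 * a + c][3 * a + c];
  }

  std::vector<double> u(m.ndof), Ku(m.ndof);
  std::vector<double> r(nf), zv(nf), p(nf), Ap(nf);
  NumericMatrix S(6, 6);
  IntegerVector iters(6);
  LogicalVector converged(6);
  const double V = (double)m.nx * m.ny * m.nz * h * h * h;
  const double s2 = std::sqrt(0.5);

  for (int cs = 0; cs < 6; ++cs) {
    // Mandel unit apparent strain tensor
    double Emat[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    if (cs < 3) Emat[cs][cs] = 1.0;
    else {
      int i = (cs == 3) ? 1 : (cs == 4) ? 0 : 0;
      int j = (cs == 3) ? 2 : (cs == 4) ? 2 : 1;
      Emat[i][j] = Emat[j][i] = s2;
    }
    // u = E.x everywhere as initial guess; fixed dofs keep this exactly
    for (int z = 0; z < m.nnz; ++z)
      for (int y = 0; y < m.nny; ++y)
        for (int x = 0; x < m.nnx; ++x) {
          long d = 3 * (x + (long)m.nnx * (y + (long)m.nny * z));
          double px = x * h, py = y * h, pz = z * h;
          u[d] = Emat[0][0] * px + Emat[0][1] * py + Emat[0][2] * pz;
          u[d + 1] = Emat[1][0] * px + Emat[1][1] * py + Emat[1][2] * pz;
          u[d + 2] = Emat[2][0] * px + Emat[2][1] * py + Emat[2][2] * pz;
        }

    // reference RHS norm: residual with zero free displacements
    std::vector<double> u0(u);
    for (long q = 0; q < nf; ++q) u0[free_dofs[q]] = 0.0;
    applyK(m, Ke, u0, Ku);
    double bnorm = 0;
    for (long q = 0; q < nf; ++q) bnorm += Ku[free_dofs[q]] * Ku[free_dofs[q]];
    bnorm = std::sqrt(bnorm);
    if (bnorm == 0) bnorm = 1.0;

    // PCG on the free dofs, starting from the affine guess
    applyK(m, Ke, u, Ku);
    double rnorm2 = 0, rz = 0;
    for (long q = 0; q < nf; ++q) {
      r[q] = -Ku[free_dofs[q]];
      zv[q] = r[q] / diag[free_dofs[q]];
      p[q] = zv[q];
      rnorm2 += r[q] * r[q];
      rz += r[q] * zv[q];
    }
    int it = 0;
    bool ok = std::sqrt(rnorm2) / bnorm <= tol;
    std::vector<double> pext(m.ndof, 0.0);
    while (!ok && it < maxit) {
      ++it;
      for (long q = 0; q < nf; ++q) pext[free_dofs[q]] = p[q];
      applyK(m, Ke, pext, Ku);
      double pAp = 0;
      for (long q = 0; q < nf; ++q) {
        Ap[q] = Ku[free_dofs[q]];
        pAp += p[q] * Ap[q];
      }
      if (pAp <= 0) stop("singular system: structure does not support the load");
      double alpha = rz / pAp;
      rnorm2 = 0;
      double rznew = 0;
      for (long q = 0; q < nf; ++q) {
        u[free_dofs[q]] += alpha * p[q];
        r[q] -= alpha * Ap[q];
        zv[q] = r[q] / diag[free_dofs[q]];
        rnorm2 += r[q] * r[q];
        rznew += r[q] * zv[q];
      }
      ok = std::sqrt(rnorm2) / bnorm <= tol;
      double beta = rznew / rz;
      rz = rznew;
      for (long q = 0; q < nf; ++q) p[q] = zv[q] + beta * p[q];
    }
    iters[cs] = it;
    converged[cs] = ok;

    // apparent stress: volume average of element stresses over the cube
    double sig[6] = {0, 0, 0, 0, 0, 0};
    double ue[24];
    for (long e = 0; e < (long)m.elems.size(); ++e) {
      const long* nd = &m.enodes[8 * e];
      for (int a = 0; a < 8; ++a) {
        long d = 3 * nd[a];
        ue[3 * a] = u[d]; ue[3 * a + 1] = u[d + 1]; ue[3 * a + 2] = u[d + 2];
      }
      double eps[6];
      for (int i = 0; i < 6; ++i) {
        double s = 0;
        for (int j = 0; j < 24; ++j) s += B0[i][j] * ue[j];
        eps[i] = s;
      }
      for (int i = 0; i < 6; ++i) {
        double s = 0;
        for (int k = 0; k < 6; ++k) s += D[i][k] * eps[k];
        sig[i] += s * h * h * h;
      }
    }
    for (int i = 0; i < 6; ++i) S(i, cs) = sig[i] / V;
  }

  return List::create(_["mandel"] = S, _["iterations"] = iters,
                      _["converged"] = converged, _["n_elements"] = (double)m.elems.size(),
                      _["n_free_dofs"] = (double)nf);
}
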