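#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Squared Euclidean distance transform of a 3D mask on an anisotropic grid,
// computed by the separable lower-envelope (parabola) algorithm, one axis at
// a time. Distances are voxel-center to voxel-center, in physical units.

static const double INF = 1e30;

// 1D squared distance transform of sampled function f at coordinates i*h.
static void dt1d(const double* f, double* d, int n, double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * h;
    while (true) {
      double xv = v[k] * h;
      double s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k]) {
        --k;
      } else {
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = INF;
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * h;
    d[q] = dx * dx + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d_sq(LogicalVector mask, IntegerVector dim,
                           NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> d(f.size());

  // pass along x (fastest-varying)
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f.data(), d.data(), nx, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)y * nx];
      dt1d(f.data(), d.data(), ny, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = d[y];
    }
  // pass along z
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = out[base + (R_xlen_t)z * nxy];
      dt1d(f.data(), d.data(), nz, spacing[2]);
      for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * nxy] = d[z];
    }
  return out;
}

// Connected-component labeling of a 3D mask under 6/18/26-connectivity.
// Breadth-first search; labels are assigned in raster-scan order of the
// first voxel encountered, so the labeling is deterministic.

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim,
                          int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);

  // neighbor offsets for the requested connectivity
  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        int m = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (m == 0) continue;
        if ((connectivity == 6 && m > 1) || (connectivity == 18 && m > 2))
          continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }
  const int nn = (int)dx.size();

  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int cz = (int)(cur / ((R_xlen_t)nx * ny));
      int rem = (int)(cur % ((R_xlen_t)nx * ny));
      int cy = rem / nx, cx = rem % nx;
      for (int k = 0; k < nn; ++k) {
        int x = cx + dx[k], y = cy + dy[k], z = cz + dz[k];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
        R_xlen_t j = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
        if (mask[j] && lab[j] == 0) {
          lab[j] = next;
          q.push(j);
        }
      }
    }
  }
  return lab;
}
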