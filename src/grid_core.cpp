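#include <Rcpp.h>
#include <vector>
#include <array>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Voxel grids are stored column-major (R array order): lin = i + nx*(j + ny*k).

static const double BIG = std::numeric_limits<double>::infinity();

// Clearance field: c(v) = min over atoms of (|v - x_i| - r_i), capped at `cap`.
// Negative inside an atom sphere.  Each atom only influences voxels within
// r_i + cap of its centre, so the sweep is local per atom.
// [[Rcpp::export]]
NumericVector cpp_clearance_field(NumericMatrix coords, NumericVector radii,
                                  NumericVector origin, double spacing,
                                  IntegerVector dims, double cap) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n, cap);
  double* c = out.begin();
  const int natom = coords.nrow();
  for (int a = 0; a < natom; ++a) {
    const double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    const double r = radii[a];
    const double reach = r + cap;
    int i0 = (int)std::ceil((ax - reach - origin[0]) / spacing);
    int i1 = (int)std::floor((ax + reach - origin[0]) / spacing);
    int j0 = (int)std::ceil((ay - reach - origin[1]) / spacing);
    int j1 = (int)std::floor((ay + reach - origin[1]) / spacing);
    int k0 = (int)std::ceil((az - reach - origin[2]) / spacing);
    int k1 = (int)std::floor((az + reach - origin[2]) / spacing);
    if (i0 < 0) i0 = 0; if (i1 > nx - 1) i1 = nx - 1;
    if (j0 < 0) j0 = 0; if (j1 > ny - 1) j1 = ny - 1;
    if (k0 < 0) k0 = 0; if (k1 > nz - 1) k1 = nz - 1;
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + k * spacing - az;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + j * spacing - ay;
        const double dyz2 = dy * dy + dz * dz;
        R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + i * spacing - ax;
          const double d = std::sqrt(dx * dx + dyz2) - r;
          if (d < c[base + i]) c[base + i] = d;
        }
      }
    }
  }
  return out;
}

// 26-connected flood fill from the grid boundary restricted to `open` voxels.
// Returns the accessible subset (solvent-connected free region).
// [[Rcpp::export]]
LogicalVector cpp_accessible(LogicalVector open, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector acc(n, false);
  std::queue<R_xlen_t> q;
  auto push = [&](int i, int j, int k) {
    R_xlen_t lin = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
    if (open[lin] && !acc[lin]) { acc[lin] = true; q.push(lin); }
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (i == 0 || i == nx - 1 || j == 0 || j == ny - 1 || k == 0 || k == nz - 1)
          push(i, j, k);
  while (!q.empty()) {
    R_xlen_t lin = q.front(); q.pop();
    int i = (int)(lin % nx);
    int j = (int)((lin / nx) % ny);
    int k = (int)(lin / ((R_xlen_t)nx * ny));
    for (int dk = -1; dk <= 1; ++dk) {
      int kk = k + dk; if (kk < 0 || kk >= nz) continue;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = j + dj; if (jj < 0 || jj >= ny) continue;
        for (int di = -1; di <= 1; ++di) {
          int ii = i + di; if (ii < 0 || ii >= nx) continue;
          if (di == 0 && dj == 0 && dk == 0) continue;
          push(ii, jj, kk);
        }
      }
    }
  }
  return acc;
}

// One-dimensional lower envelope of parabolas (distance transform of a
// sampled function, Felzenszwalb & Huttenlocher).  Sites with f = +Inf are
// skipped.  d[q] = min_p ((q-p)^2 + f[p]).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z,
                 std::vector<int>& sites) {
  sites.clear();
  for (int p = 0; p < n; ++p) if (f[p] < BIG) sites.push_back(p);
  if (sites.empty()) { for (int q = 0; q < n; ++q) d[q] = BIG; return; }
  int k = 0;
  v[0] = sites[0];
  z[0] = -BIG; z[1] = BIG;
  for (size_t si = 1; si < sites.size(); ++si) {
    int q = sites[si];
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + (double)q * q) - (f[p] + (double)p * p)) / (2.0 * q - 2.0 * p);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Full 3D distance transform of a sampled function on the voxel lattice:
// D(v) = min_u (|u - v|^2 + f(u)), distances in voxel units.
// f must be +Inf at non-site voxels.
// [[Rcpp::export]]
NumericVector cpp_dt_sampled(NumericVector f, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> D(f.begin(), f.end());
  for (R_xlen_t t = 0; t < n; ++t) if (NumericVector::is_na(D[t])) D[t] = BIG;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> fline(nmax), dline(nmax), z(nmax + 1);
  std::vector<int> v(nmax), sites;
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) fline[i] = D[base + i];
      dt1d(fline, dline, nx, v, z, sites);
      for (int i = 0; i < nx; ++i) D[base + i] = dline[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * (R_xlen_t)k;
      for (int j = 0; j < ny; ++j) fline[j] = D[base + (R_xlen_t)nx * j];
      dt1d(fline, dline, ny, v, z, sites);
      for (int j = 0; j < ny; ++j) D[base + (R_xlen_t)nx * j] = dline[j];
    }
  // z pass
  const R_xlen_t stride = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) fline[k] = D[base + stride * k];
      dt1d(fline, dline, nz, v, z, sites);
      for (int k = 0; k < nz; ++k) D[base + stride * k] = dline[k];
    }
  NumericVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) out[t] = D[t];
  return out;
}

// Connected-component labelling of a boolean mask (6/18/26 connectivity).
// Labels are assigned in raster-scan discovery order starting at 1.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int, 3>> nb;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int m = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        nb.push_back({di, dj, dk});
      }
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t lin = q.front(); q.pop();
      int i = (int)(lin % nx);
      int j = (int)((lin / nx) % ny);
      int k = (int)(lin / ((R_xlen_t)nx * ny));
      for (auto& d : nb) {
        int ii = i + d[0], jj = j + d[1], kk = k + d[2];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        R_xlen_t t = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[t] && lab[t] == 0) { lab[t] = next; q.push(t); }
      }
    }
  }
  return lab;
}
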