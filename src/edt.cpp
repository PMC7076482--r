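#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact squared Euclidean distance transform, separable lower-envelope
// algorithm (Felzenszwalb & Huttenlocher), one 1D pass per axis.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -1e30;
  z[1] = 1e30;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Distance (in voxel units) from each voxel centre to the nearest solid
// voxel centre. Solid voxels get 0. All-fluid grids get a large sentinel.
// [[Rcpp::export(name = ".edt_cpp")]]
NumericVector edt_cpp(LogicalVector solid, int nx, int ny, int nz) {
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(N);
  const double BIG = 1e18;
  for (R_xlen_t t = 0; t < N; ++t) g[t] = solid[t] ? 0.0 : BIG;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x-pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      dt1d(f, d, v, z, nx);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  // y-pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j)
        f[j] = g[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      dt1d(f, d, v, z, ny);
      for (int j = 0; j < ny; ++j)
        g[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = d[j];
    }
  // z-pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k)
        f[k] = g[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      dt1d(f, d, v, z, nz);
      for (int k = 0; k < nz; ++k)
        g[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = d[k];
    }
  NumericVector out(N);
  for (R_xlen_t t = 0; t < N; ++t) out[t] = std::sqrt(g[t]);
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}
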