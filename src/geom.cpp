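#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Closest approach of two 2D segments p0-p1, q0-q1.
// Returns squared distance; s_out/t_out get the arc parameters in [0,1].
static double seg2_dist2(double p0x, double p0y, double p1x, double p1y,
                         double q0x, double q0y, double q1x, double q1y,
                         double *s_out, double *t_out) {
  const double dx1 = p1x - p0x, dy1 = p1y - p0y;
  const double dx2 = q1x - q0x, dy2 = q1y - q0y;
  const double rx = p0x - q0x, ry = p0y - q0y;
  const double a = dx1 * dx1 + dy1 * dy1;   // |d1|^2
  const double e = dx2 * dx2 + dy2 * dy2;   // |d2|^2
  const double f = dx2 * rx + dy2 * ry;
  double s = 0.0, t = 0.0;
  const double EPS = 1e-300;
  if (a <= EPS && e <= EPS) {
    s = t = 0.0;
  } else if (a <= EPS) {
    t = std::min(1.0, std::max(0.0, f / e));
  } else {
    const double c = dx1 * rx + dy1 * ry;
    if (e <= EPS) {
      s = std::min(1.0, std::max(0.0, -c / a));
    } else {
      const double b = dx1 * dx2 + dy1 * dy2;
      const double denom = a * e - b * b;
      if (denom > EPS) {
        s = std::min(1.0, std::max(0.0, (b * f - c * e) / denom));
      } else {
        s = 0.0;  // parallel: pick one end, fix up below
      }
      t = (b * s + f) / e;
      if (t < 0.0) {
        t = 0.0;
        s = std::min(1.0, std::max(0.0, -c / a));
      } else if (t > 1.0) {
        t = 1.0;
        s = std::min(1.0, std::max(0.0, (b - c) / a));
      }
    }
  }
  const double cx = (p0x + s * dx1) - (q0x + t * dx2);
  const double cy = (p0y + s * dy1) - (q0y + t * dy2);
  if (s_out) *s_out = s;
  if (t_out) *t_out = t;
  return cx * cx + cy * cy;
}

// [[Rcpp::export(name = ".seg2_dist")]]
NumericVector seg2_dist(NumericVector p0, NumericVector p1,
                        NumericVector q0, NumericVector q1) {
  double s, t;
  double d2 = seg2_dist2(p0[0], p0[1], p1[0], p1[1],
                         q0[0], q0[1], q1[0], q1[1], &s, &t);
  return NumericVector::create(std::sqrt(d2), s, t);
}

// Lowest axis height z >= d/2 at which a horizontal candidate fibril,
// translated straight down, first touches the plate (z = d/2) or a
// previously deposited fibril (centre-line distance = sum of radii).
// fib: matrix with columns x0,y0,z0,x1,y1,z1,diameter (all horizontal).
// [[Rcpp::export(name = ".resting_height_cpp")]]
double resting_height_cpp(NumericVector c0, NumericVector c1, double dcand,
                          NumericMatrix fib, double rel_tol) {
  double z = dcand / 2.0;
  const int n = fib.nrow();
  for (int i = 0; i < n; ++i) {
    const double R = (dcand + fib(i, 6)) / 2.0;
    const double tol = rel_tol * R;
    double d2 = std::sqrt(seg2_dist2(c0[0], c0[1], c1[0], c1[1],
                                     fib(i, 0), fib(i, 1),
                                     fib(i, 3), fib(i, 4), nullptr, nullptr));
    if (d2 < R - tol) {
      const double dz = std::sqrt(std::max(R * R - d2 * d2, 0.0));
      const double zc = fib(i, 2) + dz;
      if (zc > z) z = zc;
    }
  }
  return z;
}

// All contacting fibril pairs: centre-line distance <= r_i + r_j + tol.
// Fibrils are horizontal so the 3D gap is sqrt(dxy^2 + dz^2) with the
// in-plane closest approach dxy independent of z.
// Returns matrix columns: i, j (1-based), s, t (arc params), dist.
// [[Rcpp::export(name = ".contacts_cpp")]]
NumericMatrix contacts_cpp(NumericMatrix fib, double tol_abs) {
  const int n = fib.nrow();
  std::vector<double> xlo(n), xhi(n), ylo(n), yhi(n);
  for (int i = 0; i < n; ++i) {
    xlo[i] = std::min(fib(i, 0), fib(i, 3)) - fib(i, 6);
    xhi[i] = std::max(fib(i, 0), fib(i, 3)) + fib(i, 6);
    ylo[i] = std::min(fib(i, 1), fib(i, 4)) - fib(i, 6);
    yhi[i] = std::max(fib(i, 1), fib(i, 4)) + fib(i, 6);
  }
  std::vector<double> out;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double R = (fib(i, 6) + fib(j, 6)) / 2.0 + tol_abs;
      if (xlo[j] > xhi[i] || xhi[j] < xlo[i]) continue;
      if (ylo[j] > yhi[i] || yhi[j] < ylo[i]) continue;
      const double dz = fib(i, 2) - fib(j, 2);
      if (std::fabs(dz) > R) continue;
      double s, t;
      const double dxy2 = seg2_dist2(fib(i, 0), fib(i, 1), fib(i, 3), fib(i, 4),
                                     fib(j, 0), fib(j, 1), fib(j, 3), fib(j, 4),
                                     &s, &t);
      const double d3 = std::sqrt(dxy2 + dz * dz);
      if (d3 <= R) {
        out.push_back(i + 1); out.push_back(j + 1);
        out.push_back(s); out.push_back(t); out.push_back(d3);
      }
    }
  }
  const int m = (int)(out.size() / 5);
  NumericMatrix res(m, 5);
  for (int k = 0; k < m; ++k)
    for (int c = 0; c < 5; ++c) res(k, c) = out[5 * k + c];
  colnames(res) = CharacterVector::create("i", "j", "s", "t", "dist");
  return res;
}

// Voxelize: voxel solid iff its centre lies within r of some fibril axis.
// Column pre-filter: a voxel column (x,y) can only contain solid voxels of
// fibril f if its in-plane distance to the projected axis is <= r.
// [[Rcpp::export(name = ".voxelize_cpp")]]
LogicalVector voxelize_cpp(NumericMatrix fib, int nx, int ny, int nz,
                           double h, double ox, double oy, double oz) {
  LogicalVector mask(static_cast<R_xlen_t>(nx) * ny * nz, false);
  const int n = fib.nrow();
  for (int f = 0; f < n; ++f) {
    const double r = fib(f, 6) / 2.0, r2 = r * r;
    const double x0 = fib(f, 0), y0 = fib(f, 1), z0 = fib(f, 2);
    const double x1 = fib(f, 3), y1 = fib(f, 4), z1 = fib(f, 5);
    const double dx = x1 - x0, dy = y1 - y0, dz = z1 - z0;
    const double L2 = dx * dx + dy * dy + dz * dz;
    int ilo = std::max(0, (int)std::floor((std::min(x0, x1) - r - ox) / h - 0.5));
    int ihi = std::min(nx - 1, (int)std::ceil((std::max(x0, x1) + r - ox) / h - 0.5));
    int jlo = std::max(0, (int)std::floor((std::min(y0, y1) - r - oy) / h - 0.5));
    int jhi = std::min(ny - 1, (int)std::ceil((std::max(y0, y1) + r - oy) / h - 0.5));
    int klo = std::max(0, (int)std::floor((std::min(z0, z1) - r - oz) / h - 0.5));
    int khi = std::min(nz - 1, (int)std::ceil((std::max(z0, z1) + r - oz) / h - 0.5));
    for (int j = jlo; j <= jhi; ++j) {
      const double yc = oy + (j + 0.5) * h;
      for (int i = ilo; i <= ihi; ++i) {
        const double xc = ox + (i + 0.5) * h;
        // in-plane distance from column to projected segment
        double s2d, dum;
        const double dxy2 = seg2_dist2(xc, yc, xc, yc, x0, y0, x1, y1, &dum, &s2d);
        if (dxy2 > r2) continue;
        for (int k = klo; k <= khi; ++k) {
          const double zc = oz + (k + 0.5) * h;
          // 3D point-to-segment distance
          double t = 0.0;
          if (L2 > 0) {
            t = ((xc - x0) * dx + (yc - y0) * dy + (zc - z0) * dz) / L2;
            t = std::min(1.0, std::max(0.0, t));
          }
          const double ex = xc - (x0 + t * dx);
          const double ey = yc - (y0 + t * dy);
          const double ez = zc - (z0 + t * dz);
          if (ex * ex + ey * ey + ez * ez <= r2) {
            mask[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
          }
        }
      }
    }
  }
  mask.attr("dim") = IntegerVector::create(nx, ny, nz);
  return mask;
}
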