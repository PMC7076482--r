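#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// Steady Stokes flow on a voxelized solid/fluid mask, MAC staggered grid.
//   momentum:  lap(u) = grad(q) - g,   q = p / mu   (q in 1/s)
//   continuity: div(u) = 0
//
// No-slip enters through the stencil: normal velocity components vanish
// on solid faces; tangential components see a reflected ghost across the
// wall (wall placed exactly on the cell face, second order).
//
// The saddle-point system is solved by conjugate gradients on the
// pressure Schur complement (Uzawa-CG): each CG iteration applies
// T p = div A^-1 (h grad p) by solving the three decoupled momentum
// Poisson problems with multigrid-preconditioned CG; the velocity is
// updated incrementally alongside the pressure, so div(u) is the Schur
// residual. T is symmetric positive definite and spectrally equivalent
// to the pressure mass matrix, giving a grid-size-independent iteration
// count. A final multigrid projection cleans the residual divergence to
// round-off so plane-by-plane flux constancy holds exactly.
//
// All operators live on "lattices" (cell-centred index spaces with
// optional z-periodicity); a generalized geometric multigrid with
// per-axis semi-coarsening and pure Galerkin (piecewise-constant
// prolongation) coarse operators serves both the momentum solves and the
// projection. Boundary modes: z either prescribed-pressure faces (open
// reservoirs above/below) or periodic with a body force; lateral faces
// periodic or impermeable free-slip walls.

typedef R_xlen_t XL;

static inline int wrapi(int i, int n) { return i < 0 ? i + n : (i >= n ? i - n : i); }

// ---------------------------------------------------------------------
// generic lattice level: A x = (sum cpl + dex) x - sum cpl x_nb
// bz has nz+1 planes when not z-periodic (boundary planes may carry
// diagonal-only Dirichlet weight), nz wrapped planes otherwise.
// ---------------------------------------------------------------------
struct Level {
  int nx, ny, nz;
  bool zper;
  int cx, cy, cz;  // coarsening factors towards the next level
  std::vector<float> bx, by, bz, dex;
  std::vector<float> diag;
  std::vector<double> phi, rhs, res;
  XL id(int i, int j, int k) const { return i + (XL)nx * (j + (XL)ny * k); }
  XL nc() const { return (XL)nx * ny * nz; }
  float bzf(int i, int j, int kf) const {
    if (zper) return bz[id(i, j, wrapi(kf, nz))];
    return bz[i + (XL)nx * (j + (XL)ny * kf)];
  }
};

static void level_finalize(Level &L) {
  const XL N = L.nc();
  L.diag.assign(N, 0.0f);
  for (int k = 0; k < L.nz; ++k)
    for (int j = 0; j < L.ny; ++j)
      for (int i = 0; i < L.nx; ++i) {
        const XL c = L.id(i, j, k);
        float d = L.bx[c] + L.bx[L.id(wrapi(i + 1, L.nx), j, k)] +
                  L.by[c] + L.by[L.id(i, wrapi(j + 1, L.ny), k)] +
                  L.bzf(i, j, k) + L.bzf(i, j, k + 1);
        if (!L.dex.empty()) d += L.dex[c];
        L.diag[c] = d;
      }
  L.phi.assign(N, 0.0);
  L.rhs.assign(N, 0.0);
  L.res.assign(N, 0.0);
}

static void level_apply(const Level &L, const std::vector<double> &x,
                        std::vector<double> &y) {
  const int nx = L.nx, ny = L.ny, nz = L.nz;
  const XL sxy = (XL)nx * ny;
  for (int k = 0; k < nz; ++k) {
    const bool hzm = L.zper || k > 0;
    const bool hzp = L.zper || k < nz - 1;
    const XL zmo = (L.zper && k == 0) ? sxy * (XL)(nz - 1) : -sxy;
    const XL zpo = (L.zper && k == nz - 1) ? -sxy * (XL)(nz - 1) : sxy;
    for (int j = 0; j < ny; ++j) {
      const XL row = (XL)nx * (j + (XL)ny * k);
      const XL ymo = (j == 0 ? (XL)nx * (ny - 1) : -(XL)nx);
      const XL ypo = (j == ny - 1 ? -(XL)nx * (ny - 1) : (XL)nx);
      for (int i = 0; i < nx; ++i) {
        const XL c = row + i;
        const double d = L.diag[c];
        if (d == 0.0) { y[c] = x[c]; continue; }
        double s = d * x[c];
        const XL xm = row + (i == 0 ? nx - 1 : i - 1);
        const XL xp = row + (i == nx - 1 ? 0 : i + 1);
        if (L.bx[c] != 0.0f) s -= (double)L.bx[c] * x[xm];
        if (L.bx[xp] != 0.0f) s -= (double)L.bx[xp] * x[xp];
        if (L.by[c] != 0.0f) s -= (double)L.by[c] * x[c + ymo];
        if (L.by[c + ypo] != 0.0f) s -= (double)L.by[c + ypo] * x[c + ypo];
        // bz planes share the cell indexing: plane k is at c, plane k+1
        // at c + sxy (wrapped to the bottom plane when z-periodic)
        const float bzl = L.bz[c];
        const float bzr = L.zper ? L.bz[(k == nz - 1) ? (XL)i + (XL)nx * j
                                                      : c + sxy]
                                 : L.bz[c + sxy];
        if (bzl != 0.0f && hzm) s -= (double)bzl * x[c + zmo];
        if (bzr != 0.0f && hzp) s -= (double)bzr * x[c + zpo];
        y[c] = s;
      }
    }
  }
}

static void level_smooth(Level &L, const std::vector<double> &b,
                         std::vector<double> &x, int color) {
  const int nx = L.nx, ny = L.ny, nz = L.nz;
  const XL sxy = (XL)nx * ny;
  for (int k = 0; k < nz; ++k) {
    const bool hzm = L.zper || k > 0;
    const bool hzp = L.zper || k < nz - 1;
    const XL zmo = (L.zper && k == 0) ? sxy * (XL)(nz - 1) : -sxy;
    const XL zpo = (L.zper && k == nz - 1) ? -sxy * (XL)(nz - 1) : sxy;
    for (int j = 0; j < ny; ++j) {
      const XL row = (XL)nx * (j + (XL)ny * k);
      const XL ymo = (j == 0 ? (XL)nx * (ny - 1) : -(XL)nx);
      const XL ypo = (j == ny - 1 ? -(XL)nx * (ny - 1) : (XL)nx);
      for (int i = ((j + k) & 1) == color ? 0 : 1; i < nx; i += 2) {
        const XL c = row + i;
        const double d = L.diag[c];
        if (d == 0.0) { x[c] = 0.0; continue; }
        double s = b[c];
        const XL xm = row + (i == 0 ? nx - 1 : i - 1);
        const XL xp = row + (i == nx - 1 ? 0 : i + 1);
        if (L.bx[c] != 0.0f) s += (double)L.bx[c] * x[xm];
        if (L.bx[xp] != 0.0f) s += (double)L.bx[xp] * x[xp];
        if (L.by[c] != 0.0f) s += (double)L.by[c] * x[c + ymo];
        if (L.by[c + ypo] != 0.0f) s += (double)L.by[c + ypo] * x[c + ypo];
        const float bzl = L.bz[c];
        const float bzr = L.zper ? L.bz[(k == nz - 1) ? (XL)i + (XL)nx * j
                                                      : c + sxy]
                                 : L.bz[c + sxy];
        if (bzl != 0.0f && hzm) s += (double)bzl * x[c + zmo];
        if (bzr != 0.0f && hzp) s += (double)bzr * x[c + zpo];
        x[c] = s / d;
      }
    }
  }
}

// pure Galerkin coarsening under piecewise-constant prolongation with
// per-axis factors (2 where the dimension is even and large enough)
static std::vector<Level> build_hierarchy(Level base) {
  std::vector<Level> H;
  level_finalize(base);
  H.push_back(std::move(base));
  while ((int)H.size() < 12) {
    Level &f = H.back();
    // aggregate pairs of planes along each sufficiently long axis; odd
    // sizes are allowed (the last coarse cell absorbs three fine
    // planes), which pure Galerkin under injection handles exactly
    int cx = (f.nx >= 8) ? 2 : 1;
    int cy = (f.ny >= 8) ? 2 : 1;
    int cz = (f.nz >= 4) ? 2 : 1;
    if ((XL)f.nx * f.ny * f.nz <= 4096) break;
    if (cx == 1 && cy == 1 && cz == 1) break;
    f.cx = cx; f.cy = cy; f.cz = cz;
    Level c;
    c.nx = f.nx / cx; c.ny = f.ny / cy; c.nz = f.nz / cz;
    c.zper = f.zper;
    c.cx = c.cy = c.cz = 1;
    const XL N = c.nc();
    c.bx.assign(N, 0.0f);
    c.by.assign(N, 0.0f);
    c.bz.assign(c.zper ? N : (XL)c.nx * c.ny * (c.nz + 1), 0.0f);
    c.dex.assign(N, 0.0f);
    auto mi = [](int i, int cf, int nc_) { return std::min(i / cf, nc_ - 1); };
    // fine couplings whose endpoints land in different coarse cells
    // accumulate into the corresponding coarse coupling; couplings
    // interior to a coarse cell cancel; dex sums over all children
    for (int k = 0; k < f.nz; ++k)
      for (int j = 0; j < f.ny; ++j)
        for (int i = 0; i < f.nx; ++i) {
          const XL cf_ = f.id(i, j, k);
          const int I = mi(i, cx, c.nx), J = mi(j, cy, c.ny),
                    K = mi(k, cz, c.nz);
          // x-face between fine cells i-1 (wrapped) and i
          if (f.bx[cf_] != 0.0f) {
            const int Im = mi(wrapi(i - 1, f.nx), cx, c.nx);
            if (Im != I && (i > 0 ? Im == wrapi(I - 1, c.nx) : true))
              c.bx[c.id(I, J, K)] += f.bx[cf_];
          }
          if (f.by[cf_] != 0.0f) {
            const int Jm = mi(wrapi(j - 1, f.ny), cy, c.ny);
            if (Jm != J && (j > 0 ? Jm == wrapi(J - 1, c.ny) : true))
              c.by[c.id(I, J, K)] += f.by[cf_];
          }
          if (!f.dex.empty() && f.dex[cf_] != 0.0f)
            c.dex[c.id(I, J, K)] += f.dex[cf_];
        }
    // z couplings / boundary planes
    if (c.zper) {
      for (int k = 0; k < f.nz; ++k)
        for (int j = 0; j < f.ny; ++j)
          for (int i = 0; i < f.nx; ++i) {
            const XL cf_ = f.id(i, j, k);
            if (f.bz[cf_] == 0.0f) continue;
            const int I = mi(i, cx, c.nx), J = mi(j, cy, c.ny),
                      K = mi(k, cz, c.nz);
            const int Km = mi(wrapi(k - 1, f.nz), cz, c.nz);
            if (Km != K && (k > 0 ? Km == wrapi(K - 1, c.nz) : true))
              c.bz[c.id(I, J, K)] += f.bz[cf_];
          }
    } else {
      for (int kf = 0; kf <= f.nz; ++kf)
        for (int j = 0; j < f.ny; ++j)
          for (int i = 0; i < f.nx; ++i) {
            const float bzv = f.bz[i + (XL)f.nx * (j + (XL)f.ny * kf)];
            if (bzv == 0.0f) continue;
            const int I = mi(i, cx, c.nx), J = mi(j, cy, c.ny);
            int KF;  // coarse face plane this fine face maps to, or -1
            if (kf == 0) KF = 0;
            else if (kf == f.nz) KF = c.nz;
            else {
              const int Kb = mi(kf, cz, c.nz);      // cell above the face
              const int Ka = mi(kf - 1, cz, c.nz);  // cell below
              KF = (Ka != Kb) ? Kb : -1;            // interior faces cancel
            }
            if (KF >= 0)
              c.bz[I + (XL)c.nx * (J + (XL)c.ny * KF)] += bzv;
          }
    }
    level_finalize(c);
    H.push_back(std::move(c));
  }
  return H;
}

static void vcycle(std::vector<Level> &H, size_t lev) {
  Level &L = H[lev];
  if (lev == H.size() - 1) {
    for (int s = 0; s < 40; ++s) {
      level_smooth(L, L.rhs, L.phi, 0);
      level_smooth(L, L.rhs, L.phi, 1);
    }
    return;
  }
  for (int s = 0; s < 2; ++s) {
    level_smooth(L, L.rhs, L.phi, 0);
    level_smooth(L, L.rhs, L.phi, 1);
  }
  level_apply(L, L.phi, L.res);
  for (XL t = 0; t < (XL)L.res.size(); ++t) L.res[t] = L.rhs[t] - L.res[t];
  Level &C = H[lev + 1];
  std::fill(C.rhs.begin(), C.rhs.end(), 0.0);
  std::fill(C.phi.begin(), C.phi.end(), 0.0);
  auto mi = [](int i, int cf, int nc_) { return std::min(i / cf, nc_ - 1); };
  for (int k = 0; k < L.nz; ++k)
    for (int j = 0; j < L.ny; ++j)
      for (int i = 0; i < L.nx; ++i)
        C.rhs[C.id(mi(i, L.cx, C.nx), mi(j, L.cy, C.ny),
                   mi(k, L.cz, C.nz))] += L.res[L.id(i, j, k)];
  vcycle(H, lev + 1);
  for (int k = 0; k < L.nz; ++k)
    for (int j = 0; j < L.ny; ++j)
      for (int i = 0; i < L.nx; ++i)
        if (L.diag[L.id(i, j, k)] != 0.0f)
          L.phi[L.id(i, j, k)] += C.phi[C.id(mi(i, L.cx, C.nx),
                                             mi(j, L.cy, C.ny),
                                             mi(k, L.cz, C.nz))];
  for (int s = 0; s < 2; ++s) {
    level_smooth(L, L.rhs, L.phi, 1);
    level_smooth(L, L.rhs, L.phi, 0);
  }
}

// MG-preconditioned CG on the base level of a hierarchy; x is the
// initial guess on entry, solution on exit. Returns relative residual.
static double mgpcg(std::vector<Level> &H, std::vector<double> &x,
                    const std::vector<double> &b, double tol, int maxit,
                    bool remove_mean, long *iters_out = nullptr) {
  Level &L = H[0];
  const XL N = L.nc();
  std::vector<double> r(N), z(N), p(N), Ap(N);
  double nlive = 0.0;
  for (XL t = 0; t < N; ++t) if (L.diag[t] != 0.0f) nlive += 1.0;
  auto demean = [&](std::vector<double> &v) {
    double m = 0.0;
    for (XL t = 0; t < N; ++t) if (L.diag[t] != 0.0f) m += v[t];
    m /= std::max(nlive, 1.0);
    for (XL t = 0; t < N; ++t) v[t] = (L.diag[t] != 0.0f) ? v[t] - m : v[t];
  };
  level_apply(L, x, Ap);
  double b2 = 0.0;
  for (XL t = 0; t < N; ++t) {
    r[t] = b[t] - Ap[t];
    b2 += b[t] * b[t];
  }
  if (remove_mean) demean(r);
  b2 = std::sqrt(b2);
  if (b2 == 0.0) b2 = 1e-300;
  double rz = 0.0, rel = 1.0;
  for (int it = 0; it < maxit; ++it) {
    if (iters_out) ++(*iters_out);
    double rn = 0.0;
    for (XL t = 0; t < N; ++t) rn += r[t] * r[t];
    rel = std::sqrt(rn) / b2;
    if (rel < tol) break;
    L.rhs = r;
    std::fill(L.phi.begin(), L.phi.end(), 0.0);
    vcycle(H, 0);
    z = L.phi;
    if (remove_mean) demean(z);
    double rz_new = 0.0;
    for (XL t = 0; t < N; ++t) rz_new += r[t] * z[t];
    if (rz_new <= 0.0) break;
    if (it == 0) p = z;
    else {
      const double beta = rz_new / rz;
      for (XL t = 0; t < N; ++t) p[t] = z[t] + beta * p[t];
    }
    rz = rz_new;
    level_apply(L, p, Ap);
    double pAp = 0.0;
    for (XL t = 0; t < N; ++t) pAp += p[t] * Ap[t];
    if (pAp <= 0.0) break;
    const double alpha = rz / pAp;
    for (XL t = 0; t < N; ++t) {
      x[t] += alpha * p[t];
      r[t] -= alpha * Ap[t];
    }
  }
  if (remove_mean) demean(x);
  return rel;
}

// ---------------------------------------------------------------------
// Stokes state
// ---------------------------------------------------------------------
struct Stokes {
  int nx, ny, nz, lat;
  bool zper;
  double h, qbot, qtop, gz;
  XL Nc, sxy, Nw;
  int nzw;  // z-extent of the w lattice
  std::vector<uint8_t> F, ou, ov, ow;
  std::vector<float> Du, Dv, Dw;
  std::vector<double> u, v, w, q;
  std::vector<Level> HU, HV, HW, HP;

  XL cid(int i, int j, int k) const { return i + (XL)nx * (j + (XL)ny * k); }
  XL widx(int i, int j, int k) const {  // w face, k = 0..nzw-1
    return i + (XL)nx * (j + (XL)ny * k);
  }
  bool fluid(int i, int j, int k) const {
    if (lat == 0) { i = wrapi(i, nx); j = wrapi(j, ny); }
    else if (i < 0 || i >= nx || j < 0 || j >= ny) return false;
    if (zper) k = wrapi(k, nz);
    else if (k < 0 || k >= nz) return true;
    return F[cid(i, j, k)] != 0;
  }
  bool uopen_(int i, int j, int k) const {
    if (lat == 1 && (i <= 0 || i >= nx || j < 0 || j >= ny)) return false;
    if (!zper && (k < 0 || k >= nz)) return false;
    if (zper) k = wrapi(k, nz);
    return fluid(i - 1, j, k) && fluid(i, j, k);
  }
  bool vopen_(int i, int j, int k) const {
    if (lat == 1 && (j <= 0 || j >= ny || i < 0 || i >= nx)) return false;
    if (!zper && (k < 0 || k >= nz)) return false;
    if (zper) k = wrapi(k, nz);
    return fluid(i, j - 1, k) && fluid(i, j, k);
  }
  bool wopen_(int i, int j, int kf) const {  // kf in face numbering
    if (lat == 1 && (i < 0 || i >= nx || j < 0 || j >= ny)) return false;
    if (!zper && (kf < 0 || kf > nz)) return false;
    return fluid(i, j, kf - 1) && fluid(i, j, kf);
  }

  void setup() {
    ou.assign(Nc, 0); ov.assign(Nc, 0); ow.assign(Nw, 0);
    Du.assign(Nc, 0); Dv.assign(Nc, 0); Dw.assign(Nw, 0);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const XL c = cid(i, j, k);
          if (uopen_(i, j, k)) {
            ou[c] = 1;
            float D = 6.0f;
            for (int dj = -1; dj <= 1; dj += 2) {
              if (uopen_(i, j + dj, k)) continue;
              if (lat == 1 && (j + dj < 0 || j + dj >= ny)) D -= 1.0f;
              else D += 1.0f;
            }
            for (int dk = -1; dk <= 1; dk += 2) {
              if (!zper && (k + dk < 0 || k + dk >= nz)) { D -= 1.0f; continue; }
              if (!uopen_(i, j, k + dk)) D += 1.0f;
            }
            Du[c] = D;
          }
          if (vopen_(i, j, k)) {
            ov[c] = 1;
            float D = 6.0f;
            for (int di = -1; di <= 1; di += 2) {
              if (vopen_(i + di, j, k)) continue;
              if (lat == 1 && (i + di < 0 || i + di >= nx)) D -= 1.0f;
              else D += 1.0f;
            }
            for (int dk = -1; dk <= 1; dk += 2) {
              if (!zper && (k + dk < 0 || k + dk >= nz)) { D -= 1.0f; continue; }
              if (!vopen_(i, j, k + dk)) D += 1.0f;
            }
            Dv[c] = D;
          }
        }
    for (int kf = 0; kf < nzw; ++kf)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          if (!wopen_(i, j, kf)) continue;
          const XL c = widx(i, j, kf);
          ow[c] = 1;
          float D = 6.0f;
          if (!zper && kf - 1 < 0) D -= 1.0f;
          if (!zper && kf + 1 > nz) D -= 1.0f;
          for (int di = -1; di <= 1; di += 2) {
            if (wopen_(i + di, j, kf)) continue;
            if (lat == 1 && (i + di < 0 || i + di >= nx)) D -= 1.0f;
            else D += 1.0f;
          }
          for (int dj = -1; dj <= 1; dj += 2) {
            if (wopen_(i, j + dj, kf)) continue;
            if (lat == 1 && (j + dj < 0 || j + dj >= ny)) D -= 1.0f;
            else D += 1.0f;
          }
          Dw[c] = D;
        }

    // momentum hierarchies: lattice couplings = 1 between open
    // neighbouring faces (no wrap across lateral walls), extra diagonal
    // dex = D - sum(couplings)
    auto mk = [&](const std::vector<uint8_t> &open,
                  const std::vector<float> &D, int nzl,
                  bool wrap_z) -> std::vector<Level> {
      Level B;
      B.nx = nx; B.ny = ny; B.nz = nzl; B.zper = wrap_z;
      const XL N = (XL)nx * ny * nzl;
      B.bx.assign(N, 0.0f);
      B.by.assign(N, 0.0f);
      B.bz.assign(wrap_z ? N : (XL)nx * ny * (nzl + 1), 0.0f);
      B.dex.assign(N, 0.0f);
      for (int k = 0; k < nzl; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            const XL c = B.id(i, j, k);
            if (!open[c]) continue;
            const XL xm = B.id(wrapi(i - 1, nx), j, k);
            const XL ym = B.id(i, wrapi(j - 1, ny), k);
            if ((lat == 0 || i > 0) && open[xm]) B.bx[c] = 1.0f;
            if ((lat == 0 || j > 0) && open[ym]) B.by[c] = 1.0f;
            if (wrap_z) {
              const XL zm = B.id(i, j, wrapi(k - 1, nzl));
              if (open[zm]) B.bz[c] = 1.0f;
            } else if (k > 0) {
              const XL zm = B.id(i, j, k - 1);
              if (open[zm])
                B.bz[i + (XL)nx * (j + (XL)ny * k)] = 1.0f;
            }
          }
      // dex from the stencil diagonal
      Level tmp = B;  // need coupling sums
      level_finalize(tmp);
      for (XL t = 0; t < N; ++t) {
        if (!open[t]) continue;
        const float cpl = tmp.diag[t];  // dex was zero here
        B.dex[t] = std::max(D[t] - cpl, 0.0f);
      }
      return build_hierarchy(std::move(B));
    };
    HU = mk(ou, Du, nz, zper);
    HV = mk(ov, Dv, nz, zper);
    HW = mk(ow, Dw, nzw, zper);

    // projection hierarchy on the pressure lattice; z-boundary faces in
    // pressure mode act as Dirichlet (diagonal weight, no coupling)
    Level P;
    P.nx = nx; P.ny = ny; P.nz = nz; P.zper = zper;
    P.bx.assign(Nc, 0.0f);
    P.by.assign(Nc, 0.0f);
    P.bz.assign(zper ? Nc : (XL)nx * ny * (nz + 1), 0.0f);
    for (XL t = 0; t < Nc; ++t) {
      P.bx[t] = ou[t] ? 1.0f : 0.0f;
      P.by[t] = ov[t] ? 1.0f : 0.0f;
    }
    for (XL t = 0; t < (XL)P.bz.size(); ++t) P.bz[t] = ow[t] ? 1.0f : 0.0f;
    HP = build_hierarchy(std::move(P));
  }

  double qat(int i, int j, int k, const std::vector<double> &qf,
             double qb, double qt) const {
    if (lat == 0) { i = wrapi(i, nx); j = wrapi(j, ny); }
    if (zper) k = wrapi(k, nz);
    else if (k < 0) return qb;
    else if (k >= nz) return qt;
    return qf[cid(i, j, k)];
  }

  // momentum right-hand sides for pressure field qf (sign: A u = b);
  // homogeneous ghosts when qb = qt = 0
  void rhs_all(const std::vector<double> &qf, double qb, double qt,
               double g, double sgn,
               std::vector<double> &bu, std::vector<double> &bv,
               std::vector<double> &bw) const {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const XL c = cid(i, j, k);
          bu[c] = ou[c] ?
            sgn * -h * (qat(i, j, k, qf, qb, qt) -
                        qat(i - 1, j, k, qf, qb, qt)) : 0.0;
          bv[c] = ov[c] ?
            sgn * -h * (qat(i, j, k, qf, qb, qt) -
                        qat(i, j - 1, k, qf, qb, qt)) : 0.0;
        }
    for (int kf = 0; kf < nzw; ++kf)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const XL c = widx(i, j, kf);
          bw[c] = ow[c] ?
            (sgn * -h * (qat(i, j, kf, qf, qb, qt) -
                         qat(i, j, kf - 1, qf, qb, qt)) + h * h * g) : 0.0;
        }
  }

  double div_at(int i, int j, int k, const std::vector<double> &uu,
                const std::vector<double> &vv,
                const std::vector<double> &ww) const {
    const XL c = cid(i, j, k);
    const XL xr = cid(i == nx - 1 ? 0 : i + 1, j, k);
    const XL yr = cid(i, j == ny - 1 ? 0 : j + 1, k);
    const XL wl = widx(i, j, zper ? k : k);
    const XL wr = zper ? widx(i, j, (k + 1) % nz) : widx(i, j, k + 1);
    double s = -uu[c] - vv[c] - ww[wl] + ww[wr];
    s += uu[xr] + vv[yr];
    return s / h;
  }
};

// [[Rcpp::export(name = ".stokes_cpp")]]
List stokes_cpp(LogicalVector solid, int nx, int ny, int nz, double h,
                double qbot, double qtop, double gz,
                int zmode, int lat,
                double mom_tol, int mom_maxit,
                double tol, int max_outer, int refresh_every,
                bool verbose,
                Nullable<NumericVector> u0 = R_NilValue,
                Nullable<NumericVector> v0 = R_NilValue,
                Nullable<NumericVector> w0 = R_NilValue,
                Nullable<NumericVector> q0 = R_NilValue) {
  Stokes S;
  S.nx = nx; S.ny = ny; S.nz = nz; S.lat = lat; S.zper = (zmode == 1);
  S.h = h; S.qbot = qbot; S.qtop = qtop; S.gz = gz;
  S.Nc = (XL)nx * ny * nz;
  S.sxy = (XL)nx * ny;
  S.nzw = S.zper ? nz : nz + 1;
  S.Nw = (XL)nx * ny * S.nzw;
  S.F.assign(S.Nc, 0);
  for (XL t = 0; t < S.Nc; ++t) S.F[t] = solid[t] ? 0 : 1;
  S.setup();
  S.u.assign(S.Nc, 0.0);
  S.v.assign(S.Nc, 0.0);
  S.w.assign(S.Nw, 0.0);
  S.q.assign(S.Nc, 0.0);
  if (u0.isNotNull()) { NumericVector a(u0); for (XL t = 0; t < S.Nc; ++t) S.u[t] = a[t]; }
  if (v0.isNotNull()) { NumericVector a(v0); for (XL t = 0; t < S.Nc; ++t) S.v[t] = a[t]; }
  if (w0.isNotNull()) { NumericVector a(w0); for (XL t = 0; t < S.Nw; ++t) S.w[t] = a[t]; }
  if (q0.isNotNull()) { NumericVector a(q0); for (XL t = 0; t < S.Nc; ++t) S.q[t] = a[t]; }
  else if (!S.zper) {
    for (int k = 0; k < nz; ++k) {
      const double qk = qbot + (qtop - qbot) * (k + 0.5) / nz;
      for (XL t = 0; t < S.sxy; ++t) S.q[t + S.sxy * k] = qk;
    }
  }
  for (XL t = 0; t < S.Nc; ++t) { if (!S.ou[t]) S.u[t] = 0; if (!S.ov[t]) S.v[t] = 0; }
  for (XL t = 0; t < S.Nw; ++t) if (!S.ow[t]) S.w[t] = 0;

  std::vector<double> bu(S.Nc), bv(S.Nc), bw(S.Nw);
  std::vector<double> r(S.Nc, 0.0), z(S.Nc), pdir(S.Nc, 0.0), Tp(S.Nc);
  std::vector<double> du(S.Nc, 0.0), dv(S.Nc, 0.0), dw(S.Nw, 0.0);

  // diagonal Schur preconditioner: local mobility of a cell = sum of
  // 1/D over its open faces (equalizes reservoir cells and tight
  // throats, keeping the CG directions well-scaled)
  std::vector<double> tdiag(S.Nc, 0.0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const XL c = S.cid(i, j, k);
        double s = 0.0;
        if (S.ou[c]) s += 1.0 / S.Du[c];
        const XL xr = S.cid(i == nx - 1 ? 0 : i + 1, j, k);
        if (S.ou[xr]) s += 1.0 / S.Du[xr];
        if (S.ov[c]) s += 1.0 / S.Dv[c];
        const XL yr = S.cid(i, j == ny - 1 ? 0 : j + 1, k);
        if (S.ov[yr]) s += 1.0 / S.Dv[yr];
        const XL wl = S.widx(i, j, k);
        if (S.ow[wl]) s += 1.0 / S.Dw[wl];
        const XL wr = S.zper ? S.widx(i, j, (k + 1) % nz) : S.widx(i, j, k + 1);
        if (S.ow[wr]) s += 1.0 / S.Dw[wr];
        tdiag[c] = s;
      }

  const bool nullsp = S.zper;  // constants are in the Schur nullspace
  double nfluid = 0.0;
  for (XL t = 0; t < S.Nc; ++t) if (S.HP[0].diag[t] != 0.0f) nfluid += 1.0;
  auto demean_cells = [&](std::vector<double> &x) {
    double m = 0.0;
    for (XL t = 0; t < S.Nc; ++t) if (S.HP[0].diag[t] != 0.0f) m += x[t];
    m /= std::max(nfluid, 1.0);
    for (XL t = 0; t < S.Nc; ++t)
      if (S.HP[0].diag[t] != 0.0f) x[t] -= m;
  };

  auto solve_state = [&](double mtol, int mit) {
    S.rhs_all(S.q, qbot, qtop, gz, 1.0, bu, bv, bw);
    mgpcg(S.HU, S.u, bu, mtol, mit, false);
    mgpcg(S.HV, S.v, bv, mtol, mit, false);
    mgpcg(S.HW, S.w, bw, mtol, mit, false);
  };
  // Schur residual of the SPD system: r = -div u(q)
  auto compute_div = [&](std::vector<double> &out) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const XL c = S.cid(i, j, k);
          out[c] = (S.HP[0].diag[c] != 0.0f) ?
            -S.div_at(i, j, k, S.u, S.v, S.w) : 0.0;
        }
    if (nullsp) demean_cells(out);
  };
  auto umax = [&]() {
    double m = 1e-300;
    for (XL t = 0; t < S.Nc; ++t) {
      m = std::max(m, std::fabs(S.u[t]));
      m = std::max(m, std::fabs(S.v[t]));
    }
    for (XL t = 0; t < S.Nw; ++t) m = std::max(m, std::fabs(S.w[t]));
    return m;
  };

  solve_state(mom_tol, mom_maxit);
  compute_div(r);
  double rr = 0.0;
  for (XL t = 0; t < S.Nc; ++t) rr += r[t] * r[t];
  const double rr0 = std::max(rr, 1e-300);
  int outer = 0;
  double div_rel = 1.0;
  bool first = true;
  double rz = 0.0;

  for (outer = 1; outer <= max_outer; ++outer) {
    div_rel = std::sqrt(rr / rr0);
    if (verbose && (outer % 10 == 1))
      Rcpp::Rcout << "outer " << outer << " |r|/|r0| " << div_rel << "\n";
    if (div_rel < tol) {
      // confirm against the true residual (the incremental one drifts
      // with inexact inner solves)
      solve_state(mom_tol, mom_maxit);
      compute_div(r);
      rr = 0.0;
      for (XL t = 0; t < S.Nc; ++t) rr += r[t] * r[t];
      div_rel = std::sqrt(rr / rr0);
      first = true;
      if (div_rel < tol) break;
    }
    Rcpp::checkUserInterrupt();
    for (XL t = 0; t < S.Nc; ++t)
      z[t] = (tdiag[t] > 0.0) ? r[t] / tdiag[t] : 0.0;
    if (nullsp) demean_cells(z);
    double rz_new = 0.0;
    for (XL t = 0; t < S.Nc; ++t) rz_new += r[t] * z[t];
    if (first) { pdir = z; first = false; }
    else {
      const double beta = rz_new / rz;
      for (XL t = 0; t < S.Nc; ++t) pdir[t] = z[t] + beta * pdir[t];
    }
    rz = rz_new;
    // T p = div A^-1 (h grad p): direction solves with homogeneous BCs
    S.rhs_all(pdir, 0.0, 0.0, 0.0, -1.0, bu, bv, bw);
    std::fill(du.begin(), du.end(), 0.0);
    std::fill(dv.begin(), dv.end(), 0.0);
    std::fill(dw.begin(), dw.end(), 0.0);
    long inner = 0;
    const double dt_tol = std::min(3.0 * mom_tol, 1e-2);
    mgpcg(S.HU, du, bu, dt_tol, mom_maxit, false, &inner);
    mgpcg(S.HV, dv, bv, dt_tol, mom_maxit, false, &inner);
    mgpcg(S.HW, dw, bw, dt_tol, mom_maxit, false, &inner);
    if (verbose && (outer % 10 == 1))
      Rcpp::Rcout << "  inner iters this outer: " << inner << "\n";
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const XL c = S.cid(i, j, k);
          Tp[c] = (S.HP[0].diag[c] != 0.0f) ?
            -S.div_at(i, j, k, du, dv, dw) : 0.0;
        }
    if (nullsp) demean_cells(Tp);
    double pTp = 0.0;
    for (XL t = 0; t < S.Nc; ++t) pTp += pdir[t] * Tp[t];
    if (pTp <= 0.0) { solve_state(mom_tol, mom_maxit); compute_div(r); first = true; continue; }
    const double alpha = rz / pTp;
    rr = 0.0;
    for (XL t = 0; t < S.Nc; ++t) {
      S.q[t] += alpha * pdir[t];
      r[t] -= alpha * Tp[t];
      rr += r[t] * r[t];
    }
    for (XL t = 0; t < S.Nc; ++t) {
      S.u[t] -= alpha * du[t];
      S.v[t] -= alpha * dv[t];
    }
    for (XL t = 0; t < S.Nw; ++t) S.w[t] -= alpha * dw[t];
    if (outer % refresh_every == 0) {
      // guard against drift from inexact inner solves
      solve_state(mom_tol, mom_maxit);
      compute_div(r);
      rr = 0.0;
      for (XL t = 0; t < S.Nc; ++t) rr += r[t] * r[t];
      first = true;
    }
  }

  // final polish: accurate momentum solve, then an exact projection so
  // discrete continuity holds to round-off
  solve_state(std::min(mom_tol, 1e-8), mom_maxit * 4);
  {
    std::vector<double> brhs(S.Nc, 0.0), phi(S.Nc, 0.0);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const XL c = S.cid(i, j, k);
          brhs[c] = (S.HP[0].diag[c] != 0.0f) ?
            -S.div_at(i, j, k, S.u, S.v, S.w) * h : 0.0;
        }
    mgpcg(S.HP, phi, brhs, 1e-12, 200, nullsp);
    auto phat = [&](int i, int j, int k) -> double {
      if (lat == 0) { i = wrapi(i, nx); j = wrapi(j, ny); }
      else if (i < 0 || i >= nx || j < 0 || j >= ny) return 0.0;
      if (S.zper) k = wrapi(k, nz);
      else if (k < 0 || k >= nz) return 0.0;
      return phi[S.cid(i, j, k)];
    };
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const XL c = S.cid(i, j, k);
          if (S.ou[c]) S.u[c] -= (phat(i, j, k) - phat(i - 1, j, k));
          if (S.ov[c]) S.v[c] -= (phat(i, j, k) - phat(i, j - 1, k));
        }
    for (int kf = 0; kf < S.nzw; ++kf)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const XL c = S.widx(i, j, kf);
          if (S.ow[c]) S.w[c] -= (phat(i, j, kf) - phat(i, j, kf - 1));
        }
  }

  // residual report
  double uref = umax(), mr = 0.0, dr = 0.0;
  {
    std::vector<double> t1(S.Nc), t2w(S.Nw);
    S.rhs_all(S.q, qbot, qtop, gz, 1.0, bu, bv, bw);
    level_apply(S.HU[0], S.u, t1);
    for (XL t = 0; t < S.Nc; ++t)
      if (S.ou[t]) mr = std::max(mr, std::fabs(bu[t] - t1[t]));
    level_apply(S.HV[0], S.v, t1);
    for (XL t = 0; t < S.Nc; ++t)
      if (S.ov[t]) mr = std::max(mr, std::fabs(bv[t] - t1[t]));
    level_apply(S.HW[0], S.w, t2w);
    for (XL t = 0; t < S.Nw; ++t)
      if (S.ow[t]) mr = std::max(mr, std::fabs(bw[t] - t2w[t]));
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i)
          if (S.HP[0].diag[S.cid(i, j, k)] != 0.0f)
            dr = std::max(dr,
                          std::fabs(S.div_at(i, j, k, S.u, S.v, S.w)) * h);
  }

  NumericVector U(S.Nc), V(S.Nc), Q(S.Nc), W(S.Nw);
  for (XL t = 0; t < S.Nc; ++t) { U[t] = S.u[t]; V[t] = S.v[t]; Q[t] = S.q[t]; }
  for (XL t = 0; t < S.Nw; ++t) W[t] = S.w[t];
  U.attr("dim") = IntegerVector::create(nx, ny, nz);
  V.attr("dim") = IntegerVector::create(nx, ny, nz);
  Q.attr("dim") = IntegerVector::create(nx, ny, nz);
  W.attr("dim") = IntegerVector::create(nx, ny, S.nzw);
  return List::create(_["u"] = U, _["v"] = V, _["w"] = W, _["q"] = Q,
                      _["outer"] = outer,
                      _["mom_res"] = mr / uref, _["div_res"] = dr / uref,
                      _["div_rel"] = div_rel);
}
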