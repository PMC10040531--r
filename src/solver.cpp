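// Masked staggered-grid (MAC) solver for laminar incompressible
// generalized-Newtonian flow, plus conservative donor-cell tracer
// transport. Cell-label codes shared with R/geometry.R:
//   0 = WALL, 1 = FLUID, 2 = OUTLET, >= 3 = inlet.
//
// Scheme per time step (first-order in time):
//   1. apparent viscosity per cell from the current strain field
//      (Picard lag),
//   2. explicit donor-cell advection + explicit cross-stress term,
//   3. implicit variable-viscosity diffusion (compact preconditioned CG,
//      SPD),
//   4. pressure Poisson projection (warm-started Jacobi-PCG) with
//      Dirichlet gauge p = 0 in outlet cells and Neumann elsewhere,
//   5. velocity correction on interior and outlet faces.
// Inlet faces carry a prescribed uniform velocity; walls are no-slip
// (normal faces fixed at zero, tangential ghosts mirrored); the outlet is
// zero-gradient with zero gauge pressure.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int WALL = 0, FLUID = 1, OUTLET = 2, INLET0 = 3;
static const int F_EXT = -1, F_FIX0 = 0, F_ACT = 1, F_IN = 2, F_OUT = 3;

// neighbor relation of an unknown face in the implicit diffusion stencil
static const int NB_NONE = -1;     // zero-gradient: no flux
static const int NB_MIRROR = -2;   // no-slip ghost: doubles the link
// >= 0: compact index of an unknown neighbor
// NB_FIXED encodes a Dirichlet neighbor; its face index is kept separately
static const int NB_FIXED = -3;

struct Grid {
  int nx, ny;
  double h;
  std::vector<int> lab, ut, vt;
  int cell(int i, int j) const {
    if (i < 0 || i >= nx || j < 0 || j >= ny) return WALL;
    return lab[i + nx * j];
  }
  int uidx(int i, int j) const { return i + (nx + 1) * j; }
  int vidx(int i, int j) const { return i + nx * j; }
  int cidx(int i, int j) const { return i + nx * j; }
  void classify() {
    ut.assign((nx + 1) * ny, F_EXT);
    vt.assign(nx * (ny + 1), F_EXT);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i <= nx; ++i) {
        int L = cell(i - 1, j), R = cell(i, j);
        int t = F_EXT;
        if (L == FLUID && R == FLUID) t = F_ACT;
        else if (L >= INLET0 && R == FLUID) t = F_IN;
        else if (L == FLUID && R == OUTLET) t = F_OUT;
        else if ((L == FLUID) != (R == FLUID)) t = F_FIX0;
        ut[uidx(i, j)] = t;
      }
    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int B = cell(i, j - 1), T = cell(i, j);
        int t = F_EXT;
        if (B == FLUID && T == FLUID) t = F_ACT;
        else if ((B == FLUID) != (T == FLUID)) t = F_FIX0;
        vt[vidx(i, j)] = t;
      }
  }
};

static Grid make_grid(const IntegerMatrix& lab, double h) {
  Grid g;
  g.nx = lab.nrow(); g.ny = lab.ncol(); g.h = h;
  g.lab.assign(lab.begin(), lab.end());
  g.classify();
  return g;
}

struct Rheo {
  int mode;
  double mu, mu_p, hct, k0, kinf, gc, gmin;
  double visc(double gdot) const {
    if (mode == 0) return mu;
    if (gdot < gmin) gdot = gmin;   // low-shear cutoff (gel-limit guard)
    double s = std::sqrt(gdot / gc);
    double k = (k0 + kinf * s) / (1.0 + s);
    double arg = 1.0 - 0.5 * k * hct;
    return mu_p / (arg * arg);
  }
};

// one unknown of a compact 5-point SPD system
struct Stencil {
  int face;                 // full-array face (or cell) index
  int nb[4];                // compact neighbor index or NB_* code
  int fixed_face[4];        // full-array index of a Dirichlet neighbor
  int mu1, mu2;             // cell indices for the two in-line viscosities
  int corner1, corner2;     // corner indices for the transverse links
};

// compact symmetric positive-definite system with per-step coefficients
struct Compact {
  std::vector<Stencil> st;
  std::vector<double> coef[4];  // link coefficients per unknown
  std::vector<double> diag;
  std::vector<double> x, b, r, p_, Ap, z;
  void alloc() {
    size_t n = st.size();
    for (int q = 0; q < 4; ++q) coef[q].assign(n, 0.0);
    diag.assign(n, 0.0);
    x.assign(n, 0.0); b.assign(n, 0.0); r.assign(n, 0.0);
    p_.assign(n, 0.0); Ap.assign(n, 0.0); z.assign(n, 0.0);
  }
  void apply(const std::vector<double>& v, std::vector<double>& out) const {
    size_t n = st.size();
    for (size_t k = 0; k < n; ++k) {
      double acc = diag[k] * v[k];
      for (int q = 0; q < 4; ++q) {
        int nb = st[k].nb[q];
        if (nb >= 0) acc -= coef[q][k] * v[nb];
      }
      out[k] = acc;
    }
  }
  // Jacobi-preconditioned CG; returns iterations used
  int solve(double tol_abs_inf, double tol_rel, int maxit) {
    size_t n = st.size();
    if (n == 0) return 0;
    apply(x, Ap);
    double rr = 0.0, rinf = 0.0, bn = 0.0;
    for (size_t k = 0; k < n; ++k) {
      r[k] = b[k] - Ap[k];
      z[k] = r[k] / diag[k];
      rr += r[k] * z[k];
      rinf = std::max(rinf, std::fabs(r[k]));
      bn += b[k] * b[k];
    }
    double tol2 = tol_rel * std::sqrt(bn);
    if (rinf <= tol_abs_inf || std::sqrt(rr < 0 ? 0 : rr) == 0.0) return 0;
    p_ = z;
    int it = 0;
    for (; it < maxit; ++it) {
      apply(p_, Ap);
      double pAp = 0.0;
      for (size_t k = 0; k < n; ++k) pAp += p_[k] * Ap[k];
      if (pAp <= 0.0) break;
      double alpha = rr / pAp;
      rinf = 0.0;
      double rz_new = 0.0;
      for (size_t k = 0; k < n; ++k) {
        x[k] += alpha * p_[k];
        r[k] -= alpha * Ap[k];
        z[k] = r[k] / diag[k];
        rz_new += r[k] * z[k];
        rinf = std::max(rinf, std::fabs(r[k]));
      }
      if (rinf <= tol_abs_inf) { ++it; break; }
      double rn2 = 0.0;
      for (size_t k = 0; k < n; ++k) rn2 += r[k] * r[k];
      if (std::sqrt(rn2) <= tol2) { ++it; break; }
      double beta = rz_new / rr;
      rr = rz_new;
      for (size_t k = 0; k < n; ++k) p_[k] = z[k] + beta * p_[k];
    }
    return it;
  }
};

// ghost-aware face values (mirror across no-slip walls, zero gradient
// beyond the outlet) -- used by the explicit terms only
static inline double ug(const Grid& g, const std::vector<double>& u,
                        int i, int j, double mirror_of) {
  if (i < 0 || i > g.nx || j < 0 || j >= g.ny) return -mirror_of;
  int t = g.ut[g.uidx(i, j)];
  if (t == F_EXT) {
    int L = g.cell(i - 1, j), R = g.cell(i, j);
    if (L == OUTLET || R == OUTLET) return mirror_of;
    return -mirror_of;
  }
  return u[g.uidx(i, j)];
}

static inline double vgh(const Grid& g, const std::vector<double>& v,
                         int i, int j, double mirror_of) {
  if (i < 0 || i >= g.nx || j < 0 || j > g.ny) return -mirror_of;
  int t = g.vt[g.vidx(i, j)];
  if (t == F_EXT) {
    int B = g.cell(i, j - 1), T = g.cell(i, j);
    if (B == OUTLET || T == OUTLET) return mirror_of;
    return -mirror_of;
  }
  return v[g.vidx(i, j)];
}

// corner-shear derivative fields and cell strain-rate magnitude
static void strain_fields(const Grid& g, const std::vector<double>& u,
                          const std::vector<double>& v,
                          std::vector<double>& gdot,
                          std::vector<double>& dudy_c,
                          std::vector<double>& dvdx_c) {
  int nx = g.nx, ny = g.ny; double h = g.h;
  dudy_c.assign((nx + 1) * (ny + 1), 0.0);
  dvdx_c.assign((nx + 1) * (ny + 1), 0.0);
  for (int j = 0; j <= ny; ++j)
    for (int i = 0; i <= nx; ++i) {
      double ua, ub;
      bool va = (j < ny) && g.ut[g.uidx(i, j)] != F_EXT;
      bool vb = (j > 0) && g.ut[g.uidx(i, j - 1)] != F_EXT;
      if (!va && !vb) { ua = ub = 0.0; }
      else {
        ua = va ? u[g.uidx(i, j)] : -u[g.uidx(i, j - 1)];
        ub = vb ? u[g.uidx(i, j - 1)] : -u[g.uidx(i, j)];
      }
      double wa, wb;
      bool pa = (i < nx) && g.vt[g.vidx(i, j)] != F_EXT;
      bool pb = (i > 0) && g.vt[g.vidx(i - 1, j)] != F_EXT;
      if (!pa && !pb) { wa = wb = 0.0; }
      else {
        wa = pa ? v[g.vidx(i, j)] : -v[g.vidx(i - 1, j)];
        wb = pb ? v[g.vidx(i - 1, j)] : -v[g.vidx(i, j)];
      }
      int c = i + (nx + 1) * j;
      dudy_c[c] = (ua - ub) / h;
      dvdx_c[c] = (wa - wb) / h;
    }
  gdot.assign(nx * ny, 0.0);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      if (g.lab[g.cidx(i, j)] != FLUID) continue;
      double e11 = (u[g.uidx(i + 1, j)] - u[g.uidx(i, j)]) / h;
      double e22 = (v[g.vidx(i, j + 1)] - v[g.vidx(i, j)]) / h;
      double e12 = 0.0;
      for (int dj = 0; dj <= 1; ++dj)
        for (int di = 0; di <= 1; ++di) {
          int c = (i + di) + (nx + 1) * (j + dj);
          e12 += 0.125 * (dudy_c[c] + dvdx_c[c]);
        }
      gdot[g.cidx(i, j)] = std::sqrt(2.0 * (e11 * e11 + e22 * e22 +
                                            2.0 * e12 * e12));
    }
}

static inline double mu_corner(const Grid& g, const std::vector<double>& mu,
                               int ci, int cj, double mu_def) {
  double s = 0.0; int n = 0;
  for (int dj = -1; dj <= 0; ++dj)
    for (int di = -1; di <= 0; ++di) {
      int i = ci + di, j = cj + dj;
      if (g.cell(i, j) == FLUID) { s += mu[g.cidx(i, j)]; ++n; }
    }
  return n ? s / n : mu_def;
}

// build the compact u-momentum system structure (step-independent)
static void build_usys(const Grid& g, Compact& S,
                       std::vector<int>& ucompact) {
  int nx = g.nx, ny = g.ny;
  ucompact.assign((nx + 1) * ny, -1);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i <= nx; ++i) {
      int f = g.uidx(i, j);
      if (g.ut[f] == F_ACT || g.ut[f] == F_OUT)
        ucompact[f] = (int)S.st.size(), S.st.push_back(Stencil());
    }
  size_t k = 0;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i <= nx; ++i) {
      int f = g.uidx(i, j);
      if (ucompact[f] < 0) continue;
      Stencil& s = S.st[ucompact[f]];
      s.face = f;
      s.mu1 = (g.cell(i - 1, j) == FLUID) ? g.cidx(i - 1, j) : -1; // west mu
      s.mu2 = (g.cell(i, j) == FLUID) ? g.cidx(i, j) : -1;         // east mu
      s.corner1 = i + (nx + 1) * j;           // bottom corner
      s.corner2 = i + (nx + 1) * (j + 1);     // top corner
      // neighbors: 0 = W, 1 = E, 2 = S, 3 = N
      auto cls = [&](int ii, int jj, bool xdir) {
        if (jj < 0 || jj >= ny || ii < 0 || ii > nx) return NB_MIRROR;
        int t = g.ut[g.uidx(ii, jj)];
        if (t == F_ACT || t == F_OUT) return ucompact[g.uidx(ii, jj)];
        if (t == F_FIX0 || t == F_IN) return NB_FIXED;
        // EXT: beyond the outlet -> zero gradient, else mirror
        int L = g.cell(ii - 1, jj), R = g.cell(ii, jj);
        if (L == OUTLET || R == OUTLET) return NB_NONE;
        (void)xdir;
        return NB_MIRROR;
      };
      s.nb[0] = cls(i - 1, j, true);
      s.nb[1] = cls(i + 1, j, true);
      s.nb[2] = cls(i, j - 1, false);
      s.nb[3] = cls(i, j + 1, false);
      s.fixed_face[0] = g.uidx(i - 1, j); s.fixed_face[1] = g.uidx(i + 1, j);
      s.fixed_face[2] = g.uidx(i, j - 1); s.fixed_face[3] = g.uidx(i, j + 1);
      ++k;
    }
  S.alloc();
}

static void build_vsys(const Grid& g, Compact& S,
                       std::vector<int>& vcompact) {
  int nx = g.nx, ny = g.ny;
  vcompact.assign(nx * (ny + 1), -1);
  for (int j = 0; j <= ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int f = g.vidx(i, j);
      if (g.vt[f] == F_ACT)
        vcompact[f] = (int)S.st.size(), S.st.push_back(Stencil());
    }
  for (int j = 0; j <= ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int f = g.vidx(i, j);
      if (vcompact[f] < 0) continue;
      Stencil& s = S.st[vcompact[f]];
      s.face = f;
      s.mu1 = (g.cell(i, j - 1) == FLUID) ? g.cidx(i, j - 1) : -1; // south
      s.mu2 = (g.cell(i, j) == FLUID) ? g.cidx(i, j) : -1;         // north
      s.corner1 = i + (g.nx + 1) * j;         // west corner
      s.corner2 = (i + 1) + (g.nx + 1) * j;   // east corner
      auto cls = [&](int ii, int jj) {
        if (ii < 0 || ii >= nx || jj < 0 || jj > ny) return NB_MIRROR;
        int t = g.vt[g.vidx(ii, jj)];
        if (t == F_ACT) return vcompact[g.vidx(ii, jj)];
        if (t == F_FIX0) return NB_FIXED;
        int B = g.cell(ii, jj - 1), T = g.cell(ii, jj);
        if (B == OUTLET || T == OUTLET) return NB_NONE;
        return NB_MIRROR;   // walls and the inlet plane are no-slip
      };
      // 0 = S, 1 = N, 2 = W, 3 = E  (in-line first, then transverse)
      s.nb[0] = cls(i, j - 1); s.nb[1] = cls(i, j + 1);
      s.nb[2] = cls(i - 1, j); s.nb[3] = cls(i + 1, j);
      s.fixed_face[0] = g.vidx(i, j - 1); s.fixed_face[1] = g.vidx(i, j + 1);
      s.fixed_face[2] = g.vidx(i - 1, j); s.fixed_face[3] = g.vidx(i + 1, j);
    }
  S.alloc();
}

// pressure Poisson system: constant coefficients, built once
static void build_psys(const Grid& g, Compact& S,
                       std::vector<int>& pcompact) {
  int nx = g.nx, ny = g.ny;
  double ih2 = 1.0 / (g.h * g.h);
  pcompact.assign(nx * ny, -1);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      if (g.lab[g.cidx(i, j)] == FLUID)
        pcompact[g.cidx(i, j)] = (int)S.st.size(), S.st.push_back(Stencil());
  S.alloc();
  const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int c = g.cidx(i, j);
      if (pcompact[c] < 0) continue;
      int k = pcompact[c];
      Stencil& s = S.st[k];
      s.face = c;
      double d = 0.0;
      for (int q = 0; q < 4; ++q) {
        int lb = g.cell(i + di[q], j + dj[q]);
        if (lb == FLUID) {
          s.nb[q] = pcompact[g.cidx(i + di[q], j + dj[q])];
          S.coef[q][k] = ih2;
          d += ih2;
        } else if (lb == OUTLET) {
          s.nb[q] = NB_NONE;    // Dirichlet 0 beyond the outlet
          d += ih2;
        } else {
          s.nb[q] = NB_NONE;    // Neumann at walls and inlets
        }
      }
      S.diag[k] = d;
    }
}

// [[Rcpp::export]]
List cpp_flow_run(IntegerMatrix lab_, double h, double rho,
                  int rheo_mode, double mu_const, double mu_p, double hct,
                  double k0, double kinf, double gc, double gamma_min,
                  NumericVector vin, double dt,
                  NumericMatrix u0, NumericMatrix v0,
                  double cfl_max, double tol_div, int max_cg,
                  int record_every) {
  Grid g = make_grid(lab_, h);
  int nx = g.nx, ny = g.ny, nsteps = vin.size();
  Rheo rh{rheo_mode, mu_const, mu_p, hct, k0, kinf, gc, gamma_min};
  double mu_def = rh.visc(0.0);

  std::vector<double> u(u0.begin(), u0.end()), v(v0.begin(), v0.end());
  std::vector<double> mu(nx * ny, mu_def), gdot, dudy_c, dvdx_c;
  std::vector<double> p(nx * ny, 0.0);

  Compact SU, SV, SP;
  std::vector<int> ucomp, vcomp, pcomp;
  build_usys(g, SU, ucomp);
  build_vsys(g, SV, vcomp);
  build_psys(g, SP, pcomp);

  double max_cfl_seen = 0.0, max_du = 0.0, div_max = 0.0;
  int cfl_exceeded_at = -1, piters_last = 0;
  bool diverged = false;
  List frames_u, frames_v;
  NumericVector du_hist(nsteps);
  double coef = dt / (rho * h * h);
  std::vector<double> u_old, v_old;

  for (int step = 0; step < nsteps; ++step) {
    double uin = vin[step];
    u_old = u; v_old = v;
    for (size_t k = 0; k < u.size(); ++k) {
      if (g.ut[k] == F_IN) u[k] = uin;
      else if (g.ut[k] == F_FIX0 || g.ut[k] == F_EXT) u[k] = 0.0;
    }
    for (size_t k = 0; k < v.size(); ++k)
      if (g.vt[k] == F_FIX0 || g.vt[k] == F_EXT) v[k] = 0.0;

    double umax = 0.0;
    for (size_t k = 0; k < SU.st.size(); ++k)
      umax = std::max(umax, std::fabs(u[SU.st[k].face]));
    for (size_t k = 0; k < SV.st.size(); ++k)
      umax = std::max(umax, std::fabs(v[SV.st[k].face]));
    umax = std::max(umax, std::fabs(uin));
    double cfl = umax * dt / h;
    max_cfl_seen = std::max(max_cfl_seen, cfl);
    if (cfl > cfl_max) { cfl_exceeded_at = step; break; }

    strain_fields(g, u, v, gdot, dudy_c, dvdx_c);
    if (rheo_mode != 0)
      for (int c = 0; c < nx * ny; ++c)
        if (g.lab[c] == FLUID) mu[c] = rh.visc(gdot[c]);

    // ---- u system: coefficients + RHS ----
    for (size_t k = 0; k < SU.st.size(); ++k) {
      const Stencil& s = SU.st[k];
      int f = s.face;
      int i = f % (nx + 1), j = f / (nx + 1);
      double muW = (s.mu1 >= 0) ? mu[s.mu1] : mu_def;
      double muE = (s.mu2 >= 0) ? mu[s.mu2] : mu_def;
      double muS = mu_corner(g, mu, i, j, mu_def);
      double muN = mu_corner(g, mu, i, j + 1, mu_def);
      double cW = coef * 2.0 * muW, cE = coef * 2.0 * muE;
      double cS = coef * muS, cN = coef * muN;
      double cc[4] = {cW, cE, cS, cN};
      double d = 1.0, rhs;
      for (int q = 0; q < 4; ++q) {
        SU.coef[q][k] = cc[q];
        if (s.nb[q] == NB_NONE) continue;          // zero gradient
        else if (s.nb[q] == NB_MIRROR) d += 2.0 * cc[q];
        else d += cc[q];
      }
      SU.diag[k] = d;
      // explicit advection + cross stress
      double uc = u[f];
      double adv;
      if (uc >= 0) adv = uc * (uc - ug(g, u, i - 1, j, uc)) / h;
      else adv = uc * (ug(g, u, i + 1, j, uc) - uc) / h;
      double vb = 0.25 * (vgh(g, v, i - 1, j, 0) + vgh(g, v, i, j, 0) +
                          vgh(g, v, i - 1, j + 1, 0) +
                          vgh(g, v, i, j + 1, 0));
      if (vb >= 0) adv += vb * (uc - ug(g, u, i, j - 1, uc)) / h;
      else adv += vb * (ug(g, u, i, j + 1, uc) - uc) / h;
      double cross = (muN * dvdx_c[s.corner2] - muS * dvdx_c[s.corner1]) / h;
      rhs = uc + dt * (-adv) + dt / rho * cross;
      // Dirichlet neighbors
      for (int q = 0; q < 4; ++q)
        if (s.nb[q] == NB_FIXED) rhs += cc[q] * u[s.fixed_face[q]];
      SU.b[k] = rhs;
      SU.x[k] = uc;
    }
    SU.solve(1e-14, 1e-12, max_cg);

    // ---- v system ----
    for (size_t k = 0; k < SV.st.size(); ++k) {
      const Stencil& s = SV.st[k];
      int f = s.face;
      int i = f % nx, j = f / nx;
      double muS = (s.mu1 >= 0) ? mu[s.mu1] : mu_def;
      double muN = (s.mu2 >= 0) ? mu[s.mu2] : mu_def;
      double muW = mu_corner(g, mu, i, j, mu_def);
      double muE = mu_corner(g, mu, i + 1, j, mu_def);
      double cc[4] = {coef * 2.0 * muS, coef * 2.0 * muN,
                      coef * muW, coef * muE};
      double d = 1.0;
      for (int q = 0; q < 4; ++q) {
        SV.coef[q][k] = cc[q];
        if (s.nb[q] == NB_NONE) continue;
        else if (s.nb[q] == NB_MIRROR) d += 2.0 * cc[q];
        else d += cc[q];
      }
      SV.diag[k] = d;
      double vc = v[f];
      double ub = 0.25 * (ug(g, u, i, j - 1, 0) + ug(g, u, i + 1, j - 1, 0) +
                          ug(g, u, i, j, 0) + ug(g, u, i + 1, j, 0));
      double adv;
      if (ub >= 0) adv = ub * (vc - vgh(g, v, i - 1, j, vc)) / h;
      else adv = ub * (vgh(g, v, i + 1, j, vc) - vc) / h;
      if (vc >= 0) adv += vc * (vc - vgh(g, v, i, j - 1, vc)) / h;
      else adv += vc * (vgh(g, v, i, j + 1, vc) - vc) / h;
      double cross = (muE * dudy_c[s.corner2] - muW * dudy_c[s.corner1]) / h;
      double rhs = vc + dt * (-adv) + dt / rho * cross;
      for (int q = 0; q < 4; ++q)
        if (s.nb[q] == NB_FIXED) rhs += cc[q] * v[s.fixed_face[q]];
      SV.b[k] = rhs;
      SV.x[k] = vc;
    }
    SV.solve(1e-14, 1e-12, max_cg);

    // write predictors back (fixed faces keep their BC values)
    std::vector<double>& us = u;  // in-place: unknowns get x, rest already BC
    std::vector<double>& vs = v;
    for (size_t k = 0; k < SU.st.size(); ++k) us[SU.st[k].face] = SU.x[k];
    for (size_t k = 0; k < SV.st.size(); ++k) vs[SV.st[k].face] = SV.x[k];

    // ---- projection (warm-started: SP.x persists across steps) ----
    for (size_t k = 0; k < SP.st.size(); ++k) {
      int c = SP.st[k].face;
      int i = c % nx, j = c / nx;
      double div = (us[g.uidx(i + 1, j)] - us[g.uidx(i, j)] +
                    vs[g.vidx(i, j + 1)] - vs[g.vidx(i, j)]) / h;
      SP.b[k] = -(rho / dt) * div;
    }
    piters_last = SP.solve(tol_div * rho / dt, 0.0, max_cg);

    for (size_t k = 0; k < SP.st.size(); ++k) p[SP.st[k].face] = SP.x[k];

    // ---- correction ----
    for (size_t k = 0; k < SU.st.size(); ++k) {
      int f = SU.st[k].face;
      int i = f % (nx + 1), j = f / (nx + 1);
      double pL = (g.cell(i - 1, j) == FLUID) ? p[g.cidx(i - 1, j)] : 0.0;
      double pR = (g.cell(i, j) == FLUID) ? p[g.cidx(i, j)] : 0.0;
      u[f] -= dt / rho * (pR - pL) / h;
    }
    for (size_t k = 0; k < SV.st.size(); ++k) {
      int f = SV.st[k].face;
      int i = f % nx, j = f / nx;
      v[f] -= dt / rho * (p[g.cidx(i, j)] - p[g.cidx(i, j - 1)]) / h;
    }

    // post-projection divergence + steady-state monitor
    div_max = 0.0;
    for (size_t k = 0; k < SP.st.size(); ++k) {
      int c = SP.st[k].face;
      int i = c % nx, j = c / nx;
      double div = (u[g.uidx(i + 1, j)] - u[g.uidx(i, j)] +
                    v[g.vidx(i, j + 1)] - v[g.vidx(i, j)]) / h;
      div_max = std::max(div_max, std::fabs(div));
    }
    max_du = 0.0;
    for (size_t k = 0; k < SU.st.size(); ++k)
      max_du = std::max(max_du, std::fabs(u[SU.st[k].face] -
                                          u_old[SU.st[k].face]));
    for (size_t k = 0; k < SV.st.size(); ++k)
      max_du = std::max(max_du, std::fabs(v[SV.st[k].face] -
                                          v_old[SV.st[k].face]));
    du_hist[step] = max_du;
    if (!std::isfinite(max_du)) { diverged = true; break; }

    if (record_every > 0 && ((step + 1) % record_every == 0)) {
      NumericMatrix uu(nx + 1, ny), vv(nx, ny + 1);
      std::copy(u.begin(), u.end(), uu.begin());
      std::copy(v.begin(), v.end(), vv.begin());
      frames_u.push_back(uu);
      frames_v.push_back(vv);
    }
  }

  NumericMatrix uo(nx + 1, ny), vo(nx, ny + 1), po(nx, ny), muo(nx, ny);
  std::copy(u.begin(), u.end(), uo.begin());
  std::copy(v.begin(), v.end(), vo.begin());
  std::copy(p.begin(), p.end(), po.begin());
  std::copy(mu.begin(), mu.end(), muo.begin());
  return List::create(
      _["u"] = uo, _["v"] = vo, _["p"] = po, _["mu"] = muo,
      _["max_du"] = max_du, _["du_hist"] = du_hist,
      _["max_cfl"] = max_cfl_seen, _["cfl_exceeded_at"] = cfl_exceeded_at,
      _["diverged"] = diverged, _["div_max"] = div_max,
      _["piters"] = piters_last,
      _["frames_u"] = frames_u, _["frames_v"] = frames_v);
}

// one extra, very tight projection of a velocity field: used on the
// fields handed to the tracer so that donor-cell boundedness holds to
// round-off over long washout horizons
// [[Rcpp::export]]
List cpp_project(IntegerMatrix lab_, double h, NumericMatrix u0,
                 NumericMatrix v0, double rho, double dt,
                 double tol_div, int max_cg) {
  Grid g = make_grid(lab_, h);
  int nx = g.nx, ny = g.ny;
  std::vector<double> u(u0.begin(), u0.end()), v(v0.begin(), v0.end());
  Compact SP;
  std::vector<int> pcomp;
  build_psys(g, SP, pcomp);
  for (size_t k = 0; k < SP.st.size(); ++k) {
    int c = SP.st[k].face;
    int i = c % nx, j = c / nx;
    double div = (u[g.uidx(i + 1, j)] - u[g.uidx(i, j)] +
                  v[g.vidx(i, j + 1)] - v[g.vidx(i, j)]) / h;
    SP.b[k] = -(rho / dt) * div;
  }
  int iters = SP.solve(tol_div * rho / dt, 0.0, max_cg);
  std::vector<double> p(nx * ny, 0.0);
  for (size_t k = 0; k < SP.st.size(); ++k) p[SP.st[k].face] = SP.x[k];
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i <= nx; ++i) {
      int t = g.ut[g.uidx(i, j)];
      if (t != F_ACT && t != F_OUT) continue;
      double pL = (g.cell(i - 1, j) == FLUID) ? p[g.cidx(i - 1, j)] : 0.0;
      double pR = (g.cell(i, j) == FLUID) ? p[g.cidx(i, j)] : 0.0;
      u[g.uidx(i, j)] -= dt / rho * (pR - pL) / h;
    }
  for (int j = 0; j <= ny; ++j)
    for (int i = 0; i < nx; ++i) {
      if (g.vt[g.vidx(i, j)] != F_ACT) continue;
      v[g.vidx(i, j)] -= dt / rho * (p[g.cidx(i, j)] -
                                     p[g.cidx(i, j - 1)]) / h;
    }
  double div_max = 0.0;
  for (size_t k = 0; k < SP.st.size(); ++k) {
    int c = SP.st[k].face;
    int i = c % nx, j = c / nx;
    double div = (u[g.uidx(i + 1, j)] - u[g.uidx(i, j)] +
                  v[g.vidx(i, j + 1)] - v[g.vidx(i, j)]) / h;
    div_max = std::max(div_max, std::fabs(div));
  }
  NumericMatrix uo(nx + 1, ny), vo(nx, ny + 1);
  std::copy(u.begin(), u.end(), uo.begin());
  std::copy(v.begin(), v.end(), vo.begin());
  return List::create(_["u"] = uo, _["v"] = vo, _["div_max"] = div_max,
                      _["iters"] = iters);
}

// conservative donor-cell tracer advection over frozen or cyclically
// replayed velocity frames
// [[Rcpp::export]]
List cpp_tracer_run(IntegerMatrix lab_, LogicalMatrix laa_, double h,
                    NumericVector u_frames, NumericVector v_frames,
                    int nf, double period, double dt, double t0,
                    double t_end, int sample_every, NumericMatrix c0) {
  Grid g = make_grid(lab_, h);
  int nx = g.nx, ny = g.ny;
  size_t nu = (size_t)(nx + 1) * ny, nv = (size_t)nx * (ny + 1);
  std::vector<double> c(c0.begin(), c0.end()), dc(c.size(), 0.0);
  std::vector<int> laa(laa_.begin(), laa_.end());
  int nlaa = 0;
  for (int k = 0; k < nx * ny; ++k) if (laa[k]) ++nlaa;

  // precompute flux faces: {face index, donor/receiver cells, boundary
  // outflux flags}
  struct XF { int f, L, R; bool outL, outR; };
  std::vector<XF> xf, yf;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i <= nx; ++i) {
      int t = g.ut[g.uidx(i, j)];
      if (t == F_EXT || t == F_FIX0) continue;
      XF e;
      e.f = g.uidx(i, j);
      e.L = (g.cell(i - 1, j) == FLUID) ? g.cidx(i - 1, j) : -1;
      e.R = (g.cell(i, j) == FLUID) ? g.cidx(i, j) : -1;
      e.outL = (e.L < 0);   // leaving through an inlet (u < 0)
      e.outR = (e.R < 0);   // leaving through the outlet (u > 0)
      xf.push_back(e);
    }
  for (int j = 0; j <= ny; ++j)
    for (int i = 0; i < nx; ++i) {
      if (g.vt[g.vidx(i, j)] != F_ACT) continue;
      XF e;
      e.f = g.vidx(i, j);
      e.L = g.cidx(i, j - 1);
      e.R = g.cidx(i, j);
      e.outL = e.outR = false;
      yf.push_back(e);
    }

  long nsteps = (long)std::ceil((t_end - t0) / dt - 1e-9);
  std::vector<double> ts, cl, ms, os;
  double outflux = 0.0, cmin = 1e300, cmax = -1e300;

  auto record = [&](double t) {
    double s = 0.0, m = 0.0;
    for (int k = 0; k < nx * ny; ++k) {
      if (g.lab[k] == FLUID) m += c[k];
      if (laa[k]) s += c[k];
    }
    ts.push_back(t);
    cl.push_back(nlaa ? s / nlaa : 0.0);
    ms.push_back(m * h * h);
    os.push_back(outflux);
  };
  record(t0);

  int fr_prev = -1;
  const double* uf = &u_frames[0];
  const double* vf = &v_frames[0];
  for (long step = 0; step < nsteps; ++step) {
    double t = t0 + step * dt;
    int fr = 0;
    if (nf > 1) {
      double cyc = t / period;
      double phase = cyc - std::floor(cyc);
      fr = std::min((int)(phase * nf), nf - 1);
    }
    if (fr != fr_prev) {
      uf = &u_frames[(size_t)fr * nu];
      vf = &v_frames[(size_t)fr * nv];
      fr_prev = fr;
    }
    double a = dt / h;   // phi = u*h*Cup; dC = phi*dt/h^2 = a*u*Cup
    std::fill(dc.begin(), dc.end(), 0.0);
    for (size_t k = 0; k < xf.size(); ++k) {
      const XF& e = xf[k];
      double uv = uf[e.f];
      if (uv == 0.0) continue;
      double cup = (uv > 0) ? (e.L >= 0 ? c[e.L] : 0.0)
                            : (e.R >= 0 ? c[e.R] : 0.0);
      double d = a * uv * cup;
      if (e.L >= 0) dc[e.L] -= d;
      else if (uv < 0) outflux += -d * h * h;
      if (e.R >= 0) dc[e.R] += d;
      else if (uv > 0) outflux += d * h * h;
    }
    for (size_t k = 0; k < yf.size(); ++k) {
      const XF& e = yf[k];
      double vv = vf[e.f];
      if (vv == 0.0) continue;
      double cup = (vv > 0) ? c[e.L] : c[e.R];
      double d = a * vv * cup;
      dc[e.L] -= d;
      dc[e.R] += d;
    }
    for (size_t k = 0; k < c.size(); ++k) c[k] += dc[k];
    if ((step & 15) == 0 || step == nsteps - 1) {
      for (int k = 0; k < nx * ny; ++k) {
        if (g.lab[k] != FLUID) continue;
        cmin = std::min(cmin, c[k]);
        cmax = std::max(cmax, c[k]);
      }
    }
    if ((step + 1) % sample_every == 0 || step == nsteps - 1)
      record(t0 + (step + 1) * dt);
  }

  NumericMatrix cf(nx, ny);
  std::copy(c.begin(), c.end(), cf.begin());
  return List::create(
      _["t"] = NumericVector(ts.begin(), ts.end()),
      _["c_laa"] = NumericVector(cl.begin(), cl.end()),
      _["mass"] = NumericVector(ms.begin(), ms.end()),
      _["outflux_cum"] = NumericVector(os.begin(), os.end()),
      _["c_min"] = cmin, _["c_max"] = cmax, _["c_final"] = cf);
}
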