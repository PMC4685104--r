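#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const int CANC = 1, CORT = 2, EXTR = 3, VENT = 4;

// fractional flow with linear relative permeabilities
static inline double ffrac(double s, double muo, double mua) {
  double a = s / muo, b = (1.0 - s) / mua;
  double d = a + b;
  return d > 0.0 ? a / d : 0.0;
}

// Pressure solve: conservative finite volume with harmonic-mean face
// transmissibilities, Dirichlet vents, SGS-preconditioned CG.
// amob = alpha * lambda_t per cell (zero on cortical/exterior).
// rhog = optional per-cell rho(s)*g for the buoyancy term (length 0 = off).
// [[Rcpp::export]]
List cpp_solve_pressure(IntegerVector dims, IntegerVector cls,
                        NumericVector amob, double h, NumericVector q,
                        NumericVector ventP, NumericVector P0,
                        double tol, int maxit, NumericVector rhog) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ncell = nx * ny * nz;
  const bool grav = rhog.size() > 0;

  std::vector<int> map(ncell, -1), cells;
  cells.reserve(ncell / 2);
  for (int t = 0; t < ncell; ++t)
    if (cls[t] == CANC) { map[t] = (int)cells.size(); cells.push_back(t); }
  const int n = (int)cells.size();

  // neighbor offsets in ascending full-index order (keeps CSR columns sorted)
  const int offs[6][4] = { // {di,dj,dk, zdir} zdir: -1 bottom, +1 top, 0 lateral
    {0,0,-1,-1}, {0,-1,0,0}, {-1,0,0,0}, {1,0,0,0}, {0,1,0,0}, {0,0,1,1}
  };

  std::vector<int> rowptr(n + 1, 0), colind;
  std::vector<double> val, diag(n, 0.0), b(n, 0.0), x(n, 0.0);
  colind.reserve(6 * n); val.reserve(6 * n);

  for (int r = 0; r < n; ++r) {
    int t = cells[r];
    int i = t % nx, j = (t / nx) % ny, k = t / (nx * ny);
    b[r] = q[t];
    x[r] = P0[t];
    for (int m = 0; m < 6; ++m) {
      int ii = i + offs[m][0], jj = j + offs[m][1], kk = k + offs[m][2];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
        continue;
      int u = ii + nx * (jj + ny * kk);
      double a = amob[t], bb = amob[u];
      if (!(a > 0.0 && bb > 0.0)) continue;
      if (cls[u] != CANC && cls[u] != VENT) continue;
      double T = h * 2.0 * a * bb / (a + bb);
      double gterm = 0.0;
      if (grav && offs[m][3] != 0) {
        double rbar = 0.5 * (rhog[t] + rhog[u]);
        // flux out through top face has an extra -T*rbar*h; through bottom
        // face +T*rbar*h; move to RHS
        gterm = (offs[m][3] > 0 ? 1.0 : -1.0) * T * rbar * h;
      }
      if (cls[u] == CANC) {
        diag[r] += T;
        colind.push_back(map[u]);
        val.push_back(-T);
        b[r] += gterm;
      } else { // vent: Dirichlet
        diag[r] += T;
        b[r] += T * ventP[u] + gterm;
      }
    }
    rowptr[r + 1] = (int)colind.size();
  }

  // isolated rows (no connections at all): pin to zero
  for (int r = 0; r < n; ++r)
    if (diag[r] == 0.0) { diag[r] = 1.0; b[r] = 0.0; x[r] = 0.0; }

  double bnorm = 0.0;
  for (int r = 0; r < n; ++r) bnorm += b[r] * b[r];
  bnorm = std::sqrt(bnorm);

  NumericVector P(ncell, 0.0);
  int iters = 0;
  double relres = 0.0;

  auto matvec = [&](const std::vector<double>& v, std::vector<double>& out) {
    for (int r = 0; r < n; ++r) {
      double s = diag[r] * v[r];
      for (int p = rowptr[r]; p < rowptr[r + 1]; ++p)
        s += val[p] * v[colind[p]];
      out[r] = s;
    }
  };
  // symmetric Gauss-Seidel preconditioner: (D+L) D^{-1} (D+U) z = r
  auto precond = [&](const std::vector<double>& rv, std::vector<double>& z) {
    for (int r = 0; r < n; ++r) {
      double s = rv[r];
      for (int p = rowptr[r]; p < rowptr[r + 1]; ++p) {
        int c = colind[p];
        if (c < r) s -= val[p] * z[c];
      }
      z[r] = s / diag[r];
    }
    for (int r = n - 1; r >= 0; --r) {
      double s = diag[r] * z[r];
      for (int p = rowptr[r]; p < rowptr[r + 1]; ++p) {
        int c = colind[p];
        if (c > r) s -= val[p] * z[c];
      }
      z[r] = s / diag[r];
    }
  };

  if (bnorm == 0.0) {
    std::fill(x.begin(), x.end(), 0.0);
  } else {
    std::vector<double> r(n), z(n), p(n), Ap(n);
    matvec(x, Ap);
    for (int i2 = 0; i2 < n; ++i2) r[i2] = b[i2] - Ap[i2];
    precond(r, z);
    p = z;
    double rz = 0.0, rnorm2 = 0.0;
    for (int i2 = 0; i2 < n; ++i2) { rz += r[i2] * z[i2]; rnorm2 += r[i2] * r[i2]; }
    relres = std::sqrt(rnorm2) / bnorm;
    while (relres > tol && iters < maxit) {
      matvec(p, Ap);
      double pAp = 0.0;
      for (int i2 = 0; i2 < n; ++i2) pAp += p[i2] * Ap[i2];
      if (pAp <= 0.0) break;
      double alpha = rz / pAp;
      rnorm2 = 0.0;
      for (int i2 = 0; i2 < n; ++i2) {
        x[i2] += alpha * p[i2];
        r[i2] -= alpha * Ap[i2];
        rnorm2 += r[i2] * r[i2];
      }
      precond(r, z);
      double rznew = 0.0;
      for (int i2 = 0; i2 < n; ++i2) rznew += r[i2] * z[i2];
      double beta = rznew / rz;
      rz = rznew;
      for (int i2 = 0; i2 < n; ++i2) p[i2] = z[i2] + beta * p[i2];
      relres = std::sqrt(rnorm2) / bnorm;
      ++iters;
    }
  }

  for (int r2 = 0; r2 < n; ++r2) P[cells[r2]] = x[r2];
  for (int t = 0; t < ncell; ++t) if (cls[t] == VENT) P[t] = ventP[t];
  return List::create(_["P"] = P, _["iters"] = iters, _["relres"] = relres,
                      _["n_unknowns"] = n);
}

// Upwind saturation transport. Face arrays vx/vy/vz hold face-normal Darcy
// velocities (m/s), positive toward +axis; volume rate through a face is
// v*h^2. src0 is the 0-based full index of the source cell (-1 for none);
// qoil its oil source (m^3/s).
//
// implicit = true: exact backward-Euler upwind update via a single nonlinear
// Gauss-Seidel sweep in decreasing-pressure order (the upwind flux graph is
// acyclic with respect to pressure), each cell solved by bisection.
// implicit = false: standard explicit first-order upwind update (caller
// enforces the CFL bound).
// [[Rcpp::export]]
List cpp_advect(IntegerVector dims, IntegerVector cls, NumericVector poro,
                NumericVector s, NumericVector vx, NumericVector vy,
                NumericVector vz, NumericVector P, double h, double dt,
                double muo, double mua, int src0, double qoil,
                bool implicit) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ncell = nx * ny * nz;
  const double A = h * h, V = h * h * h;

  NumericVector sn(ncell, 0.0);
  double outflow = 0.0, slack = 0.0;

  std::vector<int> cells;
  cells.reserve(ncell / 2);
  for (int t = 0; t < ncell; ++t) {
    if (cls[t] == CANC) { cells.push_back(t); sn[t] = s[t]; }
  }

  // signed face velocity seen from cell t toward neighbor dir m
  // (positive = outflow from t); also returns neighbor index or -1
  auto face_out = [&](int t, int m, int& u) -> double {
    int i = t % nx, j = (t / nx) % ny, k = t / (nx * ny);
    switch (m) {
      case 0: u = (i > 0) ? t - 1 : -1;
        return -vx[i + (nx + 1) * (j + ny * k)];
      case 1: u = (i < nx - 1) ? t + 1 : -1;
        return vx[(i + 1) + (nx + 1) * (j + ny * k)];
      case 2: u = (j > 0) ? t - nx : -1;
        return -vy[i + nx * (j + (ny + 1) * k)];
      case 3: u = (j < ny - 1) ? t + nx : -1;
        return vy[i + nx * ((j + 1) + (ny + 1) * k)];
      case 4: u = (k > 0) ? t - nx * ny : -1;
        return -vz[i + nx * (j + ny * k)];
      default: u = (k < nz - 1) ? t + nx * ny : -1;
        return vz[i + nx * (j + ny * (k + 1))];
    }
  };

  if (!implicit) {
    std::vector<double> net(cells.size(), 0.0);
    for (size_t c = 0; c < cells.size(); ++c) {
      int t = cells[c];
      double acc = (t == src0) ? qoil : 0.0;
      for (int m = 0; m < 6; ++m) {
        int u;
        double vout = face_out(t, m, u);
        if (vout == 0.0 || u < 0) continue;
        if (cls[u] != CANC && cls[u] != VENT) continue;
        double rate = vout * A;
        if (rate > 0.0) { // outflow, upwind = this cell
          double fl = ffrac(s[t], muo, mua) * rate;
          acc -= fl;
          if (cls[u] == VENT) outflow += fl * dt;
        } else {          // inflow, upwind = neighbor (vent carries s = 0)
          double sup = (cls[u] == VENT) ? 0.0 : s[u];
          acc -= ffrac(sup, muo, mua) * rate;
        }
      }
      net[c] = acc;
    }
    for (size_t c = 0; c < cells.size(); ++c) {
      int t = cells[c];
      sn[t] = s[t] + dt * net[c] / (poro[t] * V);
    }
  } else {
    // order canc cells by decreasing pressure (stable: ties keep index order;
    // equal pressures carry zero flux, so their mutual order is immaterial)
    std::vector<int> ord(cells);
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a2, int b2) { return P[a2] > P[b2]; });
    for (int t : ord) {
      double IN = (t == src0) ? qoil : 0.0;
      double OUT = 0.0;
      double vent_rate = 0.0;
      for (int m = 0; m < 6; ++m) {
        int u;
        double vout = face_out(t, m, u);
        if (vout == 0.0 || u < 0) continue;
        if (cls[u] != CANC && cls[u] != VENT) continue;
        double rate = vout * A;
        if (rate > 0.0) {
          OUT += rate;
          if (cls[u] == VENT) vent_rate += rate;
        } else {
          double sup = (cls[u] == VENT) ? 0.0 : sn[u]; // upstream already done
          IN -= ffrac(sup, muo, mua) * rate;
        }
      }
      double sc = s[t];
      double mcoef = poro[t] * V / dt;
      double x;
      if (sc == 0.0 && IN <= 0.0) {
        x = 0.0;
      } else {
        double g1 = mcoef * (1.0 - sc) + OUT - IN;
        double scale = mcoef + OUT + IN;
        if (sc == 1.0 && std::fabs(OUT - IN) <= 1e-12 * scale) {
          x = 1.0; // saturated interior: divergence residual only
        } else if (g1 <= 0.0) {
          x = 1.0; // cannot shed enough (pressure residual); track slack
          slack += -g1 * dt;
        } else {
          double lo = 0.0, hi = 1.0;
          for (int it = 0; it < 60; ++it) {
            double mid = 0.5 * (lo + hi);
            double g = mcoef * (mid - sc) + ffrac(mid, muo, mua) * OUT - IN;
            if (g > 0.0) hi = mid; else lo = mid;
          }
          x = 0.5 * (lo + hi);
        }
      }
      sn[t] = x;
      if (vent_rate > 0.0)
        outflow += ffrac(x, muo, mua) * vent_rate * dt;
    }
  }

  return List::create(_["s"] = sn, _["outflow"] = outflow,
                      _["slack"] = slack);
}
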