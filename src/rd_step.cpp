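// Implicit finite-difference stepper for the receptor-toxin-antibody
// reaction-diffusion system on a spherically symmetric shell [rho_c, rho_e].
//
// Conservative finite-volume discretization of (1/rho^2) d/drho(rho^2 k du/drho)
// on a uniform grid; boundary conditions: Dirichlet (uT0, uA0, 0) at the outer
// node, zero flux for antibody/complex and a Robin (reactive-flux) condition
// for toxin at the cell surface, coupled to the surface occupancy ODE.
// Time stepping is a theta-scheme (w = 1 backward Euler, w = 0.5
// Crank-Nicolson) with the nonlinear reaction and wall coupling resolved by
// fixed-point inner iteration.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Tridiagonal solve (Thomas algorithm); b and d are modified in place.
static void thomas(int n, const std::vector<double>& a, std::vector<double>& b,
                   const std::vector<double>& c, std::vector<double>& d,
                   std::vector<double>& x) {
  for (int i = 1; i < n; ++i) {
    double m = a[i] / b[i - 1];
    b[i] -= m * c[i - 1];
    d[i] -= m * d[i - 1];
  }
  x[n - 1] = d[n - 1] / b[n - 1];
  for (int i = n - 2; i >= 0; --i)
    x[i] = (d[i] - c[i] * x[i + 1]) / b[i];
}

struct Disc {
  int N;
  double h;
  std::vector<double> V;      // control volumes (4*pi dropped throughout)
  std::vector<double> Af;     // face areas rho_{i+1/2}^2, i = 0..N-2
  double Ac;                  // wall area rho_c^2
};

// Explicit diffusion operator [D u]_i (interior + wall volume); the wall
// reactive flux for toxin is added by the caller. Outer node untouched.
static void diff_op(const Disc& g, double kappa,
                    const std::vector<double>& u, std::vector<double>& out) {
  int N = g.N;
  out[0] = g.Af[0] * kappa * (u[1] - u[0]) / g.h;
  for (int i = 1; i < N - 1; ++i)
    out[i] = g.Af[i] * kappa * (u[i + 1] - u[i]) / g.h
           - g.Af[i - 1] * kappa * (u[i] - u[i - 1]) / g.h;
  out[N - 1] = 0.0;
}

// Assemble and solve one implicit solve for a species with given reaction
// source (already weighted), wall terms (toxin only) and Dirichlet value.
static void species_solve(const Disc& g, double kappa, double dt, double w,
                          const std::vector<double>& u_old,
                          const std::vector<double>& expl, // (1-w)*dt*[D u^n]
                          const std::vector<double>& src,  // dt * R_mix
                          double wall_diag, double wall_rhs, // toxin Robin
                          double dirichlet,
                          std::vector<double>& a, std::vector<double>& b,
                          std::vector<double>& c, std::vector<double>& d,
                          std::vector<double>& x) {
  int N = g.N;
  double f = w * dt * kappa / g.h;
  // node 0 (wall control volume)
  a[0] = 0.0;
  b[0] = g.V[0] + f * g.Af[0] + wall_diag;
  c[0] = -f * g.Af[0];
  d[0] = g.V[0] * u_old[0] + expl[0] + g.V[0] * src[0] + wall_rhs;
  for (int i = 1; i < N - 1; ++i) {
    a[i] = -f * g.Af[i - 1];
    b[i] = g.V[i] + f * (g.Af[i - 1] + g.Af[i]);
    c[i] = -f * g.Af[i];
    d[i] = g.V[i] * u_old[i] + expl[i] + g.V[i] * src[i];
  }
  a[N - 1] = 0.0; b[N - 1] = 1.0; c[N - 1] = 0.0; // Dirichlet row

  d[N - 1] = dirichlet;
  thomas(N, a, b, c, d, x);
}

// [[Rcpp::export]]
List rd_integrate_cpp(NumericVector uT0_, NumericVector uA0_,
                      NumericVector uC0_, double theta0,
                      NumericVector rho, List pars,
                      double dt, int n_steps, double w,
                      double tol, int max_inner,
                      bool detect_steady, double steady_tol) {
  const int N = rho.size();
  const double k1 = pars["k1"], k_m1 = pars["k_m1"];
  const double k2 = pars["k2"], k_m2 = pars["k_m2"], k3 = pars["k3"];
  const double r0 = pars["r0"];
  const double kT = pars["kappa_T"], kA = pars["kappa_A"], kC = pars["kappa_C"];
  const double bcT = pars["uT_outer"], bcA = pars["uA_outer"];
  const double bcC = 0.0;

  Disc g;
  g.N = N;
  g.h = (rho[N - 1] - rho[0]) / (N - 1);
  g.Ac = rho[0] * rho[0];
  g.Af.resize(N - 1);
  for (int i = 0; i < N - 1; ++i) {
    double rf = rho[i] + 0.5 * g.h;
    g.Af[i] = rf * rf;
  }
  g.V.resize(N);
  {
    double rp = rho[0] + 0.5 * g.h;
    g.V[0] = (rp * rp * rp - rho[0] * rho[0] * rho[0]) / 3.0;
    for (int i = 1; i < N - 1; ++i) {
      double rm = rho[i] - 0.5 * g.h, rq = rho[i] + 0.5 * g.h;
      g.V[i] = (rq * rq * rq - rm * rm * rm) / 3.0;
    }
    g.V[N - 1] = 1.0; // Dirichlet row, volume unused
  }

  std::vector<double> uT(uT0_.begin(), uT0_.end());
  std::vector<double> uA(uA0_.begin(), uA0_.end());
  std::vector<double> uC(uC0_.begin(), uC0_.end());
  double theta = theta0;

  // scratch
  std::vector<double> a(N), b(N), c(N), d(N);
  std::vector<double> exT(N, 0.0), exA(N, 0.0), exC(N, 0.0);
  std::vector<double> cx_old(N), src(N);
  std::vector<double> nT(N), nA(N), nC(N);   // current inner iterates
  std::vector<double> sT(N), sA(N), sC(N);   // freshly solved fields

  std::vector<double> theta_series(n_steps), wall_series(n_steps);
  int steps_done = 0, max_inner_used = 0;
  bool steady = false, failed = false;
  double fail_t = NA_REAL;

  for (int step = 0; step < n_steps; ++step) {
    // old-time quantities
    for (int i = 0; i < N; ++i)
      cx_old[i] = k1 * uT[i] * uA[i] - k_m1 * uC[i];
    double s_wall_old = k2 * (1.0 - theta) * uT[0] - k_m2 * theta;
    double sth_old = s_wall_old - k3 * theta;
    if (w < 1.0) {
      diff_op(g, kT, uT, exT);
      exT[0] -= g.Ac * r0 * s_wall_old;
      diff_op(g, kA, uA, exA);
      diff_op(g, kC, uC, exC);
      double we = (1.0 - w) * dt;
      for (int i = 0; i < N; ++i) { exT[i] *= we; exA[i] *= we; exC[i] *= we; }
      // restore for next step use: exT etc are recomputed each step anyway
    }

    nT = uT; nA = uA; nC = uC;
    double nth = theta;
    int iter = 0;
    double diff = R_PosInf;
    while (true) {
      ++iter;
      // mixed reaction source: dt * (w * cx(iterate) + (1-w) * cx(old))
      for (int i = 0; i < N; ++i) {
        double cx = k1 * nT[i] * nA[i] - k_m1 * nC[i];
        src[i] = dt * (w * cx + (1.0 - w) * cx_old[i]);
      }
      // toxin: source -cx, Robin wall terms with current theta iterate
      for (int i = 0; i < N; ++i) src[i] = -src[i];
      double wall_diag = w * dt * g.Ac * r0 * k2 * (1.0 - nth);
      double wall_rhs = w * dt * g.Ac * r0 * k_m2 * nth;
      species_solve(g, kT, dt, w, uT, exT, src, wall_diag, wall_rhs, bcT,
                    a, b, c, d, sT);
      // antibody: source -cx (same as toxin), no wall terms
      species_solve(g, kA, dt, w, uA, exA, src, 0.0, 0.0, bcA,
                    a, b, c, d, sA);
      // complex: source +cx
      for (int i = 0; i < N; ++i) src[i] = -src[i];
      species_solve(g, kC, dt, w, uC, exC, src, 0.0, 0.0, bcC,
                    a, b, c, d, sC);
      // surface occupancy, implicit in theta given the new wall toxin value
      double uTw = sT[0];
      double sth = (theta + dt * (w * k2 * uTw + (1.0 - w) * sth_old)) /
                   (1.0 + w * dt * (k2 * uTw + k_m2 + k3));
      diff = std::fabs(sth - nth);
      for (int i = 0; i < N; ++i) {
        diff = std::max(diff, std::fabs(sT[i] - nT[i]));
        diff = std::max(diff, std::fabs(sA[i] - nA[i]));
        diff = std::max(diff, std::fabs(sC[i] - nC[i]));
      }
      nT.swap(sT); nA.swap(sA); nC.swap(sC); nth = sth;
      if (diff < tol) break;
      if (iter >= max_inner) { failed = true; break; }
    }
    if (iter > max_inner_used) max_inner_used = iter;
    if (failed) { fail_t = (step + 1) * dt; break; }

    // steady-state detection: max relative change per unit time
    if (detect_steady) {
      double mx = std::fabs(nth - theta);
      for (int i = 0; i < N; ++i) {
        mx = std::max(mx, std::fabs(nT[i] - uT[i]));
        mx = std::max(mx, std::fabs(nA[i] - uA[i]));
        mx = std::max(mx, std::fabs(nC[i] - uC[i]));
      }
      if (mx / dt < steady_tol) steady = true;
    }

    uT.swap(nT); uA.swap(nA); uC.swap(nC); theta = nth;
    theta_series[step] = theta;
    wall_series[step] = uT[0];
    steps_done = step + 1;
    if (steady) break;
  }

  theta_series.resize(steps_done);
  wall_series.resize(steps_done);
  return List::create(
    _["uT"] = NumericVector(uT.begin(), uT.end()),
    _["uA"] = NumericVector(uA.begin(), uA.end()),
    _["uC"] = NumericVector(uC.begin(), uC.end()),
    _["theta"] = theta,
    _["theta_series"] = NumericVector(theta_series.begin(), theta_series.end()),
    _["uT_wall_series"] = NumericVector(wall_series.begin(), wall_series.end()),
    _["steps_done"] = steps_done,
    _["steady"] = steady,
    _["failed"] = failed,
    _["fail_t"] = fail_t,
    _["max_inner_used"] = max_inner_used);
}
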