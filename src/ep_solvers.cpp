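#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Minimal atrial cell in the Hodgkin-Huxley formalism.
// Six currents: I_Na (m^3 h), I_CaL (d f), I_Kr (xr, instantaneous
// rectification), I_Ks (xs^2), I_K1 (time-independent rectifier), I_leak.
// All constants arrive in one flat parameter vector built by cell_params()
// on the R side; the index layout below must match .cell_param_layout there.

enum ParIdx {
  P_GNA = 0, P_GCAL, P_GKR, P_GKS, P_GK1, P_GLEAK,
  P_SKR, P_SKS, P_SCAL,
  P_ENA, P_EK, P_ECA, P_ELEAK, P_CM,
  P_M_VH, P_M_K, P_M_T0, P_M_TA, P_M_TV, P_M_TS,
  P_H_VH, P_H_K, P_H_T0, P_H_TA, P_H_TV, P_H_TK,
  P_D_VH, P_D_K, P_D_T0, P_D_TA, P_D_TV, P_D_TS,
  P_F_VH, P_F_K, P_F_T0, P_F_TA, P_F_TV, P_F_TS,
  P_XR_VH, P_XR_K, P_XR_T0, P_XR_TA, P_XR_TV, P_XR_TS,
  P_RKR_VH, P_RKR_K,
  P_XS_VH, P_XS_K, P_XS_T0, P_XS_TA, P_XS_TV, P_XS_TS,
  P_K1_K, P_K1_VH,
  N_PAR
};

static const int NSTATE = 7; // V, m, h, d, f, xr, xs

static inline double sig(double v, double vh, double k) {
  return 1.0 / (1.0 + std::exp(-(v - vh) / k));
}
static inline double tau_gauss(double v, double t0, double ta, double tv, double ts) {
  double z = (v - tv) / ts;
  return t0 + ta * std::exp(-z * z);
}
static inline double time_in_beat(double t, double cl) {
  return t - std::floor(t / cl) * cl;
}

// ionic current sum and gate derivatives; y = {V,m,h,d,f,xr,xs}
static inline void derivs(const double *p, const double *y, double istim, double *dy) {
  const double V = y[0], m = y[1], h = y[2], d = y[3], f = y[4], xr = y[5], xs = y[6];

  double ina  = p[P_GNA] * m * m * m * h * (V - p[P_ENA]);
  double ical = p[P_GCAL] * p[P_SCAL] * d * f * (V - p[P_ECA]);
  double rkr  = 1.0 / (1.0 + std::exp((V - p[P_RKR_VH]) / p[P_RKR_K]));
  double ikr  = p[P_GKR] * p[P_SKR] * xr * rkr * (V - p[P_EK]);
  double iks  = p[P_GKS] * p[P_SKS] * xs * xs * (V - p[P_EK]);
  double ik1  = p[P_GK1] * (V - p[P_EK]) / (1.0 + std::exp(p[P_K1_K] * (V - p[P_K1_VH])));
  double ilk  = p[P_GLEAK] * (V - p[P_ELEAK]);

  dy[0] = -(ina + ical + ikr + iks + ik1 + ilk - istim) / p[P_CM];

  double minf = sig(V, p[P_M_VH], p[P_M_K]);
  double taum = tau_gauss(V, p[P_M_T0], p[P_M_TA], p[P_M_TV], p[P_M_TS]);
  dy[1] = (minf - m) / taum;

  double hinf = 1.0 - sig(V, p[P_H_VH], p[P_H_K]); // inactivation
  double tauh = p[P_H_T0] + p[P_H_TA] / (1.0 + std::exp((V - p[P_H_TV]) / p[P_H_TK]));
  dy[2] = (hinf - h) / tauh;

  double dinf = sig(V, p[P_D_VH], p[P_D_K]);
  double taud = tau_gauss(V, p[P_D_T0], p[P_D_TA], p[P_D_TV], p[P_D_TS]);
  dy[3] = (dinf - d) / taud;

  double finf = 1.0 - sig(V, p[P_F_VH], p[P_F_K]);
  double tauf = tau_gauss(V, p[P_F_T0], p[P_F_TA], p[P_F_TV], p[P_F_TS]);
  dy[4] = (finf - f) / tauf;

  double xrinf = sig(V, p[P_XR_VH], p[P_XR_K]);
  double tauxr = tau_gauss(V, p[P_XR_T0], p[P_XR_TA], p[P_XR_TV], p[P_XR_TS]);
  dy[5] = (xrinf - xr) / tauxr;

  double xsinf = sig(V, p[P_XS_VH], p[P_XS_K]);
  double tauxs = tau_gauss(V, p[P_XS_T0], p[P_XS_TA], p[P_XS_TV], p[P_XS_TS]);
  dy[6] = (xsinf - xs) / tauxs;
}

static inline void init_state(const double *p, double v0, double *y) {
  y[0] = v0;
  y[1] = sig(v0, p[P_M_VH], p[P_M_K]);
  y[2] = 1.0 - sig(v0, p[P_H_VH], p[P_H_K]);
  y[3] = sig(v0, p[P_D_VH], p[P_D_K]);
  y[4] = 1.0 - sig(v0, p[P_F_VH], p[P_F_K]);
  y[5] = sig(v0, p[P_XR_VH], p[P_XR_K]);
  y[6] = sig(v0, p[P_XS_VH], p[P_XS_K]);
}

static inline void rk4_step(const double *p, double *y, double istim, double dt) {
  double k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE], yt[NSTATE];
  derivs(p, y, istim, k1);
  for (int i = 0; i < NSTATE; ++i) yt[i] = y[i] + 0.5 * dt * k1[i];
  derivs(p, yt, istim, k2);
  for (int i = 0; i < NSTATE; ++i) yt[i] = y[i] + 0.5 * dt * k2[i];
  derivs(p, yt, istim, k3);
  for (int i = 0; i < NSTATE; ++i) yt[i] = y[i] + dt * k3[i];
  derivs(p, yt, istim, k4);
  for (int i = 0; i < NSTATE; ++i)
    y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// [[Rcpp::export(name = ".cell_run_cpp")]]
NumericMatrix cell_run_cpp(NumericVector par, double cycle_length_ms, int n_beats,
                           double dt_ms, double stim_amp, double stim_dur_ms,
                           double v_init) {
  if (par.size() != N_PAR) stop("parameter vector has wrong length");
  const double *p = REAL(par);
  long nstep = (long)std::llround(n_beats * cycle_length_ms / dt_ms);
  NumericMatrix out(nstep + 1, 2);
  double y[NSTATE];
  init_state(p, v_init, y);
  out(0, 0) = 0.0; out(0, 1) = y[0];
  for (long s = 0; s < nstep; ++s) {
    double t = s * dt_ms;
    double tb = time_in_beat(t, cycle_length_ms);
    double istim = (n_beats > 0 && tb < stim_dur_ms) ? stim_amp : 0.0;
    rk4_step(p, y, istim, dt_ms);
    if (!std::isfinite(y[0]))
      stop("numerical instability: non-finite membrane potential at t = %f ms (step %d)",
           t + dt_ms, (int)(s + 1));
    out(s + 1, 0) = t + dt_ms;
    out(s + 1, 1) = y[0];
  }
  return out;
}

struct BeatTracker {
  // online activation / APD90 bookkeeping for the final beat of each node
  double v_dia, v_peak, dvdt_max, t_act, t_repol;
  bool peaked, repolarized;
  void reset(double vnow) {
    v_dia = vnow; v_peak = vnow; dvdt_max = 0.0;
    t_act = NA_REAL; t_repol = NA_REAL;
    peaked = false; repolarized = false;
  }
};

// shared post-step bookkeeping for fiber solvers
static inline void track(BeatTracker &b, double vold, double vnew, double t, double dt) {
  double dvdt = (vnew - vold) / dt;
  if (dvdt > b.dvdt_max) { b.dvdt_max = dvdt; b.t_act = t; }
  if (vnew > b.v_peak) { b.v_peak = vnew; b.peaked = true; }
  if (b.peaked && !b.repolarized && R_finite(b.t_act)) {
    double v90 = b.v_peak - 0.9 * (b.v_peak - b.v_dia);
    if (vold > v90 && vnew <= v90) {
      double frac = (vold - v90) / (vold - vnew);
      b.t_repol = t - dt + frac * dt;
      b.repolarized = true;
    }
  }
}

static List fiber_core(NumericMatrix par_nodes, double dx_mm, int pacing_site,
                       double dt_ms, double cycle_length_ms, int n_beats,
                       double stim_amp, double stim_dur_ms, double v_init,
                       bool bidomain, double d_mono, double sig_i, double sig_e) {
  // one column of parameters per node (columns are contiguous in memory)
  int n = par_nodes.ncol();
  if (par_nodes.nrow() != N_PAR) stop("parameter matrix has wrong height");
  std::vector<double> y(n * NSTATE);
  for (int j = 0; j < n; ++j)
    init_state(&par_nodes(0, j), v_init, &y[j * NSTATE]);

  long nstep = (long)std::llround(n_beats * cycle_length_ms / dt_ms);
  double last_start = (n_beats - 1) * cycle_length_ms;
  std::vector<BeatTracker> bt(n);
  std::vector<double> vold(n), vnew(n), phi(n, 0.0);
  // tridiagonal workspace for the bidomain extracellular solve
  std::vector<double> cw(n), dw(n);
  bool tracking = false;

  int s_lo = std::max(0, pacing_site - 1), s_hi = std::min(n - 1, pacing_site + 1);

  for (long s = 0; s < nstep; ++s) {
    double t = s * dt_ms;
    double tb = time_in_beat(t, cycle_length_ms);
    double istim = (tb < stim_dur_ms) ? stim_amp : 0.0;

    if (!tracking && t >= last_start) {
      tracking = true;
      for (int j = 0; j < n; ++j) bt[j].reset(y[j * NSTATE]);
    }

    for (int j = 0; j < n; ++j) vold[j] = y[j * NSTATE];

    // reaction step
    for (int j = 0; j < n; ++j) {
      double st = (j >= s_lo && j <= s_hi) ? istim : 0.0;
      rk4_step(&par_nodes(0, j), &y[j * NSTATE], st, dt_ms);
    }

    // diffusion step (explicit, no-flux boundaries)
    double inv_dx2 = 1.0 / (dx_mm * dx_mm);
    if (!bidomain) {
      for (int j = 0; j < n; ++j) vnew[j] = y[j * NSTATE];
      for (int j = 0; j < n; ++j) {
        double vl = vnew[j == 0 ? 1 : j - 1];
        double vr = vnew[j == n - 1 ? n - 2 : j + 1];
        y[j * NSTATE] += dt_ms * d_mono * (vl - 2.0 * vnew[j] + vr) * inv_dx2;
      }
    } else {
      // solve (sig_i+sig_e) * Lap(phi_e) = -sig_i * Lap(Vm), phi_e[0] pinned to 0
      for (int j = 0; j < n; ++j) vnew[j] = y[j * NSTATE];
      std::vector<double> rhs(n);
      for (int j = 0; j < n; ++j) {
        double vl = vnew[j == 0 ? 1 : j - 1];
        double vr = vnew[j == n - 1 ? n - 2 : j + 1];
        rhs[j] = -sig_i * (vl - 2.0 * vnew[j] + vr) * inv_dx2;
      }
      double st = sig_i + sig_e;
      // tridiagonal: Neumann Laplacian rows scaled by st; first row replaced by phi[0]=0
      // Thomas algorithm
      double b0 = 1.0, c0 = 0.0, r0 = 0.0;
      cw[0] = c0 / b0; dw[0] = r0 / b0;
      for (int j = 1; j < n; ++j) {
        double aj, bj, cj, rj;
        if (j == n - 1) { aj = 2.0 * st * inv_dx2; bj = -2.0 * st * inv_dx2; cj = 0.0; }
        else { aj = st * inv_dx2; bj = -2.0 * st * inv_dx2; cj = st * inv_dx2; }
        rj = rhs[j];
        double m = bj - aj * cw[j - 1];
        cw[j] = cj / m;
        dw[j] = (rj - aj * dw[j - 1]) / m;
      }
      phi[n - 1] = dw[n - 1];
      for (int j = n - 2; j >= 0; --j) phi[j] = dw[j] - cw[j] * phi[j + 1];
      for (int j = 0; j < n; ++j) {
        double ul = vnew[j == 0 ? 1 : j - 1] + phi[j == 0 ? 1 : j - 1];
        double uc = vnew[j] + phi[j];
        double ur = vnew[j == n - 1 ? n - 2 : j + 1] + phi[j == n - 1 ? n - 2 : j + 1];
        y[j * NSTATE] += dt_ms * sig_i * (ul - 2.0 * uc + ur) * inv_dx2;
      }
    }

    for (int j = 0; j < n; ++j) {
      double v = y[j * NSTATE];
      if (!std::isfinite(v))
        stop("numerical instability: non-finite potential at node %d, t = %f ms", j + 1, t + dt_ms);
      if (tracking) track(bt[j], vold[j], v, t + dt_ms, dt_ms);
    }
  }

  NumericVector act(n), apd(n), vpk(n), dvm(n);
  LogicalVector cap(n);
  for (int j = 0; j < n; ++j) {
    bool captured = bt[j].dvdt_max > 5.0 && bt[j].v_peak > -10.0 && R_finite(bt[j].t_act);
    cap[j] = captured;
    act[j] = captured ? bt[j].t_act - last_start : NA_REAL;
    apd[j] = (captured && bt[j].repolarized) ? bt[j].t_repol - bt[j].t_act : NA_REAL;
    vpk[j] = bt[j].v_peak;
    dvm[j] = bt[j].dvdt_max;
  }
  return List::create(_["activation_ms"] = act, _["apd90_ms"] = apd,
                      _["v_peak_mv"] = vpk, _["dvdt_max"] = dvm,
                      _["captured"] = cap);
}

// [[Rcpp::export(name = ".fiber_run_cpp")]]
List fiber_run_cpp(NumericMatrix par_nodes, double dx_mm, double diffusion,
                   int pacing_site, double dt_ms, double cycle_length_ms,
                   int n_beats, double stim_amp, double stim_dur_ms, double v_init) {
  return fiber_core(par_nodes, dx_mm, pacing_site, dt_ms, cycle_length_ms, n_beats,
                    stim_amp, stim_dur_ms, v_init, false, diffusion, 0.0, 0.0);
}

// [[Rcpp::export(name = ".fiber_run_bidomain_cpp")]]
List fiber_run_bidomain_cpp(NumericMatrix par_nodes, double dx_mm, double sig_i,
                            double sig_e, int pacing_site, double dt_ms,
                            double cycle_length_ms, int n_beats, double stim_amp,
                            double stim_dur_ms, double v_init) {
  return fiber_core(par_nodes, dx_mm, pacing_site, dt_ms, cycle_length_ms, n_beats,
                    stim_amp, stim_dur_ms, v_init, true, 0.0, sig_i, sig_e);
}
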