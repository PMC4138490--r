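// Fixed-step backward-Euler integrator for the 13-compartment UBC model.
//
// Scheme (staggered, NEURON-like): per step the second-messenger cascade and
// the HH gates are advanced with exponential (Rush-Larsen) updates at the
// current voltage, the Markov Na occupancies are advanced implicitly, the
// branched-cable voltage system is solved implicitly (dense LU, n <= 14),
// and the calcium shells are updated implicitly from the freshly computed
// CaHVA current.  All ionic currents are linear in V once the gates are
// frozen, so the voltage solve is exact backward Euler; the GHK CaLVA
// current is treated as a constant source within the step (it is small and
// weakly voltage dependent on the dt = 0.025 ms scale used here).
//
// Units: mV, ms, nA, uS, nF, mM.  Absolute conductances are precomputed on
// the R side from densities (S/cm2) and areas.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>

using namespace Rcpp;

static const double FARADAY = 96485.332;   // C/mol
static const double GASCONST = 8.314462618; // J/(mol K)

enum MechKind {
  MECH_LEAK = 0, MECH_TRP = 1, MECH_H = 2, MECH_NA = 3, MECH_KV = 4,
  MECH_KA = 5, MECH_KCA = 6, MECH_KSLOW = 7, MECH_CAHVA = 8, MECH_CALVA = 9
};

// ---------------------------------------------------------------------------
// rate helpers (all rates 1/ms, v in mV, ca in mM)

static inline double sigm(double v, double vhalf, double k) {
  return 1.0 / (1.0 + std::exp(-(v - vhalf) / k));
}

// KV delayed rectifier (activation m^3, slow inactivation h)
static inline void kv_gates(double v, double taum_scale, double tauh_scale,
                            double &minf, double &taum, double &hinf, double &tauh) {
  minf = 1.0 / (1.0 + std::exp(-(v + 24.0) / 15.4));
  taum = taum_scale * 1000.0 * (3.4225e-5 + 0.00498 * std::exp(-v / 28.29));
  hinf = 0.31 + 0.69 / (1.0 + std::exp((v + 5.802) / 11.2));
  tauh = tauh_scale * 1000.0 * (0.0012 + 0.0023 * std::exp(-0.141 * v));
}

// KA A-type (a^3 b)
static inline void ka_gates(double v, double &ainf, double &taua,
                            double &binf, double &taub) {
  double aa = 4.88826 / (1.0 + std::exp(-(v + 9.197) / 23.327));
  double ba = 0.99285 * std::exp(-(v + 18.2791) / 19.4717);
  double ab = 0.11 / (1.0 + std::exp((v + 111.33) / 12.84));
  double bb = 0.1 / (1.0 + std::exp(-(v + 49.95) / 8.9));
  ainf = 1.0 / (1.0 + std::exp(-(v + 38.0) / 17.0));
  taua = 1.0 / (aa + ba);
  binf = 1.0 / (1.0 + std::exp((v + 78.8) / 8.4));
  taub = 1.0 / (ab + bb);
}

// KCa (BK) calcium- and voltage-dependent, single gate
static inline void kca_rates_cpp(double v, double ca, double &alpha, double &beta) {
  alpha = 2.5 / (1.0 + (1.5e-3 * std::exp(-v / 11.765)) / ca);
  beta  = 1.5 / (1.0 + ca / (1.5e-4 * std::exp(-v / 11.765)));
}

// Kslow (M-type), single gate; steady state from its own Boltzmann, tau from rates
static inline void kslow_gates(double v, double &ninf, double &taun) {
  double a = 0.0033 * std::exp((v + 30.0) / 40.0);
  double b = 0.0033 * std::exp(-(v + 30.0) / 20.0);
  ninf = 1.0 / (1.0 + std::exp(-(v + 45.0) / 6.0));
  taun = 1.0 / (a + b);
}

// CaHVA (L-type) s^2 u
static inline void cahva_gates(double v, double &sinf, double &taus,
                               double &uinf, double &tauu) {
  double as = 0.04944 * std::exp((v + 29.06) / 15.87);
  double bs = 0.08298 * std::exp(-(v + 18.66) / 25.641);
  double au = 0.0013 * std::exp(-(v + 48.0) / 18.183);
  double bu = 0.0013 * std::exp((v + 48.0) / 83.33);
  sinf = as / (as + bs); taus = 1.0 / (as + bs);
  uinf = au / (au + bu); tauu = 1.0 / (au + bu);
}

// CaLVA (T-type) m^2 h, explicit inf/tau forms
static inline void calva_gates(double v, double &minf, double &taum,
                               double &hinf, double &tauh) {
  minf = 1.0 / (1.0 + std::exp(-(v + 52.0) / 5.0));
  taum = 1.0 + 1.0 / (std::exp((v + 40.0) / 9.0) + std::exp(-(v + 102.0) / 18.0));
  hinf = 1.0 / (1.0 + std::exp((v + 72.0) / 7.0));
  tauh = 15.0 + std::exp(-(v + 32.0) / 7.0);
}

// H (HCN) single gate; vhalf is cascade-modulated
static inline void h_gates(double v, double vhalf, double slope, int tau_mode,
                           double ta, double ka, double tb, double kb,
                           double tau_scale,
                           double &linf, double &taul) {
  linf = 1.0 / (1.0 + std::exp((v - vhalf) / slope));
  if (tau_mode == 0) { // calibrated two-exponential bell
    double x = v + 91.5;
    taul = tau_scale / (ta * std::exp(-x / ka) + tb * std::exp(x / kb));
  } else {             // expression as printed
    double x = v + 91.5;
    taul = tau_scale * std::exp(0.13 * x) / (0.00225 * (1.0 + std::exp(0.2 * x)));
  }
}

// GHK flux factor for a divalent ion: I (nA) = P*A (cm^3/s) * gates * factor
// factor = z F x (ci - co e^{-x}) / (1 - e^{-x}) * 1e3, ci/co in mM
static inline double ghk_factor(double v_mV, double ci, double co, double temp_K) {
  const double z = 2.0;
  double x = z * FARADAY * (v_mV * 1e-3) / (GASCONST * temp_K);
  double ratio;
  if (std::fabs(x) < 1e-4) {
    // series expansion around the removable singularity at v = 0
    ratio = (ci - co) + x * (co + (ci - co) / 2.0);
  } else {
    ratio = x * (ci - co * std::exp(-x)) / (1.0 - std::exp(-x));
  }
  return z * FARADAY * ratio * 1e3;
}

// ---------------------------------------------------------------------------
// 13-state resurgent Na Markov scheme (Raman-Bean / Khaliq-type)
// states: C1..C5 (0-4), O (5), B (6, open-blocked), I1..I6 (7-12)

static const int NA_NSTATE = 13;

struct NaParams {
  double alpha_a, valpha, beta_a, vbeta; // alpha = alpha_a exp(v/valpha) etc.
  double gamma, delta, epsilon;
  double zeta_a, vzeta;
  double Con, Coff, Oon, Ooff;
  double v_shift; // rates evaluated at v - v_shift (scheme adapted to fit)
};

// fill A (column-convention: ds/dt = A s, A[to][from]) scaled by q
static void na_rate_matrix(double v, const NaParams &p, double q,
                           double A[NA_NSTATE][NA_NSTATE]) {
  double vs = v - p.v_shift;
  double al = p.alpha_a * std::exp(vs / p.valpha);
  double be = p.beta_a * std::exp(-vs / p.vbeta);
  double ze = p.zeta_a * std::exp(-vs / p.vzeta);
  double a = std::pow(p.Oon / p.Con, 0.25);
  double b = std::pow(p.Ooff / p.Coff, 0.25);
  std::memset(A, 0, sizeof(double) * NA_NSTATE * NA_NSTATE);
  // helper lambda to add a transition from -> to with rate r
  auto add = [&](int from, int to, double r) {
    A[to][from] += r * q;
    A[from][from] -= r * q;
  };
  // closed chain
  add(0, 1, 4.0 * al); add(1, 0, be);
  add(1, 2, 3.0 * al); add(2, 1, 2.0 * be);
  add(2, 3, 2.0 * al); add(3, 2, 3.0 * be);
  add(3, 4, al);       add(4, 3, 4.0 * be);
  add(4, 5, p.gamma);  add(5, 4, p.delta);
  // open <-> blocked
  add(5, 6, p.epsilon); add(6, 5, ze);
  // open <-> I6
  add(5, 12, p.Oon); add(12, 5, p.Ooff);
  // closed <-> inactivated
  for (int i = 0; i < 5; ++i) {
    add(i, 7 + i, p.Con * std::pow(a, i));
    add(7 + i, i, p.Coff * std::pow(b, i));
  }
  // inactivated chain
  add(7, 8, 4.0 * al * a);  add(8, 7, be * b);
  add(8, 9, 3.0 * al * a);  add(9, 8, 2.0 * be * b);
  add(9, 10, 2.0 * al * a); add(10, 9, 3.0 * be * b);
  add(10, 11, al * a);      add(11, 10, 4.0 * be * b);
  add(11, 12, p.gamma);     add(12, 11, p.delta);
}

// dense linear solve with partial pivoting, in place; n small
static void lu_solve(int n, double *M, double *b) {
  std::vector<int> piv(n);
  for (int i = 0; i < n; ++i) piv[i] = i;
  for (int k = 0; k < n; ++k) {
    int p = k;
    double mx = std::fabs(M[k * n + k]);
    for (int i = k + 1; i < n; ++i) {
      double a = std::fabs(M[i * n + k]);
      if (a > mx) { mx = a; p = i; }
    }
    if (p != k) {
      for (int j = 0; j < n; ++j) std::swap(M[k * n + j], M[p * n + j]);
      std::swap(b[k], b[p]);
    }
    double pivv = M[k * n + k];
    for (int i = k + 1; i < n; ++i) {
      double f = M[i * n + k] / pivv;
      if (f == 0.0) continue;
      for (int j = k; j < n; ++j) M[i * n + j] -= f * M[k * n + j];
      b[i] -= f * b[k];
    }
  }
  for (int i = n - 1; i >= 0; --i) {
    double s = b[i];
    for (int j = i + 1; j < n; ++j) s -= M[i * n + j] * b[j];
    b[i] = s / M[i * n + i];
  }
}

// Markov rate matrix exposed to R for testing
// [[Rcpp::export(name = ".na_rate_matrix_cpp")]]
NumericMatrix na_rate_matrix_cpp(double v, List pars, double q) {
  NaParams p;
  p.alpha_a = pars["alpha_a"]; p.valpha = pars["valpha"];
  p.beta_a = pars["beta_a"];   p.vbeta = pars["vbeta"];
  p.gamma = pars["gamma"];     p.delta = pars["delta"];
  p.epsilon = pars["epsilon"];
  p.zeta_a = pars["zeta_a"];   p.vzeta = pars["vzeta"];
  p.Con = pars["Con"]; p.Coff = pars["Coff"];
  p.Oon = pars["Oon"]; p.Ooff = pars["Ooff"];
  p.v_shift = pars.containsElementNamed("v_shift") ?
      as<double>(pars["v_shift"]) : 0.0;
  double A[NA_NSTATE][NA_NSTATE];
  na_rate_matrix(v, p, q, A);
  NumericMatrix out(NA_NSTATE, NA_NSTATE);
  for (int i = 0; i < NA_NSTATE; ++i)
    for (int j = 0; j < NA_NSTATE; ++j)
      out(i, j) = A[i][j];
  return out;
}

// ---------------------------------------------------------------------------

struct Mech {
  int kind;
  std::vector<double> g;     // uS per compartment (or P*A in cm^3/s for CaLVA)
  double erev;
  double q;                  // temperature rate multiplier
  double q2;                 // inactivation-rate multiplier (CaLVA Q10 split)
  // H extras
  double h_vhalf, h_slope, h_ta, h_ka, h_tb, h_kb, h_tau_scale;
  int h_tau_mode;
  double trp_baseline;
  double kv_taum_scale, kv_tauh_scale;
  NaParams na;
  int ngate;
  // state: gates[gate][comp]
  std::vector< std::vector<double> > gate;
  // markov state per compartment
  std::vector< std::vector<double> > mstate;
};

struct Cascade {
  double omega, tau, beta, x_total, x_half, k, gamma, y_total, delta_max;
  double trp_baseline, h_shift_max, h_shift_mid, h_shift_slope;
  double x_star, y_star;
};

static inline double cascade_alpha(double t, const std::vector<double> &pulses,
                                   double omega, double tau) {
  double a = 0.0;
  for (size_t i = 0; i < pulses.size(); ++i)
    if (t >= pulses[i] && t < pulses[i] + tau) a += omega;
  return a;
}

static inline double cascade_delta(double xs, const Cascade &c) {
  // logistic in X*, anchored so that zero drive gives exactly zero
  // conversion (the raw logistic has a small floor at X* = 0)
  double L = 1.0 / (1.0 + std::exp(-(xs - c.x_half) * c.k));
  double L0 = 1.0 / (1.0 + std::exp(c.x_half * c.k));
  double d = c.delta_max * (L - L0) / (1.0 - L0);
  return d > 0.0 ? d : 0.0;
}

static inline double h_vhalf_mod(double ynorm, double base, const Cascade &c) {
  return base + c.h_shift_max / (1.0 + std::exp((c.h_shift_mid - ynorm) / c.h_shift_slope));
}

// [[Rcpp::export(name = ".run_ubc_engine")]]
List run_ubc_engine(List model, List proto) {
  // ---- unpack model ----
  const int n = as<int>(model["n_comp"]);
  NumericVector cap = model["cap"];          // nF
  IntegerVector parent = model["parent"];    // 0-based, -1 root
  NumericVector gax = model["g_axial"];      // uS to parent
  const double temp_c = as<double>(model["temperature"]);
  const double temp_k = temp_c + 273.15;

  List mlist = model["mechs"];
  const int nm = mlist.size();
  std::vector<Mech> mech(nm);
  int idx_calva = -1, idx_cahva = -1, idx_h = -1, idx_trp = -1;
  for (int m = 0; m < nm; ++m) {
    List mm = mlist[m];
    Mech &M = mech[m];
    M.kind = as<int>(mm["kind"]);
    NumericVector g = mm["g_abs"];
    M.g.assign(g.begin(), g.end());
    M.erev = as<double>(mm["erev"]);
    M.q = as<double>(mm["q"]);
    M.q2 = mm.containsElementNamed("q2") ? as<double>(mm["q2"]) : M.q;
    M.ngate = 0;
    switch (M.kind) {
      case MECH_LEAK: case MECH_TRP: M.ngate = 0; break;
      case MECH_H: M.ngate = 1; break;
      case MECH_KV: case MECH_KA: case MECH_CAHVA: case MECH_CALVA: M.ngate = 2; break;
      case MECH_KCA: case MECH_KSLOW: M.ngate = 1; break;
      case MECH_NA: M.ngate = 0; break;
    }
    if (M.kind == MECH_H) {
      idx_h = m;
      M.h_vhalf = as<double>(mm["vhalf"]);
      M.h_slope = as<double>(mm["slope"]);
      M.h_tau_mode = as<int>(mm["tau_mode"]);
      M.h_ta = as<double>(mm["tau_a"]); M.h_ka = as<double>(mm["tau_ka"]);
      M.h_tb = as<double>(mm["tau_b"]); M.h_kb = as<double>(mm["tau_kb"]);
      M.h_tau_scale = as<double>(mm["tau_scale"]);
    }
    if (M.kind == MECH_TRP) { idx_trp = m; M.trp_baseline = as<double>(mm["baseline"]); }
    if (M.kind == MECH_KV) {
      M.kv_taum_scale = as<double>(mm["taum_scale"]);
      M.kv_tauh_scale = as<double>(mm["tauh_scale"]);
    }
    if (M.kind == MECH_CALVA) idx_calva = m;
    if (M.kind == MECH_CAHVA) idx_cahva = m;
    if (M.kind == MECH_NA) {
      List np = mm["markov"];
      M.na.alpha_a = np["alpha_a"]; M.na.valpha = np["valpha"];
      M.na.beta_a = np["beta_a"];   M.na.vbeta = np["vbeta"];
      M.na.gamma = np["gamma"];     M.na.delta = np["delta"];
      M.na.epsilon = np["epsilon"];
      M.na.zeta_a = np["zeta_a"];   M.na.vzeta = np["vzeta"];
      M.na.Con = np["Con"]; M.na.Coff = np["Coff"];
      M.na.Oon = np["Oon"]; M.na.Ooff = np["Ooff"];
      M.na.v_shift = np.containsElementNamed("v_shift") ?
          as<double>(np["v_shift"]) : 0.0;
    }
    M.gate.assign(M.ngate, std::vector<double>(n, 0.0));
    if (M.kind == MECH_NA)
      M.mstate.assign(NA_NSTATE, std::vector<double>(n, 0.0));
  }

  // calcium shells
  List calist = model["ca"];
  LogicalVector has_shell = calist["has_shell"];
  NumericVector kflux = calist["kflux"];     // mM per (nA*ms)
  const double ca_beta = as<double>(calist["beta"]);
  const double ca0 = as<double>(calist["ca0"]);
  const double cao = as<double>(calist["cao"]);

  // cascade
  List cl = model["cascade"];
  Cascade casc;
  casc.omega = cl["omega"]; casc.tau = cl["tau"]; casc.beta = cl["beta"];
  casc.x_total = cl["x_total"]; casc.x_half = cl["x_half"]; casc.k = cl["k"];
  casc.gamma = cl["gamma"]; casc.y_total = cl["y_total"];
  casc.delta_max = cl["delta_max"];
  casc.h_shift_max = cl["h_shift_max"]; casc.h_shift_mid = cl["h_shift_mid"];
  casc.h_shift_slope = cl["h_shift_slope"];
  casc.x_star = 0.0; casc.y_star = 0.0;

  // ---- unpack protocol ----
  const double dt = as<double>(proto["dt"]);
  const double t_total = as<double>(proto["t_total"]);
  const double record_dt = as<double>(proto["record_dt"]);
  const double v_init = as<double>(proto["v_init"]);
  const double i_bias = as<double>(proto["i_bias"]);
  NumericMatrix steps = proto["steps"];      // t0, t1, amp (nA), may be 0-row
  const bool vc_on = as<bool>(proto["vc_on"]);
  double g_clamp = 0.0;
  NumericMatrix vc_seg(0, 3);
  if (vc_on) {
    g_clamp = 1.0 / as<double>(proto["vc_rs"]); // uS = 1/MOhm (uS*mV = nA)
    vc_seg = as<NumericMatrix>(proto["vc_segments"]);          // t0, t1, v_cmd
  }
  std::vector<double> pulses;
  {
    NumericVector pv = proto["pulses"];
    pulses.assign(pv.begin(), pv.end());
  }
  const double omega_scale = as<double>(proto["omega_scale"]);

  const long nsteps = (long)std::llround(t_total / dt);
  const int rec_stride = std::max(1, (int)std::llround(record_dt / dt));
  const long nrec = nsteps / rec_stride + 1;

  // ---- state init ----
  std::vector<double> v(n, v_init);
  bool has_init = proto.containsElementNamed("init_state") &&
                  !Rf_isNull(proto["init_state"]);
  // gate init at steady state for v_init (or from provided state below)
  double eca_init = (GASCONST * temp_k / (2.0 * FARADAY)) * std::log(cao / ca0) * 1e3;
  std::vector<double> ca(n, ca0);
  double ynorm0 = 0.0;
  for (int m = 0; m < nm; ++m) {
    Mech &M = mech[m];
    for (int i = 0; i < n; ++i) {
      double g1, t1, g2, t2;
      switch (M.kind) {
        case MECH_H: {
          double vh = h_vhalf_mod(ynorm0, M.h_vhalf, casc);
          h_gates(v[i], vh, M.h_slope, M.h_tau_mode, M.h_ta, M.h_ka, M.h_tb,
                  M.h_kb, M.h_tau_scale, g1, t1);
          M.gate[0][i] = g1;
        } break;
        case MECH_KV:
          kv_gates(v[i], M.kv_taum_scale, M.kv_tauh_scale, g1, t1, g2, t2);
          M.gate[0][i] = g1; M.gate[1][i] = g2; break;
        case MECH_KA:
          ka_gates(v[i], g1, t1, g2, t2);
          M.gate[0][i] = g1; M.gate[1][i] = g2; break;
        case MECH_KCA: {
          double a, b; kca_rates_cpp(v[i], ca[i] > 0 ? ca[i] : ca0, a, b);
          M.gate[0][i] = a / (a + b);
        } break;
        case MECH_KSLOW:
          kslow_gates(v[i], g1, t1); M.gate[0][i] = g1; break;
        case MECH_CAHVA:
          cahva_gates(v[i], g1, t1, g2, t2);
          M.gate[0][i] = g1; M.gate[1][i] = g2; break;
        case MECH_CALVA:
          calva_gates(v[i], g1, t1, g2, t2);
          M.gate[0][i] = g1; M.gate[1][i] = g2; break;
        case MECH_NA: {
          // stationary distribution: solve A s = 0 with sum(s) = 1
          double A[NA_NSTATE][NA_NSTATE];
          na_rate_matrix(v[i], M.na, M.q, A);
          double Mx[NA_NSTATE * NA_NSTATE], b[NA_NSTATE];
          for (int r = 0; r < NA_NSTATE; ++r) {
            for (int c2 = 0; c2 < NA_NSTATE; ++c2)
              Mx[r * NA_NSTATE + c2] = (r == NA_NSTATE - 1) ? 1.0 : A[r][c2];
            b[r] = (r == NA_NSTATE - 1) ? 1.0 : 0.0;
          }
          lu_solve(NA_NSTATE, Mx, b);
          for (int s = 0; s < NA_NSTATE; ++s)
            M.mstate[s][i] = std::max(b[s], 0.0);
          double sum = 0.0;
          for (int s = 0; s < NA_NSTATE; ++s) sum += M.mstate[s][i];
          for (int s = 0; s < NA_NSTATE; ++s) M.mstate[s][i] /= sum;
        } break;
        default: break;
      }
    }
  }

  if (has_init) {
    List st = proto["init_state"];
    NumericVector vv = st["v"];
    for (int i = 0; i < n; ++i) v[i] = vv[i];
    NumericVector cc = st["ca"];
    for (int i = 0; i < n; ++i) ca[i] = cc[i];
    NumericVector cs = st["cascade"];
    casc.x_star = cs[0]; casc.y_star = cs[1];
    List gl = st["gates"];
    for (int m = 0; m < nm; ++m) {
      Mech &M = mech[m];
      if (M.ngate > 0) {
        NumericMatrix gm = gl[m];
        for (int g = 0; g < M.ngate; ++g)
          for (int i = 0; i < n; ++i) M.gate[g][i] = gm(g, i);
      }
      if (M.kind == MECH_NA) {
        NumericMatrix sm = st["markov"];
        for (int s = 0; s < NA_NSTATE; ++s)
          for (int i = 0; i < n; ++i) M.mstate[s][i] = sm(s, i);
      }
    }
  }

  // ---- recording buffers ----
  NumericVector rec_t(nrec);
  NumericMatrix rec_v(nrec, n);
  const int nscal = 10;
  // alpha, x_star, y_star_norm, delta, trp_factor, h_vhalf, i_inj, i_clamp,
  // ca_soma-like slots are in rec_ca
  NumericMatrix rec_scal(nrec, nscal);
  NumericMatrix rec_ca(nrec, n);
  // total current per mechanism (nA, summed over compartments, outward > 0)
  NumericMatrix rec_imech(nrec, nm);
  // Markov occupancy diagnostics: max |sum - 1| over run
  double max_occ_err = 0.0;
  // open-state of Na at soma (comp 0) for diagnostics
  NumericVector rec_naopen(nrec);

  std::vector<double> Mx((n) * (n)), bv(n);
  std::vector<double> gsum(n), isrc(n);

  long irec = 0;
  double ynorm = casc.y_star / casc.y_total;

  auto inj_at = [&](double t) {
    double I = i_bias;
    for (int r = 0; r < steps.nrow(); ++r)
      if (t >= steps(r, 0) && t < steps(r, 1)) I += steps(r, 2);
    return I;
  };
  auto vcmd_at = [&](double t) {
    double vc = vc_seg.nrow() > 0 ? vc_seg(0, 2) : v_init;
    for (int r = 0; r < vc_seg.nrow(); ++r)
      if (t >= vc_seg(r, 0) && t < vc_seg(r, 1)) vc = vc_seg(r, 2);
    return vc;
  };

  // record helper computes currents from current state
  double cur_alpha = 0.0, cur_delta = 0.0, cur_iinj = 0.0, cur_iclamp = 0.0;
  auto record = [&](double t) {
    rec_t[irec] = t;
    for (int i = 0; i < n; ++i) { rec_v(irec, i) = v[i]; rec_ca(irec, i) = ca[i]; }
    ynorm = casc.y_star / casc.y_total;
    rec_scal(irec, 0) = cur_alpha;
    rec_scal(irec, 1) = casc.x_star;
    rec_scal(irec, 2) = ynorm;
    rec_scal(irec, 3) = cur_delta;
    rec_scal(irec, 4) = (idx_trp >= 0 ? mech[idx_trp].trp_baseline : 0.0) + ynorm;
    rec_scal(irec, 5) = idx_h >= 0 ? h_vhalf_mod(ynorm, mech[idx_h].h_vhalf, casc) : NA_REAL;
    rec_scal(irec, 6) = cur_iinj;
    rec_scal(irec, 7) = cur_iclamp;
    rec_scal(irec, 8) = 0.0; // reserved
    rec_scal(irec, 9) = 0.0;
    for (int m = 0; m < nm; ++m) {
      double itot = 0.0;
      Mech &M = mech[m];
      for (int i = 0; i < n; ++i) {
        if (M.g[i] <= 0.0) continue;
        double gg = M.g[i], cur = 0.0;
        switch (M.kind) {
          case MECH_LEAK: cur = gg * (v[i] - M.erev); break;
          case MECH_TRP: cur = gg * (M.trp_baseline + ynorm) * (v[i] - M.erev); break;
          case MECH_H: cur = gg * M.gate[0][i] * (v[i] - M.erev); break;
          case MECH_KV: cur = gg * std::pow(M.gate[0][i], 3) * M.gate[1][i] * (v[i] - M.erev); break;
          case MECH_KA: cur = gg * std::pow(M.gate[0][i], 3) * M.gate[1][i] * (v[i] - M.erev); break;
          case MECH_KCA: cur = gg * M.gate[0][i] * (v[i] - M.erev); break;
          case MECH_KSLOW: cur = gg * M.gate[0][i] * (v[i] - M.erev); break;
          case MECH_CAHVA: {
            double eca = (GASCONST * temp_k / (2.0 * FARADAY)) *
                         std::log(cao / ca[i]) * 1e3;
            cur = gg * M.gate[0][i] * M.gate[0][i] * M.gate[1][i] * (v[i] - eca);
          } break;
          case MECH_CALVA:
            cur = gg * M.gate[0][i] * M.gate[0][i] * M.gate[1][i] *
                  ghk_factor(v[i], ca0, cao, temp_k);
            break;
          case MECH_NA: cur = gg * M.mstate[5][i] * (v[i] - M.erev); break;
        }
        itot += cur;
      }
      rec_imech(irec, m) = itot;
    }
    int na_m = -1;
    for (int m = 0; m < nm; ++m) if (mech[m].kind == MECH_NA) na_m = m;
    rec_naopen[irec] = na_m >= 0 ? mech[na_m].mstate[5][0] : NA_REAL;
    ++irec;
  };

  cur_iinj = inj_at(0.0);
  record(0.0);

  // ---- main loop ----
  for (long k = 0; k < nsteps; ++k) {
    double t = k * dt;        // state currently at t; advance to t + dt
    // 1. cascade (exponential updates; alpha held over the step)
    cur_alpha = cascade_alpha(t, pulses, casc.omega * omega_scale, casc.tau);
    {
      double r = cur_alpha + casc.beta;
      double xinf = r > 0 ? casc.x_total * cur_alpha / r : 0.0;
      casc.x_star = r > 0 ? xinf + (casc.x_star - xinf) * std::exp(-r * dt)
                          : casc.x_star;
      cur_delta = cascade_delta(casc.x_star, casc);
      double r2 = cur_delta + casc.gamma;
      double yinf = r2 > 0 ? casc.y_total * cur_delta / r2 : 0.0;
      casc.y_star = r2 > 0 ? yinf + (casc.y_star - yinf) * std::exp(-r2 * dt)
                           : casc.y_star;
    }
    ynorm = casc.y_star / casc.y_total;

    // 2. gates (Rush-Larsen at v(t)); Markov implicit
    for (int m = 0; m < nm; ++m) {
      Mech &M = mech[m];
      bool any = false;
      for (int i = 0; i < n; ++i) if (M.g[i] > 0.0) { any = true; break; }
      if (!any) continue;
      for (int i = 0; i < n; ++i) {
        if (M.g[i] <= 0.0 && M.kind != MECH_NA) continue;
        if (M.g[i] <= 0.0) continue;
        double inf1, tau1, inf2, tau2;
        switch (M.kind) {
          case MECH_H: {
            double vh = h_vhalf_mod(ynorm, M.h_vhalf, casc);
            h_gates(v[i], vh, M.h_slope, M.h_tau_mode, M.h_ta, M.h_ka,
                    M.h_tb, M.h_kb, M.h_tau_scale, inf1, tau1);
            tau1 /= M.q;
            M.gate[0][i] = inf1 + (M.gate[0][i] - inf1) * std::exp(-dt / tau1);
          } break;
          case MECH_KV:
            kv_gates(v[i], M.kv_taum_scale, M.kv_tauh_scale, inf1, tau1, inf2, tau2);
            tau1 /= M.q; tau2 /= M.q;
            M.gate[0][i] = inf1 + (M.gate[0][i] - inf1) * std::exp(-dt / tau1);
            M.gate[1][i] = inf2 + (M.gate[1][i] - inf2) * std::exp(-dt / tau2);
            break;
          case MECH_KA:
            ka_gates(v[i], inf1, tau1, inf2, tau2);
            tau1 /= M.q; tau2 /= M.q;
            M.gate[0][i] = inf1 + (M.gate[0][i] - inf1) * std::exp(-dt / tau1);
            M.gate[1][i] = inf2 + (M.gate[1][i] - inf2) * std::exp(-dt / tau2);
            break;
          case MECH_KCA: {
            double a, b; kca_rates_cpp(v[i], std::max(ca[i], 1e-9), a, b);
            a *= M.q; b *= M.q;
            double inf = a / (a + b), tg = 1.0 / (a + b);
            M.gate[0][i] = inf + (M.gate[0][i] - inf) * std::exp(-dt / tg);
          } break;
          case MECH_KSLOW:
            kslow_gates(v[i], inf1, tau1);
            tau1 /= M.q;
            M.gate[0][i] = inf1 + (M.gate[0][i] - inf1) * std::exp(-dt / tau1);
            break;
          case MECH_CAHVA:
            cahva_gates(v[i], inf1, tau1, inf2, tau2);
            tau1 /= M.q; tau2 /= M.q;
            M.gate[0][i] = inf1 + (M.gate[0][i] - inf1) * std::exp(-dt / tau1);
            M.gate[1][i] = inf2 + (M.gate[1][i] - inf2) * std::exp(-dt / tau2);
            break;
          case MECH_CALVA: {
            // Q10 = 5 on activation, Q10 = 3 (plus tau scale) on
            // inactivation: q vs q2
            calva_gates(v[i], inf1, tau1, inf2, tau2);
            tau1 /= M.q; tau2 /= M.q2;
            M.gate[0][i] = inf1 + (M.gate[0][i] - inf1) * std::exp(-dt / tau1);
            M.gate[1][i] = inf2 + (M.gate[1][i] - inf2) * std::exp(-dt / tau2);
          } break;
          case MECH_NA: {
            double A[NA_NSTATE][NA_NSTATE];
            na_rate_matrix(v[i], M.na, M.q, A);
            double Mm[NA_NSTATE * NA_NSTATE], b[NA_NSTATE];
            for (int r = 0; r < NA_NSTATE; ++r) {
              for (int c2 = 0; c2 < NA_NSTATE; ++c2)
                Mm[r * NA_NSTATE + c2] = (r == c2 ? 1.0 : 0.0) - dt * A[r][c2];
              b[r] = M.mstate[r][i];
            }
            lu_solve(NA_NSTATE, Mm, b);
            double sum = 0.0;
            for (int s = 0; s < NA_NSTATE; ++s) {
              if (b[s] < 0.0) b[s] = 0.0;
              sum += b[s];
            }
            double err = std::fabs(sum - 1.0);
            if (err > max_occ_err) max_occ_err = err;
            for (int s = 0; s < NA_NSTATE; ++s) M.mstate[s][i] = b[s] / sum;
          } break;
          default: break;
        }
      }
    }

    // 3. implicit voltage solve
    double tn = t + dt;
    // stimulus evaluated at the interval start: piecewise-constant
    // sources then have dt-independent timing
    cur_iinj = vc_on ? 0.0 : inj_at(t);
    std::fill(gsum.begin(), gsum.end(), 0.0);
    std::fill(isrc.begin(), isrc.end(), 0.0);
    for (int m = 0; m < nm; ++m) {
      Mech &M = mech[m];
      for (int i = 0; i < n; ++i) {
        if (M.g[i] <= 0.0) continue;
        double gg = 0.0, e = M.erev;
        switch (M.kind) {
          case MECH_LEAK: gg = M.g[i]; break;
          case MECH_TRP: gg = M.g[i] * (M.trp_baseline + ynorm); break;
          case MECH_H: gg = M.g[i] * M.gate[0][i]; break;
          case MECH_KV: case MECH_KA:
            gg = M.g[i] * std::pow(M.gate[0][i], 3) * M.gate[1][i]; break;
          case MECH_KCA: case MECH_KSLOW: gg = M.g[i] * M.gate[0][i]; break;
          case MECH_CAHVA: {
            gg = M.g[i] * M.gate[0][i] * M.gate[0][i] * M.gate[1][i];
            e = (GASCONST * temp_k / (2.0 * FARADAY)) * std::log(cao / ca[i]) * 1e3;
          } break;
          case MECH_CALVA: {
            // GHK current as constant source within the step
            // C dV/dt = -(sum ionic) + inj, so an outward-positive constant
            // ionic current enters the rhs with a minus sign
            double cur = M.g[i] * M.gate[0][i] * M.gate[0][i] * M.gate[1][i] *
                         ghk_factor(v[i], ca0, cao, temp_k);
            isrc[i] -= cur;
            break;
          }
          case MECH_NA: gg = M.g[i] * M.mstate[5][i]; break;
        }
        if (gg > 0.0) { gsum[i] += gg; isrc[i] += gg * e; }
      }
    }
    // assemble M V = b
    std::fill(Mx.begin(), Mx.end(), 0.0);
    double vcmd = vcmd_at(t);
    for (int i = 0; i < n; ++i) {
      double diag = cap[i] / dt + gsum[i];
      double rhs = cap[i] / dt * v[i] + isrc[i];
      if (!vc_on && i == 0) rhs += cur_iinj;
      if (vc_on && i == 0) { diag += g_clamp; rhs += g_clamp * vcmd; }
      if (parent[i] >= 0) {
        int p = parent[i];
        diag += gax[i];
        Mx[i * n + p] -= gax[i];
        Mx[p * n + p] += gax[i];
        Mx[p * n + i] -= gax[i];
      }
      Mx[i * n + i] += diag;
      bv[i] = rhs;
    }
    lu_solve(n, Mx.data(), bv.data());
    for (int i = 0; i < n; ++i) v[i] = bv[i];
    if (!std::isfinite(v[0]))
      stop("voltage diverged (NaN/Inf) at t = %f ms", tn);
    cur_iclamp = vc_on ? g_clamp * (vcmd - v[0]) : 0.0;

    // 4. calcium shells (implicit), fed by CaHVA only
    if (idx_cahva >= 0) {
      Mech &M = mech[idx_cahva];
      for (int i = 0; i < n; ++i) {
        if (!has_shell[i]) continue;
        double eca = (GASCONST * temp_k / (2.0 * FARADAY)) * std::log(cao / ca[i]) * 1e3;
        double ica = M.g[i] * M.gate[0][i] * M.gate[0][i] * M.gate[1][i] * (v[i] - eca);
        double J = -ica * kflux[i];       // mM/ms, influx positive
        ca[i] = (ca[i] + dt * (J + ca_beta * ca0)) / (1.0 + dt * ca_beta);
        if (ca[i] < 1e-9) ca[i] = 1e-9;
      }
    }

    if ((k + 1) % rec_stride == 0) record(tn);
  }

  // ---- final state snapshot ----
  List gl(nm);
  NumericMatrix msnap(NA_NSTATE, n);
  for (int m = 0; m < nm; ++m) {
    Mech &M = mech[m];
    NumericMatrix gm(std::max(M.ngate, 1), n);
    for (int g = 0; g < M.ngate; ++g)
      for (int i = 0; i < n; ++i) gm(g, i) = M.gate[g][i];
    gl[m] = gm;
    if (M.kind == MECH_NA)
      for (int s = 0; s < NA_NSTATE; ++s)
        for (int i = 0; i < n; ++i) msnap(s, i) = M.mstate[s][i];
  }
  NumericVector vf(n), cf(n);
  for (int i = 0; i < n; ++i) { vf[i] = v[i]; cf[i] = ca[i]; }

  return List::create(
    _["time"] = rec_t,
    _["v"] = rec_v,
    _["ca"] = rec_ca,
    _["scalars"] = rec_scal,
    _["i_mech"] = rec_imech,
    _["na_open_soma"] = rec_naopen,
    _["max_occupancy_error"] = max_occ_err,
    _["final_state"] = List::create(
      _["v"] = vf, _["ca"] = cf,
      _["cascade"] = NumericVector::create(casc.x_star, casc.y_star),
      _["gates"] = gl, _["markov"] = msnap),
    _["eca_init"] = eca_init
  );
}
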