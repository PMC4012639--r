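// Connor-Stevens spike-generation core: gating kinetics, fixed-step RK4
// integration with an optional gating lookup table (sweep throughput), and
// an adaptive Dormand-Prince 5(4) integrator used as an independent solver
// oracle in the tests.
//
// Units throughout: mV, ms, mS/mm^2, uA/mm^2. The capacitance arrives in
// nF/mm^2 and is converted to uF/mm^2 internally so that
// dV/dt = I/C comes out in mV/ms (uA/uF = mV/ms; uA/nF would be V/ms).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// c*u/(1 - exp(-k*u)), with the removable singularity at u = 0 evaluated by
// its first-order series (|u| < 1e-6 mV).
static inline double lin_over_expm1(double c, double u, double k) {
  if (std::fabs(u) < 1e-6) return (c / k) * (1.0 + 0.5 * k * u);
  return c * u / (1.0 - std::exp(-k * u));
}

struct Gates {
  // steady states and inverse time constants at the 18 C reference
  double minf, itm, hinf, ith, ninf, itn, ainf, ita, binf, itb;
};

// Exact evaluation of all gating steady states / inverse time constants.
static void gates_exact(double V, Gates &g) {
  double am = lin_over_expm1(0.38, V + 29.7, 0.1);
  double bm = 15.2 * std::exp(-0.0556 * (V + 54.7));
  double ah = 0.266 * std::exp(-0.05 * (V + 48.0));
  double bh = 3.8 / (1.0 + std::exp(-0.1 * (V + 18.0)));
  double an = lin_over_expm1(0.02, V + 45.7, 0.1);
  double bn = 0.25 * std::exp(-0.0125 * (V + 55.7));
  g.minf = am / (am + bm); g.itm = am + bm;
  g.hinf = ah / (ah + bh); g.ith = ah + bh;
  g.ninf = an / (an + bn); g.itn = an + bn;
  double taua = 0.3632 + 1.158 / (1.0 + std::exp(0.0497 * (V + 55.96)));
  g.ainf = std::cbrt(0.0761 * std::exp(0.0314 * (V + 94.22)) /
                     (1.0 + std::exp(0.0346 * (V + 1.17))));
  g.ita = 1.0 / taua;
  double taub = 1.24 + 2.678 / (1.0 + std::exp(0.0624 * (V + 50.0)));
  double sb = 1.0 / (1.0 + std::exp(0.0688 * (V + 53.3)));
  g.binf = sb * sb * sb * sb;
  g.itb = 1.0 / taub;
}

// ---- lookup table over V in [VT_MIN, VT_MAX], spacing VT_DV ------------
static const double VT_MIN = -150.0, VT_MAX = 100.0, VT_DV = 0.02;
static const int VT_N = (int)((VT_MAX - VT_MIN) / VT_DV) + 1;
static std::vector<double> vt_tab;  // VT_N rows x 10 values, row-major

static void build_table() {
  vt_tab.resize((size_t)VT_N * 10);
  Gates g;
  for (int i = 0; i < VT_N; ++i) {
    gates_exact(VT_MIN + i * VT_DV, g);
    double *row = &vt_tab[(size_t)i * 10];
    row[0] = g.minf; row[1] = g.itm; row[2] = g.hinf; row[3] = g.ith;
    row[4] = g.ninf; row[5] = g.itn; row[6] = g.ainf; row[7] = g.ita;
    row[8] = g.binf; row[9] = g.itb;
  }
}

static inline void gates_table(double V, Gates &g) {
  if (V <= VT_MIN || V >= VT_MAX) { gates_exact(V, g); return; }
  double x = (V - VT_MIN) / VT_DV;
  int i = (int)x;
  double f = x - i;
  const double *a = &vt_tab[(size_t)i * 10], *b = a + 10;
  g.minf = a[0] + f * (b[0] - a[0]); g.itm = a[1] + f * (b[1] - a[1]);
  g.hinf = a[2] + f * (b[2] - a[2]); g.ith = a[3] + f * (b[3] - a[3]);
  g.ninf = a[4] + f * (b[4] - a[4]); g.itn = a[5] + f * (b[5] - a[5]);
  g.ainf = a[6] + f * (b[6] - a[6]); g.ita = a[7] + f * (b[7] - a[7]);
  g.binf = a[8] + f * (b[8] - a[8]); g.itb = a[9] + f * (b[9] - a[9]);
}

struct Model {
  // temperature-scaled parameters
  double gL, gNa, gK, gA;      // peak conductances
  double EL, ENa, EK, EA;      // reversal potentials
  double Cm;
  double qm, qh, qn, qa, qb;   // per-gate rate multipliers Q10^(dT/10)
  bool use_table;
};

// signed membrane currents; I_X = g_X(V) * (V - E_X), inward currents < 0
static inline void currents(const Model &md, const double *y,
                            double &iL, double &iNa, double &iK, double &iA) {
  double V = y[0], m = y[1], h = y[2], n = y[3], a = y[4], b = y[5];
  iL  = md.gL * (V - md.EL);
  iNa = md.gNa * m * m * m * h * (V - md.ENa);
  double n2 = n * n;
  iK  = md.gK * n2 * n2 * (V - md.EK);
  iA  = md.gA * a * a * a * b * (V - md.EA);
}

static inline void deriv(const Model &md, const double *y, double ic,
                         double *dy) {
  Gates g;
  if (md.use_table) gates_table(y[0], g); else gates_exact(y[0], g);
  double iL, iNa, iK, iA;
  currents(md, y, iL, iNa, iK, iA);
  dy[0] = (ic - iL - iNa - iK - iA) / md.Cm;
  dy[1] = (g.minf - y[1]) * g.itm * md.qm;
  dy[2] = (g.hinf - y[2]) * g.ith * md.qh;
  dy[3] = (g.ninf - y[3]) * g.itn * md.qn;
  dy[4] = (g.ainf - y[4]) * g.ita * md.qa;
  dy[5] = (g.binf - y[5]) * g.itb * md.qb;
}

static Model make_model(NumericVector gbar, NumericVector erev, double Cm,
                        NumericVector q, bool use_table) {
  Model md;
  md.gL = gbar[0]; md.gNa = gbar[1]; md.gK = gbar[2]; md.gA = gbar[3];
  md.EL = erev[0]; md.ENa = erev[1]; md.EK = erev[2]; md.EA = erev[3];
  md.Cm = Cm / 1000.0;  // nF/mm^2 -> uF/mm^2
  md.qm = q[0]; md.qh = q[1]; md.qn = q[2]; md.qa = q[3]; md.qb = q[4];
  md.use_table = use_table;
  if (use_table && vt_tab.empty()) build_table();
  return md;
}

struct SimSummary {
  std::vector<double> spikes;   // interpolated upward crossings of threshold
  double na_load, k_load;       // int |I| dt over [t_start, t_stop + 20]
  double na_excess, k_excess;   // int max(0, |I_x| - |I_other|) dt, same window
  double gate_min, gate_max;
};

// Fixed-step RK4 over pre/stim/post with the step current on during
// [t_pre, t_pre + t_stim). Spike = strict upward crossing of `thr` with a
// 1 ms lockout; times linearly interpolated.
static SimSummary rk4_run(const Model &md, double amp, double t_pre,
                          double t_stim, double t_post, double dt, double thr,
                          const double *y0, NumericMatrix *trace,
                          bool steady_start = false) {
  int n_steps = (int)std::llround((t_pre + t_stim + t_post) / dt);
  double t_on = t_pre, t_off = t_pre + t_stim;
  double w_lo = t_pre, w_hi = t_pre + t_stim + 20.0;  // energy window
  SimSummary s;
  s.na_load = s.k_load = s.na_excess = s.k_excess = 0.0;
  s.gate_min = 1.0; s.gate_max = 0.0;
  double y[6], k1[6], k2[6], k3[6], k4[6], yt[6];
  for (int j = 0; j < 6; ++j) y[j] = y0[j];

  double last_spike = -1e9;
  double prevV = y[0];
  double abs_na_prev = 0.0, abs_k_prev = 0.0, exc_na_prev = 0.0,
         exc_k_prev = 0.0;
  {
    double iL, iNa, iK, iA;
    currents(md, y, iL, iNa, iK, iA);
    abs_na_prev = std::fabs(iNa);
    abs_k_prev = std::fabs(iK + iA);
    exc_na_prev = std::max(0.0, abs_na_prev - abs_k_prev);
    exc_k_prev = std::max(0.0, abs_k_prev - abs_na_prev);
    if (trace) {
      (*trace)(0, 0) = 0.0; (*trace)(0, 1) = y[0];
      for (int j = 1; j < 6; ++j) (*trace)(0, j + 1) = y[j];
      (*trace)(0, 7) = iNa; (*trace)(0, 8) = iK; (*trace)(0, 9) = iA;
      (*trace)(0, 10) = iL; (*trace)(0, 11) = 0.0;
    }
  }

  // when the caller guarantees y0 is the zero-current fixed point, the
  // silent pre-window leaves the state constant and can be skipped
  int i0 = 0;
  if (steady_start && !trace) {
    i0 = (int)std::llround(t_pre / dt);
    if (i0 > n_steps) i0 = n_steps;
  }

  for (int i = i0; i < n_steps; ++i) {
    double t = i * dt;
    // current value is constant within a step except at window edges; use
    // the stage times so the RK4 stages see the correct drive
    double ic_t   = (t >= t_on && t < t_off) ? amp : 0.0;
    double tm = t + 0.5 * dt;
    double ic_mid = (tm >= t_on && tm < t_off) ? amp : 0.0;
    double te = t + dt;
    double ic_end = (te >= t_on && te < t_off) ? amp : 0.0;

    deriv(md, y, ic_t, k1);
    for (int j = 0; j < 6; ++j) yt[j] = y[j] + 0.5 * dt * k1[j];
    deriv(md, yt, ic_mid, k2);
    for (int j = 0; j < 6; ++j) yt[j] = y[j] + 0.5 * dt * k2[j];
    deriv(md, yt, ic_mid, k3);
    for (int j = 0; j < 6; ++j) yt[j] = y[j] + dt * k3[j];
    deriv(md, yt, ic_end, k4);
    for (int j = 0; j < 6; ++j)
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);

    if (!std::isfinite(y[0]))
      stop("integration diverged at t = %.3f ms", te);
    for (int j = 1; j < 6; ++j) {
      if (y[j] < s.gate_min) s.gate_min = y[j];
      if (y[j] > s.gate_max) s.gate_max = y[j];
    }

    // spike detection: strict crossing, the trace must exceed thr
    if (prevV < thr && y[0] > thr) {
      double ts = t + dt * (thr - prevV) / (y[0] - prevV);
      if (ts - last_spike >= 1.0) {
        s.spikes.push_back(ts);
        last_spike = ts;
      }
    }
    prevV = y[0];

    // energy integrals, trapezoidal on the stored grid
    double iL, iNa, iK, iA;
    currents(md, y, iL, iNa, iK, iA);
    double abs_na = std::fabs(iNa), abs_k = std::fabs(iK + iA);
    double exc_na = std::max(0.0, abs_na - abs_k);
    double exc_k = std::max(0.0, abs_k - abs_na);
    if (t >= w_lo - dt * 0.5 && te <= w_hi + dt * 0.5) {
      s.na_load += 0.5 * dt * (abs_na_prev + abs_na);
      s.k_load += 0.5 * dt * (abs_k_prev + abs_k);
      s.na_excess += 0.5 * dt * (exc_na_prev + exc_na);
      s.k_excess += 0.5 * dt * (exc_k_prev + exc_k);
    }
    abs_na_prev = abs_na; abs_k_prev = abs_k;
    exc_na_prev = exc_na; exc_k_prev = exc_k;

    if (trace) {
      (*trace)(i + 1, 0) = te; (*trace)(i + 1, 1) = y[0];
      for (int j = 1; j < 6; ++j) (*trace)(i + 1, j + 1) = y[j];
      (*trace)(i + 1, 7) = iNa; (*trace)(i + 1, 8) = iK;
      (*trace)(i + 1, 9) = iA; (*trace)(i + 1, 10) = iL;
      (*trace)(i + 1, 11) = ic_end;
    }
  }
  return s;
}

// [[Rcpp::export]]
List cs_simulate_cpp(NumericVector gbar, NumericVector erev, double Cm,
                     NumericVector q, double amp, double t_pre, double t_stim,
                     double t_post, double dt, double thr, NumericVector y0,
                     bool keep_trace, bool use_table) {
  Model md = make_model(gbar, erev, Cm, q, use_table);
  int n_steps = (int)std::llround((t_pre + t_stim + t_post) / dt);
  NumericMatrix trace;
  NumericMatrix *tp = NULL;
  if (keep_trace) {
    trace = NumericMatrix(n_steps + 1, 12);
    tp = &trace;
  }
  SimSummary s = rk4_run(md, amp, t_pre, t_stim, t_post, dt, thr,
                         REAL(y0), tp);
  List out = List::create(
    _["spike_times"] = wrap(s.spikes),
    _["na_load"] = s.na_load, _["k_load"] = s.k_load,
    _["na_excess"] = s.na_excess, _["k_excess"] = s.k_excess,
    _["gate_min"] = s.gate_min, _["gate_max"] = s.gate_max);
  if (keep_trace) {
    colnames(trace) = CharacterVector::create(
      "time", "V", "m", "h", "n", "a", "b", "I_Na", "I_K", "I_A", "I_L",
      "I_C");
    out["trace"] = trace;
  }
  return out;
}

// Batched f-I summaries: one row per amplitude.
// [[Rcpp::export]]
List cs_fi_batch_cpp(NumericVector gbar, NumericVector erev, double Cm,
                     NumericVector q, NumericVector amps, double t_pre,
                     double t_stim, double t_post, double dt, double thr,
                     NumericVector y0, bool use_table,
                     bool steady_start) {
  Model md = make_model(gbar, erev, Cm, q, use_table);
  int n = amps.size();
  IntegerVector n_spk(n);
  NumericVector na_load(n), k_load(n), na_excess(n), k_excess(n),
      gate_min(n), gate_max(n);
  List spike_times(n);
  for (int i = 0; i < n; ++i) {
    SimSummary s = rk4_run(md, amps[i], t_pre, t_stim, t_post, dt, thr,
                           REAL(y0), NULL, steady_start);
    int cnt = 0;
    double lo = t_pre, hi = t_pre + t_stim;
    for (size_t k = 0; k < s.spikes.size(); ++k)
      if (s.spikes[k] >= lo && s.spikes[k] < hi) ++cnt;
    n_spk[i] = cnt;
    na_load[i] = s.na_load; k_load[i] = s.k_load;
    na_excess[i] = s.na_excess; k_excess[i] = s.k_excess;
    gate_min[i] = s.gate_min; gate_max[i] = s.gate_max;
    spike_times[i] = wrap(s.spikes);
  }
  return List::create(
    _["n_spikes_stim"] = n_spk, _["na_load"] = na_load,
    _["k_load"] = k_load, _["na_excess"] = na_excess,
    _["k_excess"] = k_excess, _["gate_min"] = gate_min,
    _["gate_max"] = gate_max, _["spike_times"] = spike_times);
}

// Adaptive Dormand-Prince 5(4) with PI step control; exact (non-table)
// gating evaluation throughout. Returns spike times and V sampled onto
// `t_out` by linear interpolation between accepted steps. Serves as the
// independent solver oracle for the fixed-step path.
// [[Rcpp::export]]
List cs_simulate_adaptive_cpp(NumericVector gbar, NumericVector erev,
                              double Cm, NumericVector q, double amp,
                              double t_pre, double t_stim, double t_post,
                              double thr, NumericVector y0,
                              NumericVector t_out, double rtol, double atol) {
  Model md = make_model(gbar, erev, Cm, q, false);
  const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
      a63 = 46732.0 / 5247, a64 = 49.0 / 176, a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
      e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

  double t_end = t_pre + t_stim + t_post;
  double t_on = t_pre, t_off = t_pre + t_stim;
  auto drive = [&](double t) { return (t >= t_on && t < t_off) ? amp : 0.0; };

  double y[6];
  for (int j = 0; j < 6; ++j) y[j] = y0[j];
  double t = 0.0, h = 1e-3;
  const double hmax = 0.25, hmin = 1e-10;

  std::vector<double> ts, Vs;
  ts.reserve(1 << 16); Vs.reserve(1 << 16);
  ts.push_back(0.0); Vs.push_back(y[0]);
  std::vector<double> spikes;
  double last_spike = -1e9;
  // |I_Na| integral over [t_pre, t_off + 20], trapezoid on accepted steps
  double na_load = 0.0, w_lo = t_pre, w_hi = t_off + 20.0;
  double abs_na_prev;
  {
    double iL, iNa, iK, iA;
    currents(md, y, iL, iNa, iK, iA);
    abs_na_prev = std::fabs(iNa);
  }

  double k1[6], k2[6], k3[6], k4[6], k5[6], k6[6], k7[6], yt[6], yn[6];
  deriv(md, y, drive(t), k1);
  double err_prev = 1.0;

  while (t < t_end - 1e-12) {
    // do not step across a drive discontinuity or the energy-window edge
    if (t < t_on && t + h > t_on) h = t_on - t;
    else if (t < t_off && t + h > t_off) h = t_off - t;
    else if (t < w_hi && t + h > w_hi) h = w_hi - t;
    if (t + h > t_end) h = t_end - t;

    for (int j = 0; j < 6; ++j) yt[j] = y[j] + h * a21 * k1[j];
    deriv(md, yt, drive(t + c2 * h), k2);
    for (int j = 0; j < 6; ++j)
      yt[j] = y[j] + h * (a31 * k1[j] + a32 * k2[j]);
    deriv(md, yt, drive(t + c3 * h), k3);
    for (int j = 0; j < 6; ++j)
      yt[j] = y[j] + h * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
    deriv(md, yt, drive(t + c4 * h), k4);
    for (int j = 0; j < 6; ++j)
      yt[j] = y[j] + h * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] +
                          a54 * k4[j]);
    deriv(md, yt, drive(t + c5 * h), k5);
    for (int j = 0; j < 6; ++j)
      yt[j] = y[j] + h * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] +
                          a64 * k4[j] + a65 * k5[j]);
    deriv(md, yt, drive(t + h), k6);
    for (int j = 0; j < 6; ++j)
      yn[j] = y[j] + h * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j] + b5 * k5[j] +
                          b6 * k6[j]);
    deriv(md, yn, drive(t + h), k7);

    double err = 0.0;
    for (int j = 0; j < 6; ++j) {
      double e = h * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] + e5 * k5[j] +
                      e6 * k6[j] + e7 * k7[j]);
      double sc = atol + rtol * std::max(std::fabs(y[j]), std::fabs(yn[j]));
      double r = e / sc;
      err += r * r;
    }
    err = std::sqrt(err / 6.0);

    if (err <= 1.0) {
      // accepted
      if (yn[0] > thr && y[0] < thr) {
        double tsp = t + h * (thr - y[0]) / (yn[0] - y[0]);
        if (tsp - last_spike >= 1.0) { spikes.push_back(tsp); last_spike = tsp; }
      }
      {
        double iL, iNa, iK, iA;
        currents(md, yn, iL, iNa, iK, iA);
        double abs_na = std::fabs(iNa);
        if (t >= w_lo - 1e-12 && t + h <= w_hi + 1e-12)
          na_load += 0.5 * h * (abs_na_prev + abs_na);
        abs_na_prev = abs_na;
      }
      t += h;
      for (int j = 0; j < 6; ++j) y[j] = yn[j];
      for (int j = 0; j < 6; ++j) k1[j] = k7[j];  // FSAL
      if (!std::isfinite(y[0])) stop("integration diverged at t = %.3f", t);
      ts.push_back(t); Vs.push_back(y[0]);
      double fac = 0.9 * std::pow(err > 1e-10 ? err : 1e-10, -0.7 / 5.0) *
                   std::pow(err_prev, 0.4 / 5.0);
      fac = std::min(5.0, std::max(0.2, fac));
      h = std::min(hmax, h * fac);
      err_prev = err > 1e-10 ? err : 1e-10;
    } else {
      h *= std::max(0.2, 0.9 * std::pow(err, -1.0 / 5.0));
    }
    if (h < hmin) stop("step size underflow at t = %.3f", t);
  }

  // interpolate onto t_out
  int n_out = t_out.size();
  NumericVector v_out(n_out);
  size_t idx = 0;
  for (int i = 0; i < n_out; ++i) {
    double tq = t_out[i];
    while (idx + 1 < ts.size() && ts[idx + 1] < tq) ++idx;
    if (idx + 1 >= ts.size()) { v_out[i] = Vs.back(); continue; }
    double f = (tq - ts[idx]) / (ts[idx + 1] - ts[idx]);
    v_out[i] = Vs[idx] + f * (Vs[idx + 1] - Vs[idx]);
  }
  return List::create(_["spike_times"] = wrap(spikes), _["V"] = v_out,
                      _["na_load"] = na_load,
                      _["n_accepted"] = (int)ts.size());
}

// Exact gating quantities for testing / R-side use.
// [[Rcpp::export]]
List cs_gating_cpp(NumericVector V) {
  int n = V.size();
  NumericVector minf(n), taum(n), hinf(n), tauh(n), ninf(n), taun(n),
      ainf(n), taua(n), binf(n), taub(n);
  Gates g;
  for (int i = 0; i < n; ++i) {
    gates_exact(V[i], g);
    minf[i] = g.minf; taum[i] = 1.0 / g.itm;
    hinf[i] = g.hinf; tauh[i] = 1.0 / g.ith;
    ninf[i] = g.ninf; taun[i] = 1.0 / g.itn;
    ainf[i] = g.ainf; taua[i] = 1.0 / g.ita;
    binf[i] = g.binf; taub[i] = 1.0 / g.itb;
  }
  return List::create(
    _["m_inf"] = minf, _["tau_m"] = taum, _["h_inf"] = hinf,
    _["tau_h"] = tauh, _["n_inf"] = ninf, _["tau_n"] = taun,
    _["a_inf"] = ainf, _["tau_a"] = taua, _["b_inf"] = binf,
    _["tau_b"] = taub);
}
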