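// Simulation kernels for the antennal-lobe DNP circuit models.
//
// All ODEs are advanced on a single fixed grid with an exponential-Euler
// scheme: every state equation is locally of the form dx/dt = A - B*x with
// A, B >= 0 frozen over one step, so x <- A/B + (x - A/B) * exp(-B*dt).
// This is unconditionally stable and keeps gating variables inside [0, 1].
//
// Spike-train convention: a spike train enters a synapse ODE as a unit
// amplitude in the spike's time bin (a 0/1 indicator), so a synaptic rate
// parameter alpha produces a per-spike gating increment of about
// (1 - exp(-alpha * dt)) * (1 - x).  This is what makes the documented
// parameter range [1, 1e6] meaningful at dt = 0.1 ms: rates around 1e3-1e5
// give physiological per-spike increments, values near the lower bound have
// negligible effect, and explicit-Euler solvers destabilize near the upper
// bound.
//
// Voltage equations are treated the same way by folding all conductances
// (intrinsic + synaptic) into B and all conductance-weighted reversal
// potentials plus flat currents into A.  Synaptic currents therefore use the
// instantaneous postsynaptic voltage in the driving force.
//
// Units: time s (gating ODE rates are 1/s); Connor-Stevens kinetics are
// evaluated in ms/mV as in the standard formulation; currents are uA per
// unit membrane area, conductances mS, capacitance uF.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Connor-Stevens point neuron (standard constants, Type-I excitability)
// ---------------------------------------------------------------------------

struct CSParams {
  double C;                      // uF/cm^2
  double gNa, gK, gA, gL;        // mS/cm^2
  double ENa, EK, EA, EL;        // mV
};

static CSParams cs_from_vector(const NumericVector& p) {
  CSParams q;
  q.C = p[0];
  q.gNa = p[1]; q.gK = p[2]; q.gA = p[3]; q.gL = p[4];
  q.ENa = p[5]; q.EK = p[6]; q.EA = p[7]; q.EL = p[8];
  return q;
}

struct CSState {
  double V, m, h, n, a, b;
};

// guard against 0/0 in the linoid rate functions
static inline double linoid(double x, double y) {
  double d = 1.0 - std::exp(-(x) / y);
  if (std::fabs(d) < 1e-9) return y;  // limit of x/(1-exp(-x/y)) as x -> 0
  return x / d;
}

struct CSRates {
  double m_inf, tau_m, h_inf, tau_h, n_inf, tau_n, a_inf, tau_a, b_inf, tau_b;
};

static inline CSRates cs_rates(double V) {
  CSRates r;
  double am = 0.38 * linoid(V + 29.7, 10.0);
  double bm = 15.2 * std::exp(-0.0556 * (V + 54.7));
  double ah = 0.266 * std::exp(-0.05 * (V + 48.0));
  double bh = 3.8 / (1.0 + std::exp(-0.1 * (V + 18.0)));
  double an = 0.02 * linoid(V + 45.7, 10.0);
  double bn = 0.25 * std::exp(-0.0125 * (V + 55.7));
  r.m_inf = am / (am + bm); r.tau_m = 1.0 / (am + bm);
  r.h_inf = ah / (ah + bh); r.tau_h = 1.0 / (ah + bh);
  r.n_inf = an / (an + bn); r.tau_n = 1.0 / (an + bn);
  r.a_inf = std::pow(0.0761 * std::exp(0.0314 * (V + 94.22)) /
                         (1.0 + std::exp(0.0346 * (V + 1.17))),
                     1.0 / 3.0);
  r.tau_a = 0.3632 + 1.158 / (1.0 + std::exp(0.0497 * (V + 55.96)));
  r.b_inf = std::pow(1.0 / (1.0 + std::exp(0.0688 * (V + 53.3))), 4.0);
  r.tau_b = 1.24 + 2.678 / (1.0 + std::exp(0.0624 * (V + 50.0)));
  return r;
}

static CSState cs_rest_state(const CSParams& p) {
  // settle to rest by integrating with zero input from a sensible start
  CSState s;
  s.V = -68.0;
  CSRates r = cs_rates(s.V);
  s.m = r.m_inf; s.h = r.h_inf; s.n = r.n_inf; s.a = r.a_inf; s.b = r.b_inf;
  for (int i = 0; i < 20000; ++i) {  // 200 ms at 0.01 ms
    r = cs_rates(s.V);
    double dtm = 0.01;
    s.m = r.m_inf + (s.m - r.m_inf) * std::exp(-dtm / r.tau_m);
    s.h = r.h_inf + (s.h - r.h_inf) * std::exp(-dtm / r.tau_h);
    s.n = r.n_inf + (s.n - r.n_inf) * std::exp(-dtm / r.tau_n);
    s.a = r.a_inf + (s.a - r.a_inf) * std::exp(-dtm / r.tau_a);
    s.b = r.b_inf + (s.b - r.b_inf) * std::exp(-dtm / r.tau_b);
    double gNa = p.gNa * s.m * s.m * s.m * s.h;
    double gK = p.gK * s.n * s.n * s.n * s.n;
    double gA = p.gA * s.a * s.a * s.a * s.b;
    double G = gNa + gK + gA + p.gL;
    double GE = gNa * p.ENa + gK * p.EK + gA * p.EA + p.gL * p.EL;
    double Vinf = GE / G;
    s.V = Vinf + (s.V - Vinf) * std::exp(-G / p.C * dtm);
  }
  return s;
}

// One Connor-Stevens neuron advanced step by step with optional synaptic
// conductances supplied by the caller each step.
struct CSNeuron {
  CSParams p;
  CSState s;
  double dt_ms;
  double sigma;        // noise intensity (dimensionless)
  double noise_scale;  // frozen calibration constant (mV / sqrt(s))
  double sqrt_dt_s;
  std::mt19937_64 rng;
  std::normal_distribution<double> gauss;
  // spike detection: local maximum of V above threshold, 1 ms refractory
  double V_prev, V_prev2;
  double t_last_spike;
  double spike_threshold, refractory;

  void init(const CSParams& pars, double dt_s, double sig, double nscale,
            uint64_t seed) {
    p = pars;
    s = cs_rest_state(p);
    dt_ms = dt_s * 1000.0;
    sigma = sig;
    noise_scale = nscale;
    sqrt_dt_s = std::sqrt(dt_s);
    rng.seed(seed);
    gauss = std::normal_distribution<double>(0.0, 1.0);
    V_prev = s.V; V_prev2 = s.V;
    t_last_spike = -1.0;
    spike_threshold = 0.0;
    refractory = 1e-3;
  }

  // advance one step; g_syn/gE_syn: summed synaptic conductance and
  // conductance*reversal; I_flat: flat injected current. Returns true if a
  // spike (local max above threshold) is detected at the *previous* sample.
  bool step(double t_s, double g_syn, double gE_syn, double I_flat) {
    CSRates r = cs_rates(s.V);
    s.m = r.m_inf + (s.m - r.m_inf) * std::exp(-dt_ms / r.tau_m);
    s.h = r.h_inf + (s.h - r.h_inf) * std::exp(-dt_ms / r.tau_h);
    s.n = r.n_inf + (s.n - r.n_inf) * std::exp(-dt_ms / r.tau_n);
    s.a = r.a_inf + (s.a - r.a_inf) * std::exp(-dt_ms / r.tau_a);
    s.b = r.b_inf + (s.b - r.b_inf) * std::exp(-dt_ms / r.tau_b);
    double gNa = p.gNa * s.m * s.m * s.m * s.h;
    double gK = p.gK * s.n * s.n * s.n * s.n;
    double gA = p.gA * s.a * s.a * s.a * s.b;
    double G = gNa + gK + gA + p.gL + g_syn;
    double GE = gNa * p.ENa + gK * p.EK + gA * p.EA + p.gL * p.EL + gE_syn;
    double Vinf = (GE + I_flat) / G;
    double Vnew = Vinf + (s.V - Vinf) * std::exp(-G / p.C * dt_ms);
    if (sigma > 0.0)
      Vnew += sigma * noise_scale * sqrt_dt_s * gauss(rng);
    V_prev2 = V_prev;
    V_prev = s.V;
    s.V = Vnew;
    // local max at previous sample
    if (V_prev > spike_threshold && V_prev >= s.V && V_prev > V_prev2 &&
        (t_s - t_last_spike) >= refractory) {
      t_last_spike = t_s;
      return true;
    }
    return false;
  }
};

// [[Rcpp::export]]
List cpp_simulate_cs(NumericVector I, double dt, double sigma,
                     double noise_scale, int seed, NumericVector cs_pars,
                     bool record) {
  int T = I.size();
  CSParams p = cs_from_vector(cs_pars);
  CSNeuron nr;
  nr.init(p, dt, sigma, noise_scale, (uint64_t)seed);
  NumericVector V, n;
  if (record) { V = NumericVector(T); n = NumericVector(T); }
  std::vector<double> spikes;
  for (int t = 0; t < T; ++t) {
    double ts = t * dt;
    if (record) { V[t] = nr.s.V; n[t] = nr.s.n; }
    if (nr.step(ts, 0.0, 0.0, I[t]))
      spikes.push_back(ts - dt);  // spike at the previous sample
  }
  return List::create(_["V"] = V, _["n"] = n,
                      _["spikes"] = NumericVector(spikes.begin(), spikes.end()));
}

// [[Rcpp::export]]
NumericVector cpp_fi_rates(NumericVector grid, NumericVector cs_pars,
                           double sim_time, double discard, double dt) {
  CSParams p = cs_from_vector(cs_pars);
  int G = grid.size();
  NumericVector rates(G);
  int T = (int)std::round(sim_time / dt);
  for (int g = 0; g < G; ++g) {
    CSNeuron nr;
    nr.init(p, dt, 0.0, 0.0, 1u);
    int count = 0;
    for (int t = 0; t < T; ++t) {
      double ts = t * dt;
      if (nr.step(ts, 0.0, 0.0, grid[g]) && ts - dt >= discard) ++count;
    }
    rates[g] = count / (sim_time - discard);
  }
  return rates;
}

// ---------------------------------------------------------------------------
// Differential DNP integrators
// ---------------------------------------------------------------------------

// dx/dt = alpha*drive*(1-x) - beta*x - kappa*normalizer*x
// feedback: normalizer is x itself (semi-implicit: frozen over the step)
// [[Rcpp::export]]
NumericVector cpp_simulate_dnp(NumericVector drive, NumericVector normalizer,
                               double alpha, double beta, double kappa,
                               bool feedback, double dt, double x0) {
  int T = drive.size();
  NumericVector x(T);
  double xc = x0;
  for (int t = 0; t < T; ++t) {
    x[t] = xc;
    double nrm = feedback ? xc : normalizer[t];
    double A = alpha * drive[t];
    double B = A + beta + kappa * nrm;
    if (B > 0) {
      double xi = A / B;
      xc = xi + (xc - xi) * std::exp(-B * dt);
    }
  }
  return x;
}

// Global (spatio-temporal) DNP: channels share parameters; the normalizer is
// the pooled signal: feedforward uses `pooled` (T8[v]), feedback uses the
// across-channel sum of x (T6[x]).
// [[Rcpp::export]]
NumericMatrix cpp_simulate_global_dnp(NumericMatrix drives,
                                      NumericVector pooled, double alpha,
                                      double beta, double kappa, bool feedback,
                                      double dt, double x0) {
  int R = drives.nrow(), T = drives.ncol();
  NumericMatrix x(R, T);
  std::vector<double> xc(R, x0);
  for (int t = 0; t < T; ++t) {
    double pool;
    if (feedback) {
      pool = 0.0;
      for (int r = 0; r < R; ++r) pool += xc[r];
    } else {
      pool = pooled[t];
    }
    for (int r = 0; r < R; ++r) {
      x(r, t) = xc[r];
      double A = alpha * drives(r, t);
      double B = A + beta + kappa * pool;
      if (B > 0) {
        double xi = A / B;
        xc[r] = xi + (xc[r] - xi) * std::exp(-B * dt);
      }
    }
  }
  return x;
}

// two-state cascade used by the simplified OSN front-end: calcium-like slow
// feedback y normalizing the fast transduction gating x
// [[Rcpp::export]]
NumericMatrix cpp_osn_gating(NumericMatrix v, double alpha, double beta,
                             double kappa, double alpha_s, double beta_s,
                             double dt, double warmup_s) {
  int R = v.nrow(), T = v.ncol();
  NumericMatrix x(R, T);
  std::vector<double> xc(R, 0.0), yc(R, 0.0);
  // settle at the initial (spontaneous) input so recordings start from the
  // adapted baseline state rather than a cold start
  int W = (int)std::round(warmup_s / dt);
  for (int t = -W; t < 0; ++t) {
    for (int r = 0; r < R; ++r) {
      double A = alpha * v(r, 0);
      double B = A + beta + kappa * yc[r];
      double xi = A / B;
      xc[r] = (B > 0) ? xi + (xc[r] - xi) * std::exp(-B * dt) : xc[r];
      double As = alpha_s * xc[r];
      double Bs = As + beta_s;
      double yi = As / Bs;
      yc[r] = yi + (yc[r] - yi) * std::exp(-Bs * dt);
    }
  }
  for (int t = 0; t < T; ++t) {
    for (int r = 0; r < R; ++r) {
      x(r, t) = xc[r];
      double A = alpha * v(r, t);
      double B = A + beta + kappa * yc[r];
      double xi = A / B;
      xc[r] = (B > 0) ? xi + (xc[r] - xi) * std::exp(-B * dt) : xc[r];
      double As = alpha_s * xc[r];
      double Bs = As + beta_s;
      double yi = As / Bs;
      yc[r] = yi + (yc[r] - yi) * std::exp(-Bs * dt);
    }
  }
  return x;
}

// ---------------------------------------------------------------------------
// Full antennal-lobe circuit engine
// ---------------------------------------------------------------------------
//
// theta layout (23 free parameters, canonical order):
//   [0..6]   Pre-LN pathway  : a1 b1 gOL a2 b2 k2 NTmax
//   [7..14]  Post-eLN pathway: a3 b3 k3 a4 b4 a5 b5 gOeL
//   [15..22] Post-iLN pathway: a6 b6 k6 a7 b7 a8 b8 gOiL
// fixed (rows 8-10): alpha = 1, beta = 100, gmax = 100 for the OSN->PN,
// eLN->PN and iLN->PN synapses.
//
// variant: 0 none, 1 local_feedback, 2 local_feedforward, 3 global_feedback,
//          4 global_feedforward.  Feedback variants drive the OSN->Pre-LN
// synapse with the axon-terminal neurotransmitter concentration [NT]^{OP}
// instead of the OSN spike train.
//
// pathways: logical (preln, eln, iln); inactive pathways contribute no
// current to the PN and are not simulated.

struct Dnp1 {  // single A-B gate driven by an arbitrary signal
  double x = 0.0;
  inline void step(double A, double B, double dt) {
    if (B <= 0) return;
    double xi = A / B;
    x = xi + (x - xi) * std::exp(-B * dt);
  }
};

// [[Rcpp::export]]
List cpp_simulate_circuit(NumericMatrix osn_delta, NumericVector theta,
                          int variant, LogicalVector pathways, double dt,
                          double sigma_P, double noise_scale, int seed,
                          NumericVector rev, NumericVector cs_pars,
                          bool record_traces, double warmup_s,
                          double warmup_epoch_s) {
  const int R = osn_delta.nrow(), T = osn_delta.ncol();
  const bool use_pre = pathways[0], use_e = pathways[1], use_i = pathways[2];
  const bool pre_active = use_pre && variant != 0;
  const bool pre_global = variant == 3 || variant == 4;
  const bool pre_fbk = variant == 1 || variant == 3;

  const double a1 = theta[0], b1 = theta[1], gOL = theta[2];
  const double a2 = theta[3], b2 = theta[4], k2 = theta[5], NTmax = theta[6];
  const double a3 = theta[7], b3 = theta[8], k3 = theta[9], a4 = theta[10],
               b4 = theta[11], a5 = theta[12], b5 = theta[13],
               gOeL = theta[14];
  const double a6 = theta[15], b6 = theta[16], k6 = theta[17], a7 = theta[18],
               b7 = theta[19], a8 = theta[20], b8 = theta[21],
               gOiL = theta[22];
  // fixed-value synapses onto the PN
  const double aOP = 1.0, bOP = 100.0, gOP = 100.0;
  const double aLP = 1.0, bLP = 100.0, gLP = 100.0;

  const double E_OL = rev[0], E_OP = rev[1], E_OeL = rev[2], E_eLP = rev[3],
               E_OiL = rev[4], E_iLP = rev[5];

  CSParams csp = cs_from_vector(cs_pars);

  // neurons: Pre-LN (1 if global, R if local), eLN/iLN/PN per channel
  int nL = pre_active ? (pre_global ? 1 : R) : 0;
  std::vector<CSNeuron> preln(nL), eln(use_e ? R : 0), iln(use_i ? R : 0),
      pn(R);
  // stable per-neuron seeds: hash of (master seed, population, channel)
  auto mkseed = [&](int pop, int ch) {
    uint64_t h = (uint64_t)seed * 1000003ULL + (uint64_t)pop * 8191ULL +
                 (uint64_t)ch * 131ULL + 17ULL;
    return h;
  };
  for (int i = 0; i < nL; ++i) preln[i].init(csp, dt, 0.0, 0.0, mkseed(1, i));
  for (int i = 0; i < (int)eln.size(); ++i)
    eln[i].init(csp, dt, 0.0, 0.0, mkseed(2, i));
  for (int i = 0; i < (int)iln.size(); ++i)
    iln[i].init(csp, dt, 0.0, 0.0, mkseed(3, i));
  for (int i = 0; i < R; ++i)
    pn[i].init(csp, dt, sigma_P, noise_scale, mkseed(4, i));

  // gating states
  std::vector<Dnp1> xOL(pre_active ? R : 0), xAxT(R), xOP(R);
  std::vector<Dnp1> xOeL(use_e ? R : 0), x2OeL(use_e ? R : 0),
      x3OeL(use_e ? R : 0), xeLP(use_e ? R : 0);
  std::vector<Dnp1> xOiL(use_i ? R : 0), x2OiL(use_i ? R : 0),
      x3OiL(use_i ? R : 0), xiLP(use_i ? R : 0);

  // outputs
  NumericMatrix I_OP(R, T), I_eLP(use_e ? R : 0, use_e ? T : 0),
      I_iLP(use_i ? R : 0, use_i ? T : 0);
  NumericMatrix xAxT_tr(R, T);
  NumericMatrix V_P, NT_tr, xOP_tr, xOeL_tr, xOiL_tr;
  if (record_traces) {
    V_P = NumericMatrix(R, T);
    NT_tr = NumericMatrix(R, T);
    xOP_tr = NumericMatrix(R, T);
    if (use_e) xOeL_tr = NumericMatrix(R, T);
    if (use_i) xOiL_tr = NumericMatrix(R, T);
  }
  std::vector<std::vector<double>> pn_spk(R), ln_spk(nL), eln_spk(eln.size()),
      iln_spk(iln.size());

  std::vector<double> NT(R, 0.0), deltaL(std::max(nL, 1), 0.0);

  // warm-up: cycle the initial (baseline) epoch of the input so all gating
  // variables and membranes start from their spontaneous steady state
  // instead of a cold start; nothing is recorded
  int W = (int)std::round(warmup_s / dt);
  int E = std::max(1, std::min(T, (int)std::round(warmup_epoch_s / dt)));
  for (int tt = -W; tt < T; ++tt) {
    bool warm = tt < 0;
    int t = warm ? ((tt % E) + E) % E : tt;
    double ts = warm ? tt * dt : t * dt;

    // --- Pre-LN pathway -----------------------------------------------
    if (pre_active) {
      // OSN->Pre-LN synapse (per channel); input is the OSN spike train in
      // feedforward variants, the axon-terminal [NT] in feedback variants
      double g_sum = 0.0;  // for global dendritic sum
      for (int r = 0; r < R; ++r) {
        double in = pre_fbk ? NT[r] : osn_delta(r, t);
        xOL[r].step(a1 * in, a1 * in + b1, dt);
      }
      if (pre_global) {
        for (int r = 0; r < R; ++r) g_sum += gOL * xOL[r].x;
        bool spk = preln[0].step(ts, g_sum, g_sum * E_OL, 0.0);
        deltaL[0] = spk ? 1.0 : 0.0;
        if (spk && !warm) ln_spk[0].push_back(ts - dt);
      } else {
        for (int r = 0; r < R; ++r) {
          double g = gOL * xOL[r].x;
          bool spk = preln[r].step(ts, g, g * E_OL, 0.0);
          deltaL[r] = spk ? 1.0 : 0.0;
          if (spk && !warm) ln_spk[r].push_back(ts - dt);
        }
      }
    }

    // --- Axon terminal and OSN->PN synapse ------------------------------
    for (int r = 0; r < R; ++r) {
      double inh = 0.0;
      if (pre_active) inh = k2 * (pre_global ? deltaL[0] : deltaL[r]);
      double A = a2 * osn_delta(r, t);
      xAxT[r].step(A, A + b2 + inh, dt);
      NT[r] = NTmax * xAxT[r].x;
      if (!warm) xAxT_tr(r, t) = xAxT[r].x;
      double Aop = aOP * NT[r];
      xOP[r].step(Aop, Aop + bOP, dt);
    }

    // --- Post-eLN pathway ------------------------------------------------
    if (use_e) {
      for (int r = 0; r < R; ++r) {
        double d = osn_delta(r, t);
        x2OeL[r].step(a4 * d, a4 * d + b4, dt);
        x3OeL[r].step(a5 * d, a5 * d + b5, dt);
        double A = a3 * x2OeL[r].x;
        xOeL[r].step(A, A + b3 + k3 * x3OeL[r].x, dt);
        double g = gOeL * xOeL[r].x;
        bool spk = eln[r].step(ts, g, g * E_OeL, 0.0);
        double de = spk ? 1.0 : 0.0;
        if (spk && !warm) eln_spk[r].push_back(ts - dt);
        xeLP[r].step(aLP * de, aLP * de + bLP, dt);
        if (record_traces && !warm) xOeL_tr(r, t) = xOeL[r].x;
      }
    }

    // --- Post-iLN pathway ------------------------------------------------
    if (use_i) {
      for (int r = 0; r < R; ++r) {
        double d = osn_delta(r, t);
        x2OiL[r].step(a7 * d, a7 * d + b7, dt);
        x3OiL[r].step(a8 * d, a8 * d + b8, dt);
        double A = a6 * x2OiL[r].x;
        xOiL[r].step(A, A + b6 + k6 * x3OiL[r].x, dt);
        double g = gOiL * xOiL[r].x;
        bool spk = iln[r].step(ts, g, g * E_OiL, 0.0);
        double di = spk ? 1.0 : 0.0;
        if (spk && !warm) iln_spk[r].push_back(ts - dt);
        xiLP[r].step(aLP * di, aLP * di + bLP, dt);
        if (record_traces && !warm) xOiL_tr(r, t) = xOiL[r].x;
      }
    }

    // --- PN --------------------------------------------------------------
    for (int r = 0; r < R; ++r) {
      double Vp = pn[r].s.V;
      double g = 0.0, gE = 0.0;
      double gop = gOP * xOP[r].x;
      g += gop; gE += gop * E_OP;
      if (!warm) I_OP(r, t) = gop * (E_OP - Vp);  // current into the PN
      if (use_e) {
        double ge = gLP * xeLP[r].x;
        g += ge; gE += ge * E_eLP;
        if (!warm) I_eLP(r, t) = ge * (E_eLP - Vp);
      }
      if (use_i) {
        double gi = gLP * xiLP[r].x;
        g += gi; gE += gi * E_iLP;
        if (!warm) I_iLP(r, t) = gi * (E_iLP - Vp);
      }
      bool spk = pn[r].step(ts, g, gE, 0.0);
      if (spk && !warm) pn_spk[r].push_back(ts - dt);
      if (record_traces && !warm) {
        V_P(r, t) = Vp;
        NT_tr(r, t) = NT[r];
        xOP_tr(r, t) = xOP[r].x;
      }
    }
  }

  auto to_list = [](std::vector<std::vector<double>>& v) {
    List out(v.size());
    for (size_t i = 0; i < v.size(); ++i)
      out[i] = NumericVector(v[i].begin(), v[i].end());
    return out;
  };

  List out = List::create(
      _["x_AxT"] = xAxT_tr, _["I_OP"] = I_OP, _["I_eLP"] = I_eLP,
      _["I_iLP"] = I_iLP, _["pn_spikes"] = to_list(pn_spk),
      _["preln_spikes"] = to_list(ln_spk), _["eln_spikes"] = to_list(eln_spk),
      _["iln_spikes"] = to_list(iln_spk));
  if (record_traces) {
    out["V_P"] = V_P;
    out["NT"] = NT_tr;
    out["x_OP"] = xOP_tr;
    if (use_e) out["x_OeL"] = xOeL_tr;
    if (use_i) out["x_OiL"] = xOiL_tr;
  }
  return out;
}

// bin spike times into a unit-amplitude indicator train (one bin per spike)
// [[Rcpp::export]]
NumericVector cpp_bin_deltas(NumericVector times, int n, double dt) {
  NumericVector out(n);
  for (int i = 0; i < times.size(); ++i) {
    int k = (int)std::round(times[i] / dt);
    if (k >= 0 && k < n) out[k] += 1.0;
  }
  return out;
}

// centered boxcar moving average (edge-truncated), used to smooth model
// synaptic currents before angular-distance objectives
// [[Rcpp::export]]
NumericVector cpp_boxcar(NumericVector x, int half) {
  int n = x.size();
  NumericVector out(n);
  // prefix sums
  std::vector<double> cs(n + 1, 0.0);
  for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + x[i];
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - half), hi = std::min(n - 1, i + half);
    out[i] = (cs[hi + 1] - cs[lo]) / (hi - lo + 1);
  }
  return out;
}
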