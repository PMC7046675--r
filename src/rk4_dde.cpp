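#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Fixed-step classical RK4 for the Morris-Lecar membrane equations with an
// optional delayed conductance-based autapse. The synaptic activation s enters
// the voltage equation through its value tau ms in the past, read from a
// history buffer of the already-computed grid samples (linear interpolation at
// the half-step stage times; s(t) = 0 for t <= 0, i.e. no presynaptic activity
// before the run starts).

struct MLPar {
  double C, gNa, gK, gL, ENa, EK, EL;
  double beta_m, gamma_m, beta_w, gamma_w, phi_w;
  double cosh_den; // gamma_w or 2*gamma_w depending on tau_w variant
};

struct SynPar {
  double g_syn, E_syn, tau, alpha, beta, theta_syn, k_sig;
};

struct StimPar {
  int kind; // 0 constant, 1 pulse, 2 pulse train
  double baseline, amplitude, onset, duration, period;
  int n_pulses; // 0 = until end of run
};

static inline double stim_current(const StimPar &p, double t) {
  if (p.kind == 0) return p.baseline;
  if (p.kind == 1) {
    // half-open active window [onset, onset + duration)
    return (t >= p.onset && t < p.onset + p.duration)
      ? p.baseline + p.amplitude : p.baseline;
  }
  if (t < p.onset) return p.baseline;
  double u = t - p.onset;
  double k = std::floor(u / p.period);
  if (p.n_pulses > 0 && k >= (double)p.n_pulses) return p.baseline;
  double phase = u - k * p.period;
  return (phase < p.duration) ? p.baseline + p.amplitude : p.baseline;
}

static inline double m_inf(const MLPar &p, double V) {
  return 0.5 * (1.0 + std::tanh((V - p.beta_m) / p.gamma_m));
}
static inline double w_inf(const MLPar &p, double V) {
  return 0.5 * (1.0 + std::tanh((V - p.beta_w) / p.gamma_w));
}

// s(t - tau) from the history buffer; n = index of the newest stored sample.
// Stage times t + h/2 fall between grid points, hence the linear interpolation;
// for tau < h a stage lookup can reach past the newest sample and is clamped.
static inline double s_delayed(const std::vector<double> &sh, int n,
                               double td, double h) {
  if (td <= 0.0) return 0.0;
  double x = td / h;
  int i = (int)std::floor(x);
  if (i >= n) return sh[n];
  double f = x - (double)i;
  return sh[i] + f * (sh[i + 1] - sh[i]);
}

struct Deriv { double dV, dw, ds; };

static inline Deriv ml_rhs(const MLPar &p, const SynPar &s, double V, double w,
                           double sv, double s_del, double I_app) {
  Deriv d;
  double I_syn = -s.g_syn * s_del * (V - s.E_syn);
  d.dV = (I_app + I_syn
          - p.gNa * m_inf(p, V) * (V - p.ENa)
          - p.gK * w * (V - p.EK)
          - p.gL * (V - p.EL)) / p.C;
  // dw/dt = phi_w (w_inf - w)/tau_w with tau_w = 1/cosh(.) => multiply by cosh
  d.dw = p.phi_w * (w_inf(p, V) - w) * std::cosh((V - p.beta_w) / p.cosh_den);
  double gamma = 1.0 / (1.0 + std::exp(-s.k_sig * (V - s.theta_syn)));
  d.ds = s.alpha * gamma * (1.0 - sv) - s.beta * sv;
  return d;
}

// [[Rcpp::export(name = ".rk4_dde_run")]]
List rk4_dde_run(NumericVector model, NumericVector synapse,
                 NumericVector stimulus, double t_max, double h,
                 double V0, double w0, double s0) {
  MLPar p;
  p.C = model[0]; p.gNa = model[1]; p.gK = model[2]; p.gL = model[3];
  p.ENa = model[4]; p.EK = model[5]; p.EL = model[6];
  p.beta_m = model[7]; p.gamma_m = model[8];
  p.beta_w = model[9]; p.gamma_w = model[10];
  p.phi_w = model[11]; p.cosh_den = model[12];

  SynPar sy;
  sy.g_syn = synapse[0]; sy.E_syn = synapse[1]; sy.tau = synapse[2];
  sy.alpha = synapse[3]; sy.beta = synapse[4];
  sy.theta_syn = synapse[5]; sy.k_sig = synapse[6];

  StimPar st;
  st.kind = (int)stimulus[0]; st.baseline = stimulus[1];
  st.amplitude = stimulus[2]; st.onset = stimulus[3];
  st.duration = stimulus[4]; st.period = stimulus[5];
  st.n_pulses = (int)stimulus[6];

  if (h <= 0.0) stop("integration step h must be positive");
  if (t_max < h) stop("t_max must be at least one step h");

  int nt = (int)std::llround(t_max / h);
  NumericVector Vv(nt + 1), wv(nt + 1), ssv(nt + 1), Isynv(nt + 1),
                Istimv(nt + 1);
  std::vector<double> sh(nt + 1);

  double V = V0, w = w0, sv = s0;
  Vv[0] = V; wv[0] = w; ssv[0] = sv; sh[0] = sv;
  Isynv[0] = -sy.g_syn * s_delayed(sh, 0, -sy.tau, h) * (V - sy.E_syn);
  Istimv[0] = stim_current(st, 0.0);

  for (int n = 0; n < nt; ++n) {
    double t = n * h;
    double sd0 = s_delayed(sh, n, t - sy.tau, h);
    double sdh = s_delayed(sh, n, t + 0.5 * h - sy.tau, h);
    double sd1 = s_delayed(sh, n, t + h - sy.tau, h);
    double I0 = stim_current(st, t);
    double Ih = stim_current(st, t + 0.5 * h);
    double I1 = stim_current(st, t + h);

    Deriv k1 = ml_rhs(p, sy, V, w, sv, sd0, I0);
    Deriv k2 = ml_rhs(p, sy, V + 0.5 * h * k1.dV, w + 0.5 * h * k1.dw,
                      sv + 0.5 * h * k1.ds, sdh, Ih);
    Deriv k3 = ml_rhs(p, sy, V + 0.5 * h * k2.dV, w + 0.5 * h * k2.dw,
                      sv + 0.5 * h * k2.ds, sdh, Ih);
    Deriv k4 = ml_rhs(p, sy, V + h * k3.dV, w + h * k3.dw,
                      sv + h * k3.ds, sd1, I1);

    V += h / 6.0 * (k1.dV + 2.0 * k2.dV + 2.0 * k3.dV + k4.dV);
    w += h / 6.0 * (k1.dw + 2.0 * k2.dw + 2.0 * k3.dw + k4.dw);
    sv += h / 6.0 * (k1.ds + 2.0 * k2.ds + 2.0 * k3.ds + k4.ds);

    if (!std::isfinite(V) || !std::isfinite(w) || !std::isfinite(sv))
      stop("state became non-finite at t = %f ms", t + h);

    int m = n + 1;
    Vv[m] = V; wv[m] = w; ssv[m] = sv; sh[m] = sv;
    Isynv[m] = -sy.g_syn * s_delayed(sh, m, m * h - sy.tau, h) *
               (V - sy.E_syn);
    Istimv[m] = stim_current(st, m * h);
  }

  return List::create(_["V"] = Vv, _["w"] = wv, _["s"] = ssv,
                      _["I_syn"] = Isynv, _["I_stim"] = Istimv);
}

// [[Rcpp::export(name = ".stim_current_c")]]
NumericVector stim_current_c(NumericVector stimulus, NumericVector t) {
  StimPar st;
  st.kind = (int)stimulus[0]; st.baseline = stimulus[1];
  st.amplitude = stimulus[2]; st.onset = stimulus[3];
  st.duration = stimulus[4]; st.period = stimulus[5];
  st.n_pulses = (int)stimulus[6];
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = stim_current(st, t[i]);
  return out;
}
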