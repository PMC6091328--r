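// Inner loops of the stochastic Hodgkin-Huxley Ranvier-node simulator.
//
// Voltage convention: original HH (rest at 0 mV, depolarization positive).
// All rates in 1/ms, potentials in mV, time in ms, conductances in mS/cm2,
// currents in uA/cm2, capacitance in uF/cm2 (so uA/uF = mV/ms).
//
// Channel populations are followed as Markov state counts:
//   Na: 8 states indexed h*4 + m, m in 0..3 activation particles,
//       h in {0 = inactivated, 1 = available}; open state is m3h1 (index 7).
//   K:  5 states n0..n4; open state is n4 (index 4).
// Each step uses the embedded-jump (competing-risks) law: for a state with
// outgoing rates lambda_i and total Lambda, the number of channels leaving
// is Binom(N, 1 - exp(-Lambda*dt)) and the leavers are allocated among the
// edges multinomially with weights lambda_i/Lambda (drawn as sequential
// conditional binomials).  For lambda*dt << 1 this reduces to independent
// Binom(N, lambda*dt) draws per edge; unlike raw lambda*dt probabilities it
// stays a valid law at the strongly hyperpolarized excursions that
// high-sigma noise stimulation produces, where the m-deactivation rate
// alone exceeds 1/dt.  Totals are conserved exactly and counts can never
// go negative.  At most one jump per channel per step is taken, so the
// scheme requires dt small against the dwell times that matter (10 us
// against millisecond-scale gating at physiological potentials).
//
// All random draws go through R's RNG (R::rbinom), so set.seed() in R makes
// trajectories bit-reproducible.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct HHRates {
  double am, bm, ah, bh, an, bn;
};

// Standard 1952 rate functions; removable singularities at V = 25 (alpha_m)
// and V = 10 (alpha_n) replaced by their analytic limits when the
// denominator argument is below 1e-7 in magnitude.
static inline HHRates hh_rates_at(double V) {
  HHRates r;
  double x = 25.0 - V;
  r.am = (std::fabs(x) < 1e-7) ? 1.0 : 0.1 * x / expm1(x / 10.0);
  r.bm = 4.0 * std::exp(-V / 18.0);
  r.ah = 0.07 * std::exp(-V / 20.0);
  r.bh = 1.0 / (std::exp((30.0 - V) / 10.0) + 1.0);
  x = 10.0 - V;
  r.an = (std::fabs(x) < 1e-7) ? 0.1 : 0.01 * x / expm1(x / 10.0);
  r.bn = 0.125 * std::exp(-V / 80.0);
  return r;
}

// [[Rcpp::export(name = ".hh_rates_cpp")]]
NumericVector hh_rates_cpp(double V) {
  if (!std::isfinite(V)) stop("membrane potential must be finite");
  HHRates r = hh_rates_at(V);
  return NumericVector::create(
      _["alpha_m"] = r.am, _["beta_m"] = r.bm,
      _["alpha_h"] = r.ah, _["beta_h"] = r.bh,
      _["alpha_n"] = r.an, _["beta_n"] = r.bn);
}

// Binomial sampler on R's uniform stream.  For the common regime of this
// simulator (many states with small expected mover counts) the geometric
// waiting-time method needs ~np + 1 uniforms and beats the generic
// R::rbinom machinery by a large factor; larger np falls back to rbinom.
static inline int draw_binom(int n, double p) {
  if (n <= 0 || p <= 0.0) return 0;
  if (p >= 1.0) return n;
  if (p < 0.2 && n * p < 15.0) {
    const double L = std::log1p(-p);
    int x = 0;
    int i = -1;
    for (;;) {
      i += 1 + (int) (std::log(unif_rand()) / L);
      if (i >= n) break;
      ++x;
    }
    return x;
  }
  return (int) R::rbinom((double) n, p);
}

// Draw the movers out of one state along up to `k` edges with rates
// `lam[0..k-1]` and scatter them onto `delta` at destinations
// `dest[0..k-1]`; `idx` is the source state.
static inline void move_state(int *delta, int idx, int avail,
                              const double *lam, const int *dest, int k,
                              double dt) {
  double Lambda = 0.0;
  for (int i = 0; i < k; ++i) Lambda += lam[i];
  if (Lambda <= 0.0 || avail == 0) return;
  int leavers = draw_binom(avail, -expm1(-Lambda * dt));
  delta[idx] -= leavers;
  double rem = Lambda;
  for (int i = 0; i < k - 1 && leavers > 0; ++i) {
    const int ni = draw_binom(leavers, lam[i] / rem);
    delta[dest[i]] += ni;
    leavers -= ni;
    rem -= lam[i];
  }
  delta[dest[k - 1]] += leavers;
}

// One Markov step for the Na ensemble (counts modified in place).
static void step_na_counts(int *cnt, const HHRates &r, double dt) {
  int delta[8] = {0, 0, 0, 0, 0, 0, 0, 0};
  for (int h = 0; h < 2; ++h) {
    for (int m = 0; m < 4; ++m) {
      const int idx = h * 4 + m;
      if (cnt[idx] == 0) continue;
      double lam[3];
      int dest[3];
      int k = 0;
      if (m < 3) { lam[k] = (3 - m) * r.am; dest[k++] = idx + 1; }
      if (m > 0) { lam[k] = m * r.bm; dest[k++] = idx - 1; }
      lam[k] = (h == 0 ? r.ah : r.bh);
      dest[k++] = (1 - h) * 4 + m;
      move_state(delta, idx, cnt[idx], lam, dest, k, dt);
    }
  }
  for (int i = 0; i < 8; ++i) cnt[i] += delta[i];
}

// One Markov step for the K ensemble (counts modified in place).
static void step_k_counts(int *cnt, const HHRates &r, double dt) {
  int delta[5] = {0, 0, 0, 0, 0};
  for (int n = 0; n < 5; ++n) {
    if (cnt[n] == 0) continue;
    double lam[2];
    int dest[2];
    int k = 0;
    if (n < 4) { lam[k] = (4 - n) * r.an; dest[k++] = n + 1; }
    if (n > 0) { lam[k] = n * r.bn; dest[k++] = n - 1; }
    move_state(delta, n, cnt[n], lam, dest, k, dt);
  }
  for (int i = 0; i < 5; ++i) cnt[i] += delta[i];
}

// [[Rcpp::export(name = ".step_channels_cpp")]]
List step_channels_cpp(IntegerVector na_counts, IntegerVector k_counts,
                       double U, double dt, int n_steps) {
  if (na_counts.size() != 8 || k_counts.size() != 5)
    stop("expected 8 Na states and 5 K states");
  if (!(dt > 0)) stop("dt must be positive");
  int na[8], kk[5];
  for (int i = 0; i < 8; ++i) na[i] = na_counts[i];
  for (int i = 0; i < 5; ++i) kk[i] = k_counts[i];
  const HHRates r = hh_rates_at(U);
  for (int s = 0; s < n_steps; ++s) {
    step_na_counts(na, r, dt);
    step_k_counts(kk, r, dt);
  }
  return List::create(_["na_counts"] = IntegerVector(na, na + 8),
                      _["k_counts"] = IntegerVector(kk, kk + 5));
}

// Time-average open fractions of clamped ensembles (for convergence checks
// against the deterministic steady state without shipping whole
// trajectories back to R).
// [[Rcpp::export(name = ".clamped_open_fraction_cpp")]]
NumericVector clamped_open_fraction_cpp(IntegerVector na_counts,
                                        IntegerVector k_counts, double U,
                                        double dt, int n_steps) {
  int na[8], kk[5];
  for (int i = 0; i < 8; ++i) na[i] = na_counts[i];
  for (int i = 0; i < 5; ++i) kk[i] = k_counts[i];
  long long n_na = 0, n_k = 0;
  for (int i = 0; i < 8; ++i) n_na += na[i];
  for (int i = 0; i < 5; ++i) n_k += kk[i];
  const HHRates r = hh_rates_at(U);
  double acc_na = 0.0, acc_k = 0.0;
  for (int s = 0; s < n_steps; ++s) {
    step_na_counts(na, r, dt);
    step_k_counts(kk, r, dt);
    acc_na += (double) na[7];
    acc_k += (double) kk[4];
  }
  return NumericVector::create(
      _["na_open"] = acc_na / ((double) n_steps * (double) n_na),
      _["k_open"] = acc_k / ((double) n_steps * (double) n_k));
}

// Full stochastic run: forward-Euler integration of the membrane equation
// with Markov channel stepping and online spike detection.
//
// stim: per-step stimulus samples s[k] (mV), length = number of steps.
// The effective potential U = V + s[k] perturbs the potential the channels
// and conductances sense; the integrated state variable remains V and no
// capacitive displacement current from ds/dt is injected.  `coupling`
// selects where U replaces V: 1 = gating rates only, 2 = ionic driving
// forces only, 3 = both.
// [[Rcpp::export(name = ".sim_stochastic_run_cpp")]]
List sim_stochastic_run_cpp(NumericVector stim, double V0,
                            IntegerVector na_counts, IntegerVector k_counts,
                            double I0, double dt,
                            double C_m, double g_l, double E_l,
                            double E_K, double E_Na,
                            double g_na_unit, double g_k_unit,
                            double spike_threshold, double lockout_ms,
                            double burn_in_ms, bool record_trace,
                            int coupling) {
  const int n_steps = stim.size();
  int na[8], kk[5];
  for (int i = 0; i < 8; ++i) na[i] = na_counts[i];
  for (int i = 0; i < 5; ++i) kk[i] = k_counts[i];

  double V = V0;
  std::vector<double> spikes;
  NumericVector trace;
  if (record_trace) trace = NumericVector(n_steps);

  const int lockout_steps = (int) std::ceil(lockout_ms / dt);
  int lockout_left = 0;
  double V_prev = V0;

  for (int k = 0; k < n_steps; ++k) {
    const double U = V + stim[k];
    const double U_gate = (coupling & 1) ? U : V;
    const double U_drive = (coupling & 2) ? U : V;
    const HHRates r = hh_rates_at(U_gate);
    step_na_counts(na, r, dt);
    step_k_counts(kk, r, dt);
    const double g_Na = g_na_unit * (double) na[7];
    const double g_K = g_k_unit * (double) kk[4];
    const double dV = (-g_l * (U_drive - E_l) - g_K * (U_drive - E_K) -
                       g_Na * (U_drive - E_Na) + I0) / C_m;
    V += dt * dV;
    if (!std::isfinite(V) || std::fabs(V) > 500.0)
      stop("membrane potential diverged at step %d (t = %.3f ms)", k + 1,
           (k + 1) * dt);
    const double t = (k + 1) * dt;
    if (lockout_left > 0) {
      --lockout_left;
    } else if (V_prev < spike_threshold && V >= spike_threshold) {
      if (t > burn_in_ms) spikes.push_back(t);
      lockout_left = lockout_steps;
    }
    V_prev = V;
    if (record_trace) trace[k] = V;
  }

  List out = List::create(
      _["spike_times"] = NumericVector(spikes.begin(), spikes.end()),
      _["V_final"] = V,
      _["na_counts"] = IntegerVector(na, na + 8),
      _["k_counts"] = IntegerVector(kk, kk + 5));
  if (record_trace) out["trace"] = trace;
  return out;
}

// Deterministic (infinite-channel) HH model, forward Euler.
// Returns the V trace; gating variables evolve by their ODEs.
// [[Rcpp::export(name = ".sim_deterministic_cpp")]]
NumericVector sim_deterministic_cpp(int n_steps, double dt, double I0,
                                    double C_m, double g_l, double E_l,
                                    double gbar_K, double E_K,
                                    double gbar_Na, double E_Na,
                                    double V0, double m0, double h0,
                                    double n0) {
  NumericVector trace(n_steps);
  double V = V0, m = m0, h = h0, n = n0;
  for (int k = 0; k < n_steps; ++k) {
    const HHRates r = hh_rates_at(V);
    const double g_Na = gbar_Na * m * m * m * h;
    const double g_K = gbar_K * n * n * n * n;
    const double dV = (-g_l * (V - E_l) - g_K * (V - E_K) -
                       g_Na * (V - E_Na) + I0) / C_m;
    m += dt * (r.am * (1.0 - m) - r.bm * m);
    h += dt * (r.ah * (1.0 - h) - r.bh * h);
    n += dt * (r.an * (1.0 - n) - r.bn * n);
    V += dt * dV;
    if (!std::isfinite(V) || std::fabs(V) > 500.0)
      stop("deterministic trajectory diverged at step %d; dt too large?",
           k + 1);
    trace[k] = V;
  }
  return trace;
}
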