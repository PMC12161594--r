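// Compiled kernels for the calcium-based plasticity model.
//
// Conventions: time in ms, voltages in mV, calcium in uM. Stochastic
// draws use R's RNG (norm_rand) or, in the batched kernel, an internal
// stream seeded from R's RNG; set.seed() on the R side controls
// reproducibility either way.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double f_gate(double v) {
  return 1.0 / (1.0 + std::exp(-(v - 20.0) / 2.0));
}

// Fast normal variates for the batched efficacy kernel: xoshiro256+
// stream seeded from R's RNG (set.seed() on the R side fully determines
// the draws), Box-Muller polar with a cached spare.
namespace {
struct FastNorm {
  uint64_t s[4];
  bool has_spare = false;
  double spare = 0.0;
  explicit FastNorm() {
    // derive the stream seed from R's RNG
    for (int i = 0; i < 4; ++i) {
      const uint64_t a = (uint64_t)(unif_rand() * 4294967296.0);
      const uint64_t b = (uint64_t)(unif_rand() * 4294967296.0);
      s[i] = (a << 32) ^ b ^ 0x9E3779B97F4A7C15ULL;
    }
  }
  inline uint64_t next() {
    const uint64_t result = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = (s[3] << 45) | (s[3] >> 19);
    return result;
  }
  inline double runif() {
    return (next() >> 11) * 1.1102230246251565e-16;  // 2^-53
  }
  inline double rnorm() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * runif() - 1.0;
      v = 2.0 * runif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    const double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f;
    has_spare = true;
    return u * f;
  }
};
}  // namespace

// tabulated saturating gate for the hot integration loops
namespace {
constexpr double FG_VMIN = -150.0, FG_VMAX = 150.0, FG_STEP = 0.05;
constexpr int FG_N = (int)((FG_VMAX - FG_VMIN) / FG_STEP) + 1;
const std::vector<double>& fg_table() {
  static std::vector<double> t = [] {
    std::vector<double> v(FG_N);
    for (int i = 0; i < FG_N; ++i)
      v[i] = f_gate(FG_VMIN + i * FG_STEP);
    return v;
  }();
  return t;
}
inline double f_gate_fast(double v) {
  const std::vector<double>& t = fg_table();
  if (v < FG_VMIN) v = FG_VMIN;
  if (v > FG_VMAX) v = FG_VMAX;
  const double u = (v - FG_VMIN) / FG_STEP;
  int i = (int)u;
  if (i >= FG_N - 1) i = FG_N - 2;
  return t[i] + (u - i) * (t[i + 1] - t[i]);
}
}  // namespace

static inline double mca_inf(double v) {
  return 1.0 / (1.0 + std::exp(-(v + 20.0) / 9.0));
}

// [[Rcpp::export(rng = false)]]
double cpp_f_gate(double v) { return f_gate(v); }

// [[Rcpp::export(rng = false)]]
double cpp_mca_inf(double v) { return mca_inf(v); }

// Second-order NMDAR gating driven by a presynaptic voltage trace.
// dx/dt = a_x f(Vpre) - x/tau_x ; ds/dt = a_s x (1-s) - s/tau_s
// RK4 with the drive interpolated linearly between samples.
// [[Rcpp::export(rng = false)]]
NumericVector cpp_nmda_gate(NumericVector vpre, double dt, double a_s,
                            double a_x, double tau_s, double tau_x,
                            double x0 = 0.0, double s0 = 0.0) {
  const int n = vpre.size();
  NumericVector s_out(n);
  double x = x0, s = s0;
  s_out[0] = s;
  for (int i = 0; i + 1 < n; ++i) {
    const double f0 = f_gate_fast(vpre[i]);
    const double f1 = f_gate_fast(vpre[i + 1]);
    const double fh = 0.5 * (f0 + f1);
    // k1
    double k1x = a_x * f0 - x / tau_x;
    double k1s = a_s * x * (1.0 - s) - s / tau_s;
    // k2
    double x2 = x + 0.5 * dt * k1x, s2 = s + 0.5 * dt * k1s;
    double k2x = a_x * fh - x2 / tau_x;
    double k2s = a_s * x2 * (1.0 - s2) - s2 / tau_s;
    // k3
    double x3 = x + 0.5 * dt * k2x, s3 = s + 0.5 * dt * k2s;
    double k3x = a_x * fh - x3 / tau_x;
    double k3s = a_s * x3 * (1.0 - s3) - s3 / tau_s;
    // k4
    double x4 = x + dt * k3x, s4 = s + dt * k3s;
    double k4x = a_x * f1 - x4 / tau_x;
    double k4s = a_s * x4 * (1.0 - s4) - s4 / tau_s;
    x += dt / 6.0 * (k1x + 2.0 * k2x + 2.0 * k3x + k4x);
    s += dt / 6.0 * (k1s + 2.0 * k2s + 2.0 * k3s + k4s);
    s_out[i + 1] = s;
  }
  return s_out;
}

// Exact exponential integrator for dC/dt = drive(t) - C/tau with
// piecewise-linear drive.  More accurate than RK4 for this linear ODE.
// [[Rcpp::export(rng = false)]]
NumericVector cpp_linear_filter(NumericVector drive, double tau, double dt,
                                double init = 0.0) {
  const int n = drive.size();
  NumericVector out(n);
  const double E = std::exp(-dt / tau);
  const double w1 = tau - tau * tau * (1.0 - E) / dt;
  const double w0 = tau * (1.0 - E) - w1;
  double c = init;
  out[0] = c;
  for (int i = 0; i + 1 < n; ++i) {
    c = E * c + w0 * drive[i] + w1 * drive[i + 1];
    if (c < 0.0) c = 0.0;
    out[i + 1] = c;
  }
  return out;
}

// Calcium pair (NMDAR-sourced c_pre, VGCC-sourced c_post) from voltage
// traces.  use_vpost selects the NMDAR Ca driving force: fixed V_rest
// (simple model) or the instantaneous postsynaptic potential (network
// variant).
// [[Rcpp::export(rng = false)]]
List cpp_calcium_pair(NumericVector vpre, NumericVector vpost, List consts,
                      double beta_n, double beta_v, double tau_pre,
                      double tau_post, double dt, bool use_vpost = false) {
  const double alpha_ca = consts["alpha_ca"];
  const double g_nmda = consts["g_nmda"];
  const double g_ca = consts["g_ca"];
  const double v_rest = consts["v_rest"];
  const double v_ca = consts["v_ca"];
  const double area = consts["area"];
  const double a_s = consts["a_s_nmda"], a_x = consts["a_x_nmda"];
  const double tau_s = consts["tau_s_nmda"], tau_x = consts["tau_x_nmda"];

  NumericVector s = cpp_nmda_gate(vpre, dt, a_s, a_x, tau_s, tau_x);
  const int n = vpre.size();
  NumericVector drive_pre(n), drive_post(n);
  for (int i = 0; i < n; ++i) {
    const double vref = use_vpost ? vpost[i] : v_rest;
    drive_pre[i] = alpha_ca * g_nmda * s[i] * (v_ca - vref) * beta_n;
    const double m = mca_inf(vpost[i]);
    drive_post[i] = alpha_ca * area * g_ca * m * m * (v_ca - vpost[i]) * beta_v;
  }
  NumericVector c_pre = cpp_linear_filter(drive_pre, tau_pre, dt);
  NumericVector c_post = cpp_linear_filter(drive_post, tau_post, dt);
  return List::create(_["c_pre"] = c_pre, _["c_post"] = c_post,
                      _["s_nmda"] = s);
}

// Euler-Maruyama integration of the efficacy SDE over a calcium trace that
// is tiled n_tile times (periodic stimulation protocols).  Returns the raw
// final rho of each repeat; settling to the bistable attractors is done by
// the caller (threshold at rho_star).
// [[Rcpp::export]]
NumericVector cpp_rho_final(NumericVector c_period, int n_tile, double dt,
                            double theta_p, double theta_d, double gamma_p,
                            double gamma_d, double sigma, double tau_s,
                            double rho_star, double z, double rho0,
                            int nrep) {
  const int np = c_period.size();
  NumericVector out(nrep);
  // Precompute threshold schedule for the period, run-length encoded.
  std::vector<unsigned char> hp(np), hd(np);
  for (int i = 0; i < np; ++i) {
    hp[i] = c_period[i] >= theta_p ? 1 : 0;
    hd[i] = c_period[i] >= theta_d ? 1 : 0;
  }
  struct Seg { int start, len; unsigned char p, d; };
  std::vector<Seg> segs;
  for (int i = 0; i < np;) {
    int j = i;
    while (j < np && hp[j] == hp[i] && hd[j] == hd[i]) ++j;
    segs.push_back(Seg{i, j - i, hp[i], hd[i]});
    i = j;
  }
  const double sd1 = sigma * z * std::sqrt(dt / tau_s);
  const double sd2 = sd1 * std::sqrt(2.0);
  // below both thresholds the dynamics are the noise-free cubic flow;
  // for the symmetric case rho* = 1/2 it integrates in closed form
  // (u = rho - 1/2, w = u^2 follows a logistic equation), so silent
  // stretches advance in one jump instead of step by step
  const bool exact_quiet = rho_star == 0.5;
  GetRNGstate();
  for (int r = 0; r < nrep; ++r) {
    double rho = rho0;
    for (int t = 0; t < n_tile; ++t) {
      for (size_t s = 0; s < segs.size(); ++s) {
        const Seg& sg = segs[s];
        const int h = sg.p + sg.d;
        if (h == 0 && exact_quiet) {
          const double u0 = rho - 0.5;
          const double w0 = u0 * u0;
          const double e = std::exp(0.5 * sg.len * dt / tau_s);
          const double w = 0.25 * w0 * e / (0.25 + w0 * (e - 1.0));
          rho = 0.5 + (u0 >= 0 ? std::sqrt(w) : -std::sqrt(w));
          continue;
        }
        const double sd = h == 2 ? sd2 : (h == 1 ? sd1 : 0.0);
        for (int i = 0; i < sg.len; ++i) {
          double drift = -rho * (1.0 - rho) * (rho_star - rho);
          if (sg.p) drift += gamma_p * (1.0 - rho);
          if (sg.d) drift -= gamma_d * rho;
          rho += drift * dt / tau_s;
          if (h > 0) rho += sd * norm_rand();
        }
      }
    }
    out[r] = rho;
  }
  PutRNGstate();
  return out;
}

// Gaussian moment closure of the efficacy SDE over a periodic threshold
// schedule: propagates the mean and variance of rho through the tiled
// protocol, including the cubic drift via its exact Gaussian moments
// (E[rho^2] = m^2 + v, E[rho^3] = m^3 + 3 m v, Cov(rho, rho^2) = 2 m v,
// Cov(rho, rho^3) = 3 v (m^2 + v)).  Deterministic closed-form
// propagation; the refined analytic route for the synaptic change.
// [[Rcpp::export(rng = false)]]
NumericVector cpp_moment_closure(NumericVector c_period, int n_tile,
                                 double dt, double theta_p, double theta_d,
                                 double gamma_p, double gamma_d,
                                 double sigma_eff, double tau_s,
                                 double rho_star, double rho0) {
  const int np = c_period.size();
  std::vector<unsigned char> hp(np), hd(np);
  for (int i = 0; i < np; ++i) {
    hp[i] = c_period[i] >= theta_p ? 1 : 0;
    hd[i] = c_period[i] >= theta_d ? 1 : 0;
  }
  double m = rho0, v = 0.0;
  const double idt = dt / tau_s;
  const double s2 = sigma_eff * sigma_eff * idt;
  for (int t = 0; t < n_tile; ++t) {
    for (int i = 0; i < np; ++i) {
      const double a = hp[i] ? gamma_p : 0.0;
      const double b = a + (hd[i] ? gamma_d : 0.0);
      const double m2 = m * m;
      const double cub_m = -rho_star * m + (1.0 + rho_star) * (m2 + v) -
                           (m2 * m + 3.0 * m * v);
      const double cub_c = -rho_star * v + 2.0 * (1.0 + rho_star) * m * v -
                           3.0 * v * (m2 + v);
      const double dm = (a - b * m + cub_m) * idt;
      double dv = (-2.0 * b * v + 2.0 * cub_c) * idt +
                  s2 * (hp[i] + hd[i]);
      m += dm;
      v += dv;
      if (v < 0.0) v = 0.0;
    }
  }
  return NumericVector::create(m, v);
}

// Full rho trajectory over a (non-tiled) calcium trace, recorded every
// `stride` steps.  Same dynamics as cpp_rho_final.
// [[Rcpp::export]]
NumericVector cpp_rho_trace(NumericVector c, double dt, double theta_p,
                            double theta_d, double gamma_p, double gamma_d,
                            double sigma, double tau_s, double rho_star,
                            double z, double rho0, int stride = 1) {
  const int n = c.size();
  const int nout = (n - 1) / stride + 1;
  NumericVector out(nout);
  const double sd1 = sigma * z * std::sqrt(dt / tau_s);
  const double sd2 = sd1 * std::sqrt(2.0);
  double rho = rho0;
  out[0] = rho;
  GetRNGstate();
  int k = 1;
  for (int i = 1; i < n; ++i) {
    const bool p = c[i - 1] >= theta_p, d = c[i - 1] >= theta_d;
    double drift = -rho * (1.0 - rho) * (rho_star - rho);
    if (p) drift += gamma_p * (1.0 - rho);
    if (d) drift -= gamma_d * rho;
    rho += drift * dt / tau_s;
    const int h = (p ? 1 : 0) + (d ? 1 : 0);
    if (h == 1)
      rho += sd1 * norm_rand();
    else if (h == 2)
      rho += sd2 * norm_rand();
    if (i % stride == 0 && k < nout) out[k++] = rho;
  }
  PutRNGstate();
  return out;
}

// Rule-search batch: given the unscaled periodic Ca2+ influx drive
// templates of the pairing protocol (NMDAR source from the presynaptic
// spike, VGCC source from the postsynaptic spike at lag 0), process many
// candidate parameter sets.  For each candidate:
//   * filter both drives with (tau_pre, tau_post) over n_settle+1 periods
//     and keep the final period as the periodic steady-state template;
//   * calibrate beta_nmda / beta_vgcc so the transient peaks hit the
//     target amplitudes (0.7 / 1.4 uM);
//   * rebalance gamma_d so gamma_p*alpha_p = gamma_d*alpha_d at the
//     balance lag;
//   * compute the threshold occupancies alpha_p, alpha_d at every lag
//     (postsynaptic template circularly shifted by the lag).
// [[Rcpp::export(rng = false)]]
List cpp_rule_search_batch(NumericVector drive_pre, NumericVector drive_post,
                           double dt, int n_settle, NumericVector tau_pre,
                           NumericVector tau_post, NumericVector theta_p,
                           NumericVector theta_d, NumericVector gamma_p,
                           IntegerVector lag_steps, int balance_lag_step,
                           double amp_pre_target, double amp_post_target) {
  const int np = drive_pre.size();
  const int ncand = tau_pre.size();
  const int nlag = lag_steps.size();
  NumericVector beta_n(ncand), beta_v(ncand), gamma_d_new(ncand);
  LogicalVector degenerate(ncand);
  NumericMatrix alpha_p(ncand, nlag), alpha_d(ncand, nlag);
  std::vector<double> cpre(np), cpost(np);

  for (int k = 0; k < ncand; ++k) {
    // periodic steady-state template by running n_settle+1 periods
    for (int srcix = 0; srcix < 2; ++srcix) {
      const double tau = srcix == 0 ? tau_pre[k] : tau_post[k];
      const NumericVector& d = srcix == 0 ? drive_pre : drive_post;
      std::vector<double>& out = srcix == 0 ? cpre : cpost;
      const double E = std::exp(-dt / tau);
      const double w1 = tau - tau * tau * (1.0 - E) / dt;
      const double w0 = tau * (1.0 - E) - w1;
      double c = 0.0;
      for (int rep = 0; rep <= n_settle; ++rep) {
        for (int i = 0; i < np; ++i) {
          const int inext = i + 1 < np ? i + 1 : 0;
          c = E * c + w0 * d[i] + w1 * d[inext];
          if (c < 0.0) c = 0.0;
          if (rep == n_settle) out[i] = c;
        }
      }
    }
    double amp_pre = 0.0, amp_post = 0.0;
    for (int i = 0; i < np; ++i) {
      if (cpre[i] > amp_pre) amp_pre = cpre[i];
      if (cpost[i] > amp_post) amp_post = cpost[i];
    }
    if (amp_pre <= 0.0 || amp_post <= 0.0) {
      degenerate[k] = true;
      continue;
    }
    const double bn = amp_pre_target / amp_pre;
    const double bv = amp_post_target / amp_post;
    beta_n[k] = bn;
    beta_v[k] = bv;

    auto alphas_at = [&](int lag, double* ap, double* ad) {
      int above_p = 0, above_d = 0;
      for (int i = 0; i < np; ++i) {
        int j = i - lag;
        j %= np;
        if (j < 0) j += np;
        const double c = bn * cpre[i] + bv * cpost[j];
        if (c >= theta_p[k]) ++above_p;
        if (c >= theta_d[k]) ++above_d;
      }
      *ap = (double)above_p / np;
      *ad = (double)above_d / np;
    };

    double ap_b, ad_b;
    alphas_at(balance_lag_step, &ap_b, &ad_b);
    if (ap_b <= 0.0 || ad_b <= 0.0) {
      degenerate[k] = true;
      continue;
    }
    gamma_d_new[k] = gamma_p[k] * ap_b / ad_b;
    for (int l = 0; l < nlag; ++l) {
      double ap, ad;
      alphas_at(lag_steps[l], &ap, &ad);
      alpha_p(k, l) = ap;
      alpha_d(k, l) = ad;
    }
  }
  return List::create(_["beta_n"] = beta_n, _["beta_v"] = beta_v,
                      _["gamma_d"] = gamma_d_new,
                      _["degenerate"] = degenerate, _["alpha_p"] = alpha_p,
                      _["alpha_d"] = alpha_d);
}

// Batched state-comparison kernel: many learning-rule parameter sets run
// over one set of precomputed calcium drive traces (fan-in topology; the
// postsynaptic VGCC drive is shared across synapses).
//
// drive_pre: steps x n_syn matrix of unscaled NMDAR Ca influx rates
//            (uM/ms at beta_n = 1) per presynaptic partner.
// drive_post: unscaled VGCC Ca influx rate of the postsynaptic neuron.
// rules: list of equal-length numeric vectors (beta_n, beta_v, tau_pre,
//        tau_post, theta_p, theta_d, gamma_p, gamma_d, sigma, tau_s,
//        rho_star).
// Returns per rule: mean efficacy (window average over time and synapses),
// mean across-synapse CV per step averaged over the window, and the
// per-synapse window means.
// [[Rcpp::export]]
List cpp_efficacy_batch(NumericMatrix drive_pre, NumericVector drive_post,
                        List rules, double z, double dt, double rho0,
                        int window_start) {
  const int steps = drive_pre.nrow();
  const int nsyn = drive_pre.ncol();
  NumericVector beta_n = rules["beta_n"], beta_v = rules["beta_v"],
                tau_pre = rules["tau_pre"], tau_post = rules["tau_post"],
                theta_p = rules["theta_p"], theta_d = rules["theta_d"],
                gamma_p = rules["gamma_p"], gamma_d = rules["gamma_d"],
                sigma = rules["sigma"], tau_s = rules["tau_s"],
                rho_star = rules["rho_star"];
  const int nrule = beta_n.size();
  NumericVector mean_eff(nrule), mean_cv(nrule);
  NumericMatrix syn_mean(nrule, nsyn);

  // per-rule integrator coefficients
  std::vector<double> Epre(nrule), w0p(nrule), w1p(nrule), Epost(nrule),
      w0q(nrule), w1q(nrule), sd1(nrule), sd2(nrule), inv_tau(nrule);
  for (int r = 0; r < nrule; ++r) {
    Epre[r] = std::exp(-dt / tau_pre[r]);
    w1p[r] = (tau_pre[r] -
              tau_pre[r] * tau_pre[r] * (1.0 - Epre[r]) / dt) * beta_n[r];
    w0p[r] = tau_pre[r] * (1.0 - Epre[r]) * beta_n[r] - w1p[r];
    Epost[r] = std::exp(-dt / tau_post[r]);
    w1q[r] = (tau_post[r] -
              tau_post[r] * tau_post[r] * (1.0 - Epost[r]) / dt) * beta_v[r];
    w0q[r] = tau_post[r] * (1.0 - Epost[r]) * beta_v[r] - w1q[r];
    sd1[r] = sigma[r] * z * std::sqrt(dt / tau_s[r]);
    sd2[r] = sd1[r] * std::sqrt(2.0);
    inv_tau[r] = dt / tau_s[r];
  }

  // rule x synapse state; single pass over the drive traces keeps the
  // (large) drive matrix traffic down to one read
  std::vector<double> cpre(nrule * nsyn, 0.0), rho(nrule * nsyn, rho0),
      cpost(nrule, 0.0), srho(nrule * nsyn, 0.0), scv(nrule, 0.0);
  std::vector<double> dp0(nsyn), dp1(nsyn);
  long nwin = 0;

  GetRNGstate();
  FastNorm rng;
  for (int i = 0; i + 1 < steps; ++i) {
    const double dq0 = drive_post[i], dq1 = drive_post[i + 1];
    for (int jsy = 0; jsy < nsyn; ++jsy) {
      dp0[jsy] = drive_pre(i, jsy);
      dp1[jsy] = drive_pre(i + 1, jsy);
    }
    const bool in_win = (i + 1 >= window_start);
    if (in_win) ++nwin;
    for (int r = 0; r < nrule; ++r) {
      double cq = Epost[r] * cpost[r] + w0q[r] * dq0 + w1q[r] * dq1;
      if (cq < 0.0) cq = 0.0;
      cpost[r] = cq;
      const double gp = gamma_p[r], gd = gamma_d[r], tp = theta_p[r],
                   td = theta_d[r], rs = rho_star[r];
      double* cp_r = &cpre[r * nsyn];
      double* rho_r = &rho[r * nsyn];
      double* srho_r = &srho[r * nsyn];
      double s1 = 0.0, s2 = 0.0;
      for (int jsy = 0; jsy < nsyn; ++jsy) {
        double cp = Epre[r] * cp_r[jsy] + w0p[r] * dp0[jsy] +
                    w1p[r] * dp1[jsy];
        if (cp < 0.0) cp = 0.0;
        cp_r[jsy] = cp;
        const double c = cp + cq;
        const bool ap = c >= tp, ad = c >= td;
        double rr = rho_r[jsy];
        double drift = -rr * (1.0 - rr) * (rs - rr);
        if (ap) drift += gp * (1.0 - rr);
        if (ad) drift -= gd * rr;
        rr += drift * inv_tau[r];
        const int h = (ap ? 1 : 0) + (ad ? 1 : 0);
        if (h == 1)
          rr += sd1[r] * rng.rnorm();
        else if (h == 2)
          rr += sd2[r] * rng.rnorm();
        rho_r[jsy] = rr;
        if (in_win) {
          srho_r[jsy] += rr;
          s1 += rr;
          s2 += rr * rr;
        }
      }
      if (in_win && nsyn > 1) {
        const double m = s1 / nsyn;
        double var = (s2 - nsyn * m * m) / (nsyn - 1);
        if (var < 0.0) var = 0.0;
        if (m != 0.0) scv[r] += std::sqrt(var) / m;
      }
    }
  }
  PutRNGstate();
  for (int r = 0; r < nrule; ++r) {
    double tot = 0.0;
    for (int jsy = 0; jsy < nsyn; ++jsy) {
      syn_mean(r, jsy) = srho[r * nsyn + jsy] / nwin;
      tot += srho[r * nsyn + jsy];
    }
    mean_eff[r] = tot / (nwin * (double)nsyn);
    mean_cv[r] = nsyn > 1 ? scv[r] / nwin : NA_REAL;
  }
  return List::create(_["mean"] = mean_eff, _["cv"] = mean_cv,
                      _["syn_mean"] = syn_mean);
}
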