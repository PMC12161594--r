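// Hodgkin-Huxley-based averaged-neuron and network integrator.
//
// Nine intrinsic currents (leak, Na, K, A, KS, Ca, KCa, NaP, AR), three
// synaptic receptor currents (AMPA, NMDA, GABA) and a cell-body Ca2+
// compartment per neuron.  Units: mV, ms, mS/cm2 for intrinsic
// conductances, uS for synaptic conductances, uM for Ca2+.  Intrinsic
// currents are multiplied by (area x 10) to convert to nA.
//
// The single-neuron model is the "averaged neuron": its own membrane
// potential drives its synaptic gating variables (mean-field
// self-coupling), which is what makes synaptic parameters bifurcation
// axes even for one neuron.
//
// The voltage-dependent rate/steady-state functions are fixed model forms;
// they are tabulated once on a 0.05 mV grid and linearly interpolated
// (large parameter searches make exp() the dominant cost otherwise).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

constexpr double TAB_VMIN = -150.0, TAB_VMAX = 150.0, TAB_STEP = 0.05;
constexpr int TAB_N = (int)((TAB_VMAX - TAB_VMIN) / TAB_STEP) + 1;

// table layout is interleaved (one 13-entry row per voltage bin) so a
// lookup touches two adjacent rows instead of 13 scattered vectors
enum TabCol { T_MNA = 0, T_AH, T_BH, T_AN, T_BN, T_MA3, T_HAINF, T_MKSINF,
              T_TAUKSI, T_MCA2, T_MNAP3, T_HAR, T_FG, T_NCOL };

struct VTables {
  std::vector<double> row;
  VTables() : row((size_t)TAB_N * T_NCOL) {
    for (int i = 0; i < TAB_N; ++i) {
      const double v = TAB_VMIN + i * TAB_STEP;
      double* r = &row[(size_t)i * T_NCOL];
      const double dam = (v + 33.0) / 10.0;
      const double am = std::fabs(dam) < 1e-7
                            ? 0.1 * 10.0
                            : 0.1 * (v + 33.0) / (1.0 - std::exp(-dam));
      const double bm = 4.0 * std::exp(-(v + 53.7) / 12.0);
      r[T_MNA] = am / (am + bm);
      r[T_AH] = 0.07 * std::exp(-(v + 50.0) / 10.0);
      r[T_BH] = 1.0 / (1.0 + std::exp(-(v + 20.0) / 10.0));
      const double dan = (v + 34.0) / 10.0;
      r[T_AN] = std::fabs(dan) < 1e-7
                    ? 0.01 * 10.0
                    : 0.01 * (v + 34.0) / (1.0 - std::exp(-dan));
      r[T_BN] = 0.125 * std::exp(-(v + 44.0) / 25.0);
      const double ma = 1.0 / (1.0 + std::exp(-(v + 50.0) / 2.0));
      r[T_MA3] = ma * ma * ma;
      r[T_HAINF] = 1.0 / (1.0 + std::exp((v + 80.0) / 6.0));
      r[T_MKSINF] = 1.0 / (1.0 + std::exp(-(v + 34.0) / 6.5));
      r[T_TAUKSI] =
          (std::exp(-(v + 55.0) / 30.0) + std::exp((v + 55.0) / 30.0)) / 8.0;
      const double mca = 1.0 / (1.0 + std::exp(-(v + 20.0) / 9.0));
      r[T_MCA2] = mca * mca;
      const double mnap = 1.0 / (1.0 + std::exp(-(v + 55.7) / 7.7));
      r[T_MNAP3] = mnap * mnap * mnap;
      r[T_HAR] = 1.0 / (1.0 + std::exp((v + 75.0) / 4.0));
      r[T_FG] = 1.0 / (1.0 + std::exp(-(v - 20.0) / 2.0));
    }
  }
};

const VTables& tables() {
  static VTables t;
  return t;
}

struct VLook {
  const double* r0;
  const double* r1;
  double w;
  explicit VLook(double v) {
    if (v < TAB_VMIN) v = TAB_VMIN;
    if (v > TAB_VMAX) v = TAB_VMAX;
    const double u = (v - TAB_VMIN) / TAB_STEP;
    int i = (int)u;
    if (i >= TAB_N - 1) i = TAB_N - 2;
    w = u - i;
    const double* base = tables().row.data();
    r0 = base + (size_t)i * T_NCOL;
    r1 = r0 + T_NCOL;
  }
  inline double get(int col) const {
    return r0[col] + w * (r1[col] - r0[col]);
  }
};

inline double fgate(double v) { return VLook(v).get(T_FG); }

struct HHConsts {
  double area10, c_m;
  double v_l, v_na, v_k, v_ca, v_ampa, v_nmda, v_gaba;
  double kd35, tau_ha, phi, alpha_ca;
  double tau_ampa, tau_s_nmda, tau_x_nmda, tau_gaba;
};

struct HHParams {
  double gl, gna, gk, ga, gks, gca, gkca, gnap, gar;  // mS/cm2
  double gampa, gnmda, ggaba;                          // uS
  double tau_ca;                                       // ms
  double a_ampa, a_x_nmda, a_gaba, a_s_nmda;           // 1/ms
};

HHConsts read_consts(const List& consts) {
  HHConsts c;
  const double area = as<double>(consts["area"]);
  c.area10 = area * 10.0;
  c.c_m = as<double>(consts["c_m"]);
  c.v_l = as<double>(consts["v_l"]);
  c.v_na = as<double>(consts["v_na"]);
  c.v_k = as<double>(consts["v_k"]);
  c.v_ca = as<double>(consts["v_ca"]);
  c.v_ampa = as<double>(consts["v_ampa"]);
  c.v_nmda = as<double>(consts["v_nmda"]);
  c.v_gaba = as<double>(consts["v_gaba"]);
  const double kd = as<double>(consts["kd"]);
  c.kd35 = kd * kd * kd * std::sqrt(kd);
  c.tau_ha = as<double>(consts["tau_ha"]);
  c.phi = as<double>(consts["phi"]);
  c.alpha_ca = as<double>(consts["alpha_ca"]);
  c.tau_ampa = as<double>(consts["tau_ampa"]);
  c.tau_s_nmda = as<double>(consts["tau_s_nmda"]);
  c.tau_x_nmda = as<double>(consts["tau_x_nmda"]);
  c.tau_gaba = as<double>(consts["tau_gaba"]);
  return c;
}

HHParams read_params(const NumericVector& p) {
  HHParams q;
  q.gl = p["gl"]; q.gna = p["gna"]; q.gk = p["gk"]; q.ga = p["ga"];
  q.gks = p["gks"]; q.gca = p["gca"]; q.gkca = p["gkca"];
  q.gnap = p["gnap"]; q.gar = p["gar"];
  q.gampa = p["gampa"]; q.gnmda = p["gnmda"]; q.ggaba = p["ggaba"];
  q.tau_ca = p["tau_ca"];
  q.a_ampa = p["a_ampa"]; q.a_x_nmda = p["a_x_nmda"];
  q.a_gaba = p["a_gaba"]; q.a_s_nmda = p["a_s_nmda"];
  return q;
}

// Intrinsic current sum (uA/cm2 scale, pre area conversion) and gating +
// Ca derivatives for one neuron.  y: V,hna,nk,ha,mks,ca
inline double intrinsic_rhs(const double* y, const HHParams& p,
                            const HHConsts& c, double* dy,
                            double* i_ca_out) {
  const double v = y[0], hna = y[1], nk = y[2], ha = y[3], mks = y[4],
               ca = y[5];
  const VLook L(v);
  const double mna = L.get(T_MNA);
  const double ca35 = ca > 0.0 ? ca * ca * ca * std::sqrt(ca) : 0.0;
  const double mkca = ca35 / (ca35 + c.kd35);

  const double i_l = p.gl * (v - c.v_l);
  const double i_na = p.gna * mna * mna * mna * hna * (v - c.v_na);
  const double nk2 = nk * nk;
  const double i_k = p.gk * nk2 * nk2 * (v - c.v_k);
  const double i_a = p.ga * L.get(T_MA3) * ha * (v - c.v_k);
  const double i_ks = p.gks * mks * (v - c.v_k);
  const double i_ca = p.gca * L.get(T_MCA2) * (v - c.v_ca);
  const double i_kca = p.gkca * mkca * (v - c.v_k);
  const double i_nap = p.gnap * L.get(T_MNAP3) * (v - c.v_na);
  const double i_ar = p.gar * L.get(T_HAR) * (v - c.v_k);

  dy[1] = c.phi * 4.0 * (L.get(T_AH) * (1.0 - hna) - L.get(T_BH) * hna);
  dy[2] = c.phi * 4.0 * (L.get(T_AN) * (1.0 - nk) - L.get(T_BN) * nk);
  dy[3] = c.phi * (L.get(T_HAINF) - ha) / c.tau_ha;
  dy[4] = c.phi * (L.get(T_MKSINF) - mks) * L.get(T_TAUKSI);
  dy[5] = -c.alpha_ca * (c.area10 * i_ca) - ca / p.tau_ca;
  *i_ca_out = i_ca;
  return i_l + i_na + i_k + i_a + i_ks + i_ca + i_kca + i_nap + i_ar;
}

// Single averaged neuron; state: V,hna,nk,ha,mks,ca,sampa,snmda,xnmda,sgaba
inline void single_rhs(const double* y, const HHParams& p, const HHConsts& c,
                       double* dy) {
  double i_ca;
  const double i_int = intrinsic_rhs(y, p, c, dy, &i_ca);
  const double v = y[0];
  const double sa = y[6], sn = y[7], xn = y[8], sg = y[9];
  const double i_ampa = p.gampa * sa * (v - c.v_ampa);
  const double i_nmda = p.gnmda * sn * (v - c.v_nmda);
  const double i_gaba = p.ggaba * sg * (v - c.v_gaba);
  dy[0] = -(c.area10 * i_int + i_ampa + i_nmda + i_gaba) / c.c_m;
  const double fv = fgate(v);
  dy[6] = p.a_ampa * fv - sa / c.tau_ampa;
  dy[7] = p.a_s_nmda * xn * (1.0 - sn) - sn / c.tau_s_nmda;
  dy[8] = p.a_x_nmda * fv - xn / c.tau_x_nmda;
  dy[9] = p.a_gaba * fv - sg / c.tau_gaba;
}

}  // namespace

// [[Rcpp::export(rng = false)]]
List cpp_hh_single(NumericVector params, List consts, double duration,
                   double dt, NumericVector init, double record_dt,
                   double analysis_start, bool allow_fastforward = true) {
  const HHConsts c = read_consts(consts);
  const HHParams p = read_params(params);
  const int nstate = 10;
  double y[nstate], yt[nstate], k1[nstate], k2[nstate], k3[nstate],
      k4[nstate];
  for (int i = 0; i < nstate; ++i) y[i] = init[i];

  const long nsteps = (long)std::llround(duration / dt);
  const int rec_stride = std::max(1, (int)std::llround(record_dt / dt));
  const long nrec = nsteps / rec_stride + 1;
  NumericVector v_rec(nrec);
  std::vector<double> up_cross;
  long irec = 0;
  v_rec[irec++] = y[0];
  int ncross = 0;
  double vmin = R_PosInf, vmax = R_NegInf;
  bool ok = true;

  // quiescence detection: if V stays within a hair-thin band for a long
  // window the trajectory has reached a fixed point; the remaining trace
  // is constant and integration can stop early.
  const long quiet_win = (long)std::llround(500.0 / dt);
  double band_lo = y[0], band_hi = y[0];
  long band_n = 0;
  bool frozen = false;

  for (long n = 0; n < nsteps; ++n) {
    const double vprev = y[0];
    if (!frozen) {
      single_rhs(y, p, c, k1);
      for (int i = 0; i < nstate; ++i) yt[i] = y[i] + 0.5 * dt * k1[i];
      single_rhs(yt, p, c, k2);
      for (int i = 0; i < nstate; ++i) yt[i] = y[i] + 0.5 * dt * k2[i];
      single_rhs(yt, p, c, k3);
      for (int i = 0; i < nstate; ++i) yt[i] = y[i] + dt * k3[i];
      single_rhs(yt, p, c, k4);
      for (int i = 0; i < nstate; ++i)
        y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      if (y[5] < 0.0) y[5] = 0.0;
    }
    const double v = y[0];
    if (!std::isfinite(v) || std::fabs(v) > 1000.0) {
      ok = false;
      break;
    }
    const double t_ms = (n + 1) * dt;
    if (t_ms >= analysis_start) {
      if (v < vmin) vmin = v;
      if (v > vmax) vmax = v;
      // amplitudes beyond +/-200 mV already decide the classification
      if (vmax > 200.0 || vmin < -200.0) break;
      if ((vprev < -20.0 && v >= -20.0) || (vprev >= -20.0 && v < -20.0)) {
        ++ncross;
        if (v >= -20.0) up_cross.push_back(t_ms);
      }
    }
    if ((n + 1) % rec_stride == 0 && irec < nrec) v_rec[irec++] = v;
    if (allow_fastforward && !frozen) {
      if (v < band_lo) { band_lo = v; band_n = 0; band_hi = v + 1e-2; }
      else if (v > band_hi) { band_hi = v; band_n = 0; band_lo = v - 1e-2; }
      else if (++band_n >= quiet_win) frozen = true;
    }
  }
  while (irec < nrec) v_rec[irec++] = y[0];
  NumericVector final_state(nstate);
  for (int i = 0; i < nstate; ++i) final_state[i] = y[i];
  return List::create(_["v"] = v_rec, _["record_dt"] = rec_stride * dt,
                      _["n_cross"] = ncross,
                      _["spike_times"] = wrap(up_cross), _["vmin"] = vmin,
                      _["vmax"] = vmax, _["ok"] = ok,
                      _["final_state"] = final_state);
}

// ---------------------------------------------------------------------------
// Network
// ---------------------------------------------------------------------------
// Per-neuron state (ns = 10): V,hna,nk,ha,mks,ca,sampa,snmda,xnmda,sgaba.
// Optional plasticity adds per neuron a fast NMDAR gate (xp, sp) with the
// plasticity-model kinetics plus a VGCC-sourced c_post, and per excitatory
// synapse an NMDAR-sourced c_pre and the efficacy rho (Euler-Maruyama,
// operator-split from the RK4 of the smooth states).  Optional per-neuron
// kinase states (r, a, xi) modulate conductances (post: incoming NMDA;
// intracellular: VGCC; presyn: outgoing activation coefficients).
//
// axis codes: 0 none; 1..12 gl,gna,gk,ga,gks,gca,gkca,gnap,gar,gampa,
// gnmda,ggaba; 13 presynaptic coefficients (a_ampa, a_x_nmda, a_gaba
// jointly); 14 tau_ca.

// [[Rcpp::export]]
List cpp_hh_network(NumericVector params, List consts, List net,
                    NumericVector phase_dur, NumericVector phase_mult,
                    LogicalVector phase_stim, double dt, double record_dt,
                    List plasticity, List kinase, List stim, int axis,
                    List init) {
  const HHConsts c = read_consts(consts);
  HHParams p0 = read_params(params);

  IntegerVector pre = net["pre"], post = net["post"];
  LogicalVector edge_exc = net["exc"];
  LogicalVector is_exc = net["is_exc"];
  const double gdiv_e = as<double>(net["mean_n_exc"]);
  const double gdiv_i = as<double>(net["mean_n_inh"]);
  const int nn = is_exc.size();
  const int ne = pre.size();

  const bool plast_on = as<bool>(plasticity["enabled"]);
  double pl_beta_n = 0, pl_beta_v = 0, pl_tau_pre = 1, pl_tau_post = 1,
         pl_theta_p = 0, pl_theta_d = 0, pl_gamma_p = 0, pl_gamma_d = 0,
         pl_sigma = 0, pl_tau_s = 1, pl_rho_star = 0.5, pl_z = 3.5,
         pl_rho0 = 0.5, pl_as = 0, pl_ax = 0, pl_taus = 1, pl_taux = 1,
         pl_gnmda = 1, pl_gca = 1;
  bool couple_ampa = false, rec_rho_edges = false;
  if (plast_on) {
    pl_beta_n = as<double>(plasticity["beta_n"]);
    pl_beta_v = as<double>(plasticity["beta_v"]);
    pl_tau_pre = as<double>(plasticity["tau_pre"]);
    pl_tau_post = as<double>(plasticity["tau_post"]);
    pl_theta_p = as<double>(plasticity["theta_p"]);
    pl_theta_d = as<double>(plasticity["theta_d"]);
    pl_gamma_p = as<double>(plasticity["gamma_p"]);
    pl_gamma_d = as<double>(plasticity["gamma_d"]);
    pl_sigma = as<double>(plasticity["sigma"]);
    pl_tau_s = as<double>(plasticity["tau_s"]);
    pl_rho_star = as<double>(plasticity["rho_star"]);
    pl_z = as<double>(plasticity["z"]);
    pl_rho0 = as<double>(plasticity["rho0"]);
    pl_as = as<double>(plasticity["a_s_nmda"]);
    pl_ax = as<double>(plasticity["a_x_nmda"]);
    pl_taus = as<double>(plasticity["tau_s_nmda"]);
    pl_taux = as<double>(plasticity["tau_x_nmda"]);
    pl_gnmda = as<double>(plasticity["g_nmda"]);
    pl_gca = as<double>(plasticity["g_ca"]);
    couple_ampa = as<bool>(plasticity["couple_ampa"]);
    rec_rho_edges = as<bool>(plasticity["record_rho_edges"]);
  }

  const int kin_mode = as<int>(kinase["mode"]);
  double kn_tau_r = 1, kn_tau_a = 1, kn_w = 0, kn_alpha = 0, kn_b = 0,
         kn_beta = 0, kn_i = 0, kn_c = 1, kn_d = 0, kn_e = 1, kn_theta = 0,
         kn_eps = 0, kn_max_rate = 1;
  int kin_stride = 1;
  double kn_r0 = 0, kn_a0 = 0, kn_xi0 = 0;
  bool kn_couple_a = true;
  if (kin_mode > 0) {
    kn_tau_r = as<double>(kinase["tau_r"]);
    kn_tau_a = as<double>(kinase["tau_a"]);
    kn_w = as<double>(kinase["w"]);
    kn_alpha = as<double>(kinase["alpha"]);
    kn_b = as<double>(kinase["b"]);
    kn_beta = as<double>(kinase["beta"]);
    kn_i = as<double>(kinase["i0"]);
    kn_c = as<double>(kinase["c"]);
    kn_d = as<double>(kinase["d"]);
    kn_e = as<double>(kinase["e"]);
    kn_theta = as<double>(kinase["theta"]);
    kn_eps = as<double>(kinase["epsilon"]);
    kn_max_rate = as<double>(kinase["max_rate"]);
    kin_stride = as<int>(kinase["stride"]);
    kn_r0 = as<double>(kinase["r0"]);
    kn_a0 = as<double>(kinase["a0"]);
    kn_xi0 = as<double>(kinase["xi0"]);
    kn_couple_a = as<bool>(kinase["couple_a"]);
  }

  IntegerVector stim_targets = stim["targets"];
  const double stim_rate = as<double>(stim["rate_hz"]);
  const double stim_amp = as<double>(stim["amp_na"]);
  const double stim_width = as<double>(stim["width_ms"]);
  std::vector<char> stim_mask(nn, 0);
  for (int i = 0; i < stim_targets.size(); ++i) stim_mask[stim_targets[i]] = 1;

  const int ns = 10;
  NumericMatrix y0 = init["state"];  // nn x ns
  std::vector<double> y(nn * ns), yt(nn * ns), k1(nn * ns), k2(nn * ns),
      k3(nn * ns), k4(nn * ns);
  for (int n = 0; n < nn; ++n)
    for (int s = 0; s < ns; ++s) y[n * ns + s] = y0(n, s);

  std::vector<double> xp(nn, 0.0), sp(nn, 0.0), cpost(nn, 0.0);
  std::vector<double> cpre(ne, 0.0), rho(ne, pl_rho0);
  std::vector<double> kr(nn, kn_r0), ka(nn, kn_a0), kxi(nn, kn_xi0),
      kca_acc(nn, 0.0);
  std::vector<double> mod_nmda_in(nn, 1.0), mod_vgcc(nn, 1.0),
      mod_presyn(nn, 1.0);
  if (kin_mode > 0) {
    const double cv0 = kn_couple_a ? kn_a0 : kn_r0;
    for (int i = 0; i < nn; ++i) {
      if (kin_mode == 1) mod_nmda_in[i] = kn_max_rate * cv0;
      else if (kin_mode == 2) mod_vgcc[i] = kn_max_rate * cv0;
      else mod_presyn[i] = kn_max_rate * cv0;
    }
  }

  std::vector<std::vector<int> > in_edges(nn);
  for (int e = 0; e < ne; ++e) in_edges[post[e]].push_back(e);

  double total_dur = 0.0;
  for (int i = 0; i < phase_dur.size(); ++i) total_dur += phase_dur[i];
  const long nsteps = (long)std::llround(total_dur / dt);
  const int rec_stride = std::max(1, (int)std::llround(record_dt / dt));
  const long nrec = nsteps / rec_stride + 1;

  NumericMatrix v_rec(nrec, nn);
  NumericVector rho_mean_rec(nrec), rho_sd_rec(nrec), r_rec(nrec),
      a_rec(nrec), xi_rec(nrec), cpre_mean_rec(nrec), cpost_mean_rec(nrec),
      time_rec(nrec);
  NumericMatrix rho_edge_rec(rec_rho_edges ? nrec : 1,
                             rec_rho_edges ? ne : 1);
  List spike_times(nn);
  std::vector<std::vector<double> > spikes(nn);

  const double sd1 = pl_sigma * pl_z * std::sqrt(dt / pl_tau_s);
  const double sd2 = sd1 * std::sqrt(2.0);

  const double kdtk = dt * kin_stride;
  const double ou_e = std::exp(-kn_theta * kdtk);
  const double ou_sd =
      kn_theta > 0.0 ? kn_eps * std::sqrt(1.0 - ou_e * ou_e) : 0.0;
  const double r_relax = 1.0 - std::exp(-kdtk / kn_tau_r);
  const double a_relax = 1.0 - std::exp(-kdtk / kn_tau_a);

  HHParams p = p0;
  double ge_ampa_base = 0.0, ge_nmda_base = 0.0, gi_base = 0.0;

  std::vector<double> isyn(nn), fpre(nn), vprev(nn);

  GetRNGstate();

  long irec = 0;
  double t_ms = 0.0;
  bool ok = true;
  for (int n = 0; n < nn; ++n) v_rec(irec, n) = y[n * ns];
  time_rec[irec] = 0.0;
  if (plast_on) rho_mean_rec[irec] = pl_rho0;
  irec++;

  int phase = 0;
  double phase_end = phase_dur[0];
  bool stim_on = phase_stim[0];

  auto apply_axis = [&](double m) {
    p = p0;
    switch (axis) {
      case 1: p.gl *= m; break;
      case 2: p.gna *= m; break;
      case 3: p.gk *= m; break;
      case 4: p.ga *= m; break;
      case 5: p.gks *= m; break;
      case 6: p.gca *= m; break;
      case 7: p.gkca *= m; break;
      case 8: p.gnap *= m; break;
      case 9: p.gar *= m; break;
      case 10: p.gampa *= m; break;
      case 11: p.gnmda *= m; break;
      case 12: p.ggaba *= m; break;
      case 13: p.a_ampa *= m; p.a_x_nmda *= m; p.a_gaba *= m; break;
      case 14: p.tau_ca *= m; break;
      default: break;
    }
    ge_ampa_base = p.gampa / gdiv_e;
    ge_nmda_base = p.gnmda / gdiv_e;
    gi_base = p.ggaba / gdiv_i;
  };
  apply_axis(phase_mult[0]);

  auto net_rhs = [&](const std::vector<double>& z_, std::vector<double>& dz) {
    for (int n = 0; n < nn; ++n)
      fpre[n] = fgate(z_[n * ns]) * mod_presyn[n];
    for (int n = 0; n < nn; ++n) {
      const double v = z_[n * ns];
      double ia = 0.0, in_ = 0.0, ig = 0.0;
      const std::vector<int>& ie = in_edges[n];
      for (size_t k = 0; k < ie.size(); ++k) {
        const int e = ie[k];
        const int pn = pre[e];
        if (edge_exc[e]) {
          const double sa_p = z_[pn * ns + 6];
          const double sn_p = z_[pn * ns + 7];
          const double wa = couple_ampa ? (0.5 + rho[e]) : 1.0;
          ia += ge_ampa_base * wa * sa_p * (v - c.v_ampa);
          in_ += ge_nmda_base * mod_nmda_in[n] * sn_p * (v - c.v_nmda);
        } else {
          ig += gi_base * z_[pn * ns + 9] * (v - c.v_gaba);
        }
      }
      isyn[n] = ia + in_ + ig;
    }
    for (int n = 0; n < nn; ++n) {
      const double* zz = &z_[n * ns];
      double* dd = &dz[n * ns];
      HHParams pn_ = p;
      pn_.gca *= mod_vgcc[n];
      double i_ca;
      const double i_int = intrinsic_rhs(zz, pn_, c, dd, &i_ca);
      double i_stim = 0.0;
      if (stim_on && stim_mask[n] && stim_rate > 0.0) {
        const double period = 1000.0 / stim_rate;
        const double ph = t_ms - period * std::floor(t_ms / period);
        if (ph < stim_width) i_stim = stim_amp;
      }
      dd[0] = -(c.area10 * i_int + isyn[n] - i_stim) / c.c_m;
      const double fv = fpre[n];
      const double sa = zz[6], sn = zz[7], xn = zz[8], sg = zz[9];
      dd[6] = p.a_ampa * fv - sa / c.tau_ampa;
      dd[7] = p.a_s_nmda * xn * (1.0 - sn) - sn / c.tau_s_nmda;
      dd[8] = p.a_x_nmda * fv - xn / c.tau_x_nmda;
      dd[9] = p.a_gaba * fv - sg / c.tau_gaba;
    }
  };

  const double pl_Ep = plast_on ? std::exp(-dt / pl_tau_pre) : 0.0;
  const double pl_Eq = plast_on ? std::exp(-dt / pl_tau_post) : 0.0;

  for (long n = 0; n < nsteps && ok; ++n) {
    if (t_ms >= phase_end - 1e-9 && phase + 1 < phase_dur.size()) {
      ++phase;
      phase_end += phase_dur[phase];
      stim_on = phase_stim[phase];
      apply_axis(phase_mult[phase]);
    }
    for (int i = 0; i < nn; ++i) vprev[i] = y[i * ns];

    net_rhs(y, k1);
    for (size_t i = 0; i < y.size(); ++i) yt[i] = y[i] + 0.5 * dt * k1[i];
    net_rhs(yt, k2);
    for (size_t i = 0; i < y.size(); ++i) yt[i] = y[i] + 0.5 * dt * k2[i];
    net_rhs(yt, k3);
    for (size_t i = 0; i < y.size(); ++i) yt[i] = y[i] + dt * k3[i];
    net_rhs(yt, k4);
    for (size_t i = 0; i < y.size(); ++i)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    t_ms = (n + 1) * dt;

    for (int i = 0; i < nn; ++i) {
      double& ca = y[i * ns + 5];
      if (ca < 0.0) ca = 0.0;
      const double v = y[i * ns];
      if (!std::isfinite(v) || std::fabs(v) > 1000.0) { ok = false; break; }
      if (vprev[i] < -20.0 && v >= -20.0) spikes[i].push_back(t_ms);
    }
    if (!ok) break;

    if (plast_on) {
      for (int i = 0; i < nn; ++i) {
        const double v = y[i * ns];
        const double fv = fgate(v);
        xp[i] += dt * (pl_ax * fv - xp[i] / pl_taux);
        sp[i] += dt * (pl_as * xp[i] * (1.0 - sp[i]) - sp[i] / pl_taus);
        const VLook L(v);
        const double m2 = L.get(T_MCA2);
        const double drive = c.alpha_ca * c.area10 * pl_gca * m2 *
                             (c.v_ca - v) * pl_beta_v;
        cpost[i] = pl_Eq * cpost[i] + (1.0 - pl_Eq) * pl_tau_post * drive;
        if (cpost[i] < 0.0) cpost[i] = 0.0;
      }
      for (int e = 0; e < ne; ++e) {
        if (!edge_exc[e]) continue;
        const int q = post[e];
        const double vq = y[q * ns];
        const double drive =
            c.alpha_ca * pl_gnmda * sp[pre[e]] * (c.v_ca - vq) * pl_beta_n;
        cpre[e] = pl_Ep * cpre[e] + (1.0 - pl_Ep) * pl_tau_pre * drive;
        if (cpre[e] < 0.0) cpre[e] = 0.0;
        const double ctot = cpre[e] + cpost[q];
        const bool ap = ctot >= pl_theta_p, ad = ctot >= pl_theta_d;
        double rr = rho[e];
        double drift = -rr * (1.0 - rr) * (pl_rho_star - rr);
        if (ap) drift += pl_gamma_p * (1.0 - rr);
        if (ad) drift -= pl_gamma_d * rr;
        rr += drift * dt / pl_tau_s;
        const int h = (ap ? 1 : 0) + (ad ? 1 : 0);
        if (h == 1) rr += sd1 * norm_rand();
        else if (h == 2) rr += sd2 * norm_rand();
        rho[e] = rr;
      }
    }

    if (kin_mode > 0) {
      for (int i = 0; i < nn; ++i) {
        double cain = 0.0;
        if (kin_mode == 2) {
          cain = y[i * ns + 5];
        } else if (kin_mode == 1) {
          double s = 0.0;
          int m = 0;
          const std::vector<int>& ie = in_edges[i];
          for (size_t k = 0; k < ie.size(); ++k)
            if (edge_exc[ie[k]]) { s += cpre[ie[k]] + cpost[i]; ++m; }
          cain = m > 0 ? s / m : 0.0;
        } else {
          const double v = y[i * ns];
          const VLook L(v);
          const double i_ca_pre = p.gca * L.get(T_MCA2) * (v - c.v_ca);
          double proxy = -c.alpha_ca * c.area10 * i_ca_pre * pl_beta_v;
          cain = proxy > 0.0 ? proxy : 0.0;
        }
        kca_acc[i] += cain;
      }
      if ((n + 1) % kin_stride == 0) {
        for (int i = 0; i < nn; ++i) {
          const double ca_mean = kca_acc[i] / kin_stride;
          kca_acc[i] = 0.0;
          kxi[i] = ou_e * kxi[i] + (ou_sd > 0.0 ? ou_sd * norm_rand() : 0.0);
          const double rin = kn_w * kr[i] + kn_alpha * ca_mean -
                             kn_b * ka[i] + kn_i + kxi[i];
          const double rinf = 1.0 / (1.0 + std::exp(-kn_c * rin));
          const double ainf = 1.0 /
              (1.0 + std::exp(-kn_e * (kr[i] - kn_beta * ca_mean - kn_d)));
          kr[i] += (rinf - kr[i]) * r_relax;
          ka[i] += (ainf - ka[i]) * a_relax;
          const double cv = kn_couple_a ? ka[i] : kr[i];
          if (kin_mode == 1) mod_nmda_in[i] = kn_max_rate * cv;
          else if (kin_mode == 2) mod_vgcc[i] = kn_max_rate * cv;
          else mod_presyn[i] = kn_max_rate * cv;
        }
      }
    }

    if ((n + 1) % rec_stride == 0 && irec < nrec) {
      for (int i = 0; i < nn; ++i) v_rec(irec, i) = y[i * ns];
      time_rec[irec] = t_ms;
      if (plast_on) {
        double s1 = 0.0, s2 = 0.0, sc1 = 0.0, sc2 = 0.0;
        int m = 0;
        for (int e = 0; e < ne; ++e)
          if (edge_exc[e]) { s1 += rho[e]; s2 += rho[e] * rho[e];
                             sc1 += cpre[e]; ++m; }
        for (int i = 0; i < nn; ++i) sc2 += cpost[i];
        rho_mean_rec[irec] = s1 / m;
        rho_sd_rec[irec] =
            m > 1 ? std::sqrt(std::max(0.0, (s2 - s1 * s1 / m) / (m - 1)))
                  : 0.0;
        cpre_mean_rec[irec] = sc1 / m;
        cpost_mean_rec[irec] = sc2 / nn;
        if (rec_rho_edges)
          for (int e = 0; e < ne; ++e) rho_edge_rec(irec, e) = rho[e];
      }
      if (kin_mode > 0) {
        double sr = 0.0, sa_ = 0.0, sx = 0.0;
        for (int i = 0; i < nn; ++i) { sr += kr[i]; sa_ += ka[i]; sx += kxi[i]; }
        r_rec[irec] = sr / nn;
        a_rec[irec] = sa_ / nn;
        xi_rec[irec] = sx / nn;
      }
      irec++;
    }
  }
  PutRNGstate();

  for (int i = 0; i < nn; ++i) spike_times[i] = wrap(spikes[i]);
  NumericVector rho_final(ne);
  for (int e = 0; e < ne; ++e) rho_final[e] = rho[e];
  return List::create(
      _["time"] = time_rec, _["v"] = v_rec, _["spikes"] = spike_times,
      _["rho_mean"] = rho_mean_rec, _["rho_sd"] = rho_sd_rec,
      _["cpre_mean"] = cpre_mean_rec, _["cpost_mean"] = cpost_mean_rec,
      _["rho_final"] = rho_final, _["rho_edges"] = rho_edge_rec,
      _["r"] = r_rec, _["a"] = a_rec, _["xi"] = xi_rec, _["ok"] = ok,
      _["n_recorded"] = irec);
}
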