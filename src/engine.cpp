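// Fixed-step integrator for the four-population basal ganglia network
// (TH, STN, GPe, GPi single-compartment conductance models) and for
// isolated single cells. Gating kinetics follow the Rubin & Terman (2004) /
// So et al. (2012) model family; conductances, reversal potentials and bias
// currents are supplied from R (see inst/extdata/cell_params.json).
//
// Conventions: V in mV, t in ms, currents in uA/cm^2, conductances in
// mS/cm^2, Cm in uF/cm^2. All synaptic currents enter dV/dt as
// -g * sum(s) * (V - E_syn).
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double sig(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// ---------------------------------------------------------------------------
// Cell parameter structs (filled from R lists)
// ---------------------------------------------------------------------------
struct THp {
  double Cm, gL, EL, gNa, ENa, gK, EK, gT, ET;
};
struct GPp { // shared layout for STN / GPe / GPi
  double Cm, gL, EL, gNa, ENa, gK, EK, gCa, ECa, gT, ET;
  double gAHP, k1, eps, kca;
  double phih, phin, phir;
};

static double chan_g(const List& cell, const char* name) {
  List ch = as<List>(cell["channels"]);
  List c = as<List>(ch[name]);
  return as<double>(c["g"]);
}
static double chan_E(const List& cell, const char* name) {
  List ch = as<List>(cell["channels"]);
  List c = as<List>(ch[name]);
  return as<double>(c["E"]);
}

static THp parse_th(const List& cell) {
  THp p;
  p.Cm = as<double>(cell["Cm"]);
  p.gL = chan_g(cell, "L");  p.EL = chan_E(cell, "L");
  p.gNa = chan_g(cell, "Na"); p.ENa = chan_E(cell, "Na");
  p.gK = chan_g(cell, "K");  p.EK = chan_E(cell, "K");
  p.gT = chan_g(cell, "T");  p.ET = chan_E(cell, "T");
  return p;
}
static GPp parse_gp(const List& cell) {
  GPp p;
  p.Cm = as<double>(cell["Cm"]);
  p.gL = chan_g(cell, "L");  p.EL = chan_E(cell, "L");
  p.gNa = chan_g(cell, "Na"); p.ENa = chan_E(cell, "Na");
  p.gK = chan_g(cell, "K");  p.EK = chan_E(cell, "K");
  p.gCa = chan_g(cell, "Ca"); p.ECa = chan_E(cell, "Ca");
  p.gT = chan_g(cell, "T");  p.ET = chan_E(cell, "T");
  List ahp = as<List>(cell["ahp"]);
  p.gAHP = as<double>(ahp["g"]); p.k1 = as<double>(ahp["k1"]);
  List ca = as<List>(cell["ca"]);
  p.eps = as<double>(ca["eps"]); p.kca = as<double>(ca["kca"]);
  List phi = as<List>(cell["phi"]);
  p.phih = as<double>(phi["h"]); p.phin = as<double>(phi["n"]);
  p.phir = as<double>(phi["r"]);
  return p;
}

// ---------------------------------------------------------------------------
// Cell derivatives.  state layouts:
//   TH : V, h, r
//   STN/GPe/GPi : V, h, n, r, Ca
// iext is the full signed external sum (synaptic + SMC/DBS + bias).
// ---------------------------------------------------------------------------
static inline void th_deriv(const THp& p, const double* y, double iext,
                            double* dy) {
  const double V = y[0], h = y[1], r = y[2];
  const double minf = sig((V + 37.0) / 7.0);
  const double hinf = sig(-(V + 41.0) / 4.0);
  const double ah = 0.128 * std::exp(-(V + 46.0) / 18.0);
  const double bh = 4.0 * sig((V + 23.0) / 5.0);
  const double pinf = sig((V + 60.0) / 6.2);
  const double rinf = sig(-(V + 84.0) / 4.0);
  const double taur = 0.15 * (28.0 + std::exp(-(V + 25.0) / 10.5));
  const double IL = p.gL * (V - p.EL);
  const double INa = p.gNa * minf * minf * minf * h * (V - p.ENa);
  const double kg = 0.75 * (1.0 - h);
  const double IK = p.gK * kg * kg * kg * kg * (V - p.EK);
  const double IT = p.gT * pinf * pinf * r * (V - p.ET);
  dy[0] = (-IL - INa - IK - IT + iext) / p.Cm;
  dy[1] = (hinf - h) * (ah + bh);
  dy[2] = (rinf - r) / taur;
}

static inline void stn_deriv(const GPp& p, const double* y, double iext,
                             double* dy) {
  const double V = y[0], h = y[1], nn = y[2], r = y[3], Ca = y[4];
  const double minf = sig((V + 30.0) / 15.0);
  const double hinf = sig(-(V + 39.0) / 3.1);
  const double ninf = sig((V + 32.0) / 8.0);
  const double tauh = 1.0 + 500.0 * sig(-(V + 57.0) / 3.0);
  const double taun = 1.0 + 100.0 * sig(-(V + 80.0) / 26.0);
  const double rinf = sig(-(V + 67.0) / 2.0);
  const double taur = 40.0 + 17.5 * sig(-(V + 68.0) / 2.2);
  const double ainf = sig((V + 63.0) / 7.8);
  const double binf = sig((r - 0.4) / 0.1) - sig(-4.0);
  const double sinf = sig((V + 39.0) / 8.0);
  const double IL = p.gL * (V - p.EL);
  const double INa = p.gNa * minf * minf * minf * h * (V - p.ENa);
  const double n2 = nn * nn;
  const double IK = p.gK * n2 * n2 * (V - p.EK);
  const double ICa = p.gCa * sinf * sinf * (V - p.ECa);
  const double IT = p.gT * ainf * ainf * ainf * binf * binf * (V - p.ET);
  const double IAHP = p.gAHP * (V - p.EK) * Ca / (Ca + p.k1);
  dy[0] = (-IL - INa - IK - ICa - IT - IAHP + iext) / p.Cm;
  dy[1] = p.phih * (hinf - h) / tauh;
  dy[2] = p.phin * (ninf - nn) / taun;
  dy[3] = p.phir * (rinf - r) / taur;
  dy[4] = p.eps * (-ICa - IT - p.kca * Ca);
}

static inline void gp_deriv(const GPp& p, const double* y, double iext,
                            double* dy) {
  const double V = y[0], h = y[1], nn = y[2], r = y[3], Ca = y[4];
  const double minf = sig((V + 37.0) / 10.0);
  const double hinf = sig(-(V + 58.0) / 12.0);
  const double ninf = sig((V + 50.0) / 14.0);
  const double tauhn = 0.05 + 0.27 * sig(-(V + 40.0) / 12.0);
  const double rinf = sig(-(V + 70.0) / 2.0);
  const double taur = 30.0;
  const double ainf = sig((V + 57.0) / 2.0);
  const double sinf = sig((V + 35.0) / 2.0);
  const double IL = p.gL * (V - p.EL);
  const double INa = p.gNa * minf * minf * minf * h * (V - p.ENa);
  const double n2 = nn * nn;
  const double IK = p.gK * n2 * n2 * (V - p.EK);
  const double ICa = p.gCa * sinf * sinf * (V - p.ECa);
  const double IT = p.gT * ainf * ainf * ainf * r * (V - p.ET);
  const double IAHP = p.gAHP * (V - p.EK) * Ca / (Ca + p.k1);
  dy[0] = (-IL - INa - IK - ICa - IT - IAHP + iext) / p.Cm;
  dy[1] = p.phih * (hinf - h) / tauhn;
  dy[2] = p.phin * (ninf - nn) / tauhn;
  dy[3] = p.phir * (rinf - r) / taur;
  dy[4] = p.eps * (-ICa - IT - p.kca * Ca);
}

// Exposed for R-side consistency tests against the pure-R kinetics.
// state: TH c(V,h,r); STN/GPe/GPi c(V,h,n,r,Ca).  Returns d(state)/dt.
// [[Rcpp::export]]
NumericVector cpp_cell_deriv(std::string cell_type, List cell,
                             NumericVector state, double iext) {
  if (cell_type == "TH") {
    THp p = parse_th(cell);
    NumericVector dy(3);
    th_deriv(p, state.begin(), iext, dy.begin());
    return dy;
  }
  GPp p = parse_gp(cell);
  NumericVector dy(5);
  if (cell_type == "STN") stn_deriv(p, state.begin(), iext, dy.begin());
  else gp_deriv(p, state.begin(), iext, dy.begin());
  return dy;
}

// ---------------------------------------------------------------------------
// Synaptic gate: ds/dt = alpha * H(Vpre) * (1 - s) - beta * s,
// H(V) = 1 / (1 + exp(-(V + 20)/2))  (spike-shaped activation).
// ---------------------------------------------------------------------------
static inline double syn_deriv(double s, double Vpre, double alpha,
                               double beta) {
  const double H = sig((Vpre + 20.0) / 2.0);
  return alpha * H * (1.0 - s) - beta * s;
}

// ---------------------------------------------------------------------------
// Single-cell run: external current sampled on a grid (iext[k] at t = k*iext_dt),
// plus a constant bias.  Returns voltage trace, spike times, final state.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_run_single(std::string cell_type, List cell, double bias,
                    NumericVector iext, double iext_dt, double dt,
                    double duration, std::string method, NumericVector init,
                    double spike_threshold, double refractory,
                    int record_every, double g_load, double E_load) {
  const bool is_th = (cell_type == "TH");
  const int ns = is_th ? 3 : 5;
  if (init.size() != ns) stop("init state has wrong length for %s", cell_type.c_str());
  THp thp; GPp gpp;
  if (is_th) thp = parse_th(cell); else gpp = parse_gp(cell);
  const bool rk4 = (method == "rk4");
  const int nstep = (int)std::llround(duration / dt);
  const int niext = iext.size();

  std::vector<double> y(init.begin(), init.end());
  std::vector<double> k1(ns), k2(ns), k3(ns), k4(ns), yt(ns);
  std::vector<double> vtrace, ttrace, spikes;
  double last_spike = -1e9;

  auto ix = [&](double t) -> double {
    if (niext == 0) return 0.0;
    int k = (int)std::floor(t / iext_dt + 0.5);
    if (k < 0 || k >= niext) return 0.0;
    return iext[k];
  };
  auto f = [&](double t, const double* yy, double* dyy) {
    const double ie = ix(t) + bias - g_load * (yy[0] - E_load);
    if (is_th) th_deriv(thp, yy, ie, dyy);
    else if (cell_type == "STN") stn_deriv(gpp, yy, ie, dyy);
    else gp_deriv(gpp, yy, ie, dyy);
  };

  for (int s = 0; s < nstep; ++s) {
    const double t = s * dt;
    const double vprev = y[0];
    if (s % record_every == 0) { vtrace.push_back(y[0]); ttrace.push_back(t); }
    f(t, y.data(), k1.data());
    if (rk4) {
      for (int i = 0; i < ns; ++i) yt[i] = y[i] + 0.5 * dt * k1[i];
      f(t + 0.5 * dt, yt.data(), k2.data());
      for (int i = 0; i < ns; ++i) yt[i] = y[i] + 0.5 * dt * k2[i];
      f(t + 0.5 * dt, yt.data(), k3.data());
      for (int i = 0; i < ns; ++i) yt[i] = y[i] + dt * k3[i];
      f(t + dt, yt.data(), k4.data());
      for (int i = 0; i < ns; ++i)
        y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    } else {
      for (int i = 0; i < ns; ++i) y[i] += dt * k1[i];
    }
    // clamp gates to [0,1] (V is y[0]; Ca, if present, is last and clamped >= 0)
    const int glast = is_th ? 2 : 3;
    for (int i = 1; i <= glast; ++i) {
      if (y[i] < 0.0) y[i] = 0.0;
      if (y[i] > 1.0) y[i] = 1.0;
    }
    if (!is_th && y[4] < 0.0) y[4] = 0.0;
    if (std::fabs(y[0]) > 200.0)
      stop("numerical blow-up at t = %.3f ms (single %s cell)", t, cell_type.c_str());
    if (vprev < spike_threshold && y[0] > spike_threshold &&
        (t + dt) - last_spike >= refractory) {
      last_spike = t + dt;
      spikes.push_back(t + dt);
    }
  }
  vtrace.push_back(y[0]); ttrace.push_back(nstep * dt);
  return List::create(_["t"] = ttrace, _["v"] = vtrace,
                      _["spikes"] = spikes,
                      _["final_state"] = NumericVector(y.begin(), y.end()));
}

// ---------------------------------------------------------------------------
// Full network run.
//   cells:   list(TH=, STN=, GPe=, GPi=) parameter lists
//   topo:    list(gpi2th [n x 1], gpe2stn [n x 2], stn2gpe [n x 2],
//                 gpe2gpe [n x 2], stn2gpi [n x 2], gpe2gpi [n x 2]) 1-based
//   syn:     list(g_gpi2th, g_gpe2stn, g_stn2gpe, g_gpe2gpe, g_stn2gpi,
//                 g_gpe2gpi, E_exc, E_inh, alpha_exc, beta_exc, alpha_inh,
//                 beta_inh)
//   smc:     list(onsets = list of per-TH-neuron onset vectors, amplitude, width)
//   dbs:     current samples at t = k * dbs_dt (empty for none)
//   bias:    c(STN, GPe, GPi) bias currents for the chosen condition
//   init:    list(TH = n x 3, STN = n x 5, GPe = n x 5, GPi = n x 5,
//                 s = n x 3 [sSTN, sGPe, sGPi]) initial states
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_run_network(List cells, List topo, List syn, List smc,
                     NumericVector dbs, double dbs_dt, LogicalVector dbs_targets,
                     NumericVector bias, double dt, double duration,
                     std::string method, List init, double spike_threshold,
                     double refractory, int n_record, int record_every) {
  THp th = parse_th(as<List>(cells["TH"]));
  GPp stn = parse_gp(as<List>(cells["STN"]));
  GPp gpe = parse_gp(as<List>(cells["GPe"]));
  GPp gpi = parse_gp(as<List>(cells["GPi"]));

  IntegerMatrix gpi2th = as<IntegerMatrix>(topo["gpi2th"]);
  IntegerMatrix gpe2stn = as<IntegerMatrix>(topo["gpe2stn"]);
  IntegerMatrix stn2gpe = as<IntegerMatrix>(topo["stn2gpe"]);
  IntegerMatrix gpe2gpe = as<IntegerMatrix>(topo["gpe2gpe"]);
  IntegerMatrix stn2gpi = as<IntegerMatrix>(topo["stn2gpi"]);
  IntegerMatrix gpe2gpi = as<IntegerMatrix>(topo["gpe2gpi"]);
  const int n = gpi2th.nrow();

  const double g_gpi2th = as<double>(syn["g_gpi2th"]);
  const double g_gpe2stn = as<double>(syn["g_gpe2stn"]);
  const double g_stn2gpe = as<double>(syn["g_stn2gpe"]);
  const double g_gpe2gpe = as<double>(syn["g_gpe2gpe"]);
  const double g_stn2gpi = as<double>(syn["g_stn2gpi"]);
  const double g_gpe2gpi = as<double>(syn["g_gpe2gpi"]);
  const double E_exc = as<double>(syn["E_exc"]);
  const double E_inh = as<double>(syn["E_inh"]);
  const double a_exc = as<double>(syn["alpha_exc"]);
  const double b_exc = as<double>(syn["beta_exc"]);
  const double a_inh = as<double>(syn["alpha_inh"]);
  const double b_inh = as<double>(syn["beta_inh"]);
  // sign of the intra-pallidal (GPe->GPe, GPe->GPi) terms as they enter
  // dV/dt: +1 reproduces the membrane equations as printed (Eqs. 4-5 style),
  // -1 gives conventional hyperpolarizing inhibition.
  const double gpe_sign = as<double>(syn["gpe_term_sign"]);

  List smc_onsets = as<List>(smc["onsets"]);
  const double smc_amp = as<double>(smc["amplitude"]);
  const double smc_w = as<double>(smc["width"]);
  std::vector<NumericVector> smc_on(n);
  std::vector<int> smc_idx(n, 0);
  for (int i = 0; i < n; ++i) smc_on[i] = as<NumericVector>(smc_onsets[i]);

  const bool tgt_stn = dbs_targets[0], tgt_gpe = dbs_targets[1],
             tgt_gpi = dbs_targets[2];
  const double bias_stn = bias[0], bias_gpe = bias[1], bias_gpi = bias[2];
  const int ndbs = dbs.size();

  // state packing
  const int oTH = 0, oSTN = 3 * n, oGPe = 8 * n, oGPi = 13 * n, oS = 18 * n;
  const int ntot = 21 * n;
  std::vector<double> y(ntot), k1(ntot), k2(ntot), k3(ntot), k4(ntot), yt(ntot);
  {
    NumericMatrix mTH = as<NumericMatrix>(init["TH"]);
    NumericMatrix mSTN = as<NumericMatrix>(init["STN"]);
    NumericMatrix mGPe = as<NumericMatrix>(init["GPe"]);
    NumericMatrix mGPi = as<NumericMatrix>(init["GPi"]);
    NumericMatrix mS = as<NumericMatrix>(init["s"]);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < 3; ++j) y[oTH + j * n + i] = mTH(i, j);
      for (int j = 0; j < 5; ++j) y[oSTN + j * n + i] = mSTN(i, j);
      for (int j = 0; j < 5; ++j) y[oGPe + j * n + i] = mGPe(i, j);
      for (int j = 0; j < 5; ++j) y[oGPi + j * n + i] = mGPi(i, j);
      for (int j = 0; j < 3; ++j) y[oS + j * n + i] = mS(i, j);
    }
  }

  auto dbs_at = [&](double t) -> double {
    if (ndbs == 0) return 0.0;
    int k = (int)std::floor(t / dbs_dt + 0.5);
    if (k < 0 || k >= ndbs) return 0.0;
    return dbs[k];
  };
  auto smc_at = [&](int i, double t) -> double {
    NumericVector& on = smc_on[i];
    int& idx = smc_idx[i];
    const int len = on.size();
    while (idx < len && on[idx] + smc_w <= t) ++idx;
    if (idx < len && t >= on[idx]) return smc_amp;
    return 0.0;
  };

  auto f = [&](double t, const double* yy, double* dyy) {
    const double idbs = dbs_at(t);
    const double* sSTN = yy + oS;
    const double* sGPe = yy + oS + n;
    const double* sGPi = yy + oS + 2 * n;
    double st[5], dst[5];
    for (int i = 0; i < n; ++i) {
      // TH
      {
        const double V = yy[oTH + i];
        const double isyn = -g_gpi2th * sGPi[gpi2th(i, 0)] * (V - E_inh);
        const double ie = isyn + smc_at(i, t);
        st[0] = V; st[1] = yy[oTH + n + i]; st[2] = yy[oTH + 2 * n + i];
        th_deriv(th, st, ie, dst);
        dyy[oTH + i] = dst[0]; dyy[oTH + n + i] = dst[1];
        dyy[oTH + 2 * n + i] = dst[2];
      }
      // STN
      {
        const double V = yy[oSTN + i];
        const double sin_ = sGPe[gpe2stn(i, 0)] + sGPe[gpe2stn(i, 1)];
        double ie = -g_gpe2stn * sin_ * (V - E_inh) + bias_stn;
        if (tgt_stn) ie += idbs;
        for (int j = 0; j < 5; ++j) st[j] = yy[oSTN + j * n + i];
        stn_deriv(stn, st, ie, dst);
        for (int j = 0; j < 5; ++j) dyy[oSTN + j * n + i] = dst[j];
      }
      // GPe
      {
        const double V = yy[oGPe + i];
        const double se = sSTN[stn2gpe(i, 0)] + sSTN[stn2gpe(i, 1)];
        const double si = sGPe[gpe2gpe(i, 0)] + sGPe[gpe2gpe(i, 1)];
        double ie = -g_stn2gpe * se * (V - E_exc) +
                    gpe_sign * g_gpe2gpe * si * (V - E_inh) + bias_gpe;
        if (tgt_gpe) ie += idbs;
        for (int j = 0; j < 5; ++j) st[j] = yy[oGPe + j * n + i];
        gp_deriv(gpe, st, ie, dst);
        for (int j = 0; j < 5; ++j) dyy[oGPe + j * n + i] = dst[j];
      }
      // GPi
      {
        const double V = yy[oGPi + i];
        const double se = sSTN[stn2gpi(i, 0)] + sSTN[stn2gpi(i, 1)];
        const double si = sGPe[gpe2gpi(i, 0)] + sGPe[gpe2gpi(i, 1)];
        double ie = -g_stn2gpi * se * (V - E_exc) +
                    gpe_sign * g_gpe2gpi * si * (V - E_inh) + bias_gpi;
        if (tgt_gpi) ie += idbs;
        for (int j = 0; j < 5; ++j) st[j] = yy[oGPi + j * n + i];
        gp_deriv(gpi, st, ie, dst);
        for (int j = 0; j < 5; ++j) dyy[oGPi + j * n + i] = dst[j];
      }
      // synaptic gates (one per presynaptic neuron)
      dyy[oS + i] = syn_deriv(sSTN[i], yy[oSTN + i], a_exc, b_exc);
      dyy[oS + n + i] = syn_deriv(sGPe[i], yy[oGPe + i], a_inh, b_inh);
      dyy[oS + 2 * n + i] = syn_deriv(sGPi[i], yy[oGPi + i], a_inh, b_inh);
    }
  };

  const bool rk4 = (method == "rk4");
  const int nstep = (int)std::llround(duration / dt);
  const int nrec = std::min(n_record, n);

  std::vector<std::vector<double>> spk(4 * n);
  std::vector<double> last_spike(4 * n, -1e9);
  const int vcols = 4 * nrec;
  const int nrow_v = (nrec > 0) ? (nstep / record_every + 1) : 0;
  NumericMatrix vrec(nrow_v, vcols);
  NumericVector vrec_t(nrow_v);
  int vrow = 0;
  long clamp_events = 0;

  const int voff[4] = {oTH, oSTN, oGPe, oGPi};

  for (int s = 0; s < nstep; ++s) {
    const double t = s * dt;
    if (nrec > 0 && s % record_every == 0 && vrow < nrow_v) {
      for (int p = 0; p < 4; ++p)
        for (int i = 0; i < nrec; ++i) vrec(vrow, p * nrec + i) = y[voff[p] + i];
      vrec_t[vrow] = t;
      ++vrow;
    }
    // previous voltages for spike detection
    double vprev_s;
    static std::vector<double> vprev;
    vprev.resize(4 * n);
    for (int p = 0; p < 4; ++p)
      for (int i = 0; i < n; ++i) vprev[p * n + i] = y[voff[p] + i];

    f(t, y.data(), k1.data());
    if (rk4) {
      for (int i = 0; i < ntot; ++i) yt[i] = y[i] + 0.5 * dt * k1[i];
      f(t + 0.5 * dt, yt.data(), k2.data());
      for (int i = 0; i < ntot; ++i) yt[i] = y[i] + 0.5 * dt * k2[i];
      f(t + 0.5 * dt, yt.data(), k3.data());
      for (int i = 0; i < ntot; ++i) yt[i] = y[i] + dt * k3[i];
      f(t + dt, yt.data(), k4.data());
      for (int i = 0; i < ntot; ++i)
        y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    } else {
      for (int i = 0; i < ntot; ++i) y[i] += dt * k1[i];
    }
    // clamp all gating variables (everything except V and Ca) to [0,1]
    for (int i = 0; i < n; ++i) {
      for (int j = 1; j <= 2; ++j) { // TH h, r
        double& g = y[oTH + j * n + i];
        if (g < 0.0) { if (g < -1e-6) ++clamp_events; g = 0.0; }
        if (g > 1.0) { if (g > 1.0 + 1e-6) ++clamp_events; g = 1.0; }
      }
      const int offs[3] = {oSTN, oGPe, oGPi};
      for (int p = 0; p < 3; ++p) {
        for (int j = 1; j <= 3; ++j) { // h, n, r
          double& g = y[offs[p] + j * n + i];
          if (g < 0.0) { if (g < -1e-6) ++clamp_events; g = 0.0; }
          if (g > 1.0) { if (g > 1.0 + 1e-6) ++clamp_events; g = 1.0; }
        }
        double& ca = y[offs[p] + 4 * n + i];
        if (ca < 0.0) ca = 0.0;
      }
      for (int j = 0; j < 3; ++j) { // synaptic s
        double& g = y[oS + j * n + i];
        if (g < 0.0) { if (g < -1e-6) ++clamp_events; g = 0.0; }
        if (g > 1.0) { if (g > 1.0 + 1e-6) ++clamp_events; g = 1.0; }
      }
    }
    // spike detection (strict upward crossing + refractory)
    const double tnew = t + dt;
    for (int p = 0; p < 4; ++p) {
      for (int i = 0; i < n; ++i) {
        const double vn = y[voff[p] + i];
        if (std::fabs(vn) > 200.0)
          stop("numerical blow-up at t = %.3f ms (population %d, neuron %d)",
               tnew, p + 1, i + 1);
        vprev_s = vprev[p * n + i];
        const int id = p * n + i;
        if (vprev_s < spike_threshold && vn > spike_threshold &&
            tnew - last_spike[id] >= refractory) {
          last_spike[id] = tnew;
          spk[id].push_back(tnew);
        }
      }
    }
  }
  if (nrec > 0 && vrow < nrow_v) {
    for (int p = 0; p < 4; ++p)
      for (int i = 0; i < nrec; ++i) vrec(vrow, p * nrec + i) = y[voff[p] + i];
    vrec_t[vrow] = nstep * dt;
  }

  List spikes(4);
  CharacterVector pops = CharacterVector::create("TH", "STN", "GPe", "GPi");
  for (int p = 0; p < 4; ++p) {
    List li(n);
    for (int i = 0; i < n; ++i)
      li[i] = NumericVector(spk[p * n + i].begin(), spk[p * n + i].end());
    spikes[p] = li;
  }
  spikes.names() = pops;

  // final state back to matrices
  NumericMatrix fTH(n, 3), fSTN(n, 5), fGPe(n, 5), fGPi(n, 5), fS(n, 3);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < 3; ++j) fTH(i, j) = y[oTH + j * n + i];
    for (int j = 0; j < 5; ++j) fSTN(i, j) = y[oSTN + j * n + i];
    for (int j = 0; j < 5; ++j) fGPe(i, j) = y[oGPe + j * n + i];
    for (int j = 0; j < 5; ++j) fGPi(i, j) = y[oGPi + j * n + i];
    for (int j = 0; j < 3; ++j) fS(i, j) = y[oS + j * n + i];
  }
  return List::create(
      _["spikes"] = spikes, _["v"] = vrec, _["v_t"] = vrec_t,
      _["n_recorded"] = nrec, _["clamp_events"] = (double)clamp_events,
      _["final_state"] = List::create(_["TH"] = fTH, _["STN"] = fSTN,
                                      _["GPe"] = fGPe, _["GPi"] = fGPi,
                                      _["s"] = fS));
}
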