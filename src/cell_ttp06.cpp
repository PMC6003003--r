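// ten Tusscher-Panfilov (2006) human ventricular myocyte model.
// Fixed-step integrator: Rush-Larsen exponential update for the 13
// gate-like variables, forward Euler for Vm and ion concentrations with
// the analytic (quadratic) rapid-buffering update for the three Ca pools.
// Units: mV, ms, mM, uA/uF throughout.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// state vector layout (19 entries, order shared with the R side)
enum {
  iV = 0, iKi, iNai, iCai, iCass, iCasr,
  Gm, Gh, Gj, Gxr1, Gxr2, Gxs, Gr, Gs, Gd, Gf, Gf2, Gfcass, Grbar,
  NSTATE
};

// fixed model constants
static const double Ko = 5.4, Cao = 2.0, Nao = 140.0;
static const double Vc = 0.016404, Vsr = 0.001094, Vss = 0.00005468;
static const double Bufc = 0.2, Kbufc = 0.001;
static const double Bufsr = 10.0, Kbufsr = 0.3;
static const double Bufss = 0.4, Kbufss = 0.00025;
static const double Vmaxup = 0.006375, Kup = 0.00025;
static const double Vrel = 0.102, k1p = 0.15, k2p = 0.045, k3 = 0.060,
                    k4 = 0.005, EC = 1.5, maxsr = 2.5, minsr = 1.0;
static const double Vleak = 0.00036, Vxfer = 0.0038;
static const double Rgas = 8314.472, Frd = 96485.3415, Temp = 310.0;
static const double RTONF = Rgas * Temp / Frd;
static const double CAPAC = 0.185;             // uF
static const double GNa = 14.838, GK1 = 5.405, GKr = 0.153;
static const double pKNa = 0.03;
static const double GCaL = 0.00003980, GbCa = 0.000592, GbNa = 0.00029;
static const double knaca = 1000.0, KmNai = 87.5, KmCa = 1.38, ksat = 0.1,
                    ncag = 0.35;
static const double knak = 2.724, KmK = 1.0, KmNa = 40.0;
static const double GpCa = 0.1238, KpCa = 0.0005, GpK = 0.0146;

// cell types: 0 = endo, 1 = M, 2 = epi (Gto and the s-gate differ; the
// caller supplies the total gKs = base * 1.3 * scale)
static inline double gto_for(int ct) { return ct == 0 ? 0.073 : 0.294; }

struct Currents {
  double INa, IK1, Ito, IKr, IKs, ICaL, INaCa, INaK,
         IpCa, IpK, IbCa, IbNa, Iion;
};

static void compute_currents(const double *X, int ct, double gks,
                             Currents &c) {
  const double V = X[iV], Ki = X[iKi], Nai = X[iNai], Cai = X[iCai],
               Cass = X[iCass];
  const double Ek  = RTONF * std::log(Ko / Ki);
  const double Ena = RTONF * std::log(Nao / Nai);
  const double Eks = RTONF * std::log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
  const double Eca = 0.5 * RTONF * std::log(Cao / Cai);

  c.INa = GNa * X[Gm] * X[Gm] * X[Gm] * X[Gh] * X[Gj] * (V - Ena);

  const double Ak1 = 0.1 / (1.0 + std::exp(0.06 * (V - Ek - 200.0)));
  const double Bk1 = (3.0 * std::exp(0.0002 * (V - Ek + 100.0)) +
                      std::exp(0.1 * (V - Ek - 10.0))) /
                     (1.0 + std::exp(-0.5 * (V - Ek)));
  c.IK1 = GK1 * Ak1 / (Ak1 + Bk1) * (V - Ek);

  c.Ito = gto_for(ct) * X[Gr] * X[Gs] * (V - Ek);
  c.IKr = GKr * std::sqrt(Ko / 5.4) * X[Gxr1] * X[Gxr2] * (V - Ek);
  c.IKs = gks * X[Gxs] * X[Gxs] * (V - Eks);

  const double vf = (V - 15.0) * Frd / (Rgas * Temp);
  double drv;
  if (std::fabs(vf) < 1e-7) {          // removable singularity at V = 15 mV
    drv = 2.0 * Frd * (0.25 * Cass - Cao) * (1.0 - vf);
  } else {
    drv = 4.0 * (V - 15.0) * Frd * Frd / (Rgas * Temp) *
          (0.25 * Cass * std::exp(2.0 * vf) - Cao) /
          (std::exp(2.0 * vf) - 1.0);
  }
  c.ICaL = GCaL * X[Gd] * X[Gf] * X[Gf2] * X[Gfcass] * drv;

  const double evf  = std::exp(ncag * V * Frd / (Rgas * Temp));
  const double evf1 = std::exp((ncag - 1.0) * V * Frd / (Rgas * Temp));
  c.INaCa = knaca *
            (evf * Nai * Nai * Nai * Cao - evf1 * Nao * Nao * Nao * Cai * 2.5) /
            ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
             (1.0 + ksat * evf1));

  c.INaK = knak * Ko * Nai /
           ((Ko + KmK) * (Nai + KmNa) *
            (1.0 + 0.1245 * std::exp(-0.1 * V * Frd / (Rgas * Temp)) +
             0.0353 * std::exp(-V * Frd / (Rgas * Temp))));

  c.IpCa = GpCa * Cai / (Cai + KpCa);
  c.IpK  = GpK * (V - Ek) / (1.0 + std::exp((25.0 - V) / 5.98));
  c.IbCa = GbCa * (V - Eca);
  c.IbNa = GbNa * (V - Ena);

  c.Iion = c.INa + c.IK1 + c.Ito + c.IKr + c.IKs + c.ICaL + c.INaCa +
           c.INaK + c.IpCa + c.IpK + c.IbCa + c.IbNa;
}

static inline double rl_update(double y, double yinf, double tau, double dt) {
  return yinf - (yinf - y) * std::exp(-dt / tau);
}

// one integrator step; Istim in uA/uF (negative = depolarizing)
static void cell_step(double *X, int ct, double gks, double Istim, double dt) {
  Currents c;
  compute_currents(X, ct, gks, c);
  const double V = X[iV];

  // gate steady states and time constants
  const double Minf = 1.0 / std::pow(1.0 + std::exp((-56.86 - V) / 9.03), 2);
  const double am = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
  const double bm = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
                    0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
  const double tauM = am * bm;

  const double Hinf = 1.0 / std::pow(1.0 + std::exp((V + 71.55) / 7.43), 2);
  double tauH;
  if (V >= -40.0) {
    tauH = 0.1688 * (1.0 + std::exp(-(V + 10.66) / 11.1));
  } else {
    const double ah = 0.057 * std::exp(-(V + 80.0) / 6.8);
    const double bh = 2.7 * std::exp(0.079 * V) +
                      3.1e5 * std::exp(0.3485 * V);
    tauH = 1.0 / (ah + bh);
  }

  const double Jinf = Hinf;
  double tauJ;
  if (V >= -40.0) {
    const double bj = 0.6 * std::exp(0.057 * V) /
                      (1.0 + std::exp(-0.1 * (V + 32.0)));
    tauJ = 1.0 / bj;
  } else {
    const double aj = (-2.5428e4 * std::exp(0.2444 * V) -
                       6.948e-6 * std::exp(-0.04391 * V)) *
                      (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    const double bj = 0.02424 * std::exp(-0.01052 * V) /
                      (1.0 + std::exp(-0.1378 * (V + 40.14)));
    tauJ = 1.0 / (aj + bj);
  }

  const double Xr1inf = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
  const double axr1 = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
  const double bxr1 = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
  const double tauXr1 = axr1 * bxr1;

  const double Xr2inf = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
  const double axr2 = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
  const double bxr2 = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
  const double tauXr2 = axr2 * bxr2;

  const double Xsinf = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
  const double axs = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0));
  const double bxs = 1.0 / (1.0 + std::exp((V - 35.0) / 15.0));
  const double tauXs = axs * bxs + 80.0;

  const double Rinf = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
  const double tauR = 9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;

  double Sinf, tauS;
  if (ct == 0) {                              // endo s-gate
    Sinf = 1.0 / (1.0 + std::exp((V + 28.0) / 5.0));
    tauS = 1000.0 * std::exp(-(V + 67.0) * (V + 67.0) / 1000.0) + 8.0;
  } else {                                    // M and epi share the s-gate
    Sinf = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
    tauS = 85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
           5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
  }

  const double Dinf = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
  const double ad = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
  const double bd = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
  const double cd = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
  const double tauD = ad * bd + cd;

  const double Finf = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
  const double tauF = 1102.5 * std::exp(-(V + 27.0) * (V + 27.0) / 225.0) +
                      200.0 / (1.0 + std::exp((13.0 - V) / 10.0)) +
                      180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0;

  const double F2inf = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
  const double tauF2 = 562.0 * std::exp(-(V + 27.0) * (V + 27.0) / 240.0) +
                       31.0 / (1.0 + std::exp((25.0 - V) / 10.0)) +
                       80.0 / (1.0 + std::exp((V + 30.0) / 10.0));

  const double css = X[iCass] / 0.05;
  const double Fcassinf = 0.6 / (1.0 + css * css) + 0.4;
  const double tauFcass = 80.0 / (1.0 + css * css) + 2.0;

  // SR release (4-state RyR reduced to Rbar + algebraic open fraction)
  const double Casr = X[iCasr], Cass = X[iCass], Cai = X[iCai];
  const double kcasr = maxsr - (maxsr - minsr) /
                               (1.0 + (EC / Casr) * (EC / Casr));
  const double kk1 = k1p / kcasr;
  const double kk2 = k2p * kcasr;
  const double Rbinf = k4 / (kk2 * Cass + k4);
  const double tauRb = 1.0 / (kk2 * Cass + k4);
  const double OO = kk1 * Cass * Cass * X[Grbar] /
                    (k3 + kk1 * Cass * Cass);

  const double Irel  = Vrel * OO * (Casr - Cass);
  const double Ileak = Vleak * (Casr - Cai);
  const double Iup   = Vmaxup / (1.0 + Kup * Kup / (Cai * Cai));
  const double Ixfer = Vxfer * (Cass - Cai);

  // concentration updates (forward Euler + analytic buffer equilibrium)
  const double invVcF2 = 1.0 / (2.0 * Vc * Frd);
  const double invVcF  = 1.0 / (Vc * Frd);
  const double invVssF2 = 1.0 / (2.0 * Vss * Frd);

  {
    const double CaCSQN = Bufsr * Casr / (Casr + Kbufsr);
    const double dsr = dt * (Iup - Irel - Ileak);
    const double b = Bufsr - CaCSQN - dsr - Casr + Kbufsr;
    const double cc = Kbufsr * (CaCSQN + dsr + Casr);
    X[iCasr] = (std::sqrt(b * b + 4.0 * cc) - b) / 2.0;
  }
  {
    const double CaSSBuf = Bufss * Cass / (Cass + Kbufss);
    const double dss = dt * (-Ixfer * (Vc / Vss) + Irel * (Vsr / Vss) -
                             c.ICaL * invVssF2 * CAPAC);
    const double b = Bufss - CaSSBuf - dss - Cass + Kbufss;
    const double cc = Kbufss * (CaSSBuf + dss + Cass);
    X[iCass] = (std::sqrt(b * b + 4.0 * cc) - b) / 2.0;
  }
  {
    const double CaBuf = Bufc * Cai / (Cai + Kbufc);
    const double dca = dt * (-(c.IbCa + c.IpCa - 2.0 * c.INaCa) * invVcF2 *
                                 CAPAC -
                             (Iup - Ileak) * (Vsr / Vc) + Ixfer);
    const double b = Bufc - CaBuf - dca - Cai + Kbufc;
    const double cc = Kbufc * (CaBuf + dca + Cai);
    X[iCai] = (std::sqrt(b * b + 4.0 * cc) - b) / 2.0;
  }

  X[iNai] += dt * (-(c.INa + c.IbNa + 3.0 * c.INaK + 3.0 * c.INaCa) *
                   invVcF * CAPAC);
  X[iKi]  += dt * (-(Istim + c.IK1 + c.Ito + c.IKr + c.IKs - 2.0 * c.INaK +
                     c.IpK) * invVcF * CAPAC);

  // gates
  X[Gm]   = rl_update(X[Gm], Minf, tauM, dt);
  X[Gh]   = rl_update(X[Gh], Hinf, tauH, dt);
  X[Gj]   = rl_update(X[Gj], Jinf, tauJ, dt);
  X[Gxr1] = rl_update(X[Gxr1], Xr1inf, tauXr1, dt);
  X[Gxr2] = rl_update(X[Gxr2], Xr2inf, tauXr2, dt);
  X[Gxs]  = rl_update(X[Gxs], Xsinf, tauXs, dt);
  X[Gr]   = rl_update(X[Gr], Rinf, tauR, dt);
  X[Gs]   = rl_update(X[Gs], Sinf, tauS, dt);
  X[Gd]   = rl_update(X[Gd], Dinf, tauD, dt);
  X[Gf]   = rl_update(X[Gf], Finf, tauF, dt);
  X[Gf2]  = rl_update(X[Gf2], F2inf, tauF2, dt);
  X[Gfcass] = rl_update(X[Gfcass], Fcassinf, tauFcass, dt);
  X[Grbar]  = rl_update(X[Grbar], Rbinf, tauRb, dt);

  X[iV] = V - dt * (c.Iion + Istim);
}

static const char *state_name(int k) {
  static const char *nm[NSTATE] = {
    "V_m", "K_i", "Na_i", "Ca_i", "Ca_ss", "Ca_sr",
    "m", "h", "j", "xr1", "xr2", "xs", "r", "s", "d", "f", "f2",
    "fCass", "Rbar"};
  return nm[k];
}

static void check_finite(const double *X, double t) {
  for (int k = 0; k < NSTATE; ++k) {
    if (!std::isfinite(X[k])) {
      stop("solver divergence: state component '%s' Gs non-finite at t = "
           "%.3f ms (reduce dt or check parameters)", state_name(k), t);
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_state_init() {
  NumericVector x(NSTATE);
  CharacterVector nm(NSTATE);
  for (int k = 0; k < NSTATE; ++k) nm[k] = state_name(k);
  x[iV] = -86.2;  x[iKi] = 138.3; x[iNai] = 7.67;
  x[iCai] = 0.00007; x[iCass] = 0.00007; x[iCasr] = 1.3;
  x[Gm] = 0.0; x[Gh] = 0.75; x[Gj] = 0.75;
  x[Gxr1] = 0.0; x[Gxr2] = 1.0; x[Gxs] = 0.0;
  x[Gr] = 0.0; x[Gs] = 1.0; x[Gd] = 0.0;
  x[Gf] = 1.0; x[Gf2] = 1.0; x[Gfcass] = 1.0; x[Grbar] = 1.0;
  x.attr("names") = nm;
  return x;
}

// [[Rcpp::export]]
NumericVector cpp_cell_currents(NumericVector state, int celltype,
                                double gks) {
  if (state.size() != NSTATE) stop("state must have %d components", NSTATE);
  Currents c;
  compute_currents(REAL(state), celltype, gks, c);
  NumericVector out = NumericVector::create(
      _["I_Na"] = c.INa, _["I_K1"] = c.IK1, _["I_to"] = c.Ito,
      _["I_Kr"] = c.IKr, _["I_Ks"] = c.IKs, _["I_CaL"] = c.ICaL,
      _["I_NaCa"] = c.INaCa, _["I_NaK"] = c.INaK, _["I_pCa"] = c.IpCa,
      _["I_pK"] = c.IpK, _["I_bCa"] = c.IbCa, _["I_bNa"] = c.IbNa,
      _["I_ion"] = c.Iion);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_cell_step_n(NumericVector state, int celltype, double gks,
                              double Istim, double dt, int n) {
  NumericVector out = clone(state);
  double *X = REAL(out);
  for (int i = 0; i < n; ++i) {
    cell_step(X, celltype, gks, Istim, dt);
  }
  check_finite(X, n * dt);
  out.attr("names") = state.attr("names");
  return out;
}

// Pace a single cell for n_beats at the given BCL; record the last
// `rec_beats` beats every `rec_every` steps.  Returns traces (t relative to
// the start of the recorded window), per-sample Vm, Cai, IKs, and the final
// full state.
// [[Rcpp::export]]
List cpp_pace(NumericVector state0, int celltype, double gks, double bcl,
              int n_beats, double stim_amp, double stim_dur,
              double stim_offset, double dt, int rec_beats, int rec_every) {
  if (state0.size() != NSTATE) stop("state must have %d components", NSTATE);
  NumericVector st = clone(state0);
  double *X = REAL(st);

  const int steps_per_beat = (int)std::lround(bcl / dt);
  const long total_steps = (long)steps_per_beat * n_beats;
  const long rec_start = (long)steps_per_beat * (n_beats - rec_beats);
  const int nrec = (int)((total_steps - rec_start) / rec_every) + 1;

  NumericVector tt(nrec), vv(nrec), ca(nrec), ks(nrec);
  int ir_ = 0;

  for (long s = 0; s <= total_steps; ++s) {
    const double t = s * dt;
    if (s >= rec_start && (s - rec_start) % rec_every == 0 && ir_ < nrec) {
      Currents c;
      compute_currents(X, celltype, gks, c);
      tt[ir_] = t - rec_start * dt;
      vv[ir_] = X[iV];
      ca[ir_] = X[iCai];
      ks[ir_] = c.IKs;
      ++ir_;
    }
    if (s == total_steps) break;
    const double tb = t - bcl * std::floor(t / bcl);
    const double Istim =
        (tb >= stim_offset && tb < stim_offset + stim_dur) ? stim_amp : 0.0;
    cell_step(X, celltype, gks, Istim, dt);
    if ((s & 0x3FFF) == 0) check_finite(X, t);
  }
  check_finite(X, total_steps * dt);

  return List::create(_["t"] = tt, _["Vm"] = vv, _["Cai"] = ca,
                      _["IKs"] = ks, _["state"] = st,
                      _["rec_beats"] = rec_beats, _["bcl"] = bcl);
}

// 1-D monodomain cable, operator splitting: reaction = cell_step per node,
// diffusion = explicit 3-point Laplacian with no-flux ends.
// Records Vm at every node for the last beat and returns activation times
// (first upstroke crossing of `act_thresh` within the last beat, linearly
// interpolated).
// [[Rcpp::export]]
List cpp_run_cable(NumericVector state0, int celltype, double gks,
                   int n_nodes, double dx, double Dcoef, double bcl,
                   int n_beats, double stim_amp, double stim_dur,
                   int n_stim_nodes, double dt, int rec_every,
                   double act_thresh) {
  if (state0.size() != NSTATE) stop("state must have %d components", NSTATE);
  const double cfl = Dcoef * dt / (dx * dx);
  if (cfl > 0.5)
    stop("CFL violation: D*dt/dx^2 = %.3f > 0.5; reduce dt or increase dx",
         cfl);

  std::vector<double> X((size_t)n_nodes * NSTATE);
  for (int i = 0; i < n_nodes; ++i)
    for (int k = 0; k < NSTATE; ++k) X[(size_t)i * NSTATE + k] = state0[k];

  const int steps_per_beat = (int)std::lround(bcl / dt);
  const long total_steps = (long)steps_per_beat * n_beats;
  const long rec_start = (long)steps_per_beat * (n_beats - 1);
  const int nrec = (int)((total_steps - rec_start) / rec_every) + 1;

  NumericMatrix Vmat(nrec, n_nodes);
  NumericVector tt(nrec);
  NumericVector act(n_nodes, NA_REAL);
  std::vector<double> vprev(n_nodes), vnew(n_nodes);
  int ir_ = 0;

  for (long s = 0; s <= total_steps; ++s) {
    const double t = s * dt;
    if (s >= rec_start && (s - rec_start) % rec_every == 0 && ir_ < nrec) {
      tt[ir_] = t - rec_start * dt;
      for (int i = 0; i < n_nodes; ++i)
        Vmat(ir_, i) = X[(size_t)i * NSTATE + iV];
      ++ir_;
    }
    if (s == total_steps) break;

    const double tb = t - bcl * std::floor(t / bcl);
    const bool stim_on = (tb >= 0.0 && tb < stim_dur);

    for (int i = 0; i < n_nodes; ++i)
      vprev[i] = X[(size_t)i * NSTATE + iV];

    // reaction
    for (int i = 0; i < n_nodes; ++i) {
      const double Istim = (stim_on && i < n_stim_nodes) ? stim_amp : 0.0;
      cell_step(&X[(size_t)i * NSTATE], celltype, gks, Istim, dt);
    }
    // diffusion on the pre-reaction voltage field, no-flux boundaries
    for (int i = 0; i < n_nodes; ++i) {
      const double vl = vprev[i == 0 ? 1 : i - 1];
      const double vr = vprev[i == n_nodes - 1 ? n_nodes - 2 : i + 1];
      vnew[i] = dt * Dcoef * (vl - 2.0 * vprev[i] + vr) / (dx * dx);
    }
    for (int i = 0; i < n_nodes; ++i) {
      double *Xi = &X[(size_t)i * NSTATE];
      Xi[iV] += vnew[i];
      // activation detection (whole-step crossing) within the last beat
      if (s >= rec_start && R_IsNA(act[i]) && vprev[i] < act_thresh &&
          Xi[iV] >= act_thresh) {
        const double frac = (act_thresh - vprev[i]) / (Xi[iV] - vprev[i]);
        act[i] = (t - rec_start * dt) + dt * frac;
      }
      if (!std::isfinite(Xi[iV]))
        stop("cable blow-up at node %d, t = %.2f ms (CFL or stimulus "
             "settings)", i + 1, t);
    }
  }

  return List::create(_["t"] = tt, _["Vmat"] = Vmat, _["act_ms"] = act,
                      _["dx"] = dx, _["bcl"] = bcl);
}
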