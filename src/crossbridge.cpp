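// Rice-style four-state crossbridge scheme driven by a cytosolic Ca trace.
//
// Occupancies [N, P, XB_PreR, XB_PostR] form a linear chain once the
// regulatory rates are frozen at the (midpoint) troponin saturation, so each
// step advances them with an exact 4x4 matrix exponential; this is
// unconditionally stable under the very fast P->N rate the (TCa)^-7.5
// power law produces at diastolic Ca.  Troponin binding, strains and the
// sarcomere-length/force-integral pair are linear in their own variable and
// use exact exponential (Rush-Larsen-type) updates.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// state layout (9)
enum { sTCa = 0, sN, sP, sPre, sPost, sxPre, sxPost, sSL, sFint, XBNSTATE };

struct XbPars {
  double kon, koff;            // troponin Ca binding, 1/(mM ms), 1/ms
  double Knp, Kpn, nexp;       // regulatory rates (1/ms) and exponent
  double fapp, gapp, hf, hb, gxb;  // crossbridge cycle rates, 1/ms
  double x0;                   // power-stroke strain, um
  double phi;                  // strain-kinetic mixing factor
  double visc, mass, KSE;      // Eq 9/11 mechanical constants
  double SL0, SLrest;          // um
  double PCon, PExp;           // passive (titin-like) force curve
  int mode;                    // 0 isosarcometric, 1 isometric, 2 isotonic
  double F_after_fixed;        // isotonic afterload (normalized force)
  double duty_pre, duty_post, duty_post_max;
};

static XbPars parse_pars(NumericVector p) {
  XbPars q;
  q.kon = p["kon"]; q.koff = p["koff"];
  q.Knp = p["K_np"]; q.Kpn = p["K_pn"]; q.nexp = p["n_exp"];
  q.fapp = p["f_aapT"]; q.gapp = p["g_aapT"];
  q.hf = p["h_fT"]; q.hb = p["h_bT"]; q.gxb = p["g_xbT"];
  q.x0 = p["x0"]; q.phi = p["phi"];
  q.visc = p["viscosity"]; q.mass = p["mass"]; q.KSE = p["KSE"];
  q.SL0 = p["SL_0"]; q.SLrest = p["SL_rest"];
  q.PCon = p["PCon"]; q.PExp = p["PExp"];
  q.mode = (int)p["mode"];
  q.F_after_fixed = p["F_afterload_fixed"];
  const double D = q.gapp * q.hb + q.gapp * q.gxb + q.hf * q.gxb +
                   q.fapp * (q.hb + q.gxb) + q.fapp * q.hf;
  q.duty_pre = q.fapp * (q.hb + q.gxb) / D;
  q.duty_post = q.fapp * q.hf / D;
  q.duty_post_max = q.duty_post;
  return q;
}

static inline double f_passive(const XbPars &q, double SL) {
  const double d = SL - q.SLrest;
  return d >= 0 ? q.PCon * (std::exp(q.PExp * d) - 1.0)
                : -q.PCon * (std::exp(-q.PExp * d) - 1.0);
}

static inline double f_active(const XbPars &q, const double *S) {
  return (S[sPre] * S[sxPre] + S[sPost] * S[sxPost]) /
         (q.x0 * q.duty_post_max);
}

static inline double f_afterload(const XbPars &q, const double *S) {
  if (q.mode == 2) return q.F_after_fixed;
  return q.KSE * (S[sSL] - q.SL0);
}

// exact exponential update of dy/dt = -a*y + b over dt (a >= 0)
static inline double expo_update(double y, double a, double b, double dt) {
  if (a <= 0.0) return y + b * dt;
  const double yinf = b / a;
  return yinf + (y - yinf) * std::exp(-a * dt);
}

// Exact affine update of the sarcomere-length / force-integral pair.
// With z = SL - SL_0 and the active/passive forces frozen over the step,
//   dz/dt    = (Fint - z * visc) / mass
//   dFint/dt = Fnet0 - keff * z        (keff: series spring + linearized
//                                        passive stiffness)
// is linear; the pair is a very fast damped oscillator (angular frequency
// sqrt(keff/mass) ~ 1e3 / ms at default constants), so it is advanced with
// the exact matrix exponential of the augmented 3x3 affine system.
static void sl_update(double *S, const XbPars &q, double dt) {
  const double z = S[sSL] - q.SL0;
  const double Fa = f_active(q, S);
  const double Fp = f_passive(q, S[sSL]);
  const double Fpre = f_passive(q, q.SL0);
  const double kse = (q.mode == 2) ? 0.0 : q.KSE;
  // linearized passive stiffness at the current SL
  const double d = S[sSL] - q.SLrest;
  const double kp = q.PCon * q.PExp * std::exp(q.PExp * std::fabs(d));
  const double keff = kse + kp;
  // force at z held constant minus the parts linear in z
  const double Faft0 = (q.mode == 2) ? q.F_after_fixed : kse * z;
  const double Fnet0 = Fa + Fp - Fpre - Faft0 + keff * z;

  arma::mat M(3, 3, arma::fill::zeros);
  M(0, 0) = -q.visc / q.mass;  M(0, 1) = 1.0 / q.mass;
  M(1, 0) = -keff;             M(1, 2) = Fnet0;
  arma::vec x = {z, S[sFint], 1.0};
  arma::vec xn = arma::expmat(M * dt) * x;
  S[sSL] = q.SL0 + xn(0);
  S[sFint] = xn(1);
}

// one step; returns ATP consumed during the step (g_xbT * XB_PostR * dt,
// via trapezoid of the occupancy)
static double xb_step(double *S, const XbPars &q, double ca, double dt,
                      int *clip_count) {
  // troponin saturation: half-step, rates at midpoint, then full update
  const double a_t = q.kon * ca + q.koff;
  const double tca_mid = expo_update(S[sTCa], a_t, q.kon * ca, 0.5 * dt);
  const double tca_new = expo_update(S[sTCa], a_t, q.kon * ca, dt);

  const double tca = std::max(tca_mid, 1e-8);
  const double knp = q.Knp * std::pow(tca, q.nexp);
  const double kpn = q.Kpn * std::pow(tca, -q.nexp);

  arma::mat A(4, 4, arma::fill::zeros);
  A(0, 0) = -knp;            A(0, 1) = kpn;
  A(1, 0) = knp;             A(1, 1) = -(kpn + q.fapp);
  A(1, 2) = q.gapp;          A(1, 3) = q.gxb;
  A(2, 1) = q.fapp;          A(2, 2) = -(q.gapp + q.hf);
  A(2, 3) = q.hb;
  A(3, 2) = q.hf;            A(3, 3) = -(q.hb + q.gxb);

  arma::vec p = {S[sN], S[sP], S[sPre], S[sPost]};
  const double post_old = S[sPost];
  arma::vec pn = arma::expmat(A * dt) * p;

  // mechanics (strain rates are moderate; exponential per-variable updates)
  double dSL = 0.0;
  if (q.mode != 0)
    dSL = (S[sFint] + (q.SL0 - S[sSL]) * q.visc) / q.mass;
  // clamp the instantaneous SL velocity fed to the strain kinetics; the
  // SL update itself is exact below
  if (dSL > 10.0) dSL = 10.0;
  if (dSL < -10.0) dSL = -10.0;

  const double a1 = q.phi / q.duty_pre * (q.fapp + q.hb);
  const double b1 = 0.5 * dSL +
                    q.phi / q.duty_pre * q.hb * (S[sxPost] - q.x0);
  const double a2 = q.phi / q.duty_post * q.hf;
  const double b2 = 0.5 * dSL + a2 * (S[sxPre] + q.x0);

  S[sTCa] = tca_new;
  S[sN] = pn(0); S[sP] = pn(1); S[sPre] = pn(2); S[sPost] = pn(3);
  S[sxPre] = expo_update(S[sxPre], a1, b1, dt);
  S[sxPost] = expo_update(S[sxPost], a2, b2, dt);
  // physical strain envelope (~7 power strokes); only reachable under
  // sustained unloaded shortening in isotonic mode
  const double xcap = 0.05;
  if (S[sxPre] > xcap) S[sxPre] = xcap;
  if (S[sxPre] < -xcap) S[sxPre] = -xcap;
  if (S[sxPost] > xcap) S[sxPost] = xcap;
  if (S[sxPost] < -xcap) S[sxPost] = -xcap;
  if (q.mode != 0) {
    sl_update(S, q, dt);
    if (S[sSL] < 1.4) { S[sSL] = 1.4; S[sFint] = 0.0; ++(*clip_count); }
    if (S[sSL] > 2.4) { S[sSL] = 2.4; S[sFint] = 0.0; ++(*clip_count); }
  }
  return q.gxb * 0.5 * (post_old + S[sPost]) * dt;
}

// [[Rcpp::export]]
NumericVector cpp_xb_step(NumericVector state, double ca, NumericVector pars,
                          double dt) {
  if (state.size() != XBNSTATE) stop("xb state must have %d components",
                                     XBNSTATE);
  XbPars q = parse_pars(pars);
  NumericVector out = clone(state);
  int clip = 0;
  xb_step(REAL(out), q, ca, dt, &clip);
  out.attr("names") = state.attr("names");
  if (clip > 0) out.attr("clipped") = true;
  return out;
}

// Run the crossbridge model over a Ca trace sampled on a uniform grid
// (ca_dt spacing, starting at t = 0); the integrator interpolates linearly.
// [[Rcpp::export]]
List cpp_xb_run(NumericVector state0, NumericVector ca_trace, double ca_dt,
                NumericVector pars, double dt, int rec_every) {
  if (state0.size() != XBNSTATE) stop("xb state must have %d components",
                                      XBNSTATE);
  XbPars q = parse_pars(pars);
  std::vector<double> S(REAL(state0), REAL(state0) + XBNSTATE);

  const int nca = ca_trace.size();
  const double t_end = (nca - 1) * ca_dt;
  const long nsteps = (long)std::floor(t_end / dt + 0.5);
  const int nrec = (int)(nsteps / rec_every) + 1;

  NumericVector tt(nrec), Nn(nrec), Pp(nrec), pre(nrec), post(nrec),
      tca(nrec), fa(nrec), fp(nrec), faft(nrec), sl(nrec), atp(nrec),
      cai(nrec);
  double atp_total = 0.0;
  int clip = 0, ir = 0;

  for (long s = 0; s <= nsteps; ++s) {
    const double t = s * dt;
    // linear interpolation of the Ca trace
    double u = t / ca_dt;
    int k = (int)u; if (k >= nca - 1) k = nca - 2;
    const double frac = u - k;
    const double ca = ca_trace[k] * (1.0 - frac) + ca_trace[k + 1] * frac;

    if (s % rec_every == 0 && ir < nrec) {
      tt[ir] = t; Nn[ir] = S[sN]; Pp[ir] = S[sP];
      pre[ir] = S[sPre]; post[ir] = S[sPost]; tca[ir] = S[sTCa];
      fa[ir] = f_active(q, S.data()); fp[ir] = f_passive(q, S[sSL]);
      faft[ir] = f_afterload(q, S.data()); sl[ir] = S[sSL];
      atp[ir] = q.gxb * S[sPost] * 1000.0;  // 1/s
      cai[ir] = ca;
      ++ir;
    }
    if (s == nsteps) break;
    atp_total += xb_step(S.data(), q, ca, dt, &clip);
  }

  NumericVector fin(XBNSTATE);
  for (int k2 = 0; k2 < XBNSTATE; ++k2) fin[k2] = S[k2];
  fin.attr("names") = state0.attr("names");

  return List::create(_["t"] = tt, _["Cai"] = cai, _["N_xb"] = Nn,
                      _["P_xb"] = Pp, _["XB_PreR"] = pre,
                      _["XB_PostR"] = post, _["TCa_Tot"] = tca,
                      _["F_active"] = fa, _["F_passive"] = fp,
                      _["F_afterload"] = faft, _["SL"] = sl,
                      _["atp_rate"] = atp, _["atp_total"] = atp_total,
                      _["state"] = fin, _["n_clipped"] = clip);
}

// single exact update of the SL / force-integral pair (identity in
// isosarcometric mode); used by the R-level sarcomere-length stepper
// [[Rcpp::export]]
NumericVector cpp_sl_step(NumericVector state, NumericVector pars,
                          double dt) {
  if (state.size() != XBNSTATE) stop("xb state must have %d components",
                                     XBNSTATE);
  XbPars q = parse_pars(pars);
  NumericVector out = clone(state);
  if (q.mode != 0) {
    double *S = REAL(out);
    sl_update(S, q, dt);
    bool clip = false;
    if (S[sSL] < 1.4) { S[sSL] = 1.4; S[sFint] = 0.0; clip = true; }
    if (S[sSL] > 2.4) { S[sSL] = 2.4; S[sFint] = 0.0; clip = true; }
    if (clip) out.attr("clipped") = true;
  }
  out.attr("names") = state.attr("names");
  return out;
}
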