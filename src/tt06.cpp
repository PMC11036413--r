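// Ten Tusscher-Panfilov (2006) human ventricular myocyte model and an
// operator-split monodomain tissue stepper.
//
// Units: mV, ms, mM; currents in pA/pF (== uA/cm^2 at Cm = 1 uF/cm^2).
// Gating variables advance by Rush-Larsen exponential steps with
// voltage-indexed lookup tables; concentrations by forward Euler with
// analytic (quadratic) buffering, as in the original model code.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// ---- physical constants -------------------------------------------------
static const double RGAS = 8314.472;     // mJ/(mol K)
static const double FRDY = 96485.3415;   // C/mol
static const double TEMP = 310.0;        // K
static const double RTONF = RGAS * TEMP / FRDY;
static const double FONRT = 1.0 / RTONF;

static const double Ko = 5.4, Cao = 2.0, Nao = 140.0;
static const double Vc = 0.016404, Vsr = 0.001094, Vss = 0.00005468;
static const double Bufc = 0.2, Kbufc = 0.001;
static const double Bufsr = 10.0, Kbufsr = 0.3;
static const double Bufss = 0.4, Kbufss = 0.00025;
static const double Vmaxup = 0.006375, Kup = 0.00025;
static const double Vrel = 0.102, k1p = 0.15, k2p = 0.045, k3 = 0.060,
                    k4 = 0.005, EC = 1.5, maxsr = 2.5, minsr = 1.0;
static const double Vleak = 0.00036, Vxfer = 0.0038;
static const double CAPACITANCE = 0.185;
static const double pKNa = 0.03;
static const double GK1 = 5.405, GNa = 14.838, GbNa = 0.00029;
static const double KmK = 1.0, KmNa = 40.0, knak = 2.724;
static const double GCaL = 0.00003980, GbCa = 0.000592;
static const double knaca = 1000.0, KmNai = 87.5, KmCa = 1.38, ksat = 0.1,
                    ncx_g = 0.35;
static const double GpCa = 0.1238, KpCa = 0.0005, GpK = 0.0146;
static const double Gkr_base = 0.153;
// epicardial base cell: all transmural layers derive from it by Gks scaling
static const double Gks_base = 0.392, Gto_base = 0.294;

static const double invVcF = 1.0 / (Vc * FRDY);
static const double invVcF2 = 1.0 / (2.0 * Vc * FRDY);
static const double invVssF2 = 1.0 / (2.0 * Vss * FRDY);

// state layout (after Vm): 18 entries
enum { iKi = 0, iNai, iCai, iCaSS, iCaSR, iM, iH, iJ, iXr1, iXr2, iXs,
       iR, iS, iD, iF, iF2, iFCass, iRR, NSTATE };

// ---- voltage lookup tables ---------------------------------------------
struct LUT {
  double vmin, vmax, step, inv_step;
  int n;
  // per entry: 11 gates x (inf, rl) + 6 auxiliary voltage terms
  std::vector<double> tab;  // n * 28
  double dt;

  static double sq(double x) { return x * x; }

  void build(double dt_) {
    dt = dt_;
    vmin = -120.0; vmax = 80.0; step = 0.02;
    inv_step = 1.0 / step;
    n = (int)std::floor((vmax - vmin) * inv_step) + 2;
    tab.assign((size_t)n * 28, 0.0);
    for (int i = 0; i < n; ++i) {
      double V = vmin + i * step;
      double *e = &tab[(size_t)i * 28];
      // m
      double minf = 1.0 / sq(1.0 + std::exp((-56.86 - V) / 9.03));
      double am = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
      double bm = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
                  0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
      double taum = am * bm;
      // h
      double hinf = 1.0 / sq(1.0 + std::exp((V + 71.55) / 7.43));
      double ah, bh;
      if (V >= -40.0) {
        ah = 0.0;
        bh = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
      } else {
        ah = 0.057 * std::exp(-(V + 80.0) / 6.8);
        bh = 2.7 * std::exp(0.079 * V) + 310000.0 * std::exp(0.3485 * V);
      }
      double tauh = 1.0 / (ah + bh);
      // j
      double jinf = hinf;
      double aj, bj;
      if (V >= -40.0) {
        aj = 0.0;
        bj = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
      } else {
        aj = (-25428.0 * std::exp(0.2444 * V) -
              6.948e-6 * std::exp(-0.04391 * V)) * (V + 37.78) /
             (1.0 + std::exp(0.311 * (V + 79.23)));
        bj = 0.02424 * std::exp(-0.01052 * V) /
             (1.0 + std::exp(-0.1378 * (V + 40.14)));
      }
      double tauj = 1.0 / (aj + bj);
      // xr1
      double xr1inf = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
      double axr1 = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
      double bxr1 = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
      double tauxr1 = axr1 * bxr1;
      // xr2
      double xr2inf = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
      double axr2 = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
      double bxr2 = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
      double tauxr2 = axr2 * bxr2;
      // xs
      double xsinf = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
      double axs = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0));
      double bxs = 1.0 / (1.0 + std::exp((V - 35.0) / 15.0));
      double tauxs = axs * bxs + 80.0;
      // r (transient outward activation)
      double rinf = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
      double taur = 9.5 * std::exp(-sq(V + 40.0) / 1800.0) + 0.8;
      // s (epicardial formulation)
      double sinf = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
      double taus = 85.0 * std::exp(-sq(V + 45.0) / 320.0) +
                    5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
      // d
      double dinf = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
      double ad = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
      double bd = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
      double cd = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
      double taud = ad * bd + cd;
      // f
      double finf = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
      double tauf = 1102.5 * std::exp(-sq(V + 27.0) / 225.0) +
                    200.0 / (1.0 + std::exp((13.0 - V) / 10.0)) +
                    180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0;
      // f2
      double f2inf = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
      double tauf2 = 562.0 * std::exp(-sq(V + 27.0) / 240.0) +
                     31.0 / (1.0 + std::exp((25.0 - V) / 10.0)) +
                     80.0 / (1.0 + std::exp((V + 30.0) / 10.0));
      int q = 0;
      e[q++] = minf;   e[q++] = std::exp(-dt / taum);
      e[q++] = hinf;   e[q++] = std::exp(-dt / tauh);
      e[q++] = jinf;   e[q++] = std::exp(-dt / tauj);
      e[q++] = xr1inf; e[q++] = std::exp(-dt / tauxr1);
      e[q++] = xr2inf; e[q++] = std::exp(-dt / tauxr2);
      e[q++] = xsinf;  e[q++] = std::exp(-dt / tauxs);
      e[q++] = rinf;   e[q++] = std::exp(-dt / taur);
      e[q++] = sinf;   e[q++] = std::exp(-dt / taus);
      e[q++] = dinf;   e[q++] = std::exp(-dt / taud);
      e[q++] = finf;   e[q++] = std::exp(-dt / tauf);
      e[q++] = f2inf;  e[q++] = std::exp(-dt / tauf2);
      // auxiliary voltage-only factors
      double recnak = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V * FONRT) +
                             0.0353 * std::exp(-V * FONRT));
      double recpk = 1.0 / (1.0 + std::exp((25.0 - V) / 5.98));
      double e1 = std::exp(ncx_g * V * FONRT);
      double e2 = std::exp((ncx_g - 1.0) * V * FONRT);
      // L-type driving terms: ICaL = GCaL*d*f*f2*fcass*(calA*CaSS - calB)
      double z = 2.0 * (V - 15.0) * FONRT;
      double C = 4.0 * (V - 15.0) * FRDY * FONRT;  // 4 (V-15) F^2 / RT
      double calA, calB;
      if (std::fabs(z) < 1e-6) {  // removable singularity at V = 15
        // limits: C e/(e-1) -> 2F, C/(e-1) -> 2F
        calA = 0.25 * 2.0 * FRDY;
        calB = 2.0 * FRDY * Cao;
      } else {
        double ez = std::exp(z);
        calA = C * 0.25 * ez / (ez - 1.0);
        calB = C * Cao / (ez - 1.0);
      }
      e[q++] = recnak; e[q++] = recpk; e[q++] = e1; e[q++] = e2;
      e[q++] = calA;   e[q++] = calB;
    }
  }

  inline const double *row(double V, double &w) const {
    double x = (V - vmin) * inv_step;
    if (x < 0.0) x = 0.0;
    if (x > n - 2) x = n - 2;
    int i = (int)x;
    w = x - i;
    return &tab[(size_t)i * 28];
  }
};

// one reaction step for a single cell; scales = {gna, gcal, gkr, gks}
// Ist > 0 is a depolarizing external stimulus in pA/pF.
// returns dVm/dt (mV/ms) actually applied.
static inline double tt06_step(double &V, double *s, const double *sc,
                               double Ist, double dt, const LUT &lut,
                               double dV_diff) {
  double w;
  const double *a = lut.row(V, w);
  const double *b = a + 28;
  #define LU(k) (a[k] + w * (b[k] - a[k]))

  double Ek  = RTONF * std::log(Ko / s[iKi]);
  double Ena = RTONF * std::log(Nao / s[iNai]);
  double Eks = RTONF * std::log((Ko + pKNa * Nao) /
                                (s[iKi] + pKNa * s[iNai]));
  double Eca = 0.5 * RTONF * std::log(Cao / s[iCai]);

  // IK1 rectification (depends on V - Ek, kept out of the LUT)
  double vk = V - Ek;
  double ak1 = 0.1 / (1.0 + std::exp(0.06 * (vk - 200.0)));
  double bk1 = (3.0 * std::exp(0.0002 * (vk + 100.0)) +
                std::exp(0.1 * (vk - 10.0))) /
               (1.0 + std::exp(-0.5 * vk));
  double IK1 = GK1 * ak1 / (ak1 + bk1) * vk;

  double INa = GNa * sc[0] * s[iM] * s[iM] * s[iM] * s[iH] * s[iJ] * (V - Ena);
  double ICaL = GCaL * sc[1] * s[iD] * s[iF] * s[iF2] * s[iFCass] *
                (LU(26) * s[iCaSS] - LU(27));
  double Ito = Gto_base * s[iR] * s[iS] * vk;
  double IKr = Gkr_base * sc[2] * std::sqrt(Ko / 5.4) * s[iXr1] * s[iXr2] * vk;
  double IKs = Gks_base * sc[3] * s[iXs] * s[iXs] * (V - Eks);
  double INaK = knak * (Ko / (Ko + KmK)) *
                (s[iNai] / (s[iNai] + KmNa)) * LU(22);
  double nai3 = s[iNai] * s[iNai] * s[iNai];
  double INaCa = knaca / ((KmNai * KmNai * KmNai + Nao * Nao * Nao) *
                          (KmCa + Cao) * (1.0 + ksat * LU(25))) *
                 (LU(24) * nai3 * Cao - LU(25) * Nao * Nao * Nao *
                  s[iCai] * 2.5);
  double IpCa = GpCa * s[iCai] / (KpCa + s[iCai]);
  double IpK = GpK * LU(23) * vk;
  double IbNa = GbNa * (V - Ena);
  double IbCa = GbCa * (V - Eca);

  double Iion = IK1 + Ito + IKr + IKs + ICaL + INaK + INa + IbNa +
                INaCa + IbCa + IpK + IpCa;

  // calcium subsystem
  double casr = s[iCaSR], cass = s[iCaSS], cai = s[iCai];
  double kcasr = maxsr - (maxsr - minsr) / (1.0 + (EC / casr) * (EC / casr));
  double k1 = k1p / kcasr, k2 = k2p * kcasr;
  s[iRR] += dt * (k4 * (1.0 - s[iRR]) - k2 * cass * s[iRR]);
  double OO = k1 * cass * cass * s[iRR] / (k3 + k1 * cass * cass);
  double Irel = Vrel * OO * (casr - cass);
  double Ileak = Vleak * (casr - cai);
  double Iup = Vmaxup / (1.0 + (Kup * Kup) / (cai * cai));
  double Ixfer = Vxfer * (cass - cai);

  {
    double csqn = Bufsr * casr / (casr + Kbufsr);
    double dsr = dt * (Iup - Irel - Ileak);
    double bj = Bufsr - csqn - dsr - casr + Kbufsr;
    double cj = Kbufsr * (csqn + dsr + casr);
    s[iCaSR] = (std::sqrt(bj * bj + 4.0 * cj) - bj) / 2.0;
  }
  {
    double buf = Bufss * cass / (cass + Kbufss);
    double dss = dt * (-Ixfer * (Vc / Vss) + Irel * (Vsr / Vss) -
                       ICaL * invVssF2 * CAPACITANCE);
    double bj = Bufss - buf - dss - cass + Kbufss;
    double cj = Kbufss * (buf + dss + cass);
    s[iCaSS] = (std::sqrt(bj * bj + 4.0 * cj) - bj) / 2.0;
  }
  {
    double buf = Bufc * cai / (cai + Kbufc);
    double dci = dt * (-(IbCa + IpCa - 2.0 * INaCa) * invVcF2 * CAPACITANCE -
                       (Iup - Ileak) * (Vsr / Vc) + Ixfer);
    double bj = Bufc - buf - dci - cai + Kbufc;
    double cj = Kbufc * (buf + dci + cai);
    s[iCai] = (std::sqrt(bj * bj + 4.0 * cj) - bj) / 2.0;
  }
  s[iNai] += dt * (-(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) *
                   invVcF * CAPACITANCE);
  s[iKi] += dt * (-(IK1 + Ito + IKr + IKs - 2.0 * INaK + IpK - Ist) *
                  invVcF * CAPACITANCE);

  // Rush-Larsen gate updates
  s[iM]   = LU(0)  + (s[iM]   - LU(0))  * LU(1);
  s[iH]   = LU(2)  + (s[iH]   - LU(2))  * LU(3);
  s[iJ]   = LU(4)  + (s[iJ]   - LU(4))  * LU(5);
  s[iXr1] = LU(6)  + (s[iXr1] - LU(6))  * LU(7);
  s[iXr2] = LU(8)  + (s[iXr2] - LU(8))  * LU(9);
  s[iXs]  = LU(10) + (s[iXs]  - LU(10)) * LU(11);
  s[iR]   = LU(12) + (s[iR]   - LU(12)) * LU(13);
  s[iS]   = LU(14) + (s[iS]   - LU(14)) * LU(15);
  s[iD]   = LU(16) + (s[iD]   - LU(16)) * LU(17);
  s[iF]   = LU(18) + (s[iF]   - LU(18)) * LU(19);
  s[iF2]  = LU(20) + (s[iF2]  - LU(20)) * LU(21);
  double fcinf = 0.6 / (1.0 + (cass / 0.05) * (cass / 0.05)) + 0.4;
  double taufc = 80.0 / (1.0 + (cass / 0.05) * (cass / 0.05)) + 2.0;
  s[iFCass] = fcinf + (s[iFCass] - fcinf) * std::exp(-dt / taufc);

  double dVdt = -Iion + Ist + dV_diff;
  V += dt * dVdt;
  return dVdt;
  #undef LU
}

// [[Rcpp::export]]
NumericVector tt06_initial_state_cpp() {
  NumericVector out(NSTATE + 1);
  out[0] = -86.2;                 // Vm
  double s[NSTATE];
  s[iKi] = 138.3; s[iNai] = 7.67; s[iCai] = 0.00007; s[iCaSS] = 0.00007;
  s[iCaSR] = 1.3; s[iM] = 0.0; s[iH] = 0.75; s[iJ] = 0.75;
  s[iXr1] = 0.0; s[iXr2] = 1.0; s[iXs] = 0.0; s[iR] = 0.0; s[iS] = 1.0;
  s[iD] = 0.0; s[iF] = 1.0; s[iF2] = 1.0; s[iFCass] = 1.0; s[iRR] = 1.0;
  for (int k = 0; k < NSTATE; ++k) out[k + 1] = s[k];
  out.attr("names") = CharacterVector::create(
      "Vm", "Ki", "Nai", "Cai", "CaSS", "CaSR", "m", "h", "j", "xr1",
      "xr2", "xs", "r", "s", "d", "f", "f2", "fcass", "Rq");
  return out;
}

// Pace a single cell for n_beats at the given cycle length.
// Records the Vm(t) trace of the last beat (stride in steps) and per-beat
// (activation, repolarization) pairs: activation = time of max dVm/dt in the
// upstroke episode, repolarization = -70 mV downward crossing.
// [[Rcpp::export]]
List tt06_pace_cpp(NumericVector state0, NumericVector scales,
                   int n_beats, double bcl, double stim_amp,
                   double stim_dur, double dt, int trace_stride) {
  if (state0.size() != NSTATE + 1) stop("state vector must have 19 entries");
  LUT lut; lut.build(dt);
  double V = state0[0];
  double s[NSTATE];
  for (int k = 0; k < NSTATE; ++k) s[k] = state0[k + 1];
  double sc[4] = { scales[0], scales[1], scales[2], scales[3] };

  long steps_per_beat = (long)std::llround(bcl / dt);
  long stim_steps = (long)std::llround(stim_dur / dt);

  std::vector<double> tr_t, tr_v;
  NumericVector act(n_beats, NA_REAL), rep(n_beats, NA_REAL);

  bool in_ep = false; double best_dvdt = 0.0, best_t = NA_REAL;
  int ep_beat = -1;

  for (int beat = 0; beat < n_beats; ++beat) {
    bool last = (beat == n_beats - 1);
    for (long k = 0; k < steps_per_beat; ++k) {
      double t = beat * bcl + k * dt;
      double Ist = (k < stim_steps) ? stim_amp : 0.0;
      double Vold = V;
      if (last && (k % trace_stride == 0)) { tr_t.push_back(t); tr_v.push_back(V); }
      double dVdt = tt06_step(V, s, sc, Ist, dt, lut, 0.0);
      if (!std::isfinite(V)) stop("integration failure: non-finite Vm at t=%f", t);
      if (!in_ep && V >= -60.0 && V > Vold) {
        in_ep = true; best_dvdt = -1e300; ep_beat = beat;
      }
      if (in_ep) {
        if (dVdt > best_dvdt) { best_dvdt = dVdt; best_t = t; }
        if (Vold > -70.0 && V <= -70.0) {
          double tc = t + dt * (Vold + 70.0) / (Vold - V);
          if (ep_beat >= 0 && !R_finite(act[ep_beat])) {
            act[ep_beat] = best_t; rep[ep_beat] = tc;
          }
          in_ep = false;
        }
      }
    }
  }
  return List::create(
      _["state"] = [&]{ NumericVector o(NSTATE + 1); o[0] = V;
        for (int k = 0; k < NSTATE; ++k) o[k + 1] = s[k];
        o.attr("names") = state0.attr("names"); return o; }(),
      _["trace_t"] = wrap(tr_t), _["trace_v"] = wrap(tr_v),
      _["act"] = act, _["rep"] = rep);
}

// Monodomain stepper on an arbitrary mesh.
//
// lap_* : CSR of A = M^-1 K / (beta Cm) so that diffusion contributes
//         dVm/dt = -(A V). Explicit forward-Euler diffusion.
// stim_nodes: list of 1-based node index vectors.
// Records up to max_cross (activation, repolarization) pairs per node.
// [[Rcpp::export]]
List monodomain_cpp(NumericVector V0, NumericMatrix S0, NumericMatrix scales,
                    IntegerVector lap_p, IntegerVector lap_j,
                    NumericVector lap_x,
                    List stim_nodes, NumericVector stim_amp,
                    NumericVector stim_onset, NumericVector stim_dur,
                    double dt, double duration, int max_cross,
                    int snapshot_stride, double act_thresh,
                    double rep_thresh, bool early_stop) {
  int n = V0.size();
  if (S0.nrow() != n || S0.ncol() != NSTATE) stop("bad state matrix");
  if (scales.nrow() != n || scales.ncol() != 4) stop("bad scales matrix");
  if ((int)lap_p.size() != n + 1) stop("bad CSR pointer length");

  LUT lut; lut.build(dt);
  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> S((size_t)n * NSTATE);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < NSTATE; ++k) S[(size_t)i * NSTATE + k] = S0(i, k);
  // row-major copy: NumericMatrix is column-major but the cell kernel
  // expects a node's 4 scale factors contiguous
  std::vector<double> SC((size_t)n * 4);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 4; ++k) SC[(size_t)i * 4 + k] = scales(i, k);

  int nstim = stim_nodes.size();
  std::vector<std::vector<int>> snodes(nstim);
  double last_stim_end = 0.0;
  for (int q = 0; q < nstim; ++q) {
    IntegerVector v = stim_nodes[q];
    snodes[q].assign(v.begin(), v.end());
    for (auto &z : snodes[q]) z -= 1;
    double e = stim_onset[q] + stim_dur[q];
    if (e > last_stim_end) last_stim_end = e;
  }

  long nsteps = (long)std::llround(duration / dt);
  NumericMatrix act(n, max_cross), rep(n, max_cross);
  std::fill(act.begin(), act.end(), NA_REAL);
  std::fill(rep.begin(), rep.end(), NA_REAL);
  IntegerVector nact(n, 0), nrep(n, 0);

  std::vector<char> in_ep(n, 0);
  std::vector<double> best_dvdt(n, 0.0), best_t(n, 0.0);
  std::vector<double> ist(n, 0.0), du(n, 0.0);

  int nsnap = snapshot_stride > 0 ? (int)(nsteps / snapshot_stride) + 1 : 0;
  NumericMatrix snaps(nsnap > 0 ? n : 0, nsnap);
  std::vector<double> snap_t;
  int isnap = 0;

  double t_end = duration;
  for (long k = 0; k < nsteps; ++k) {
    double t = k * dt;
    // external stimuli
    std::fill(ist.begin(), ist.end(), 0.0);
    bool stim_now = false;
    for (int q = 0; q < nstim; ++q) {
      if (t >= stim_onset[q] && t < stim_onset[q] + stim_dur[q]) {
        stim_now = true;
        for (int idx : snodes[q]) ist[idx] = stim_amp[q];
      }
    }
    // diffusion term du = -(A V)
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int p = lap_p[i]; p < lap_p[i + 1]; ++p)
        acc += lap_x[p] * V[lap_j[p]];
      du[i] = -acc;
    }
    double vmax = -1e300, dvmax = 0.0;
    for (int i = 0; i < n; ++i) {
      double Vold = V[i];
      double dVdt = tt06_step(V[i], &S[(size_t)i * NSTATE], &SC[(size_t)i * 4],
                              ist[i], dt, lut, du[i]);
      if (!std::isfinite(V[i]))
        stop("integration failure: non-finite Vm at node %d, t=%f", i + 1, t);
      if (V[i] > vmax) vmax = V[i];
      double ad = std::fabs(dVdt); if (ad > dvmax) dvmax = ad;
      // per-node upstroke automaton: 0 rest, 1 rising, 2 depolarized.
      // activation (time of max dVm/dt) is committed once the upstroke
      // passes -20 mV; repolarization at the -70 mV downward crossing.
      if (in_ep[i] == 0) {
        if (V[i] >= act_thresh && V[i] > Vold) {
          in_ep[i] = 1; best_dvdt[i] = -1e300;
        }
      }
      if (in_ep[i] == 1) {
        if (dVdt > best_dvdt[i]) { best_dvdt[i] = dVdt; best_t[i] = t; }
        if (V[i] >= -20.0) {
          if (nact[i] < max_cross) act(i, nact[i]) = best_t[i];
          nact[i] += 1;
          in_ep[i] = 2;
        } else if (Vold > rep_thresh && V[i] <= rep_thresh) {
          in_ep[i] = 0;  // sub-threshold bump, no activation
        }
      } else if (in_ep[i] == 2) {
        if (Vold > rep_thresh && V[i] <= rep_thresh) {
          double tc = t + dt * (Vold - rep_thresh) / (Vold - V[i]);
          if (nrep[i] < max_cross && nact[i] - 1 < max_cross &&
              nact[i] >= 1)
            rep(i, nact[i] - 1) = tc;
          nrep[i] += 1;
          in_ep[i] = 0;
        }
      }
    }
    if (nsnap > 0 && (k % snapshot_stride == 0) && isnap < nsnap) {
      for (int i = 0; i < n; ++i) snaps(i, isnap) = V[i];
      snap_t.push_back(t);
      ++isnap;
    }
    // quiescence: everything at rest and no stimulus pending -> stop
    if (early_stop && !stim_now && (k % 50 == 49) &&
        t > last_stim_end + 5.0 && vmax < -65.0 && dvmax < 0.05) {
      t_end = t + dt;
      break;
    }
    if ((k & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix Sout(n, NSTATE);
  for (int i = 0; i < n; ++i)
    for (int kk = 0; kk < NSTATE; ++kk) Sout(i, kk) = S[(size_t)i * NSTATE + kk];
  NumericVector Vout(V.begin(), V.end());

  List out = List::create(
      _["act"] = act, _["rep"] = rep, _["n_act"] = nact,
      _["Vm"] = Vout, _["states"] = Sout, _["t_end"] = t_end);
  if (nsnap > 0) {
    out["snapshots"] = snaps;
    out["snapshot_times"] = wrap(snap_t);
  }
  return out;
}
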