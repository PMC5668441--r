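// Spontaneous hiPSC-CM action-potential model with late sodium current.
//
// Base membrane model: the Paci hiPSC-CM ventricular-like model family
// (Paci et al. 2013, Ann Biomed Eng; 2015 revision), itself built on the
// ten Tusscher 2004 human ventricular formulations.  Voltage is carried in
// volts, time in seconds, concentrations in mM, currents in A/F; gate rate
// expressions use millivolts (u = 1000*V) as in the source models.
//
// I_NaL: one activation gate (mL) and one slow inactivation gate (hL) in
// Hodgkin-Huxley form (O'Hara-Rudy lineage steady states, tau_hL = 200 ms).
// The V1763M gain-of-function variant scales g_NaL and depolarises the hL
// steady-state curve; both knobs are model parameters calibrated in R.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---- state layout ----------------------------------------------------------
enum StateIx { iV = 0, im, ih, ij, id, if1, if2, ifCa, iXr1, iXr2, iXs, iXf,
               iq, ir, igG, imL, ihL, iNai, iCai, iCaSR, NSTATE };
// gates are states im..ihL (14 of them), updated by Rush-Larsen
static const int GATE0 = im, GATE1 = ihL;

// ---- parameter layout ------------------------------------------------------
enum ParIx { pgNa = 0, pgNaL, pPCaL, pgKr, pgKs, pgK1, pgf, pgto, pkNCX,
             ppNaK, pgpCa, pMutScale, pMutShift, pMutTauF, pGeno, NPARAM };
// blocks: 0 = I_Na, 1 = I_NaL, 2 = I_Kr, 3 = I_CaL

enum CurIx { cNa = 0, cNaL, cCaL, cKr, cKs, cK1, cf, cto, cNCX, cNaK, cpCa,
             cbNa, cbCa, NCUR };

// ---- fixed physical constants (Paci 2013 ventricular) ----------------------
static const double F     = 96485.3415;   // C/mol
static const double Rgas  = 8.314472;     // J/(mol K)
static const double T     = 310.0;        // K
static const double Cm    = 9.87109e-11;  // F
static const double Vc    = 8800.0;       // um^3, cytosol
static const double VSR   = 583.73;       // um^3, SR
static const double Nao   = 151.0;        // mM
static const double Ko    = 5.4;          // mM
static const double Cao   = 1.8;          // mM
static const double Ki    = 150.0;        // mM (fixed)
static const double g_b_Na = 0.9;         // S/F
static const double g_b_Ca = 0.69264;     // S/F
static const double VmaxUp = 0.56064;     // mM/s
static const double Kup    = 2.5e-4;      // mM
static const double V_leak = 4.4444e-4;   // 1/s
static const double a_rel  = 16.464;      // mM/s
static const double b_rel  = 0.25;        // mM
static const double c_rel  = 8.232;       // mM/s
static const double Buf_C  = 0.25,  Kbuf_C  = 0.001; // cytosolic Ca buffer, mM
static const double Buf_SR = 10.0,  Kbuf_SR = 0.3;   // SR Ca buffer, mM
static const double KmCa = 1.38, KmNai = 87.5, Ksat = 0.1;
static const double gamma_ncx = 0.35, alpha_ncx = 2.8571432;
static const double Km_K = 1.0, Km_Na = 40.0;  // NaK pump
static const double KPCa = 0.0005;             // mM
static const double PkNa = 0.03;
static const double E_f  = -0.017;             // V, funny-current reversal
static const double tau_hL = 0.200;            // s, I_NaL slow inactivation

struct RhsOut {
  double dy[NSTATE];
  double inf[NSTATE];   // gate steady states (gate slots only)
  double tau[NSTATE];   // gate time constants, s; tau<=0 means frozen gate
  double cur[NCUR];
};

static inline double sq(double x) { return x * x; }

// Right-hand side + Rush-Larsen gate info + currents.
static void rhs(const double *y, const double *p, const double *blk,
                RhsOut &o) {
  const double V = y[iV];           // volts
  const double u = 1000.0 * V;      // mV, for rate expressions
  const double RTF = Rgas * T / F;  // ~0.02671 V

  const double Nai = y[iNai], Cai = y[iCai], CaSR = y[iCaSR];

  const double E_Na = RTF * std::log(Nao / Nai);
  const double E_K  = RTF * std::log(Ko / Ki);
  const double E_Ks = RTF * std::log((Ko + PkNa * Nao) / (Ki + PkNa * Nai));
  const double E_Ca = 0.5 * RTF * std::log(Cao / Cai);

  // ---- I_Na (m^3 h j), ten Tusscher/Luo-Rudy lineage ----
  const double INa = blk[0] * p[pgNa] * y[im]*y[im]*y[im] * y[ih] * y[ij] *
                     (V - E_Na);
  const double m_inf = std::pow(1.0 / (1.0 + std::exp((-u - 34.1) / 5.9)),
                                1.0 / 3.0);
  const double alpha_m = 1.0 / (1.0 + std::exp((-u - 60.0) / 5.0));
  const double beta_m  = 0.1 / (1.0 + std::exp((u + 35.0) / 5.0)) +
                         0.1 / (1.0 + std::exp((u - 50.0) / 200.0));
  const double taum = alpha_m * beta_m / 1000.0;

  const double h_inf = 1.0 / std::sqrt(1.0 + std::exp((u + 72.1) / 5.7));
  double tauh;
  if (u < -40.0) {
    const double ah = 0.057 * std::exp(-(u + 80.0) / 6.8);
    const double bh = 2.7 * std::exp(0.079 * u) +
                      3.1e5 * std::exp(0.3485 * u);
    tauh = 1.5 / ((ah + bh) * 1000.0);
  } else {
    const double bh = 0.77 / (0.13 * (1.0 + std::exp((u + 10.66) / -11.1)));
    tauh = 1.5 / (bh * 1000.0);
  }

  const double j_inf = h_inf;
  double tauj;
  if (u < -40.0) {
    const double aj = (-25428.0 * std::exp(0.2444 * u) -
                       6.948e-6 * std::exp(-0.04391 * u)) * (u + 37.78) /
                      (1.0 + std::exp(0.311 * (u + 79.23)));
    const double bj = 0.02424 * std::exp(-0.01052 * u) /
                      (1.0 + std::exp(-0.1378 * (u + 40.14)));
    tauj = 7.0 / ((aj + bj) * 1000.0);
  } else {
    const double bj = 0.6 * std::exp(0.057 * u) /
                      (1.0 + std::exp(-0.1 * (u + 32.0)));
    tauj = 7.0 / (bj * 1000.0);
  }

  // ---- I_NaL (mL * hL), O'Hara-Rudy lineage gates ----
  const bool mut = p[pGeno] > 0.5;
  const double gNaL_eff = p[pgNaL] * (mut ? p[pMutScale] : 1.0);
  const double hshift   = mut ? p[pMutShift] : 0.0;  // mV, depolarising > 0
  const double tauhL_eff = tau_hL * (mut ? p[pMutTauF] : 1.0);
  const double INaL = blk[1] * gNaL_eff * y[imL] * y[ihL] * (V - E_Na);
  const double mL_inf = 1.0 / (1.0 + std::exp(-(u + 42.85) / 5.264));
  const double hL_inf = 1.0 / (1.0 + std::exp((u + 87.61 - hshift) / 7.488));

  // ---- I_CaL, GHK flux with d f1 f2 fCa gates ----
  const double x = 2.0 * V / RTF;  // 2VF/RT
  double ghk;
  if (std::fabs(x) < 1e-7) {
    ghk = 2.0 * F * (Cai - 0.341 * Cao);  // limit V -> 0
  } else {
    ghk = 4.0 * V * F * F / (Rgas * T) *
          (Cai * std::exp(x) - 0.341 * Cao) / (std::exp(x) - 1.0);
  }
  const double ICaL = blk[3] * p[pPCaL] * ghk *
                      y[id] * y[if1] * y[if2] * y[ifCa];

  const double d_inf = 1.0 / (1.0 + std::exp(-(u + 9.1) / 7.0));
  const double ad = 0.25 + 1.4 / (1.0 + std::exp((-u - 35.0) / 13.0));
  const double bd = 1.4 / (1.0 + std::exp((u + 5.0) / 5.0));
  const double gd = 1.0 / (1.0 + std::exp((-u + 50.0) / 20.0));
  const double taud = (ad * bd + gd) / 1000.0;

  const double f1_inf = 1.0 / (1.0 + std::exp((u + 26.0) / 3.0));
  const double constf1 = (f1_inf - y[if1] > 0.0)
                             ? 1.0 + 1433.0 * (Cai - 50.0e-6) : 1.0;
  const double tauf1 = (20.0 +
      1102.5 * std::exp(-sq(sq((u + 27.0)) / 15.0)) +
      200.0 / (1.0 + std::exp((13.0 - u) / 10.0)) +
      180.0 / (1.0 + std::exp((30.0 + u) / 10.0))) *
      std::max(constf1, 1.0) / 1000.0;

  const double f2_inf = 0.33 + 0.67 / (1.0 + std::exp((u + 32.0) / 4.0));
  const double tauf2 = (600.0 * std::exp(-sq(u + 25.0) / 170.0) +
                        31.0 / (1.0 + std::exp((25.0 - u) / 10.0)) +
                        16.0 / (1.0 + std::exp((30.0 + u) / 10.0))) / 1000.0;

  const double afca = 1.0 / (1.0 + std::pow(Cai / 0.0006, 8.0));
  const double bfca = 0.1 / (1.0 + std::exp((Cai - 0.0009) / 0.0001));
  const double gfca = 0.3 / (1.0 + std::exp((Cai - 0.00075) / 0.0008));
  const double fCa_inf = (afca + bfca + gfca) / 1.3156;
  const bool fca_frozen = (V > -0.06) && (fCa_inf > y[ifCa]);
  const double taufCa = 0.002;  // s

  // ---- I_Kr (Xr1 Xr2), Ca_o-dependent activation midpoint ----
  const double IKr = blk[2] * p[pgKr] * std::sqrt(Ko / 5.4) *
                     y[iXr1] * y[iXr2] * (V - E_K);
  const double L0 = 0.025, Qkr = 2.3;
  const double Vhalf = 1000.0 * (-RTF / Qkr *
      std::log(std::pow(1.0 + Cao / 2.6, 4.0) /
               (L0 * std::pow(1.0 + Cao / 0.58, 4.0))) - 0.019);
  const double Xr1_inf = 1.0 / (1.0 + std::exp((Vhalf - u) / 4.9));
  const double aXr1 = 450.0 / (1.0 + std::exp((-45.0 - u) / 10.0));
  const double bXr1 = 6.0 / (1.0 + std::exp((30.0 + u) / 11.5));
  const double tauXr1 = aXr1 * bXr1 / 1e6;  // (ms*ms scale) -> s
  const double Xr2_inf = 1.0 / (1.0 + std::exp((u + 88.0) / 50.0));
  const double aXr2 = 3.0 / (1.0 + std::exp((-60.0 - u) / 20.0));
  const double bXr2 = 1.12 / (1.0 + std::exp((-60.0 + u) / 20.0));
  const double tauXr2 = aXr2 * bXr2 / 1000.0;

  // ---- I_Ks (Xs^2), Ca-sensitised ----
  const double IKs = p[pgKs] * sq(y[iXs]) * (V - E_Ks) *
                     (1.0 + 0.6 / (1.0 + std::pow(3.8e-5 / Cai, 1.4)));
  const double Xs_inf = 1.0 / (1.0 + std::exp((-u - 20.0) / 16.0));
  const double aXs = 1100.0 / std::sqrt(1.0 + std::exp((-10.0 - u) / 6.0));
  const double bXs = 1.0 / (1.0 + std::exp((-60.0 + u) / 20.0));
  const double tauXs = aXs * bXs / 1e6;

  // ---- I_K1, instantaneous rectifier ----
  const double du = u - 1000.0 * E_K;
  const double aK1 = 3.91 / (1.0 + std::exp(0.5942 * (du - 200.0)));
  const double bK1 = (-1.509 * std::exp(0.0002 * (du + 100.0)) +
                      std::exp(0.5886 * (du - 10.0))) /
                     (1.0 + std::exp(0.4547 * du));
  const double xK1 = aK1 / (aK1 + bK1);
  const double IK1 = p[pgK1] * xK1 * std::sqrt(Ko / 5.4) * (V - E_K);

  // ---- I_f, funny current ----
  const double If = p[pgf] * y[iXf] * (V - E_f);
  const double Xf_inf = 1.0 / (1.0 + std::exp((u + 77.85) / 5.0));
  const double tauXf = 1.9 / (1.0 + std::exp((u + 15.0) / 10.0));  // s

  // ---- I_to (q r) ----
  const double Ito = p[pgto] * y[iq] * y[ir] * (V - E_K);
  const double q_inf = 1.0 / (1.0 + std::exp((u + 53.0) / 13.0));
  const double tauq = (6.06 + 39.102 /
      (0.57 * std::exp(-0.08 * (u + 44.0)) +
       0.065 * std::exp(0.1 * (u + 45.93)))) / 1000.0;
  const double r_inf = 1.0 / (1.0 + std::exp(-(u - 22.3) / 18.75));
  const double taur = (2.75352 + 14.40516 /
      (1.037 * std::exp(0.09 * (u + 30.61)) +
       0.369 * std::exp(-0.12 * (u + 23.84)))) / 1000.0;

  // ---- pumps and exchangers ----
  const double INaK = p[ppNaK] * Ko / (Ko + Km_K) * Nai / (Nai + Km_Na) /
      (1.0 + 0.1245 * std::exp(-0.1 * V / RTF) +
       0.0353 * std::exp(-V / RTF));
  const double INCX = p[pkNCX] *
      (std::exp(gamma_ncx * V / RTF) * Nai * Nai * Nai * Cao -
       std::exp((gamma_ncx - 1.0) * V / RTF) * Nao * Nao * Nao * Cai *
           alpha_ncx) /
      ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
       (1.0 + Ksat * std::exp((gamma_ncx - 1.0) * V / RTF)));
  const double IpCa = p[pgpCa] * Cai / (Cai + KPCa);
  const double IbNa = g_b_Na * (V - E_Na);
  const double IbCa = g_b_Ca * (V - E_Ca);

  // ---- SR calcium handling ----
  const double Iup   = VmaxUp / (1.0 + sq(Kup) / sq(Cai));
  const double Ileak = (CaSR - Cai) * V_leak;
  const double Irel  = (c_rel + a_rel * sq(CaSR) / (sq(b_rel) + sq(CaSR))) *
                       y[id] * y[igG];
  double g_inf;
  if (Cai <= 0.00035)
    g_inf = 1.0 / (1.0 + std::pow(Cai / 0.00035, 6.0));
  else
    g_inf = 1.0 / (1.0 + std::pow(Cai / 0.00035, 16.0));
  const bool g_frozen = (g_inf > y[igG]) && (V > -0.06);
  const double taug = 0.002;  // s

  // ---- assemble ----
  o.cur[cNa] = INa;   o.cur[cNaL] = INaL; o.cur[cCaL] = ICaL;
  o.cur[cKr] = IKr;   o.cur[cKs]  = IKs;  o.cur[cK1]  = IK1;
  o.cur[cf]  = If;    o.cur[cto]  = Ito;  o.cur[cNCX] = INCX;
  o.cur[cNaK] = INaK; o.cur[cpCa] = IpCa;
  o.cur[cbNa] = IbNa; o.cur[cbCa] = IbCa;

  double Isum = 0.0;
  for (int k = 0; k < NCUR; ++k) Isum += o.cur[k];
  o.dy[iV] = -Isum;  // V/s (currents are A/F)

  for (int k = 0; k < NSTATE; ++k) { o.inf[k] = 0.0; o.tau[k] = -1.0; }
  o.inf[im] = m_inf;   o.tau[im] = taum;
  o.inf[ih] = h_inf;   o.tau[ih] = tauh;
  o.inf[ij] = j_inf;   o.tau[ij] = tauj;
  o.inf[id] = d_inf;   o.tau[id] = taud;
  o.inf[if1] = f1_inf; o.tau[if1] = tauf1;
  o.inf[if2] = f2_inf; o.tau[if2] = tauf2;
  o.inf[ifCa] = fCa_inf; o.tau[ifCa] = fca_frozen ? -1.0 : taufCa;
  o.inf[iXr1] = Xr1_inf; o.tau[iXr1] = tauXr1;
  o.inf[iXr2] = Xr2_inf; o.tau[iXr2] = tauXr2;
  o.inf[iXs] = Xs_inf;   o.tau[iXs] = tauXs;
  o.inf[iXf] = Xf_inf;   o.tau[iXf] = tauXf;
  o.inf[iq] = q_inf;     o.tau[iq] = tauq;
  o.inf[ir] = r_inf;     o.tau[ir] = taur;
  o.inf[igG] = g_inf;    o.tau[igG] = g_frozen ? -1.0 : taug;
  o.inf[imL] = mL_inf;   o.tau[imL] = taum;    // shares I_Na activation tau
  o.inf[ihL] = hL_inf;   o.tau[ihL] = tauhL_eff;

  // gate derivatives (reported for diagnostics; RL update does not use them)
  for (int k = GATE0; k <= GATE1; ++k)
    o.dy[k] = (o.tau[k] > 0.0) ? (o.inf[k] - y[k]) / o.tau[k] : 0.0;

  // ---- ion concentration balances ----
  const double conv = Cm / (Vc * 1e-18 * F);  // (A/F) -> mM/s
  o.dy[iNai] = -conv * (INa + INaL + IbNa + 3.0 * INaK + 3.0 * INCX);
  const double bufc = 1.0 / (1.0 + Buf_C * Kbuf_C / sq(Cai + Kbuf_C));
  const double bufsr = 1.0 / (1.0 + Buf_SR * Kbuf_SR / sq(CaSR + Kbuf_SR));
  o.dy[iCai] = bufc * (Ileak - Iup + Irel -
                       (ICaL + IbCa + IpCa - 2.0 * INCX) * conv / 2.0);
  o.dy[iCaSR] = bufsr * Vc / VSR * (Iup - (Irel + Ileak));
}

// one Rush-Larsen + forward-Euler step of size dt (y -> ynew)
static void rl_step(const double *y, const double *p, const double *blk,
                    double dt, double *ynew) {
  RhsOut o;
  rhs(y, p, blk, o);
  for (int k = 0; k < NSTATE; ++k) {
    if (k >= GATE0 && k <= GATE1) {
      if (o.tau[k] > 0.0)
        ynew[k] = o.inf[k] + (y[k] - o.inf[k]) * std::exp(-dt / o.tau[k]);
      else
        ynew[k] = y[k];  // frozen gate
    } else {
      ynew[k] = y[k] + dt * o.dy[k];
    }
  }
}

static inline void clamp_state(double *y) {
  for (int k = GATE0; k <= GATE1; ++k) {
    if (y[k] < 0.0) y[k] = 0.0;
    if (y[k] > 1.0) y[k] = 1.0;
  }
  if (y[iCai] < 1e-9) y[iCai] = 1e-9;
  if (y[iCaSR] < 1e-9) y[iCaSR] = 1e-9;
  if (y[iNai] < 1e-3) y[iNai] = 1e-3;
}

// typical magnitudes for the absolute error weights
static const double TYP[NSTATE] = {
  0.1,                                  // V (volts)
  1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1,  // gates
  10.0,   // Nai
  1e-4,   // Cai
  0.3     // CaSR
};

// [[Rcpp::export(name = ".integrate_model")]]
List integrate_model(NumericVector y0, NumericVector params,
                     NumericVector blocks, double t_end,
                     double record_from, double dt_out,
                     double rtol, double atol, double max_step,
                     bool record_currents) {
  if (y0.size() != NSTATE) stop("state vector must have %d entries", NSTATE);
  if (params.size() != NPARAM) stop("parameter vector must have %d entries",
                                    NPARAM);
  if (blocks.size() != 4) stop("block vector must have 4 entries");
  for (int k = 0; k < NSTATE; ++k)
    if (!std::isfinite(y0[k])) stop("non-finite initial state");

  const double min_step = 1e-10;
  double y[NSTATE], y1[NSTATE], yh[NSTATE], y2[NSTATE];
  double p[NPARAM], blk[4];
  for (int k = 0; k < NSTATE; ++k) y[k] = y0[k];
  for (int k = 0; k < NPARAM; ++k) p[k] = params[k];
  for (int k = 0; k < 4; ++k) blk[k] = blocks[k];

  std::vector<double> rec_t, rec_v, rec_dvdt, rec_inal;
  std::vector<double> rec_cur;  // row-major NCUR per record if requested
  long n_out = 0;
  if (t_end >= record_from && dt_out > 0)
    n_out = (long)std::floor((t_end - record_from) / dt_out) + 1;
  rec_t.reserve(n_out > 0 ? n_out : 0);

  int status = 0;  // 0 ok, 1 nonfinite/step collapse
  double t = 0.0, dt = 1e-5;
  long nsteps = 0, nreject = 0;
  long next_rec = 0;  // index of next output point

  auto record = [&](double tt, const double *yy) {
    RhsOut o;
    rhs(yy, p, blk, o);
    rec_t.push_back(tt);
    rec_v.push_back(1000.0 * yy[iV]);
    rec_dvdt.push_back(o.dy[iV]);
    rec_inal.push_back(o.cur[cNaL]);
    if (record_currents)
      for (int k = 0; k < NCUR; ++k) rec_cur.push_back(o.cur[k]);
  };

  // record t = record_from == 0 case before stepping
  if (n_out > 0 && record_from <= 0.0) { record(0.0, y); next_rec = 1; }

  while (t < t_end - 1e-12 && status == 0) {
    if (dt > max_step) dt = max_step;
    // do not step past t_end or the next output time
    double t_target = t_end;
    if (next_rec < n_out) {
      double t_next_out = record_from + next_rec * dt_out;
      if (t_next_out < t_target) t_target = t_next_out;
    }
    bool hit = false;
    if (t + dt >= t_target - 1e-12) { dt = t_target - t; hit = true; }
    if (hit && dt < min_step) {
      // target closer than the minimum step: snap to it without integrating
      t = t_target;
      if (next_rec < n_out &&
          std::fabs(t - (record_from + next_rec * dt_out)) < 1e-9) {
        record(t, y);
        ++next_rec;
      }
      dt = max_step;
      continue;
    }
    if (dt < min_step) { status = 1; break; }

    // full step and two half steps
    rl_step(y, p, blk, dt, y1);
    rl_step(y, p, blk, 0.5 * dt, yh);
    clamp_state(yh);
    rl_step(yh, p, blk, 0.5 * dt, y2);

    double err = 0.0;
    bool finite = true;
    for (int k = 0; k < NSTATE; ++k) {
      if (!std::isfinite(y1[k]) || !std::isfinite(y2[k])) { finite = false; break; }
      double sc = atol * TYP[k] + rtol * std::max(std::fabs(y1[k]),
                                                  std::fabs(y2[k]));
      double e = (y2[k] - y1[k]) / sc;
      err += e * e;
    }
    err = std::sqrt(err / NSTATE);

    if (!finite) {
      dt *= 0.25;
      ++nreject;
      if (dt < min_step) { status = 1; break; }
      continue;
    }
    if (err > 1.0) {
      dt *= std::max(0.2, 0.9 * std::pow(err, -0.5));
      ++nreject;
      continue;
    }

    // accept: local extrapolation (2nd order), clamp to physical ranges
    for (int k = 0; k < NSTATE; ++k) y[k] = 2.0 * y2[k] - y1[k];
    clamp_state(y);
    t += dt;
    ++nsteps;
    if (hit && next_rec < n_out &&
        std::fabs(t - (record_from + next_rec * dt_out)) < 1e-9) {
      record(t, y);
      ++next_rec;
    }
    double fac = (err > 1e-12) ? 0.9 * std::pow(err, -0.5) : 2.0;
    dt *= std::min(2.0, std::max(0.2, fac));
    if (nsteps % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector fin(NSTATE);
  for (int k = 0; k < NSTATE; ++k) fin[k] = y[k];

  List out = List::create(
      _["time"] = wrap(rec_t), _["Vm"] = wrap(rec_v),
      _["dVdt"] = wrap(rec_dvdt), _["INaL"] = wrap(rec_inal),
      _["final_state"] = fin, _["status"] = status,
      _["n_steps"] = (double)nsteps, _["n_reject"] = (double)nreject,
      _["t_reached"] = t);
  if (record_currents) {
    NumericMatrix cm(NCUR, (int)rec_t.size());
    for (size_t i = 0; i < rec_cur.size(); ++i) cm[i] = rec_cur[i];
    out["currents"] = cm;  // NCUR x n, filled column-wise
  }
  return out;
}

// [[Rcpp::export(name = ".model_rhs")]]
List model_rhs(NumericVector y, NumericVector params, NumericVector blocks) {
  if (y.size() != NSTATE) stop("state vector must have %d entries", NSTATE);
  if (params.size() != NPARAM) stop("parameter vector must have %d entries",
                                    NPARAM);
  for (int k = 0; k < NSTATE; ++k)
    if (!std::isfinite(y[k]))
      stop("non-finite state: numerical breakdown");
  double yy[NSTATE], p[NPARAM], blk[4];
  for (int k = 0; k < NSTATE; ++k) yy[k] = y[k];
  for (int k = 0; k < NPARAM; ++k) p[k] = params[k];
  for (int k = 0; k < 4; ++k) blk[k] = blocks[k];
  RhsOut o;
  rhs(yy, p, blk, o);
  NumericVector dy(NSTATE), inf(NSTATE), tau(NSTATE), cur(NCUR);
  for (int k = 0; k < NSTATE; ++k) {
    dy[k] = o.dy[k]; inf[k] = o.inf[k]; tau[k] = o.tau[k];
  }
  for (int k = 0; k < NCUR; ++k) cur[k] = o.cur[k];
  return List::create(_["dydt"] = dy, _["currents"] = cur,
                      _["gate_inf"] = inf, _["gate_tau"] = tau);
}
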