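// Fixed-step RK4 integration of the trichome day model.
//
// The rate laws here mirror the exported R functions (pet_rate, rp_rate,
// close_energy_budget, fe_pool_tendencies, ...) one-to-one; the test suite
// cross-checks this path against an R-side stepper built from those
// functions. Daily integrals (gross C fixation, N2 fixation, RP, RESP, O2
// production and exchange) are carried as additional RK4 states so the O2
// budget closes to integrator precision.

#include <Rcpp.h>
using namespace Rcpp;

struct Pars {
  double vPETmax, kFePS, alpha_I, beta;
  double kFeNF, kO2NF, N_max, kCS;
  double e_per_O2, nL, aL, aA, aC, nC, aN, nN, m, aRESP;
  double vRPmax, kO2RP;
  double vCSmax, kCH2O, kCSi;
  double kappa_O2, rho_C;
  double TPSmaxBF, kFePS_syn, TBFmaxPS, kFePS_dec, TNFmaxBF, kFeBF_syn,
         TNFmaxNA;
  double lim_CH2O, lim_O2, lim_FeBF;
};

static inline double getp(const NumericVector& p, const char* nm) {
  return as<double>(p[nm]);
}

static Pars load_pars(const NumericVector& p) {
  Pars q;
  q.vPETmax = getp(p, "vPETmax"); q.kFePS = getp(p, "kFePS");
  q.alpha_I = getp(p, "alpha_I"); q.beta = getp(p, "beta");
  q.kFeNF = getp(p, "kFeNF"); q.kO2NF = getp(p, "kO2NF");
  q.N_max = getp(p, "N_max"); q.kCS = getp(p, "kCS");
  q.e_per_O2 = getp(p, "e_per_O2"); q.nL = getp(p, "nadph_per_e_LPET");
  q.aL = getp(p, "atp_per_e_LPET"); q.aA = getp(p, "atp_per_e_AET");
  q.aC = getp(p, "atp_per_C_CF"); q.nC = getp(p, "nadph_per_C_CF");
  q.aN = getp(p, "atp_per_N_NF"); q.nN = getp(p, "nadph_per_N_NF");
  q.m = getp(p, "atp_maintenance"); q.aRESP = getp(p, "atp_per_C_RESP");
  q.vRPmax = getp(p, "vRPmax"); q.kO2RP = getp(p, "kO2RP");
  q.vCSmax = getp(p, "vCSmax"); q.kCH2O = getp(p, "kCH2O");
  q.kCSi = getp(p, "kCSi");
  q.kappa_O2 = getp(p, "kappa_O2"); q.rho_C = getp(p, "rho_C");
  q.TPSmaxBF = getp(p, "TPSmaxBF"); q.kFePS_syn = getp(p, "kFePS_syn");
  q.TBFmaxPS = getp(p, "TBFmaxPS"); q.kFePS_dec = getp(p, "kFePS_dec");
  q.TNFmaxBF = getp(p, "TNFmaxBF"); q.kFeBF_syn = getp(p, "kFeBF_syn");
  q.TNFmaxNA = getp(p, "TNFmaxNA");
  q.lim_CH2O = getp(p, "lim_CH2O"); q.lim_O2 = getp(p, "lim_O2");
  q.lim_FeBF = getp(p, "lim_FeBF");
  return q;
}

static inline double pos(double x) { return x > 0.0 ? x : 0.0; }
static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}
static inline double srclim(double pool, double k) {
  pool = pos(pool);
  return pool / (pool + k);
}

// state layout: 0 CH2O, 1 CS, 2 N, 3 O2, 4 FePS, 5 FeBF, 6 FeNFa, 7 FeNFi,
// integrals: 8 CF, 9 NF, 10 RP, 11 RESP, 12 O2prod (mol O2 (mol C)-1),
// 13 O2 exchange (mol m-3)
#define NSTATE 14
#define NFLUX 16

static void deriv(double t, const double* y, double* dy, double* flux,
                  const Pars& q, double I, double O2amb,
                  bool dynamic, bool recycle) {
  const double CH2O = pos(y[0]), CS = pos(y[1]), N = pos(y[2]),
               O2 = pos(y[3]), FePS = pos(y[4]), FeBF = pos(y[5]),
               FeNFa = pos(y[6]);

  const double lightf = 1.0 - std::exp(-q.alpha_I * I);
  const double Ncl = N > q.N_max ? q.N_max : N;
  const double Phi = lightf * CS / (CS + q.kCS) * (q.N_max - Ncl) / q.N_max;

  const double V_RP = q.vRPmax * Phi * q.kO2RP / (O2 + q.kO2RP) *
                      srclim(CH2O, q.lim_CH2O) * srclim(O2, q.lim_O2);
  const double V_PET = q.vPETmax * FePS / (FePS + q.kFePS) * lightf *
                       std::exp(-q.beta * V_RP);

  // energy budget closure (see close_energy_budget in R)
  double x = 0.0, V_NFmax = 0.0, V_NF = 0.0, V_CF = 0.0, V_RESP = 0.0;
  const double dNF = q.aA - q.aL + q.nL * q.aN / q.nN;
  const double dCF = q.aA - q.aL + q.nL * q.aC / q.nC;
  const double atp_max = V_PET * q.aA;
  if (atp_max <= q.m || V_PET <= 0.0) {
    V_RESP = (q.m - pos(atp_max)) / q.aRESP *
             srclim(CH2O, q.lim_CH2O) * srclim(O2, q.lim_O2);
  } else {
    double x1 = (V_PET * q.aA - q.m) / (V_PET * dNF);
    if (x1 > 1.0) x1 = 1.0;
    V_NFmax = V_PET * x1 * q.nL / q.nN;
    const double capN = clamp01((q.N_max - N) / (0.02 * q.N_max));
    V_NF = V_NFmax * FeNFa / (FeNFa + q.kFeNF) *
           (1.0 - O2 / (O2 + q.kO2NF)) * capN;
    x = clamp01((V_PET * q.aA - q.m - V_NF * (q.aN - q.nN * q.aC / q.nC)) /
                (V_PET * dCF));
    V_CF = pos((V_PET * x * q.nL - V_NF * q.nN) / q.nC);
  }

  const double V_CS = q.vCSmax * CH2O / (CH2O + q.kCH2O) *
                      q.kCSi / (CS + q.kCSi);

  // iron translocation
  double syn_ps = 0.0, dec_ps = 0.0, syn_nf = 0.0;
  if (dynamic) {
    syn_ps = q.TPSmaxBF * lightf * (1.0 - FePS / (FePS + q.kFePS_syn)) *
             srclim(FeBF, q.lim_FeBF);
    dec_ps = q.TBFmaxPS * FePS / (FePS + q.kFePS_dec) *
             std::exp(-q.beta * V_RP);
    syn_nf = q.TNFmaxBF * Phi * FeBF / (FeBF + q.kFeBF_syn);
  }
  const double inact = q.TNFmaxNA * FeNFa / (FeNFa + q.kFeNF) *
                       O2 / (O2 + q.kO2NF);

  const double o2prod = x * V_PET / q.e_per_O2;     // mol O2 (mol C)-1 s-1
  const double o2exch = q.kappa_O2 * (O2amb - O2);  // mol m-3 s-1

  dy[0] = V_CF - V_CS - V_RP - V_RESP;
  dy[1] = V_CS;
  dy[2] = V_NF;
  dy[3] = q.rho_C * (o2prod - V_RP - V_RESP) + o2exch;
  dy[4] = syn_ps - dec_ps;
  dy[5] = dec_ps - syn_ps - syn_nf + (recycle ? inact : 0.0);
  dy[6] = syn_nf - inact;
  dy[7] = recycle ? 0.0 : inact;
  dy[8] = V_CF; dy[9] = V_NF; dy[10] = V_RP; dy[11] = V_RESP;
  dy[12] = o2prod; dy[13] = o2exch;

  if (flux) {
    flux[0] = V_PET; flux[1] = x; flux[2] = V_NFmax; flux[3] = V_NF;
    flux[4] = V_CF; flux[5] = V_RP; flux[6] = V_RESP; flux[7] = V_CS;
    flux[8] = Phi; flux[9] = syn_ps; flux[10] = dec_ps; flux[11] = syn_nf;
    flux[12] = inact; flux[13] = o2prod; flux[14] = o2exch;
    flux[15] = I;
  }
}

static inline double light_of(double t, bool sinus, double Iamp,
                              double day_length) {
  if (!sinus) return Iamp;
  double v = Iamp * std::sin(M_PI * t / day_length);
  return v > 0.0 ? v : 0.0;
}

// [[Rcpp::export(name = ".simulate_day_cpp")]]
List simulate_day_cpp(NumericVector y0, NumericVector params,
                      bool sinusoidal, double I_amp, double day_length,
                      double O2_ambient, bool dynamic, bool recycle,
                      double dt, int save_every) {
  if (y0.size() != 8) stop("y0 must have 8 elements");
  const Pars q = load_pars(params);
  const int nstep = (int)std::lround(day_length / dt);
  if (std::abs(nstep * dt - day_length) > 1e-6 * day_length)
    stop("dt must divide day_length");

  double y[NSTATE], k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE],
         yt[NSTATE], flux[NFLUX];
  for (int i = 0; i < 8; ++i) y[i] = y0[i];
  for (int i = 8; i < NSTATE; ++i) y[i] = 0.0;

  const int nsave = nstep / save_every + 1;
  NumericMatrix out(nsave, 1 + NSTATE + NFLUX);
  int row = 0;

  for (int s = 0; s <= nstep; ++s) {
    const double t = s * dt;
    const double I = light_of(t, sinusoidal, I_amp, day_length);
    if (s % save_every == 0) {
      deriv(t, y, k1, flux, q, I, O2_ambient, dynamic, recycle);
      out(row, 0) = t;
      for (int i = 0; i < NSTATE; ++i) out(row, 1 + i) = y[i];
      for (int i = 0; i < NFLUX; ++i) out(row, 1 + NSTATE + i) = flux[i];
      ++row;
    }
    if (s == nstep) break;

    deriv(t, y, k1, nullptr, q, I, O2_ambient, dynamic, recycle);
    for (int i = 0; i < NSTATE; ++i) yt[i] = y[i] + 0.5 * dt * k1[i];
    double Ih = light_of(t + 0.5 * dt, sinusoidal, I_amp, day_length);
    deriv(t, yt, k2, nullptr, q, Ih, O2_ambient, dynamic, recycle);
    for (int i = 0; i < NSTATE; ++i) yt[i] = y[i] + 0.5 * dt * k2[i];
    deriv(t, yt, k3, nullptr, q, Ih, O2_ambient, dynamic, recycle);
    for (int i = 0; i < NSTATE; ++i) yt[i] = y[i] + dt * k3[i];
    double I1 = light_of(t + dt, sinusoidal, I_amp, day_length);
    deriv(t, yt, k4, nullptr, q, I1, O2_ambient, dynamic, recycle);
    for (int i = 0; i < NSTATE; ++i) {
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      if (!R_finite(y[i]))
        stop("non-finite state (component %d) at step %d", i + 1, s + 1);
    }
    // numerical floor: rate laws already vanish with their source pools,
    // so any undershoot is an O(dt^5) residual
    for (int i = 0; i < 8; ++i) if (y[i] < 0.0) y[i] = 0.0;
  }

  NumericVector yT(NSTATE);
  for (int i = 0; i < NSTATE; ++i) yT[i] = y[i];
  return List::create(_["trace"] = out, _["final"] = yT);
}
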