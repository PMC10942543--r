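// Euler-Maruyama integrators for the single-cell myocyte model and the 1D
// gap-junction-coupled vessel. The right-hand side mirrors the R reference
// implementation (compute_currents/derivatives); a unit test asserts
// agreement to near machine precision.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <map>
#include <string>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-based RNG: splitmix64 streams + Box-Muller normal pairs.
// Substream s of master seed m is seeded with splitmix64 scrambles of
// (m, s); each step consumes one uniform pair -> one normal pair.
// ---------------------------------------------------------------------------
struct SplitMix {
  uint64_t state;
  explicit SplitMix(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double uniform() { // in (0, 1]
    return (next() >> 11) * (1.0 / 9007199254740992.0) +
           (0.5 / 9007199254740992.0);
  }
  void normal_pair(double* z1, double* z2) {
    double u1 = uniform(), u2 = uniform();
    double r = std::sqrt(-2.0 * std::log(u1));
    *z1 = r * std::cos(2.0 * M_PI * u2);
    *z2 = r * std::sin(2.0 * M_PI * u2);
  }
};

static SplitMix make_stream(uint64_t master, uint64_t stream) {
  SplitMix seeder(master * 0x9E3779B97F4A7C15ULL + 0x853C49E6748FEA9BULL);
  uint64_t a = seeder.next();
  SplitMix mix(a ^ (stream * 0xD1342543DE82EF95ULL + 0x2545F4914F6CDD1DULL));
  mix.next(); // burn-in
  return mix;
}

// ---------------------------------------------------------------------------
// Parameters
// ---------------------------------------------------------------------------
struct Rates5 { double x1, x2, x3, x4, x5; };

struct Params {
  double F, R, T;
  double Na_out, K_out, Ca_out;
  double Vol_cyt, Vol_SR, Vol_Jun, C_m;
  double P_Ca, G_Kv21, G_Kv15, P_BKCa, N_BK;
  double G_NaNSC, G_KNSC, G_Nab, G_Kb, G_Cab;
  double I_NaKmax, Km_NaK_K, Km_NaK_Na, Q10;
  double P_NCX, gamma_x, k_sat_NCX;
  double I_PMCAbar, Km_PMCA;
  double bk_vh0, bk_slope_ca, bk_k, bk_tau_scale, bk_tau_floor;
  Rates5 dL, dF, kv21, kv15;
  double serca_vmax, serca_km;
  double ryr_nu_rel, ryr_nu_leak, ryr_thr, ryr_k, ryr_kjun, ryr_hill, ryr_tau;
  double k_JunCyt;
  double k_BUFon, k_BUFoff, BUF_T;
  bool clamp_ions;
  double rtf; // RT/F in mV
};

static Rates5 get_rates(const std::map<std::string, double>& m,
                        const std::string& pre) {
  Rates5 r;
  r.x1 = m.at(pre + ".x1"); r.x2 = m.at(pre + ".x2");
  r.x3 = m.at(pre + ".x3"); r.x4 = m.at(pre + ".x4");
  r.x5 = m.at(pre + ".x5");
  return r;
}

static Params params_from_vector(const NumericVector& pv) {
  std::map<std::string, double> m;
  CharacterVector nm = pv.names();
  for (int i = 0; i < pv.size(); ++i) m[as<std::string>(nm[i])] = pv[i];
  Params p;
  p.F = m.at("F"); p.R = m.at("R"); p.T = m.at("T");
  p.Na_out = m.at("Na_out"); p.K_out = m.at("K_out"); p.Ca_out = m.at("Ca_out");
  p.Vol_cyt = m.at("Vol_cyt"); p.Vol_SR = m.at("Vol_SR");
  p.Vol_Jun = m.at("Vol_Jun"); p.C_m = m.at("C_m");
  p.P_Ca = m.at("P_Ca"); p.G_Kv21 = m.at("G_Kv21"); p.G_Kv15 = m.at("G_Kv15");
  p.P_BKCa = m.at("P_BKCa"); p.N_BK = m.at("N_BK");
  p.G_NaNSC = m.at("G_NaNSC"); p.G_KNSC = m.at("G_KNSC");
  p.G_Nab = m.at("G_Nab"); p.G_Kb = m.at("G_Kb"); p.G_Cab = m.at("G_Cab");
  p.I_NaKmax = m.at("I_NaKmax"); p.Km_NaK_K = m.at("Km_NaK_K");
  p.Km_NaK_Na = m.at("Km_NaK_Na"); p.Q10 = m.at("Q10");
  p.P_NCX = m.at("P_NCX"); p.gamma_x = m.at("gamma_x");
  p.k_sat_NCX = m.at("k_sat_NCX");
  p.I_PMCAbar = m.at("I_PMCAbar"); p.Km_PMCA = m.at("Km_PMCA");
  p.bk_vh0 = m.at("bk_vh0"); p.bk_slope_ca = m.at("bk_slope_ca");
  p.bk_k = m.at("bk_k");
  p.bk_tau_scale = m.at("bk_tau_scale"); p.bk_tau_floor = m.at("bk_tau_floor");
  p.dL = get_rates(m, "dL"); p.dF = get_rates(m, "dF");
  p.kv21 = get_rates(m, "kv21"); p.kv15 = get_rates(m, "kv15");
  p.serca_vmax = m.at("serca_vmax"); p.serca_km = m.at("serca_km");
  p.ryr_nu_rel = m.at("ryr_nu_rel"); p.ryr_nu_leak = m.at("ryr_nu_leak");
  p.ryr_thr = m.at("ryr_thr"); p.ryr_k = m.at("ryr_k");
  p.ryr_kjun = m.at("ryr_kjun"); p.ryr_hill = m.at("ryr_hill");
  p.ryr_tau = m.at("ryr_tau");
  p.k_JunCyt = m.at("k_JunCyt");
  p.k_BUFon = m.at("k_BUFon"); p.k_BUFoff = m.at("k_BUFoff");
  p.BUF_T = m.at("BUF_T");
  p.clamp_ions = m.at("clamp_ions") != 0.0;
  p.rtf = 1000.0 * p.R * p.T / p.F;
  return p;
}

// ---------------------------------------------------------------------------
// Model equations. State layout: V dL dF x21 x15 xab r Ca_i Ca_SR Ca_Jun
// BUF Na_in K_in (13).
// ---------------------------------------------------------------------------
static const int NS = 13;
enum { iV, idL, idF, ix21, ix15, ixab, ir, iCai, iCaSR, iCaJun, iBUF,
       iNa, iK };
static const int NC = 12; // recorded currents

static inline double ghk(double V, int z, double P, double ci, double co,
                         const Params& p) {
  double u = z * V / p.rtf;
  double zF = z * p.F;
  if (std::fabs(u) < 1e-4) {
    return P * zF * ((ci - co) + u * (ci + co) / 2.0 +
                     u * u * (ci - co) / 12.0);
  }
  double eu = std::exp(u);
  return P * zF * u * (ci * eu - co) / (eu - 1.0);
}

static inline void gate_ss_tau(double V, const Rates5& r, double* ninf,
                               double* tau) {
  double a = r.x1 * std::exp(V / r.x2);
  double b = r.x3 * std::exp(V / r.x4);
  *ninf = a / (a + b);
  *tau = 1.0 / (a + b) + r.x5;
}

struct Currents {
  double I_Ca, I_Kv21, I_Kv15, I_BK, I_NSC, I_NaK, I_NCX, I_PMCA;
  double I_Nab, I_Kb, I_Cab, I_ion;
  double I_NaNSC, I_KNSC;
};

static Currents currents_at(const double* s, const Params& p) {
  Currents c;
  double V = s[iV];
  double E_K = p.rtf * std::log(p.K_out / s[iK]);
  double E_Na = p.rtf * std::log(p.Na_out / s[iNa]);
  double E_Ca = p.rtf / 2.0 * std::log(p.Ca_out / s[iCai]);
  c.I_Ca = ghk(V, 2, p.P_Ca * s[idL] * s[idF], s[iCai], p.Ca_out, p);
  c.I_Kv21 = p.G_Kv21 * s[ix21] * (V - E_K);
  c.I_Kv15 = p.G_Kv15 * s[ix15] * (V - E_K);
  c.I_BK = ghk(V, 1, p.P_BKCa * (p.N_BK / 8.0) * s[ixab], s[iK], p.K_out, p);
  double E_NSC = p.rtf * std::log((1.3 * p.K_out + 0.9 * p.Na_out) /
                                  (1.3 * s[iK] + 0.9 * s[iNa]));
  c.I_NaNSC = p.G_NaNSC * (V - E_NSC);
  c.I_KNSC = p.G_KNSC * (V - E_NSC);
  c.I_NSC = c.I_NaNSC + c.I_KNSC;
  double vf = V / p.rtf;
  double N1 = std::pow(p.K_out, 1.1) /
              (std::pow(p.K_out, 1.1) + std::pow(p.Km_NaK_K, 1.1));
  double N2 = std::pow(s[iNa], 1.7) /
              (std::pow(s[iNa], 1.7) + std::pow(p.Km_NaK_Na, 1.7));
  double N0 = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * vf) +
                     2.19e-3 * std::exp(p.Na_out / 49.71) *
                         std::exp(-1.9 * vf));
  double Npow = std::pow(p.Q10, (p.T - 309.2) / 10.0);
  c.I_NaK = p.I_NaKmax * N1 * N2 * N0 * Npow;
  double na3 = s[iNa] * s[iNa] * s[iNa];
  double nao3 = p.Na_out * p.Na_out * p.Na_out;
  double phiF = std::exp(p.gamma_x * vf);
  double phiR = std::exp((p.gamma_x - 1.0) * vf);
  c.I_NCX = p.P_NCX *
            (na3 * p.Ca_out * phiF - nao3 * s[iCai] * phiR) /
            (1.0 + p.k_sat_NCX * (nao3 * s[iCai] + na3 * p.Ca_out));
  c.I_PMCA = p.I_PMCAbar * s[iCai] * s[iCai] /
             (s[iCai] * s[iCai] + p.Km_PMCA * p.Km_PMCA);
  c.I_Nab = p.G_Nab * (V - E_Na);
  c.I_Kb = p.G_Kb * (V - E_K);
  c.I_Cab = p.G_Cab * (V - E_Ca);
  c.I_ion = c.I_Kv15 + c.I_Kv21 + c.I_BK + c.I_Kb + c.I_Ca + c.I_PMCA +
            c.I_Cab + c.I_NCX + c.I_NSC + c.I_NaK + c.I_Nab;
  return c;
}

static void rhs(const double* s, const Params& p, bool vclamp, double* ds,
                Currents* cout) {
  Currents c = currents_at(s, p);
  if (cout) *cout = c;
  double V = s[iV];
  double ninf, tau;
  gate_ss_tau(V, p.dL, &ninf, &tau);
  ds[idL] = (ninf - s[idL]) / tau;
  gate_ss_tau(V, p.dF, &ninf, &tau);
  ds[idF] = (ninf - s[idF]) / tau;
  gate_ss_tau(V, p.kv21, &ninf, &tau);
  ds[ix21] = (ninf - s[ix21]) / tau;
  gate_ss_tau(V, p.kv15, &ninf, &tau);
  ds[ix15] = (ninf - s[ix15]) / tau;
  double ca_jun_uM = s[iCaJun] * 1e3;
  double vh = p.bk_vh0 - p.bk_slope_ca * std::log(ca_jun_uM);
  double xab_inf = 1.0 / (1.0 + std::exp(-(V - vh) / p.bk_k));
  double xab_tau = p.bk_tau_scale / std::cosh(V / 40.0) + p.bk_tau_floor;
  ds[ixab] = (xab_inf - s[ixab]) / xab_tau;
  double phi = 1.0 / (1.0 + std::exp(-(s[iCaSR] - p.ryr_thr) / p.ryr_k));
  double cjn = std::pow(s[iCaJun], p.ryr_hill);
  double kjn = std::pow(p.ryr_kjun, p.ryr_hill);
  double psi = cjn / (cjn + kjn);
  ds[ir] = (phi * psi - s[ir]) / p.ryr_tau;
  double jser = p.serca_vmax * s[iCai] / (s[iCai] + p.serca_km);
  double jryr = (p.ryr_nu_leak + p.ryr_nu_rel * s[ir]) *
                (s[iCaSR] - s[iCaJun]);
  double jjc = p.k_JunCyt * (s[iCaJun] - s[iCai]);
  double sarc = -(c.I_Ca + c.I_Cab + c.I_PMCA - 2.0 * c.I_NCX) /
                (2.0 * p.F * p.Vol_cyt) * 1e-12;
  double buf = p.k_BUFon * s[iCai] * (p.BUF_T - s[iBUF]) -
               p.k_BUFoff * s[iBUF];
  ds[iCai] = sarc - jser + jjc - buf;
  ds[iCaSR] = (p.Vol_cyt / p.Vol_SR) * (jser - jryr);
  ds[iCaJun] = (p.Vol_cyt / p.Vol_Jun) * (jryr - jjc);
  ds[iBUF] = buf;
  if (p.clamp_ions) {
    ds[iNa] = 0.0;
    ds[iK] = 0.0;
  } else {
    double denom = p.F * p.Vol_cyt;
    ds[iK] = -(c.I_Kv21 + c.I_Kv15 + c.I_BK + c.I_Kb - 2.0 * c.I_NaK +
               c.I_KNSC) / denom * 1e-12;
    ds[iNa] = -(3.0 * c.I_NCX + 3.0 * c.I_NaK + c.I_Nab + c.I_NaNSC) /
              denom * 1e-12;
  }
  ds[iV] = vclamp ? 0.0 : -c.I_ion / p.C_m;
}

static inline void clamp_gates(double* s) {
  static const int gates[6] = {idL, idF, ix21, ix15, ixab, ir};
  for (int g = 0; g < 6; ++g) {
    if (s[gates[g]] < 0.0) s[gates[g]] = 0.0;
    if (s[gates[g]] > 1.0) s[gates[g]] = 1.0;
  }
}

static void record_currents(const Currents& c, NumericMatrix& m, int row) {
  m(row, 0) = c.I_Ca; m(row, 1) = c.I_Kv21; m(row, 2) = c.I_Kv15;
  m(row, 3) = c.I_BK; m(row, 4) = c.I_NSC; m(row, 5) = c.I_NaK;
  m(row, 6) = c.I_NCX; m(row, 7) = c.I_PMCA; m(row, 8) = c.I_Nab;
  m(row, 9) = c.I_Kb; m(row, 10) = c.I_Cab; m(row, 11) = c.I_ion;
}

// [[Rcpp::export]]
List cpp_derivatives(NumericVector state, NumericVector pv, bool vclamp) {
  Params p = params_from_vector(pv);
  double s[NS], ds[NS];
  for (int i = 0; i < NS; ++i) s[i] = state[i];
  Currents c;
  rhs(s, p, vclamp, ds, &c);
  NumericVector out(NS);
  NumericMatrix cur(1, NC);
  for (int i = 0; i < NS; ++i) out[i] = ds[i];
  record_currents(c, cur, 0);
  return List::create(_["dstate"] = out, _["currents"] = cur);
}

// [[Rcpp::export]]
List cpp_simulate_cell(NumericVector state0, NumericVector pv,
                       double duration, double dt, double sigma_V,
                       double sigma_SR, int seed, int stream, bool vclamp,
                       NumericVector vcmd, int vcmd_offset,
                       double sample_every) {
  Params p = params_from_vector(pv);
  long n_steps = (long)std::llround(duration / dt);
  long stride = std::max(1L, (long)std::llround(sample_every / dt));
  long n_out = n_steps / stride;
  NumericVector time(n_out);
  NumericMatrix smat(n_out, NS), cmat(n_out, NC);
  double s[NS], ds[NS];
  for (int i = 0; i < NS; ++i) s[i] = state0[i];
  SplitMix rng = make_stream((uint64_t)seed, (uint64_t)stream);
  bool noisy = (sigma_V > 0.0) || (sigma_SR > 0.0);
  double sqdt = std::sqrt(dt);
  long out_i = 0;
  Currents c;
  for (long step = 0; step < n_steps; ++step) {
    if (vclamp && vcmd.size() > 0) {
      long idx = vcmd_offset + step;
      if (idx >= vcmd.size()) idx = vcmd.size() - 1;
      s[iV] = vcmd[idx];
    }
    rhs(s, p, vclamp, ds, &c);
    if (step % stride == 0 && out_i < n_out) {
      time[out_i] = step * dt;
      for (int i = 0; i < NS; ++i) smat(out_i, i) = s[i];
      record_currents(c, cmat, out_i);
      ++out_i;
    }
    for (int i = 0; i < NS; ++i) s[i] += ds[i] * dt;
    if (noisy) {
      double z1, z2;
      rng.normal_pair(&z1, &z2);
      if (!vclamp) s[iV] += sigma_V * z1 * sqdt;
      s[iCaSR] += sigma_SR * z2 * sqdt;
    }
    clamp_gates(s);
    if (!R_finite(s[iV]) || !R_finite(s[iCai])) {
      stop("integration failure (non-finite state) at t = %f ms", step * dt);
    }
  }
  NumericVector fin(NS);
  for (int i = 0; i < NS; ++i) fin[i] = s[i];
  return List::create(_["time"] = time, _["state"] = smat,
                      _["currents"] = cmat, _["final_state"] = fin);
}

// [[Rcpp::export]]
List cpp_simulate_vessel(NumericMatrix states0, NumericVector pv,
                         double couple_rate, double duration, double dt,
                         double sigma_V, double sigma_SR, int seed,
                         int stream0, double sample_every) {
  Params p = params_from_vector(pv);
  int ncell = states0.nrow();
  long n_steps = (long)std::llround(duration / dt);
  long stride = std::max(1L, (long)std::llround(sample_every / dt));
  long n_out = n_steps / stride;
  NumericVector time(n_out);
  NumericMatrix Vmat(n_out, ncell), Camat(n_out, ncell);
  std::vector<double> s(ncell * NS), ds(NS), vnow(ncell);
  for (int c = 0; c < ncell; ++c)
    for (int i = 0; i < NS; ++i) s[c * NS + i] = states0(c, i);
  std::vector<SplitMix> rng;
  rng.reserve(ncell);
  for (int c = 0; c < ncell; ++c)
    rng.push_back(make_stream((uint64_t)seed, (uint64_t)(stream0 + c)));
  bool noisy = (sigma_V > 0.0) || (sigma_SR > 0.0);
  double sqdt = std::sqrt(dt);
  long out_i = 0;
  for (long step = 0; step < n_steps; ++step) {
    for (int c = 0; c < ncell; ++c) vnow[c] = s[c * NS + iV];
    bool record = (step % stride == 0 && out_i < n_out);
    for (int c = 0; c < ncell; ++c) {
      double* sc = &s[c * NS];
      rhs(sc, p, false, ds.data(), nullptr);
      // sealed (no-flux) ends: mirror boundary
      double vm = (c > 0) ? vnow[c - 1] : vnow[c];
      double vp = (c < ncell - 1) ? vnow[c + 1] : vnow[c];
      ds[iV] += couple_rate * (vm - 2.0 * vnow[c] + vp);
      if (record) {
        Vmat(out_i, c) = sc[iV];
        Camat(out_i, c) = sc[iCai];
      }
      for (int i = 0; i < NS; ++i) sc[i] += ds[i] * dt;
      if (noisy) {
        double z1, z2;
        rng[c].normal_pair(&z1, &z2);
        sc[iV] += sigma_V * z1 * sqdt;
        sc[iCaSR] += sigma_SR * z2 * sqdt;
      }
      clamp_gates(sc);
      if (!R_finite(sc[iV])) {
        stop("vessel integration failure in cell %d at t = %f ms", c + 1,
             step * dt);
      }
    }
    if (record) {
      time[out_i] = step * dt;
      ++out_i;
    }
  }
  NumericMatrix fin(ncell, NS);
  for (int c = 0; c < ncell; ++c)
    for (int i = 0; i < NS; ++i) fin(c, i) = s[c * NS + i];
  return List::create(_["time"] = time, _["V"] = Vmat, _["Ca_i"] = Camat,
                      _["final_states"] = fin);
}
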