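// Stochastic whole-cell engine: an ensemble of calcium release units
// (7-channel LCC clusters + 49-channel RyR2 clusters, dyadic subspace and
// jSR compartments) coupled to bulk myoplasm/NSR calcium, membrane voltage
// and a rat-like sarcolemmal current set.  Channel gating is per-step
// Bernoulli/binomial with probability 1 - exp(-rate*dt); concentrations are
// advanced by explicit Euler, except the stiff dyadic Ca:CaM mass-action
// step and the Hodgkin-Huxley gates, which use exact exponential
// (Rush-Larsen) relaxation.  The adaptive timestep enforces the
// "at most 10% of CRUs change channel state per step" rule by
// trial-and-reject: a violating step is discarded and redrawn at smaller dt.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----
// splitmix64: one independent, reproducible stream per release site.
struct SiteRng {
  uint64_t s;
  SiteRng() : s(0) {}
  explicit SiteRng(uint64_t seed) : s(seed) {}
  inline uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  inline double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

static inline uint64_t mix_seed(uint64_t seed, uint64_t stream) {
  uint64_t z = seed * 0x9E3779B97F4A7C15ULL + stream * 0xD1B54A32D192ED03ULL + 1ULL;
  z = (z ^ (z >> 33)) * 0xFF51AFD7ED558CCDULL;
  z = (z ^ (z >> 33)) * 0xC4CEB9FE1A85EC53ULL;
  return z ^ (z >> 33);
}

// P(at least one event) of an exponential clock over one step
static inline double pstep(double x) {
  return (x < 1e-4) ? x * (1.0 - 0.5 * x) : -std::expm1(-x);
}

// exact binomial draw by CDF inversion (single uniform; n is small)
static inline int binom_draw(int n, double p, SiteRng &g) {
  if (n <= 0 || p <= 0.0) return 0;
  if (p >= 0.98) {              // near-certain regime: explicit Bernoullis
    int k = 0;
    for (int j = 0; j < n; ++j) if (g.unif() < p) ++k;
    return k;
  }
  double u = g.unif();
  double q = 1.0 - p, r = p / q;
  double pmf = std::pow(q, (double) n);
  double cdf = pmf;
  int k = 0;
  while (u > cdf && k < n) {
    pmf *= r * (double) (n - k) / (double) (k + 1);
    ++k;
    cdf += pmf;
  }
  return k;
}

// ------------------------------------------------------------- params ----
struct Params {
  double cdi_factor, cam_total, cam_kon, cam_koff;
  double k24_base, k42, k12_a, k12_b, k21_a, k21_b, k16_a, k16_b, k61_a, k61_b;
  double k23_a, k23_b, k32_a, k32_b, k25_a, k25_b, k52_a, k52_b;
  int n_lcc; double nu_lcc, ca_o_uM;
  double ry_kopen, ry_cahalf, ry_hill, ry_lumfloor, ry_lumgain, ry_lumhalf,
         ry_lumhill, ry_coup, ry_kclose; int n_ryr; double nu_ryr;
  double v_myo, v_nsr, v_ds, v_jsr, beta_jsr, tau_eff, tau_refill;
  int n_cru_full;
  double bm_t, bm_on, bm_off, bsl_t, bsl_on, bsl_off, bsr_t, bsr_on, bsr_off;
  double serca_vmax, serca_km, serca_hill, k_leak, nsr_max, load_hill;
  double cm, g_na, g_to, g_ss, g_k1, g_bca, g_bna, i_nak_max, km_nai, km_ko;
  double k_ncx, eta_ncx, ksat_ncx, km_na_ncx, km_ca_ncx, g_pca, km_pca;
  double na_o, k_o, ca_o_mM, rtf;
  double nj_frac, nj_nu, nj_vhalf, nj_vslope;
  double dt_min, dt_max, dt_init, dt_grow, dt_shrink, max_frac, max_rel, max_dv;
  double v0, ca_myo0, ca_nsr0, na0, k0, ca_ds0, ca_jsr0;
};

static double gd(const List &l, const char *nm) { return as<double>(l[nm]); }

static Params unpack(const List &pp) {
  Params p;
  List var = pp["variant"], cam = pp["cam"], lcc = pp["lcc"], ryr = pp["ryr"],
       geo = pp["geometry"], buf = pp["buffers"], ser = pp["serca"],
       mem = pp["membrane"], nj = pp["dhpr_nj"], dtc = pp["dt_control"],
       ini = pp["init"];
  p.cdi_factor = gd(var, "cdi_factor");
  p.cam_total = gd(cam, "cam_total"); p.cam_kon = gd(cam, "k_on");
  p.cam_koff = gd(cam, "k_off");
  p.k24_base = gd(lcc, "k24_base"); p.k42 = gd(lcc, "k42");
  p.k12_a = gd(lcc, "k12_a"); p.k12_b = gd(lcc, "k12_b");
  p.k21_a = gd(lcc, "k21_a"); p.k21_b = gd(lcc, "k21_b");
  p.k16_a = gd(lcc, "k16_a"); p.k16_b = gd(lcc, "k16_b");
  p.k61_a = gd(lcc, "k61_a"); p.k61_b = gd(lcc, "k61_b");
  p.k23_a = gd(lcc, "k23_a"); p.k23_b = gd(lcc, "k23_b");
  p.k32_a = gd(lcc, "k32_a"); p.k32_b = gd(lcc, "k32_b");
  p.k25_a = gd(lcc, "k25_a"); p.k25_b = gd(lcc, "k25_b");
  p.k52_a = gd(lcc, "k52_a"); p.k52_b = gd(lcc, "k52_b");
  p.n_lcc = as<int>(lcc["n_lcc"]); p.nu_lcc = gd(lcc, "nu_lcc");
  p.ca_o_uM = gd(lcc, "ca_o");
  p.ry_kopen = gd(ryr, "k_open_base"); p.ry_cahalf = gd(ryr, "ca_half");
  p.ry_hill = gd(ryr, "hill"); p.ry_lumfloor = gd(ryr, "lum_floor");
  p.ry_lumgain = gd(ryr, "luminal_gain"); p.ry_lumhalf = gd(ryr, "lum_half");
  p.ry_lumhill = gd(ryr, "lum_hill"); p.ry_coup = gd(ryr, "coupling_strength");
  p.ry_kclose = gd(ryr, "k_close"); p.n_ryr = as<int>(ryr["n_ryr"]);
  p.nu_ryr = gd(ryr, "nu_ryr");
  p.v_myo = gd(geo, "v_myo_pl"); p.v_nsr = gd(geo, "v_nsr_pl");
  p.v_ds = gd(geo, "v_ds_pl"); p.v_jsr = gd(geo, "v_jsr_pl");
  p.beta_jsr = gd(geo, "beta_jsr"); p.tau_eff = gd(geo, "tau_efflux");
  p.tau_refill = gd(geo, "tau_refill");
  p.n_cru_full = as<int>(geo["n_cru_full"]);
  List bm = buf["myo"], bsl = buf["sl"], bsr = buf["srm"];
  p.bm_t = gd(bm, "total"); p.bm_on = gd(bm, "k_on"); p.bm_off = gd(bm, "k_off");
  p.bsl_t = gd(bsl, "total"); p.bsl_on = gd(bsl, "k_on"); p.bsl_off = gd(bsl, "k_off");
  p.bsr_t = gd(bsr, "total"); p.bsr_on = gd(bsr, "k_on"); p.bsr_off = gd(bsr, "k_off");
  p.serca_vmax = gd(ser, "vmax"); p.serca_km = gd(ser, "km");
  p.serca_hill = gd(ser, "hill"); p.k_leak = gd(ser, "k_leak");
  p.nsr_max = gd(ser, "nsr_max"); p.load_hill = gd(ser, "load_hill");
  p.cm = gd(mem, "cm"); p.g_na = gd(mem, "g_na"); p.g_to = gd(mem, "g_to");
  p.g_ss = gd(mem, "g_ss"); p.g_k1 = gd(mem, "g_k1");
  p.g_bca = gd(mem, "g_bca"); p.g_bna = gd(mem, "g_bna");
  p.i_nak_max = gd(mem, "i_nak_max"); p.km_nai = gd(mem, "km_nai");
  p.km_ko = gd(mem, "km_ko");
  p.k_ncx = gd(mem, "k_ncx"); p.eta_ncx = gd(mem, "eta_ncx");
  p.ksat_ncx = gd(mem, "ksat_ncx"); p.km_na_ncx = gd(mem, "km_na_ncx");
  p.km_ca_ncx = gd(mem, "km_ca_ncx");
  p.g_pca = gd(mem, "g_pca"); p.km_pca = gd(mem, "km_pca");
  p.na_o = gd(mem, "na_o"); p.k_o = gd(mem, "k_o");
  p.ca_o_mM = gd(mem, "ca_o_mM"); p.rtf = gd(mem, "rtf");
  p.nj_frac = gd(nj, "fraction"); p.nj_nu = gd(nj, "nu");
  p.nj_vhalf = gd(nj, "v_half"); p.nj_vslope = gd(nj, "v_slope");
  p.dt_min = gd(dtc, "dt_min"); p.dt_max = gd(dtc, "dt_max");
  p.dt_init = gd(dtc, "dt_init"); p.dt_grow = gd(dtc, "grow");
  p.dt_shrink = gd(dtc, "shrink"); p.max_frac = gd(dtc, "max_frac_cru");
  p.max_rel = gd(dtc, "max_rel_inc"); p.max_dv = gd(dtc, "max_dv");
  p.v0 = gd(ini, "v"); p.ca_myo0 = gd(ini, "ca_myo");
  p.ca_nsr0 = gd(ini, "ca_nsr"); p.na0 = gd(ini, "na_i");
  p.k0 = gd(ini, "k_i"); p.ca_ds0 = gd(ini, "ca_ds");
  p.ca_jsr0 = gd(ini, "ca_jsr");
  return p;
}

// ------------------------------------------------------ channel rates ----
struct LccRates { double k12, k21, k16, k61, k23, k32, k25, k52, k42; };

static inline LccRates lcc_rates_at(const Params &p, double v) {
  LccRates r;
  r.k12 = p.k12_a * std::exp(v / p.k12_b);
  r.k21 = p.k21_a * std::exp(-v / p.k21_b);
  r.k16 = p.k16_a * std::exp(-v / p.k16_b);
  r.k61 = p.k61_a * std::exp(v / p.k61_b);
  r.k23 = p.k23_a * std::exp(v / p.k23_b);
  r.k32 = p.k32_a * std::exp(-v / p.k32_b);
  r.k25 = p.k25_a * std::exp(v / p.k25_b);
  r.k52 = p.k52_a * std::exp(-v / p.k52_b);
  r.k42 = p.k42;
  return r;
}

static inline double ryr_kopen(const Params &p, double ca, double jsr, double f) {
  double ah = std::pow(ca, p.ry_hill);
  double act = ah / (ah + std::pow(p.ry_cahalf, p.ry_hill));
  double jh = std::pow(jsr, p.ry_lumhill);
  double lum = p.ry_lumfloor +
    p.ry_lumgain * jh / (jh + std::pow(p.ry_lumhalf, p.ry_lumhill));
  return p.ry_kopen * act * lum * (1.0 + p.ry_coup * f);
}

// one LCC channel step; states 0..5 = C1 O2 O3 C4 C5 C6
static inline int lcc_step(int s, const LccRates &r, double k24, double dt,
                           SiteRng &g) {
  double u = g.unif();
  switch (s) {
  case 0: { // C1 -> O2 | C6
    double rtot = r.k12 + r.k16;
    double pp = pstep(rtot * dt);
    if (u < pp) return (u / pp * rtot < r.k12) ? 1 : 5;
    return 0; }
  case 1: { // O2 -> C1 | O3 | C4 | C5
    double rtot = r.k21 + r.k23 + k24 + r.k25;
    double pp = pstep(rtot * dt);
    if (u < pp) {
      double w = u / pp * rtot;
      if (w < r.k21) return 0;
      if (w < r.k21 + r.k23) return 2;
      if (w < r.k21 + r.k23 + k24) return 3;
      return 4;
    }
    return 1; }
  case 2: return (u < pstep(r.k32 * dt)) ? 1 : 2;  // O3 -> O2
  case 3: return (u < pstep(r.k42 * dt)) ? 1 : 3;  // C4 -> O2
  case 4: return (u < pstep(r.k52 * dt)) ? 1 : 4;  // C5 -> O2
  default: return (u < pstep(r.k61 * dt)) ? 0 : 5; // C6 -> C1
  }
}

// -------------------------------------------------------- LR-style HH ----
// sodium-channel gate kinetics; taus in ms
static inline void na_gates(double v, double &minf, double &taum,
                            double &hinf, double &tauh,
                            double &jinf, double &tauj) {
  double am = (std::fabs(v + 47.13) < 1e-6) ? 3.2
    : 0.32 * (v + 47.13) / (1.0 - std::exp(-0.1 * (v + 47.13)));
  double bm = 0.08 * std::exp(-v / 11.0);
  double ah, bh, aj, bj;
  if (v < -40.0) {
    ah = 0.135 * std::exp((80.0 + v) / -6.8);
    bh = 3.56 * std::exp(0.079 * v) + 3.1e5 * std::exp(0.35 * v);
    aj = (-1.2714e5 * std::exp(0.2444 * v) - 3.474e-5 * std::exp(-0.04391 * v)) *
         (v + 37.78) / (1.0 + std::exp(0.311 * (v + 79.23)));
    bj = 0.1212 * std::exp(-0.01052 * v) / (1.0 + std::exp(-0.1378 * (v + 40.14)));
  } else {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + std::exp((v + 10.66) / -11.1)));
    aj = 0.0;
    bj = 0.3 * std::exp(-2.535e-7 * v) / (1.0 + std::exp(-0.1 * (v + 32.0)));
  }
  minf = am / (am + bm); taum = 1.0 / (am + bm);
  hinf = ah / (ah + bh); tauh = 1.0 / (ah + bh);
  jinf = aj / (aj + bj); tauj = 1.0 / (aj + bj);
}

static inline double k1_inf(double v, double e_k) {
  double vk = v - e_k;
  double a = 1.02 / (1.0 + std::exp(0.2385 * (vk - 59.215)));
  double b = (0.49124 * std::exp(0.08032 * (vk + 5.476)) +
              std::exp(0.06175 * (vk - 594.31))) /
             (1.0 + std::exp(-0.5143 * (vk + 4.753)));
  return a / (a + b);
}

struct Currents {
  double i_na, i_to, i_ss, i_k1, i_nak, i_ncx, i_bca, i_bna, i_pca;
};

static inline Currents membrane_currents_c(const Params &p, double v,
                                           double ca_myo, double na_i,
                                           double k_i, double gm, double gh,
                                           double gj, double gr, double gs) {
  Currents c;
  double e_na = p.rtf * std::log(p.na_o / na_i);
  double e_k = p.rtf * std::log(p.k_o / k_i);
  double ca_mM = ca_myo * 1e-3;
  double e_ca = 0.5 * p.rtf * std::log(p.ca_o_mM / ca_mM);
  c.i_na = p.g_na * gm * gm * gm * gh * gj * (v - e_na);
  c.i_to = p.g_to * gr * gs * (v - e_k);
  double rss = 1.0 / (1.0 + std::exp(-(v + 11.5) / 11.82));
  c.i_ss = p.g_ss * rss * (v - e_k);
  c.i_k1 = p.g_k1 * k1_inf(v, e_k) * (v - e_k);
  double vfrt = v / p.rtf;
  double sig = (std::exp(p.na_o / 67.3) - 1.0) / 7.0;
  double fnak = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * vfrt) +
                       0.0365 * sig * std::exp(-vfrt));
  c.i_nak = p.i_nak_max * fnak * (p.k_o / (p.k_o + p.km_ko)) /
            (1.0 + std::pow(p.km_nai / na_i, 1.5));
  double na3 = na_i * na_i * na_i, nao3 = p.na_o * p.na_o * p.na_o;
  c.i_ncx = p.k_ncx *
    (std::exp(p.eta_ncx * vfrt) * na3 * p.ca_o_mM -
     std::exp((p.eta_ncx - 1.0) * vfrt) * nao3 * ca_mM) /
    ((std::pow(p.km_na_ncx, 3.0) + nao3) * (p.km_ca_ncx + p.ca_o_mM) *
     (1.0 + p.ksat_ncx * std::exp((p.eta_ncx - 1.0) * vfrt)));
  c.i_bca = p.g_bca * (v - e_ca);
  c.i_bna = p.g_bna * (v - e_na);
  c.i_pca = p.g_pca * ca_myo / (ca_myo + p.km_pca);
  return c;
}

// ----------------------------------------------------------- simulate ----
// [[Rcpp::export]]
List cpp_simulate(List params, List protocol) {
  Params p = unpack(params);

  const int n_cru = as<int>(protocol["n_cru"]);
  const double duration = as<double>(protocol["duration"]);
  const double hz = as<double>(protocol["pacing_hz"]);
  const double stim_amp = as<double>(protocol["stim_amplitude"]);
  const double stim_width = as<double>(protocol["stim_width"]);
  const double stim_start = as<double>(protocol["stim_start"]);
  const double lcc_scale = as<double>(protocol["lcc_scale"]);
  const double serca_scale = as<double>(protocol["serca_scale"]);
  const double out_dt = as<double>(protocol["out_dt"]);
  const double rec_frac = as<double>(protocol["record_fraction"]);
  const uint64_t seed = (uint64_t) as<double>(protocol["seed"]);
  const bool freeze_bulk = protocol.containsElementNamed("freeze_bulk") ?
    as<bool>(protocol["freeze_bulk"]) : false;

  bool clamped = false;
  std::vector<double> clamp_t, clamp_v;
  if (protocol.containsElementNamed("clamp") && !Rf_isNull(protocol["clamp"])) {
    List cli = protocol["clamp"];
    NumericVector ct = cli["t"], cv = cli["v"];
    clamp_t.assign(ct.begin(), ct.end());
    clamp_v.assign(cv.begin(), cv.end());
    clamped = true;
  }
  auto clamp_voltage = [&](double tt) {
    size_t k = 0;
    while (k + 1 < clamp_t.size() && tt >= clamp_t[k + 1]) ++k;
    return clamp_v[k];
  };

  const int NL = p.n_lcc, NR = p.n_ryr;
  const double scale = (double) p.n_cru_full / (double) n_cru;
  const double vds_vmyo = p.v_ds / p.v_myo;
  const double vds_vjsr = p.v_ds / p.v_jsr;
  const double vjsr_vnsr = p.v_jsr / p.v_nsr;
  const double vjsr_vmyo = p.v_jsr / p.v_myo;
  const double vmyo_vnsr = p.v_myo / p.v_nsr;
  // 1 pA/pF of Ca2+ current <-> this many uM/s in the myoplasm volume
  const double flux_per_i_ca =
    p.cm * 1e-12 / (2.0 * 96485.0 * p.v_myo * 1e-12) * 1e6;
  const double flux_per_i_1 = 2.0 * flux_per_i_ca;  // one charge per ion moved
  const double conv_na_mM = p.cm * 1e-12 / (96485.0 * p.v_myo * 1e-12) * 1e3;

  // ---- state ----
  std::vector<int8_t> lcc((size_t) n_cru * NL, (int8_t) 5);  // all C6
  std::vector<int> nryr(n_cru, 0);
  std::vector<double> ca_ds(n_cru, p.ca_ds0), ca_jsr(n_cru, p.ca_jsr0);
  std::vector<double> bsl(n_cru), bsr(n_cru), ccam(n_cru);
  {
    double cc0 = p.ca_ds0 * p.ca_ds0 * p.cam_total /
                 (p.ca_ds0 * p.ca_ds0 + p.cam_koff / p.cam_kon);
    double bsl0 = p.bsl_t * p.ca_ds0 / (p.ca_ds0 + p.bsl_off / p.bsl_on);
    double bsr0 = p.bsr_t * p.ca_ds0 / (p.ca_ds0 + p.bsr_off / p.bsr_on);
    for (int i = 0; i < n_cru; ++i) { ccam[i] = cc0; bsl[i] = bsl0; bsr[i] = bsr0; }
  }
  double v = p.v0, ca_myo = p.ca_myo0, ca_nsr = p.ca_nsr0;
  double na_i = p.na0, k_i = p.k0;
  double b_myo = p.bm_t * ca_myo / (ca_myo + p.bm_off / p.bm_on);
  double gm, gh, gj, gr, gs;
  { double mi, tm, hi, th, ji, tj;
    na_gates(v, mi, tm, hi, th, ji, tj);
    gm = mi; gh = hi; gj = ji;
    gr = 1.0 / (1.0 + std::exp(-(v + 10.6) / 11.4));
    gs = 1.0 / (1.0 + std::exp((v + 45.3) / 6.88)); }
  if (clamped) v = clamp_voltage(0.0);

  std::vector<SiteRng> rng(n_cru), rng_new(n_cru);
  for (int i = 0; i < n_cru; ++i) rng[i] = SiteRng(mix_seed(seed, (uint64_t) i));

  // ---- output buffers ----
  const int n_rec = std::max(0, std::min(n_cru, (int) std::ceil(rec_frac * n_cru)));
  const int n_samp_max = (int) std::floor(duration / out_dt) + 2;
  const int NC = 14;
  NumericMatrix out(n_samp_max, NC);
  NumericMatrix rec_cads(n_rec > 0 ? n_samp_max : 0, n_rec);
  NumericMatrix rec_cajsr(n_rec > 0 ? n_samp_max : 0, n_rec);
  IntegerMatrix rec_nryr(n_rec > 0 ? n_samp_max : 0, n_rec);
  IntegerMatrix rec_nlcc(n_rec > 0 ? n_samp_max : 0, n_rec);
  int n_samp = 0;

  // ---- trial buffers ----
  std::vector<int8_t> lcc_new((size_t) n_cru * NL);
  std::vector<int> nryr_new(n_cru);
  std::vector<double> cads_new(n_cru), cajsr_new(n_cru),
    bsl_new(n_cru), bsr_new(n_cru), ccam_new(n_cru);

  double t = 0.0, dt = p.dt_init;
  double cum_ext = 0.0, cum_itot_mv = 0.0;
  double next_sample = 0.0;
  long n_steps = 0, n_rej_frac = 0, n_rej_inc = 0, n_over_rule = 0,
       n_shrink_inc = 0;
  double dt_sum = 0.0, dt_minseen = 1e9, dt_maxseen = 0.0;
  const int frac_limit = (int) std::floor(p.max_frac * n_cru);
  const double cl = (hz > 0) ? 1.0 / hz : 0.0;

  auto total_calcium = [&]() {
    double per = 0.0;
    for (int i = 0; i < n_cru; ++i) {
      per += (ca_ds[i] + 2.0 * ccam[i] + bsl[i] + bsr[i]) * vds_vmyo +
             ca_jsr[i] / p.beta_jsr * vjsr_vmyo;
    }
    return ca_myo + b_myo + ca_nsr / vmyo_vnsr + scale * per;
  };

  auto record = [&]() {
    if (n_samp >= n_samp_max) { next_sample += out_dt; return; }
    double sum_jl = 0, sum_jr = 0;
    int nlo = 0; long nro = 0;
    for (int i = 0; i < n_cru; ++i) {
      int nopen = 0;
      for (int c = 0; c < NL; ++c) {
        int s = lcc[(size_t) i * NL + c];
        if (s == 1 || s == 2) ++nopen;
      }
      nlo += nopen; nro += nryr[i];
      sum_jl += nopen * p.nu_lcc * lcc_scale * (p.ca_o_uM - ca_ds[i]);
      sum_jr += nryr[i] * p.nu_ryr * (ca_jsr[i] - ca_ds[i]);
    }
    Currents cc = membrane_currents_c(p, v, ca_myo, na_i, k_i, gm, gh, gj, gr, gs);
    double j_lcc_myo = scale * sum_jl * vds_vmyo;
    double dinf = 1.0 / (1.0 + std::exp(-(v - p.nj_vhalf) / p.nj_vslope));
    double j_nj = p.nj_frac * p.nj_nu * lcc_scale * dinf *
                  (p.ca_o_uM - ca_myo) / p.ca_o_uM;
    double ca2m = std::pow(ca_myo, p.serca_hill);
    double loadf = 1.0 - std::pow(ca_nsr / p.nsr_max, p.load_hill);
    if (loadf < 0.0) loadf = 0.0;
    out(n_samp, 0) = t;       out(n_samp, 1) = v;
    out(n_samp, 2) = ca_myo;  out(n_samp, 3) = ca_nsr;
    out(n_samp, 4) = -j_lcc_myo / flux_per_i_ca;
    out(n_samp, 5) = cc.i_ncx;
    out(n_samp, 6) = -j_nj / flux_per_i_ca;
    out(n_samp, 7) = scale * sum_jr * vds_vmyo;
    out(n_samp, 8) = serca_scale * p.serca_vmax * loadf * ca2m /
                     (ca2m + std::pow(p.serca_km, p.serca_hill));
    out(n_samp, 9) = total_calcium();
    out(n_samp, 10) = cum_ext;
    out(n_samp, 11) = cum_itot_mv;
    out(n_samp, 12) = (double) nlo;
    out(n_samp, 13) = (double) nro;
    for (int j = 0; j < n_rec; ++j) {
      rec_cads(n_samp, j) = ca_ds[j];
      rec_cajsr(n_samp, j) = ca_jsr[j];
      rec_nryr(n_samp, j) = nryr[j];
      int nl = 0;
      for (int c = 0; c < NL; ++c) {
        int s = lcc[(size_t) j * NL + c];
        if (s == 1 || s == 2) ++nl;
      }
      rec_nlcc(n_samp, j) = nl;
    }
    ++n_samp;
    next_sample += out_dt;
  };

  record();  // t = 0

  while (t < duration) {
    if (t + dt > duration) dt = duration - t;
    bool accepted = false;
    int tries = 0;
    double dv = 0, dca_myo = 0, dca_nsr = 0, dna = 0, dk = 0, db_myo = 0;
    double gm_n = 0, gh_n = 0, gj_n = 0, gr_n = 0, gs_n = 0;
    double ext_flux = 0, itot = 0;
    bool inc_viol_next = false;

    while (!accepted) {
      ++tries;
      if (tries > 200)
        stop("crusim engine: timestep controller failed to converge at t=%g s", t);
      LccRates lr = lcc_rates_at(p, v);
      int changed = 0;
      double maxrel = 0.0;
      double sum_jl = 0, sum_je = 0, sum_ref = 0;

      for (int i = 0; i < n_cru; ++i) {
        SiteRng g = rng[i];  // trial copy; committed only on acceptance
        bool ch = false;
        double k24 = p.cdi_factor * p.k24_base * ccam[i];
        int nopen = 0;
        for (int c = 0; c < NL; ++c) {
          int s = lcc[(size_t) i * NL + c];
          int sn = lcc_step(s, lr, k24, dt, g);
          lcc_new[(size_t) i * NL + c] = (int8_t) sn;
          if (sn != s) ch = true;
          if (sn == 1 || sn == 2) ++nopen;
        }
        double f = (double) nryr[i] / NR;
        double ko = ryr_kopen(p, ca_ds[i], ca_jsr[i], f);
        int n_up = binom_draw(NR - nryr[i], pstep(ko * dt), g);
        int n_dn = binom_draw(nryr[i], pstep(p.ry_kclose * dt), g);
        int nr = nryr[i] + n_up - n_dn;
        nryr_new[i] = nr;
        if (n_up + n_dn > 0) ch = true;
        if (ch) ++changed;
        rng_new[i] = g;

        double jl = nopen * p.nu_lcc * lcc_scale * (p.ca_o_uM - ca_ds[i]);
        double jr = nr * p.nu_ryr * (ca_jsr[i] - ca_ds[i]);
        double je = (ca_ds[i] - ca_myo) / p.tau_eff;
        double rsl = p.bsl_on * ca_ds[i] * (p.bsl_t - bsl[i]) - p.bsl_off * bsl[i];
        double rsr = p.bsr_on * ca_ds[i] * (p.bsr_t - bsr[i]) - p.bsr_off * bsr[i];
        // exact exponential update of the stiff Ca:CaM mass-action step
        double ca2 = ca_ds[i] * ca_ds[i];
        double lam = p.cam_kon * ca2 + p.cam_koff;
        double cceq = p.cam_kon * ca2 * p.cam_total / lam;
        double dcc = (cceq - ccam[i]) * pstep(lam * dt);
        double dca = dt * (jl + jr - je - rsl - rsr) - 2.0 * dcc;
        cads_new[i] = ca_ds[i] + dca;
        ccam_new[i] = ccam[i] + dcc;
        bsl_new[i] = bsl[i] + dt * rsl;
        bsr_new[i] = bsr[i] + dt * rsr;
        double djsr = dt * p.beta_jsr *
          ((ca_nsr - ca_jsr[i]) / p.tau_refill - jr * vds_vjsr);
        cajsr_new[i] = ca_jsr[i] + djsr;
        double rel = std::fabs(dca) / (ca_ds[i] + 1.0);
        if (rel > maxrel) maxrel = rel;
        rel = std::fabs(djsr) / (ca_jsr[i] + 10.0);
        if (rel > maxrel) maxrel = rel;
        sum_jl += jl; sum_je += je;
        sum_ref += (ca_nsr - ca_jsr[i]);
      }

      // ---- membrane + bulk ----
      double i_stim = 0.0;
      if (!clamped && hz > 0 && t >= stim_start) {
        double el = t - stim_start;
        double ph = el - cl * std::floor(el / cl);
        if (ph < stim_width) i_stim = stim_amp;
      }
      Currents cc = membrane_currents_c(p, v, ca_myo, na_i, k_i, gm, gh, gj, gr, gs);
      double j_lcc_myo = scale * sum_jl * vds_vmyo;
      double dinf = 1.0 / (1.0 + std::exp(-(v - p.nj_vhalf) / p.nj_vslope));
      double j_nj = p.nj_frac * p.nj_nu * lcc_scale * dinf *
                    (p.ca_o_uM - ca_myo) / p.ca_o_uM;
      double i_lcc = -j_lcc_myo / flux_per_i_ca;
      double i_nj = -j_nj / flux_per_i_ca;
      double ca2m = std::pow(ca_myo, p.serca_hill);
      double loadf = 1.0 - std::pow(ca_nsr / p.nsr_max, p.load_hill);
      if (loadf < 0.0) loadf = 0.0;
      double j_serca = serca_scale * p.serca_vmax * loadf * ca2m /
                       (ca2m + std::pow(p.serca_km, p.serca_hill));
      double j_leak = p.k_leak * (ca_nsr - ca_myo);
      double j_ncx_ca = cc.i_ncx * flux_per_i_1;   // +ve current = Ca entry
      double j_bca_in = -cc.i_bca * flux_per_i_ca;
      double j_pca_out = cc.i_pca * flux_per_i_ca;
      double r_bm = p.bm_on * ca_myo * (p.bm_t - b_myo) - p.bm_off * b_myo;

      itot = cc.i_na + cc.i_to + cc.i_ss + cc.i_k1 + cc.i_nak + cc.i_ncx +
             cc.i_bca + cc.i_bna + cc.i_pca + i_lcc + i_nj + i_stim;
      dv = clamped ? 0.0 : -itot * dt * 1e3;

      dca_myo = dt * (scale * sum_je * vds_vmyo + j_nj + j_ncx_ca + j_bca_in -
                      j_pca_out - j_serca + j_leak - r_bm);
      db_myo = dt * r_bm;
      dca_nsr = dt * ((j_serca - j_leak) * vmyo_vnsr -
                      scale * sum_ref / p.tau_refill * vjsr_vnsr);
      dna = -dt * (cc.i_na + cc.i_bna + 3.0 * cc.i_nak + 3.0 * cc.i_ncx) * conv_na_mM;
      dk = -dt * (cc.i_to + cc.i_ss + cc.i_k1 + i_stim - 2.0 * cc.i_nak) * conv_na_mM;
      ext_flux = j_lcc_myo + j_nj + j_ncx_ca + j_bca_in - j_pca_out;

      if (freeze_bulk) {
        dv = 0; dca_myo = 0; dca_nsr = 0; dna = 0; dk = 0; db_myo = 0;
        ext_flux = 0; itot = 0;
      }

      // HH gates: exact exponential relaxation (Rush-Larsen)
      { double mi, tm, hi, th, ji, tj;
        na_gates(v, mi, tm, hi, th, ji, tj);
        double dms = dt * 1e3;
        gm_n = mi + (gm - mi) * std::exp(-dms / tm);
        gh_n = hi + (gh - hi) * std::exp(-dms / th);
        gj_n = ji + (gj - ji) * std::exp(-dms / tj);
        double ri = 1.0 / (1.0 + std::exp(-(v + 10.6) / 11.4));
        double tr = 0.0035 * std::exp(-(v / 30.0) * (v / 30.0)) + 0.0015;
        double si = 1.0 / (1.0 + std::exp((v + 45.3) / 6.88));
        double tsv = 0.065 * std::exp(-std::pow((v + 70.0) / 30.0, 2.0)) + 0.012;
        gr_n = ri + (gr - ri) * std::exp(-dt / tr);
        gs_n = si + (gs - si) * std::exp(-dt / tsv); }

      double relb = std::fabs(dca_myo) / (ca_myo + 0.05);
      if (relb > maxrel) maxrel = relb;
      relb = std::fabs(dca_nsr) / (ca_nsr + 10.0);
      if (relb > maxrel) maxrel = relb;

      // Rejection (discard + redraw at smaller dt) happens only for the
      // collective ">10% of CRUs changed state" rule and for states that
      // would leave the physical domain.  Accuracy violations (relative
      // increment / voltage step) instead shrink the NEXT step: rejecting
      // on them would systematically censor the rare single-channel
      // openings that trigger them.
      bool frac_viol = (changed > frac_limit) && (changed > 1);
      bool neg_viol = false;
      for (int i = 0; i < n_cru && !neg_viol; ++i) {
        if (cads_new[i] < 0 || cajsr_new[i] < 0 || !std::isfinite(cads_new[i]))
          neg_viol = true;
      }
      if (ca_myo + dca_myo < 0 || ca_nsr + dca_nsr < 0) neg_viol = true;
      if ((frac_viol || neg_viol) && dt > p.dt_min) {
        dt = std::max(dt * p.dt_shrink, p.dt_min);
        if (frac_viol) ++n_rej_frac; else ++n_rej_inc;
        continue;
      }
      if (frac_viol) ++n_over_rule;  // accepted at dt_min despite the rule
      inc_viol_next = (maxrel > p.max_rel) || (std::fabs(dv) > p.max_dv);

      // ---- commit ----
      std::copy(lcc_new.begin(), lcc_new.end(), lcc.begin());
      std::copy(nryr_new.begin(), nryr_new.end(), nryr.begin());
      std::copy(cads_new.begin(), cads_new.end(), ca_ds.begin());
      std::copy(cajsr_new.begin(), cajsr_new.end(), ca_jsr.begin());
      std::copy(bsl_new.begin(), bsl_new.end(), bsl.begin());
      std::copy(bsr_new.begin(), bsr_new.end(), bsr.begin());
      std::copy(ccam_new.begin(), ccam_new.end(), ccam.begin());
      std::copy(rng_new.begin(), rng_new.end(), rng.begin());
      accepted = true;
    }

    v += dv; ca_myo += dca_myo; ca_nsr += dca_nsr; b_myo += db_myo;
    na_i += dna; k_i += dk;
    gm = gm_n; gh = gh_n; gj = gj_n; gr = gr_n; gs = gs_n;
    cum_ext += dt * ext_flux;
    cum_itot_mv += clamped ? 0.0 : itot * dt * 1e3;
    t += dt;
    if (clamped) v = clamp_voltage(t);

    if (!std::isfinite(v) || !std::isfinite(ca_myo) || !std::isfinite(ca_nsr))
      stop("crusim engine: non-finite state (v/ca_myo/ca_nsr) at t=%g s", t);
    if (ca_myo < 0) stop("crusim engine: ca_myo went negative at t=%g s", t);
    if (ca_nsr < 0) stop("crusim engine: ca_nsr went negative at t=%g s", t);
    for (int i = 0; i < n_cru; ++i) {
      if (ca_ds[i] < 0)
        stop("crusim engine: ca_ds (CRU %d) negative at t=%g s", i + 1, t);
      if (ca_jsr[i] < 0)
        stop("crusim engine: ca_jsr (CRU %d) negative at t=%g s", i + 1, t);
    }

    ++n_steps; dt_sum += dt;
    if (dt < dt_minseen) dt_minseen = dt;
    if (dt > dt_maxseen) dt_maxseen = dt;

    while (t >= next_sample - 1e-12 && next_sample <= duration + 1e-12) record();

    dt = inc_viol_next ? std::max(dt * p.dt_shrink, p.dt_min)
                       : std::min(dt * p.dt_grow, p.dt_max);
    if (inc_viol_next) ++n_shrink_inc;
    if ((n_steps & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  CharacterVector cn = CharacterVector::create(
    "t", "v", "ca_myo", "ca_nsr", "i_lcc", "i_ncx", "i_dhpr_nj", "j_ryr",
    "j_serca", "total_ca", "cum_external", "cum_itotal_mv", "n_lcc_open",
    "n_ryr_open");
  NumericMatrix out_trim(n_samp, NC);
  for (int r = 0; r < n_samp; ++r)
    for (int c = 0; c < NC; ++c) out_trim(r, c) = out(r, c);
  colnames(out_trim) = cn;

  List rec = R_NilValue;
  if (n_rec > 0) {
    NumericMatrix cads_t(n_samp, n_rec), cajsr_t(n_samp, n_rec);
    IntegerMatrix nryr_t(n_samp, n_rec), nlcc_t(n_samp, n_rec);
    for (int r = 0; r < n_samp; ++r)
      for (int j = 0; j < n_rec; ++j) {
        cads_t(r, j) = rec_cads(r, j); cajsr_t(r, j) = rec_cajsr(r, j);
        nryr_t(r, j) = rec_nryr(r, j); nlcc_t(r, j) = rec_nlcc(r, j);
      }
    rec = List::create(_["ids"] = seq_len(n_rec), _["ca_ds"] = cads_t,
                       _["ca_jsr"] = cajsr_t, _["n_ryr_open"] = nryr_t,
                       _["n_lcc_open"] = nlcc_t);
  }

  List stats = List::create(
    _["n_steps"] = (double) n_steps,
    _["n_reject_frac"] = (double) n_rej_frac,
    _["n_reject_neg"] = (double) n_rej_inc,
    _["n_shrink_inc"] = (double) n_shrink_inc,
    _["n_accepted_over_rule"] = (double) n_over_rule,
    _["dt_mean"] = n_steps > 0 ? dt_sum / n_steps : NA_REAL,
    _["dt_min_seen"] = dt_minseen, _["dt_max_seen"] = dt_maxseen);

  return List::create(_["ts"] = out_trim, _["cru"] = rec, _["stats"] = stats,
                      _["final_v"] = v, _["final_ca_myo"] = ca_myo,
                      _["final_ca_nsr"] = ca_nsr, _["final_na_i"] = na_i,
                      _["final_k_i"] = k_i);
}

// --------------------------------------------- single-channel occupancy ----
// [[Rcpp::export]]
IntegerVector cpp_lcc_occupancy(NumericMatrix Q, int n_samples,
                                double sample_every, double dt, int seed,
                                int init) {
  SiteRng g(mix_seed((uint64_t) seed, 0));
  int s = init - 1;
  IntegerVector counts(6);
  int steps_per_sample = (int) std::round(sample_every / dt);
  for (int k = 0; k < n_samples; ++k) {
    for (int st = 0; st < steps_per_sample; ++st) {
      double rtot = -Q(s, s);
      if (rtot <= 0) continue;
      double u = g.unif();
      double pp = pstep(rtot * dt);
      if (u < pp) {
        double w = u / pp * rtot, cum = 0;
        for (int d = 0; d < 6; ++d) {
          if (d == s) continue;
          cum += Q(s, d);
          if (w < cum) { s = d; break; }
        }
      }
    }
    counts[s] += 1;
  }
  return counts;
}

// ----------------------------------------- clamped RyR2 cluster (Euler) ----
// [[Rcpp::export]]
List cpp_ryr_cluster_clamped(double ca_ds, double ca_jsr, List ryr,
                             double duration, double dt, int seed,
                             double sample_every) {
  Params p;  // only the RyR fields are used
  p.ry_kopen = gd(ryr, "k_open_base"); p.ry_cahalf = gd(ryr, "ca_half");
  p.ry_hill = gd(ryr, "hill"); p.ry_lumfloor = gd(ryr, "lum_floor");
  p.ry_lumgain = gd(ryr, "luminal_gain"); p.ry_lumhalf = gd(ryr, "lum_half");
  p.ry_lumhill = gd(ryr, "lum_hill"); p.ry_coup = gd(ryr, "coupling_strength");
  p.ry_kclose = gd(ryr, "k_close"); p.n_ryr = as<int>(ryr["n_ryr"]);
  SiteRng g(mix_seed((uint64_t) seed, 0));
  int n = 0;
  const int NR = p.n_ryr;
  long nsteps = (long) std::round(duration / dt);
  long per_samp = std::max((long) std::round(sample_every / dt), 1L);
  double open_time = 0.0;
  double first_open = -1.0;
  std::vector<int> samples;
  samples.reserve((size_t) (nsteps / per_samp) + 2);
  double pc = pstep(p.ry_kclose * dt);
  for (long st = 0; st < nsteps; ++st) {
    double f = (double) n / NR;
    double ko = ryr_kopen(p, ca_ds, ca_jsr, f);
    int up = binom_draw(NR - n, pstep(ko * dt), g);
    int dn = binom_draw(n, pc, g);
    n += up - dn;
    open_time += (double) n / NR * dt;
    if (first_open < 0 && n > 0) first_open = (st + 1) * dt;
    if ((st + 1) % per_samp == 0) samples.push_back(n);
  }
  return List::create(_["p_open"] = open_time / duration,
                      _["samples"] = wrap(samples),
                      _["first_open_t"] = first_open);
}
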