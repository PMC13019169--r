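// Rejection-free (BKL/Gillespie) kinetic Monte Carlo for the 2D Ising
// conformational-spread model on an L x L free-boundary lattice.
//
// Per event: one exponential waiting time from the total rate, one uniform
// draw to pick the event from a binary sum tree (O(log N) update/select).
// Spin flips re-rate only the flipped site and its <=4 neighbours; optional
// methylation dynamics enter the same event queue with per-site rates.
// Randomness comes from R's RNG so seeding via set.seed() at the R level
// gives bit-reproducible trajectories.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// Flat binary sum tree over n leaves (padded to a power of two).
struct SumTree {
  int npad;
  std::vector<double> t;
  void init(int nleaves) {
    npad = 1;
    while (npad < nleaves) npad <<= 1;
    t.assign(2 * npad, 0.0);
  }
  void set(int i, double v) {
    i += npad;
    t[i] = v;
    for (i >>= 1; i >= 1; i >>= 1) t[i] = t[2 * i] + t[2 * i + 1];
  }
  double total() const { return t[1]; }
  // Select leaf by cumulative weight; u in [0, total).
  int select(double u) const {
    int i = 1;
    while (i < npad) {
      i <<= 1;
      if (u >= t[i]) { u -= t[i]; ++i; }
    }
    return i - npad;
  }
};

struct Lattice {
  int L, N;
  double omega0, HL;
  std::vector<signed char> spin;      // +1 active, -1 inactive
  std::vector<double> hb;             // static per-site biasing field
  std::vector<double> Jright, Jdown;  // bond couplings (free boundaries)
  // adaptation
  bool adapt;
  double alpha, kR, kB;
  int M, m0;
  std::vector<int> m;
  SumTree tree;  // 2N leaves: [0,N) spin flips, [N,2N) methylation events
  int n_active;
  // fast path: homogeneous J, uniform field, no adaptation -> the flip rate
  // only depends on (sigma, sum of neighbour spins) and can be tabled
  bool fast;
  double Jglob;
  double rate_tab[2][9];  // [ (sigma+1)/2 ][ S + 4 ]

  int idx(int r, int c) const { return r * L + c; }

  double site_field(int i) const {
    double h = hb[i];
    if (adapt) h += alpha * (double)(m0 - m[i]);  // negative feedback
    return h;
  }

  void build_table() {
    for (int s = -1; s <= 1; s += 2)
      for (int S = -4; S <= 4; ++S)
        rate_tab[(s + 1) / 2][S + 4] =
            omega0 * std::exp(-s * Jglob * S + (hb[0] + HL) * 0.5 * s);
  }

  double flip_rate(int i) const {
    int r = i / L, c = i % L;
    if (fast) {
      int S = 0;
      if (c > 0)     S += spin[i - 1];
      if (c < L - 1) S += spin[i + 1];
      if (r > 0)     S += spin[i - L];
      if (r < L - 1) S += spin[i + L];
      return rate_tab[(spin[i] + 1) / 2][S + 4];
    }
    double nb = 0.0;
    if (c > 0)     nb += Jright[idx(r, c - 1)] * spin[i - 1];
    if (c < L - 1) nb += Jright[i] * spin[i + 1];
    if (r > 0)     nb += Jdown[idx(r - 1, c)] * spin[i - L];
    if (r < L - 1) nb += Jdown[i] * spin[i + L];
    double s = (double)spin[i];
    return omega0 * std::exp(-s * nb + (site_field(i) + HL) * 0.5 * s);
  }

  double meth_rate(int i) const {
    if (!adapt) return 0.0;
    if (spin[i] > 0) return (m[i] > 0) ? kB * omega0 : 0.0;   // active: demethylate
    return (m[i] < M) ? kR * omega0 : 0.0;                    // inactive: methylate
  }

  void rerate_site(int i) { tree.set(i, flip_rate(i)); }
  void rerate_meth(int i) { if (adapt) tree.set(N + i, meth_rate(i)); }

  void rerate_all() {
    if (fast) build_table();  // the ligand field may have changed
    for (int i = 0; i < N; ++i) {
      tree.set(i, flip_rate(i));
      if (adapt) tree.set(N + i, meth_rate(i));
    }
  }

  void do_flip(int i) {
    spin[i] = -spin[i];
    n_active += (spin[i] > 0) ? 1 : -1;
    int r = i / L, c = i % L;
    rerate_site(i);
    if (c > 0)     rerate_site(i - 1);
    if (c < L - 1) rerate_site(i + 1);
    if (r > 0)     rerate_site(i - L);
    if (r < L - 1) rerate_site(i + L);
    rerate_meth(i);  // eligibility flips with activity
  }

  void do_meth(int i) {
    m[i] += (spin[i] > 0) ? -1 : 1;  // active loses, inactive gains
    rerate_site(i);                  // field changed at site i only
    rerate_meth(i);
  }
};

void build_lattice(Lattice &lat, int L, IntegerVector spins0, double omega0,
                   double HL0, NumericVector site_bias, double Jglobal,
                   IntegerVector species, double J_same, double J_cross,
                   bool adapt, double alpha, int M, int m0, double kR,
                   double kB, IntegerVector m_init) {
  lat.L = L;
  lat.N = L * L;
  lat.omega0 = omega0;
  lat.HL = HL0;
  lat.adapt = adapt;
  lat.alpha = alpha;
  lat.M = M;
  lat.m0 = m0;
  lat.kR = kR;
  lat.kB = kB;
  lat.spin.resize(lat.N);
  for (int i = 0; i < lat.N; ++i) lat.spin[i] = (signed char)spins0[i];
  lat.hb.assign(lat.N, 0.0);
  if (site_bias.size() == lat.N)
    for (int i = 0; i < lat.N; ++i) lat.hb[i] = site_bias[i];
  lat.Jright.assign(lat.N, Jglobal);
  lat.Jdown.assign(lat.N, Jglobal);
  if (species.size() == lat.N) {
    for (int r = 0; r < L; ++r)
      for (int c = 0; c < L; ++c) {
        int i = lat.idx(r, c);
        if (c < L - 1)
          lat.Jright[i] = (species[i] == species[i + 1]) ? J_same : J_cross;
        if (r < L - 1)
          lat.Jdown[i] = (species[i] == species[i + L]) ? J_same : J_cross;
      }
  }
  lat.m.assign(lat.N, m0);
  if (m_init.size() == lat.N)
    for (int i = 0; i < lat.N; ++i) lat.m[i] = m_init[i];
  lat.Jglob = Jglobal;
  bool uniform_h = true;
  for (int i = 1; i < lat.N; ++i)
    if (lat.hb[i] != lat.hb[0]) { uniform_h = false; break; }
  lat.fast = !adapt && species.size() != lat.N && uniform_h;
  if (lat.fast) lat.build_table();
  lat.n_active = 0;
  for (int i = 0; i < lat.N; ++i)
    if (lat.spin[i] > 0) ++lat.n_active;
  lat.tree.init(adapt ? 2 * lat.N : lat.N);
  lat.rerate_all();
}

}  // namespace

// [[Rcpp::export(name = ".cs_simulate")]]
List cs_simulate(int L, IntegerVector spins0, double J, double Hb_global,
                 NumericVector site_bias, double HL0, double omega0,
                 double duration, double sample_interval,
                 IntegerVector species, double J_same, double J_cross,
                 bool adapt, double alpha, int M, int m0, double kR,
                 double kB, IntegerVector m_init, NumericVector prot_t,
                 NumericVector prot_dH, double max_events,
                 bool keep_mean_m) {
  if (L < 2) stop("L must be >= 2");
  if (duration <= 0 || sample_interval <= 0 || duration < sample_interval)
    stop("need duration > sample_interval > 0");

  // fold the uniform biasing field into the per-site static field
  NumericVector hb_site(L * L, Hb_global);
  if (site_bias.size() == L * L)
    for (int i = 0; i < L * L; ++i) hb_site[i] += site_bias[i];

  Lattice lat;
  build_lattice(lat, L, spins0, omega0, HL0, hb_site, J, species, J_same,
                J_cross, adapt, alpha, M, m0, kR, kB, m_init);

  int n_samples = (int)std::floor(duration / sample_interval) + 1;
  NumericVector times(n_samples), activity(n_samples);
  NumericVector mean_m(keep_mean_m && adapt ? n_samples : 0);
  long long msum = 0;
  if (lat.adapt) for (int i = 0; i < lat.N; ++i) msum += lat.m[i];

  double t = 0.0;
  int s = 0;         // next sample index
  int p = 0;         // next protocol step
  double n_ev = 0.0;
  const double invN = 1.0 / (double)lat.N;

  while (s < n_samples) {
    double total = lat.tree.total();
    if (!(total > 0.0)) stop("total event rate vanished");
    double wait = R::exp_rand() / total;
    double t_next = t + wait;

    // ligand-field protocol step before the next event: advance to the
    // step time, re-rate, and redraw (exact for exponential waiting times)
    if (p < prot_t.size() && prot_t[p] < t_next) {
      double tp = prot_t[p];
      while (s < n_samples && s * sample_interval <= tp) {
        times[s] = s * sample_interval;
        activity[s] = 0.5 * (1.0 + ((double)(2 * lat.n_active - lat.N)) * invN);
        if (mean_m.size()) mean_m[s] = (double)msum * invN;
        ++s;
      }
      t = tp;
      lat.HL += prot_dH[p];
      ++p;
      lat.rerate_all();
      continue;
    }

    // emit samples strictly before the event (piecewise-constant read-out)
    while (s < n_samples && s * sample_interval < t_next) {
      times[s] = s * sample_interval;
      activity[s] = (double)lat.n_active * invN;
      if (mean_m.size()) mean_m[s] = (double)msum * invN;
      ++s;
    }
    if (s >= n_samples || t_next > duration) {
      // fill any trailing samples with the final state
      while (s < n_samples) {
        times[s] = s * sample_interval;
        activity[s] = (double)lat.n_active * invN;
        if (mean_m.size()) mean_m[s] = (double)msum * invN;
        ++s;
      }
      t = std::min(t_next, duration);
      break;
    }

    t = t_next;
    double u = unif_rand() * total;
    int e = lat.tree.select(u);
    if (e >= 2 * lat.N) e = 2 * lat.N - 1;  // guard fp edge
    if (e < lat.N) {
      lat.do_flip(e);
    } else {
      int i = e - lat.N;
      msum += (lat.spin[i] > 0) ? -1 : 1;
      lat.do_meth(i);
    }
    n_ev += 1.0;
    if (n_ev >= max_events) {
      while (s < n_samples) {
        times[s] = s * sample_interval;
        activity[s] = (double)lat.n_active * invN;
        if (mean_m.size()) mean_m[s] = (double)msum * invN;
        ++s;
      }
      break;
    }
  }

  IntegerVector fs(lat.N), fm(lat.N);
  for (int i = 0; i < lat.N; ++i) {
    fs[i] = lat.spin[i];
    fm[i] = lat.m[i];
  }
  return List::create(_["times"] = times, _["activity"] = activity,
                      _["mean_m"] = mean_m, _["final_spins"] = fs,
                      _["final_m"] = fm, _["n_events"] = n_ev,
                      _["final_time"] = t, _["final_HL"] = lat.HL);
}

// Full-crossing switching extractor for (noise-free) simulated activity
// traces. Events are alternating complete crossings between the low band
// (a < th_lo) and the high band (a > th_hi); for each event it records the
// last time the trace sat in the source band (transition start), the first
// mid-crossing (event time) and the first time it reaches the target band
// (transition end). state0 carries the hysteresis state across chunks.
// [[Rcpp::export(name = ".cs_crossings")]]
List cs_crossings(NumericVector t, NumericVector a, double th_lo,
                  double th_hi, double mid) {
  int n = a.size();
  std::vector<double> t_start, t_mid, t_end;
  std::vector<int> dir;
  int st = 0;
  double last_in_band = NA_REAL, crossed_mid = NA_REAL;
  for (int i = 0; i < n; ++i) {
    double x = a[i];
    if (st == 0) {
      if (x > th_hi) { st = 1; last_in_band = t[i]; }
      else if (x < th_lo) { st = -1; last_in_band = t[i]; }
      continue;
    }
    if (st == 1) {
      if (x > th_hi) { last_in_band = t[i]; crossed_mid = NA_REAL; }
      else {
        if (ISNA(crossed_mid) && x < mid) crossed_mid = t[i];
        if (x < th_lo) {
          dir.push_back(-1); t_start.push_back(last_in_band);
          t_mid.push_back(ISNA(crossed_mid) ? t[i] : crossed_mid);
          t_end.push_back(t[i]);
          st = -1; last_in_band = t[i]; crossed_mid = NA_REAL;
        }
      }
    } else {
      if (x < th_lo) { last_in_band = t[i]; crossed_mid = NA_REAL; }
      else {
        if (ISNA(crossed_mid) && x > mid) crossed_mid = t[i];
        if (x > th_hi) {
          dir.push_back(1); t_start.push_back(last_in_band);
          t_mid.push_back(ISNA(crossed_mid) ? t[i] : crossed_mid);
          t_end.push_back(t[i]);
          st = 1; last_in_band = t[i]; crossed_mid = NA_REAL;
        }
      }
    }
  }
  return List::create(_["t_start"] = wrap(t_start), _["t_event"] = wrap(t_mid),
                      _["t_end"] = wrap(t_end), _["direction"] = wrap(dir));
}

// Time-weighted occupancy of every configuration of a tiny lattice (L <= 3),
// indexed by the bitmask sum_i a_i 2^i (row-major). Oracle companion for the
// exact Boltzmann enumeration.
// [[Rcpp::export(name = ".cs_occupancy")]]
NumericVector cs_occupancy(int L, IntegerVector spins0, double J, double Hb,
                           double HL, double omega0, double n_events) {
  if (L < 2 || L > 3) stop("occupancy tracking is limited to L in {2, 3}");
  NumericVector hb(L * L, Hb);
  Lattice lat;
  build_lattice(lat, L, spins0, omega0, HL, hb, J, IntegerVector(0), 0.0, 0.0,
                false, 0.0, 0, 0, 0.0, 0.0, IntegerVector(0));
  int N = lat.N;
  unsigned int code = 0;
  for (int i = 0; i < N; ++i)
    if (lat.spin[i] > 0) code |= (1u << i);
  NumericVector occ(1 << N, 0.0);
  for (double ev = 0; ev < n_events; ++ev) {
    double total = lat.tree.total();
    double wait = R::exp_rand() / total;
    occ[code] += wait;
    int e = lat.tree.select(unif_rand() * total);
    if (e >= N) e = N - 1;
    lat.do_flip(e);
    code ^= (1u << e);
  }
  double z = 0.0;
  for (double v : occ) z += v;
  for (int i = 0; i < occ.size(); ++i) occ[i] /= z;
  return occ;
}
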