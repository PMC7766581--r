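// Monte Carlo core: energy model, displacement/pivot moves, parallel
// tempering driver and simulated annealing for the FENE/LJ bead-spring
// chain with bending stiffness. Reduced units (eps_LJ = r0 = kB = 1 by
// default, but all scales are taken from the parameter list).
//
// RNG is self-contained (xoshiro256++ seeded via splitmix64) so that runs
// are reproducible from a single master seed independently of R's RNG
// state: one stream per temperature thread plus one for the exchange
// scheduler.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------- RNG ----

static inline uint64_t splitmix64(uint64_t &z) {
  z += 0x9e3779b97f4a7c15ULL;
  uint64_t t = z;
  t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
  t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
  return t ^ (t >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(z);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }  // [0, 1)
  inline int unif_int(int n) {
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

// thread k of a run gets stream seed derived from (master, k)
static inline uint64_t stream_seed(double master, int k) {
  uint64_t z = (uint64_t)master;
  z ^= 0x5851f42d4c957f2dULL * (uint64_t)(k + 1);
  uint64_t s = splitmix64(z);
  return s;
}

// -------------------------------------------------------------- model ----

struct Model {
  double eps, r0, sigma, sig6, rc, rc2, vshift, Rf, Kf, kappa, theta0, kB;
  int N;
};

static Model model_from_list(const List &p) {
  Model m;
  m.eps    = as<double>(p["epsilon_lj"]);
  m.r0     = as<double>(p["r0"]);
  m.sigma  = as<double>(p["sigma"]);
  m.rc     = as<double>(p["r_cutoff"]);
  m.vshift = as<double>(p["v_shift"]);
  m.Rf     = as<double>(p["fene_R"]);
  m.Kf     = as<double>(p["fene_K"]);
  m.kappa  = as<double>(p["kappa"]);
  m.theta0 = as<double>(p["theta0"]);
  m.kB     = as<double>(p["kB"]);
  m.N      = as<int>(p["n_monomers"]);
  m.sig6   = std::pow(m.sigma, 6);
  m.rc2    = m.rc * m.rc;
  return m;
}

static inline double vlj_r2(const Model &m, double r2) {
  double x6 = m.sig6 / (r2 * r2 * r2);
  return 4.0 * m.eps * (x6 * x6 - x6);
}

static inline double vnb_r2(const Model &m, double r2) {
  if (r2 >= m.rc2) return 0.0;
  return vlj_r2(m, r2) - m.vshift;
}

static inline double vbond(const Model &m, double r) {
  double q = (r - m.r0) / m.Rf;
  double one = 1.0 - q * q;
  if (one <= 0.0) return INF;
  return -0.5 * m.Kf * m.Rf * m.Rf * std::log(one) + vlj_r2(m, r * r) - m.vshift;
}

static inline double vbend_from_cos(const Model &m, double cth) {
  if (cth > 1.0) cth = 1.0;
  if (cth < -1.0) cth = -1.0;
  if (m.theta0 == 0.0) return m.kappa * (1.0 - cth);
  double th = std::acos(cth);
  return m.kappa * (1.0 - std::cos(th - m.theta0));
}

// positions: flat vector, monomer i at p[3i], p[3i+1], p[3i+2]
typedef std::vector<double> Pos;

static inline double dist2(const Pos &p, int i, int j) {
  double dx = p[3 * i] - p[3 * j];
  double dy = p[3 * i + 1] - p[3 * j + 1];
  double dz = p[3 * i + 2] - p[3 * j + 2];
  return dx * dx + dy * dy + dz * dz;
}

// cosine of the bend angle at interior monomer l (angle between bond
// vectors b_{l-1} = r_l - r_{l-1} and b_l = r_{l+1} - r_l; 0 = straight)
static inline double cos_bend(const Pos &p, int l) {
  double ax = p[3 * l] - p[3 * (l - 1)];
  double ay = p[3 * l + 1] - p[3 * (l - 1) + 1];
  double az = p[3 * l + 2] - p[3 * (l - 1) + 2];
  double bx = p[3 * (l + 1)] - p[3 * l];
  double by = p[3 * (l + 1) + 1] - p[3 * l + 1];
  double bz = p[3 * (l + 1) + 2] - p[3 * l + 2];
  double na = std::sqrt(ax * ax + ay * ay + az * az);
  double nb = std::sqrt(bx * bx + by * by + bz * bz);
  return (ax * bx + ay * by + az * bz) / (na * nb);
}

static void total_energy_components(const Pos &p, const Model &m, double out[4]) {
  int N = m.N;
  double enb = 0.0, eb = 0.0, ebend = 0.0;
  for (int i = 2; i < N; ++i)
    for (int j = 0; j < i - 1; ++j)
      enb += vnb_r2(m, dist2(p, i, j));
  for (int i = 0; i < N - 1; ++i) {
    double vb = vbond(m, std::sqrt(dist2(p, i, i + 1)));
    if (!std::isfinite(vb)) { out[0] = enb; out[1] = INF; out[2] = ebend; out[3] = INF; return; }
    eb += vb;
  }
  if (m.kappa != 0.0)
    for (int l = 1; l < N - 1; ++l)
      ebend += vbend_from_cos(m, cos_bend(p, l));
  out[0] = enb; out[1] = eb; out[2] = ebend; out[3] = enb + eb + ebend;
}

static inline double total_energy(const Pos &p, const Model &m) {
  double out[4];
  total_energy_components(p, m, out);
  return out[3];
}

// energy terms touching monomer i (for displacement deltas): non-bonded
// pairs (i, j) with |i-j| >= 2, bonds (i-1,i), (i,i+1), bends at i-1, i, i+1
static double local_energy(const Pos &p, const Model &m, int i) {
  int N = m.N;
  double e = 0.0;
  for (int j = 0; j < N; ++j) {
    if (j == i || j == i - 1 || j == i + 1) continue;
    e += vnb_r2(m, dist2(p, i, j));
  }
  if (i > 0) {
    double vb = vbond(m, std::sqrt(dist2(p, i - 1, i)));
    if (!std::isfinite(vb)) return INF;
    e += vb;
  }
  if (i < N - 1) {
    double vb = vbond(m, std::sqrt(dist2(p, i, i + 1)));
    if (!std::isfinite(vb)) return INF;
    e += vb;
  }
  if (m.kappa != 0.0) {
    for (int l = i - 1; l <= i + 1; ++l)
      if (l >= 1 && l <= N - 2) e += vbend_from_cos(m, cos_bend(p, l));
  }
  return e;
}

// Rodrigues rotation of point v about unit axis u by angle phi
static inline void rotate_about(double *v, const double *u, double cphi, double sphi) {
  double ux = u[0], uy = u[1], uz = u[2];
  double x = v[0], y = v[1], z = v[2];
  double dot = ux * x + uy * y + uz * z;
  double cx = uy * z - uz * y, cy = uz * x - ux * z, cz = ux * y - uy * x;
  v[0] = x * cphi + cx * sphi + ux * dot * (1.0 - cphi);
  v[1] = y * cphi + cy * sphi + uy * dot * (1.0 - cphi);
  v[2] = z * cphi + cz * sphi + uz * dot * (1.0 - cphi);
}

// rotate tail i+1..N-1 about axis through monomer i; result in `tail`
// (tail[0..2] = new position of monomer i+1, ...)
static void pivot_tail(const Pos &p, int i, const double *axis, double phi,
                       std::vector<double> &tail) {
  int N = (int)p.size() / 3;
  double cphi = std::cos(phi), sphi = std::sin(phi);
  tail.resize(3 * (N - i - 1));
  for (int j = i + 1; j < N; ++j) {
    double v[3] = {p[3 * j] - p[3 * i], p[3 * j + 1] - p[3 * i + 1],
                   p[3 * j + 2] - p[3 * i + 2]};
    rotate_about(v, axis, cphi, sphi);
    tail[3 * (j - i - 1)]     = v[0] + p[3 * i];
    tail[3 * (j - i - 1) + 1] = v[1] + p[3 * i + 1];
    tail[3 * (j - i - 1) + 2] = v[2] + p[3 * i + 2];
  }
}

// delta for a pivot at monomer i (0-based interior, 1..N-2): bend at i plus
// non-bonded pairs straddling the pivot. Bond lengths and all other angles
// are preserved by the rigid rotation.
static double pivot_delta(const Pos &p, const Model &m, int i,
                          const std::vector<double> &tail) {
  int N = m.N;
  double d = 0.0;
  // straddling non-bonded pairs: j <= i, k >= i+1, k - j >= 2
  for (int j = 0; j <= i; ++j) {
    double pj0 = p[3 * j], pj1 = p[3 * j + 1], pj2 = p[3 * j + 2];
    for (int k = std::max(i + 1, j + 2); k < N; ++k) {
      int t = 3 * (k - i - 1);
      double dx = pj0 - p[3 * k], dy = pj1 - p[3 * k + 1], dz = pj2 - p[3 * k + 2];
      double r2old = dx * dx + dy * dy + dz * dz;
      dx = pj0 - tail[t]; dy = pj1 - tail[t + 1]; dz = pj2 - tail[t + 2];
      double r2new = dx * dx + dy * dy + dz * dz;
      d += vnb_r2(m, r2new) - vnb_r2(m, r2old);
    }
  }
  if (m.kappa != 0.0 && i >= 1 && i <= N - 2) {
    double ax = p[3 * i] - p[3 * (i - 1)];
    double ay = p[3 * i + 1] - p[3 * (i - 1) + 1];
    double az = p[3 * i + 2] - p[3 * (i - 1) + 2];
    double bx_old = p[3 * (i + 1)] - p[3 * i];
    double by_old = p[3 * (i + 1) + 1] - p[3 * i + 1];
    double bz_old = p[3 * (i + 1) + 2] - p[3 * i + 2];
    double bx_new = tail[0] - p[3 * i];
    double by_new = tail[1] - p[3 * i + 1];
    double bz_new = tail[2] - p[3 * i + 2];
    double na = std::sqrt(ax * ax + ay * ay + az * az);
    double nb_old = std::sqrt(bx_old * bx_old + by_old * by_old + bz_old * bz_old);
    double nb_new = std::sqrt(bx_new * bx_new + by_new * by_new + bz_new * bz_new);
    double c_old = (ax * bx_old + ay * by_old + az * bz_old) / (na * nb_old);
    double c_new = (ax * bx_new + ay * by_new + az * bz_new) / (na * nb_new);
    d += vbend_from_cos(m, c_new) - vbend_from_cos(m, c_old);
  }
  return d;
}

static inline bool metropolis(double delta, double kBT, Xoshiro &rng) {
  if (!std::isfinite(delta)) return false;
  if (delta <= 0.0) return true;
  return rng.unif() < std::exp(-delta / kBT);
}

static double rg2_of(const Pos &p, int N) {
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < N; ++i) { cx += p[3 * i]; cy += p[3 * i + 1]; cz += p[3 * i + 2]; }
  cx /= N; cy /= N; cz /= N;
  double s = 0;
  for (int i = 0; i < N; ++i) {
    double dx = p[3 * i] - cx, dy = p[3 * i + 1] - cy, dz = p[3 * i + 2] - cz;
    s += dx * dx + dy * dy + dz * dz;
  }
  return s / N;
}

// one displacement sweep (N attempted single-monomer moves)
static void displacement_sweep(Pos &p, double &E, const Model &m, double kBT,
                               double rd, Xoshiro &rng, long &acc, long &att) {
  int N = m.N;
  for (int t = 0; t < N; ++t) {
    int i = rng.unif_int(N);
    double old_local = local_energy(p, m, i);
    double ox = p[3 * i], oy = p[3 * i + 1], oz = p[3 * i + 2];
    p[3 * i]     = ox + rd * (rng.unif() - 0.5);
    p[3 * i + 1] = oy + rd * (rng.unif() - 0.5);
    p[3 * i + 2] = oz + rd * (rng.unif() - 0.5);
    double delta = local_energy(p, m, i) - old_local;
    ++att;
    if (metropolis(delta, kBT, rng)) {
      E += delta;
      ++acc;
    } else {
      p[3 * i] = ox; p[3 * i + 1] = oy; p[3 * i + 2] = oz;
    }
  }
}

static void random_unit_vector(Xoshiro &rng, double *u) {
  // Marsaglia rejection on the unit disc
  double a, b, s;
  do {
    a = 2.0 * rng.unif() - 1.0;
    b = 2.0 * rng.unif() - 1.0;
    s = a * a + b * b;
  } while (s >= 1.0 || s == 0.0);
  double f = 2.0 * std::sqrt(1.0 - s);
  u[0] = a * f; u[1] = b * f; u[2] = 1.0 - 2.0 * s;
}

// one pivot sweep (N-2 attempted tail rotations); no-op for N < 3
static void pivot_sweep(Pos &p, double &E, const Model &m, double kBT,
                        Xoshiro &rng, long &acc, long &att,
                        std::vector<double> &tail) {
  int N = m.N;
  if (N < 3) return;
  for (int t = 0; t < N - 2; ++t) {
    int i = 1 + rng.unif_int(N - 2);  // interior monomer, 0-based
    double axis[3];
    random_unit_vector(rng, axis);
    double phi = 2.0 * M_PI * rng.unif();
    pivot_tail(p, i, axis, phi, tail);
    double delta = pivot_delta(p, m, i, tail);
    ++att;
    if (metropolis(delta, kBT, rng)) {
      E += delta;
      ++acc;
      std::copy(tail.begin(), tail.end(), p.begin() + 3 * (i + 1));
    }
  }
}

static Pos pos_from_matrix(const NumericMatrix &x) {
  int N = x.nrow();
  Pos p(3 * N);
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 3; ++c) p[3 * i + c] = x(i, c);
  return p;
}

static NumericMatrix pos_to_matrix(const Pos &p) {
  int N = (int)p.size() / 3;
  NumericMatrix x(N, 3);
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 3; ++c) x(i, c) = p[3 * i + c];
  return x;
}

// ---------------------------------------------------------- interface ----

// [[Rcpp::export]]
NumericVector cpp_total_energy(NumericMatrix pos, List params) {
  Model m = model_from_list(params);
  Pos p = pos_from_matrix(pos);
  double out[4];
  total_energy_components(p, m, out);
  return NumericVector::create(_["nonbonded"] = out[0], _["bonded"] = out[1],
                               _["bending"] = out[2], _["total"] = out[3]);
}

// [[Rcpp::export]]
double cpp_displacement_delta(NumericMatrix pos, List params, int i,
                              NumericVector shift) {
  Model m = model_from_list(params);
  Pos p = pos_from_matrix(pos);
  int i0 = i - 1;
  double before = local_energy(p, m, i0);
  p[3 * i0] += shift[0]; p[3 * i0 + 1] += shift[1]; p[3 * i0 + 2] += shift[2];
  double after = local_energy(p, m, i0);
  if (!std::isfinite(after)) return INF;
  return after - before;
}

// [[Rcpp::export]]
double cpp_pivot_delta(NumericMatrix pos, List params, int i,
                       NumericVector axis, double angle) {
  Model m = model_from_list(params);
  Pos p = pos_from_matrix(pos);
  int i0 = i - 1;
  double a[3] = {axis[0], axis[1], axis[2]};
  double na = std::sqrt(a[0] * a[0] + a[1] * a[1] + a[2] * a[2]);
  a[0] /= na; a[1] /= na; a[2] /= na;
  std::vector<double> tail;
  pivot_tail(p, i0, a, angle, tail);
  return pivot_delta(p, m, i0, tail);
}

// [[Rcpp::export]]
List cpp_calibrate_rd(NumericMatrix pos0, List params, double T, double rd0,
                      int trial_sweeps, double lo, double hi, double factor,
                      int max_rounds, double seed) {
  Model m = model_from_list(params);
  Pos p = pos_from_matrix(pos0);
  double E = total_energy(p, m);
  double kBT = m.kB * T;
  Xoshiro rng(stream_seed(seed, 0));
  double rd = rd0, acc_rate = NA_REAL;
  bool ok = false;
  int round = 0;
  for (round = 1; round <= max_rounds; ++round) {
    long acc = 0, att = 0;
    for (int s = 0; s < trial_sweeps; ++s)
      displacement_sweep(p, E, m, kBT, rd, rng, acc, att);
    acc_rate = (double)acc / (double)att;
    if (acc_rate >= lo && acc_rate <= hi) { ok = true; break; }
    if (acc_rate > hi) rd *= factor; else rd /= factor;
  }
  return List::create(_["rd"] = rd, _["acceptance"] = acc_rate,
                      _["rounds"] = round, _["converged"] = ok,
                      _["pos"] = pos_to_matrix(p));
}

// Parallel tempering driver. Threads are temperature slots; replicas
// (conformations) move between threads at exchange epochs. Histograms are
// accumulated every measurement sweep on a fixed uniform energy grid
// (out-of-range energies are clamped into the edge bins).
// [[Rcpp::export]]
List cpp_pt_run(NumericMatrix pos0, List params, NumericVector temps,
                NumericVector rd, IntegerVector disp_per_pivot,
                int therm_sweeps, int meas_sweeps, int exchange_period,
                int stride, double bin_lo, double bin_width, int n_bins,
                double seed) {
  Model m = model_from_list(params);
  int K = temps.size();
  int N = m.N;

  std::vector<Pos> pos(K, pos_from_matrix(pos0));
  std::vector<double> E(K);
  std::vector<Xoshiro> rng;
  rng.reserve(K + 1);
  for (int k = 0; k < K; ++k) rng.emplace_back(stream_seed(seed, k + 1));
  Xoshiro xrng(stream_seed(seed, 0));  // exchange scheduler stream
  for (int k = 0; k < K; ++k) E[k] = total_energy(pos[k], m);

  IntegerMatrix hist(n_bins, K);
  int n_rec = (stride > 0 && meas_sweeps > 0) ? meas_sweeps / stride : 0;
  NumericMatrix e_series(n_rec, K), rg2_series(n_rec, K);
  std::vector<long> acc_d(K, 0), att_d(K, 0), acc_p(K, 0), att_p(K, 0);
  std::vector<long> x_acc(std::max(K - 1, 0), 0), x_att(std::max(K - 1, 0), 0);
  std::vector<double> min_E(K, INF);
  std::vector<Pos> min_pos(K, Pos(3 * N, 0.0));
  std::vector<int> replica(K);       // replica id currently in thread k
  for (int k = 0; k < K; ++k) replica[k] = k;
  std::vector<int> rep_min_thread(K), rep_max_thread(K);
  for (int k = 0; k < K; ++k) { rep_min_thread[k] = k; rep_max_thread[k] = k; }
  std::vector<double> tail;

  long epoch = 0;
  int rec = 0;
  long total_sweeps = (long)therm_sweeps + (long)meas_sweeps;
  for (long s = 1; s <= total_sweeps; ++s) {
    bool measuring = s > therm_sweeps;
    for (int k = 0; k < K; ++k) {
      double kBT = m.kB * temps[k];
      displacement_sweep(pos[k], E[k], m, kBT, rd[k], rng[k], acc_d[k], att_d[k]);
      if (disp_per_pivot[k] > 0 && s % disp_per_pivot[k] == 0)
        pivot_sweep(pos[k], E[k], m, kBT, rng[k], acc_p[k], att_p[k], tail);
      if (E[k] < min_E[k]) { min_E[k] = E[k]; min_pos[k] = pos[k]; }
    }
    if (s % 1000 == 0)  // re-sync cached energies against accumulated drift
      for (int k = 0; k < K; ++k) E[k] = total_energy(pos[k], m);
    if (measuring) {
      long ms = s - therm_sweeps;
      for (int k = 0; k < K; ++k) {
        int b = (int)std::floor((E[k] - bin_lo) / bin_width);
        if (b < 0) b = 0;
        if (b >= n_bins) b = n_bins - 1;
        hist(b, k) += 1;
      }
      if (stride > 0 && ms % stride == 0 && rec < n_rec) {
        for (int k = 0; k < K; ++k) {
          e_series(rec, k) = E[k];
          rg2_series(rec, k) = rg2_of(pos[k], N);
        }
        ++rec;
      }
    }
    if (exchange_period > 0 && s % exchange_period == 0 && K > 1) {
      int parity = (int)(epoch % 2);
      ++epoch;
      for (int k = parity; k + 1 < K; k += 2) {
        double darg = (E[k] - E[k + 1]) *
          (1.0 / (m.kB * temps[k]) - 1.0 / (m.kB * temps[k + 1]));
        ++x_att[k];
        double u = xrng.unif();
        if (darg >= 0.0 || u < std::exp(darg)) {
          std::swap(pos[k], pos[k + 1]);
          std::swap(E[k], E[k + 1]);
          std::swap(replica[k], replica[k + 1]);
          ++x_acc[k];
        }
      }
      for (int k = 0; k < K; ++k) {
        int r = replica[k];
        if (k < rep_min_thread[r]) rep_min_thread[r] = k;
        if (k > rep_max_thread[r]) rep_max_thread[r] = k;
      }
    }
  }

  int gk = 0;
  for (int k = 1; k < K; ++k) if (min_E[k] < min_E[gk]) gk = k;
  List min_conf(K);
  for (int k = 0; k < K; ++k) min_conf[k] = pos_to_matrix(min_pos[k]);
  List final_conf(K);
  for (int k = 0; k < K; ++k) final_conf[k] = pos_to_matrix(pos[k]);

  NumericVector accd(K), accp(K), accx(std::max(K - 1, 0));
  for (int k = 0; k < K; ++k) {
    accd[k] = att_d[k] ? (double)acc_d[k] / att_d[k] : NA_REAL;
    accp[k] = att_p[k] ? (double)acc_p[k] / att_p[k] : NA_REAL;
  }
  for (int k = 0; k + 1 < K; ++k)
    accx[k] = x_att[k] ? (double)x_acc[k] / x_att[k] : NA_REAL;

  return List::create(
      _["hist"] = hist, _["e_series"] = e_series, _["rg2_series"] = rg2_series,
      _["min_energy"] = NumericVector(min_E.begin(), min_E.end()),
      _["min_conformations"] = min_conf, _["final_conformations"] = final_conf,
      _["global_min_thread"] = gk + 1,
      _["acc_displacement"] = accd, _["acc_pivot"] = accp,
      _["acc_exchange"] = accx,
      _["replica_min_thread"] = IntegerVector(rep_min_thread.begin(), rep_min_thread.end()) + 1,
      _["replica_max_thread"] = IntegerVector(rep_max_thread.begin(), rep_max_thread.end()) + 1,
      _["final_energy"] = NumericVector(E.begin(), E.end()));
}

// Fixed-temperature Metropolis run (used for equilibrium checks and as a
// building block); records E and Rgyr^2 every `stride` sweeps.
// [[Rcpp::export]]
List cpp_mc_fixed_t(NumericMatrix pos0, List params, double T, double rd,
                    int n_sweeps, int stride, int disp_per_pivot, double seed) {
  Model m = model_from_list(params);
  Pos p = pos_from_matrix(pos0);
  double E = total_energy(p, m);
  double kBT = m.kB * T;
  Xoshiro rng(stream_seed(seed, 1));
  long acc_d = 0, att_d = 0, acc_p = 0, att_p = 0;
  std::vector<double> tail;
  int n_rec = stride > 0 ? n_sweeps / stride : 0;
  NumericVector e_series(n_rec), rg2_series(n_rec);
  int rec = 0;
  for (int s = 1; s <= n_sweeps; ++s) {
    displacement_sweep(p, E, m, kBT, rd, rng, acc_d, att_d);
    if (disp_per_pivot > 0 && s % disp_per_pivot == 0)
      pivot_sweep(p, E, m, kBT, rng, acc_p, att_p, tail);
    if (s % 1000 == 0) E = total_energy(p, m);
    if (stride > 0 && s % stride == 0 && rec < n_rec) {
      e_series[rec] = E;
      rg2_series[rec] = rg2_of(p, m.N);
      ++rec;
    }
  }
  return List::create(
      _["e_series"] = e_series, _["rg2_series"] = rg2_series,
      _["final_pos"] = pos_to_matrix(p), _["final_energy"] = E,
      _["acc_displacement"] = att_d ? (double)acc_d / att_d : NA_REAL,
      _["acc_pivot"] = att_p ? (double)acc_p / att_p : NA_REAL);
}

// Simulated annealing: Metropolis dynamics over a decreasing temperature
// schedule with on-the-fly step-size adaptation; returns the best-ever
// conformation and energy.
// [[Rcpp::export]]
List cpp_anneal(NumericMatrix pos0, List params, NumericVector temps,
                int sweeps_per_stage, int disp_per_pivot, double rd0,
                double seed) {
  Model m = model_from_list(params);
  Pos p = pos_from_matrix(pos0);
  double E = total_energy(p, m);
  Xoshiro rng(stream_seed(seed, 1));
  std::vector<double> tail;
  double rd = rd0;
  Pos best_p = p;
  double best_E = E;
  int n_stages = temps.size();
  const int adapt_block = 100;
  for (int st = 0; st < n_stages; ++st) {
    double kBT = m.kB * temps[st];
    long acc_d = 0, att_d = 0, acc_p = 0, att_p = 0;
    for (int s = 1; s <= sweeps_per_stage; ++s) {
      displacement_sweep(p, E, m, kBT, rd, rng, acc_d, att_d);
      if (disp_per_pivot > 0 && s % disp_per_pivot == 0)
        pivot_sweep(p, E, m, kBT, rng, acc_p, att_p, tail);
      if (s % 500 == 0) E = total_energy(p, m);
      if (E < best_E) { best_E = E; best_p = p; }
      if (s % adapt_block == 0 && att_d > 0) {
        double a = (double)acc_d / att_d;
        if (a > 0.55 && rd < 2.0) rd *= 1.1;
        else if (a < 0.45 && rd > 1e-4) rd /= 1.1;
        acc_d = att_d = 0;
      }
    }
  }
  best_E = total_energy(best_p, m);
  return List::create(_["best_pos"] = pos_to_matrix(best_p),
                      _["best_energy"] = best_E,
                      _["final_pos"] = pos_to_matrix(p),
                      _["final_energy"] = total_energy(p, m),
                      _["final_rd"] = rd);
}
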