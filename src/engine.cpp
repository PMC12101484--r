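#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <utility>
#define RESTRICT __restrict__
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Deterministic RNG: xoshiro256++ seeded through splitmix64.  Self-contained
// so trajectories are bit-identical for a given seed regardless of R's RNG
// state or the C++ standard library's distribution implementations.
// ---------------------------------------------------------------------------
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  // uniform on (0,1): never exactly 0, safe for log()
  inline double unif() { return ((next() >> 11) + 1) * (1.0 / 9007199254740993.0); }
  bool have_spare = false;
  double spare = 0.0;
  inline double gauss() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925287 * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

static inline double mimg(double d, double L) { return d - L * std::nearbyint(d / L); }

// fast minimum image for |d| < 1.5 L (always true for wrapped coordinates)
static inline double mimg1(double d, double halfL, double L) {
  if (d > halfL) return d - L;
  if (d < -halfL) return d + L;
  return d;
}

// ---------------------------------------------------------------------------
// Simulation context
// ---------------------------------------------------------------------------
struct Ctx {
  int N = 0, bpc = 0, nch = 0;
  double L[3] = {0, 0, 0};
  double hL[3] = {0, 0, 0};
  double eps = 0.4, K = 40.0, R0 = 1.5, R0sq = 2.25, half_KR0sq = 45.0;
  double rc = 2.5, rc2 = 6.25, skin = 0.3, rlist = 2.8, rlist2 = 7.84;
  bool shift_lj = false;
  double ushift = 0.0;
  bool bonded_lj = true;
  double fclamp = -1.0;   // <= 0: no clamping
  bool all_pairs = false; // force O(N^2) neighbour enumeration (reference path)
  std::vector<double> x, v, f;
  std::vector<int> chain;        // per bead
  std::vector<uint8_t> act;      // per chain
  // neighbour (Verlet) list; per-pair periodic image shift (in units of L)
  // frozen at build time: a pair whose image could change between rebuilds
  // sits near half a box length away, far outside the cutoff either way
  std::vector<int> nb_i, nb_j;
  std::vector<signed char> nb_sx, nb_sy, nb_sz;
  std::vector<double> xref;
  double pe = 0.0;
};

static inline signed char im_shift(double raw, double halfL) {
  if (raw > halfL) return -1;
  if (raw < -halfL) return 1;
  return 0;
}

static void build_list(Ctx &c) {
  // positions are wrapped only here (and when snapshots are emitted):
  // between rebuilds coordinates evolve unwrapped, so raw pair
  // differences change continuously and the frozen image shifts and
  // displacement tracking stay exact
  for (int i = 0; i < c.N; ++i)
    for (int d = 0; d < 3; ++d)
      c.x[3 * i + d] = mimg(c.x[3 * i + d], c.L[d]);
  c.nb_i.clear();
  c.nb_j.clear();
  c.nb_sx.clear();
  c.nb_sy.clear();
  c.nb_sz.clear();
  const double r2max = c.rlist2;
  int nc[3];
  double cs[3];
  bool cells_ok = !c.all_pairs && c.N >= 256; // all-pairs wins for tiny systems
  for (int d = 0; d < 3; ++d) {
    nc[d] = (int)std::floor(c.L[d] / c.rlist);
    if (nc[d] < 3) cells_ok = false;
    cs[d] = c.L[d] / std::max(nc[d], 1);
  }
  if (!cells_ok) {
    for (int i = 0; i < c.N; ++i)
      for (int j = i + 1; j < c.N; ++j) {
        double rx = c.x[3 * i] - c.x[3 * j];
        double ry = c.x[3 * i + 1] - c.x[3 * j + 1];
        double rz = c.x[3 * i + 2] - c.x[3 * j + 2];
        double dx = mimg(rx, c.L[0]);
        double dy = mimg(ry, c.L[1]);
        double dz = mimg(rz, c.L[2]);
        if (dx * dx + dy * dy + dz * dz < r2max) {
          c.nb_i.push_back(i); c.nb_j.push_back(j);
          c.nb_sx.push_back(im_shift(rx, c.hL[0]));
          c.nb_sy.push_back(im_shift(ry, c.hL[1]));
          c.nb_sz.push_back(im_shift(rz, c.hL[2]));
        }
      }
  } else {
    int ncell = nc[0] * nc[1] * nc[2];
    std::vector<int> head(ncell, -1), nxt(c.N, -1), cellof(c.N);
    for (int i = 0; i < c.N; ++i) {
      int cx = (int)std::floor((c.x[3 * i] + 0.5 * c.L[0]) / cs[0]);
      int cy = (int)std::floor((c.x[3 * i + 1] + 0.5 * c.L[1]) / cs[1]);
      int cz = (int)std::floor((c.x[3 * i + 2] + 0.5 * c.L[2]) / cs[2]);
      if (cx < 0) cx = 0; if (cx >= nc[0]) cx = nc[0] - 1;
      if (cy < 0) cy = 0; if (cy >= nc[1]) cy = nc[1] - 1;
      if (cz < 0) cz = 0; if (cz >= nc[2]) cz = nc[2] - 1;
      int cc = (cz * nc[1] + cy) * nc[0] + cx;
      cellof[i] = cc;
      nxt[i] = head[cc];
      head[cc] = i;
    }
    // half stencil: self + 13 forward neighbour cells
    static const int off[14][3] = {
      {0, 0, 0}, {1, 0, 0}, {-1, 1, 0}, {0, 1, 0}, {1, 1, 0},
      {-1, -1, 1}, {0, -1, 1}, {1, -1, 1}, {-1, 0, 1}, {0, 0, 1},
      {1, 0, 1}, {-1, 1, 1}, {0, 1, 1}, {1, 1, 1}};
    for (int cz = 0; cz < nc[2]; ++cz)
      for (int cy = 0; cy < nc[1]; ++cy)
        for (int cx = 0; cx < nc[0]; ++cx) {
          int c1 = (cz * nc[1] + cy) * nc[0] + cx;
          for (int k = 0; k < 14; ++k) {
            int ox = (cx + off[k][0] + nc[0]) % nc[0];
            int oy = (cy + off[k][1] + nc[1]) % nc[1];
            int oz = (cz + off[k][2] + nc[2]) % nc[2];
            int c2 = (oz * nc[1] + oy) * nc[0] + ox;
            if (k > 0 && c2 == c1) continue; // degenerate wrap (small cell counts)
            for (int i = head[c1]; i >= 0; i = nxt[i]) {
              int jstart = (c2 == c1) ? nxt[i] : head[c2];
              for (int j = jstart; j >= 0; j = nxt[j]) {
                int a = i < j ? i : j;
                int b = i < j ? j : i;
                double rx = c.x[3 * a] - c.x[3 * b];
                double ry = c.x[3 * a + 1] - c.x[3 * b + 1];
                double rz = c.x[3 * a + 2] - c.x[3 * b + 2];
                double dx = mimg1(rx, c.hL[0], c.L[0]);
                double dy = mimg1(ry, c.hL[1], c.L[1]);
                double dz = mimg1(rz, c.hL[2], c.L[2]);
                if (dx * dx + dy * dy + dz * dz < r2max) {
                  c.nb_i.push_back(a);
                  c.nb_j.push_back(b);
                  c.nb_sx.push_back(im_shift(rx, c.hL[0]));
                  c.nb_sy.push_back(im_shift(ry, c.hL[1]));
                  c.nb_sz.push_back(im_shift(rz, c.hL[2]));
                }
              }
            }
          }
        }
  }
  c.xref = c.x;
}

static inline bool list_stale(const Ctx &c) {
  double lim = 0.25 * c.skin * c.skin; // (skin/2)^2
  for (int i = 0; i < c.N; ++i) {
    double dx = c.x[3 * i] - c.xref[3 * i];
    double dy = c.x[3 * i + 1] - c.xref[3 * i + 1];
    double dz = c.x[3 * i + 2] - c.xref[3 * i + 2];
    if (dx * dx + dy * dy + dz * dz > lim) return true;
  }
  return false;
}

// forces + potential energy; throws on overlap/overstretch
static void compute_forces(Ctx &c, double f_act, double bias_k, long step) {
  std::fill(c.f.begin(), c.f.end(), 0.0);
  c.pe = 0.0;
  const double eps = c.eps;
  const double L0 = c.L[0], L1 = c.L[1], L2 = c.L[2];
  const size_t np = c.nb_i.size();
  const int *RESTRICT pi = c.nb_i.data();
  const int *RESTRICT pj = c.nb_j.data();
  const signed char *RESTRICT sx = c.nb_sx.data();
  const signed char *RESTRICT sy = c.nb_sy.data();
  const signed char *RESTRICT sz = c.nb_sz.data();
  const double *RESTRICT X = c.x.data();
  double *RESTRICT F = c.f.data();
  for (size_t p = 0; p < np; ++p) {
    int i = pi[p], j = pj[p];
    double dx = X[3 * i] - X[3 * j] + sx[p] * L0;
    double dy = X[3 * i + 1] - X[3 * j + 1] + sy[p] * L1;
    double dz = X[3 * i + 2] - X[3 * j + 2] + sz[p] * L2;
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= c.rc2) continue;
    if (!c.bonded_lj && c.chain[i] == c.chain[j] && (j - i) == 1) continue;
    if (r2 < 1e-12)
      stop("singular overlap between beads %d and %d at step %ld", i + 1, j + 1, step);
    double sr2 = 1.0 / r2;
    double sr6 = sr2 * sr2 * sr2;
    double e = 4.0 * eps * (sr6 * sr6 - sr6);
    if (c.shift_lj) e -= c.ushift;
    double fr = 24.0 * eps * (2.0 * sr6 * sr6 - sr6) * sr2; // (F/r)
    if (c.fclamp > 0.0) {
      double r = std::sqrt(r2);
      double fmag = std::fabs(fr) * r;
      if (fmag > c.fclamp) fr = (fr > 0 ? 1.0 : -1.0) * c.fclamp / r;
    }
    c.pe += e;
    F[3 * i] += fr * dx; F[3 * i + 1] += fr * dy; F[3 * i + 2] += fr * dz;
    F[3 * j] -= fr * dx; F[3 * j + 1] -= fr * dy; F[3 * j + 2] -= fr * dz;
  }
  // FENE bonds between consecutive beads of each chain
  for (int ch = 0; ch < c.nch; ++ch) {
    int base = ch * c.bpc;
    for (int k = 0; k < c.bpc - 1; ++k) {
      int i = base + k, j = base + k + 1;
      double dx = mimg1(c.x[3 * i] - c.x[3 * j], c.hL[0], c.L[0]);
      double dy = mimg1(c.x[3 * i + 1] - c.x[3 * j + 1], c.hL[1], c.L[1]);
      double dz = mimg1(c.x[3 * i + 2] - c.x[3 * j + 2], c.hL[2], c.L[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= c.R0sq)
        stop("FENE bond overstretched (r >= R0) on chain %d between beads %d and %d at step %ld",
             ch + 1, k + 1, k + 2, step);
      // never clamp the FENE restoring force: bonds must stay below R0
      double fr = -c.K / (1.0 - r2 / c.R0sq); // attractive: F_i = fr * dx
      c.pe += -c.half_KR0sq * std::log1p(-r2 / c.R0sq);
      c.f[3 * i] += fr * dx; c.f[3 * i + 1] += fr * dy; c.f[3 * i + 2] += fr * dz;
      c.f[3 * j] -= fr * dx; c.f[3 * j + 1] -= fr * dy; c.f[3 * j + 2] -= fr * dz;
    }
  }
  // constant active force along +z on the head (first) bead of active chains
  if (f_act != 0.0)
    for (int ch = 0; ch < c.nch; ++ch)
      if (c.act[ch]) c.f[3 * (ch * c.bpc) + 2] += f_act;
  // harmonic bias toward the box centre (origin), per bead
  if (bias_k > 0.0)
    for (int i = 0; i < 3 * c.N; ++i) {
      c.f[i] -= bias_k * c.x[i];
      c.pe += 0.5 * bias_k * c.x[i] * c.x[i];
    }
}

static Ctx make_ctx(NumericMatrix pos, NumericMatrix vel, IntegerVector chain,
                    LogicalVector active_chain, List par) {
  Ctx c;
  c.N = pos.nrow();
  c.nch = active_chain.size();
  c.bpc = c.N / c.nch;
  if (c.bpc * c.nch != c.N) stop("bead count is not a multiple of the chain count");
  NumericVector box = par["box"];
  for (int d = 0; d < 3; ++d) { c.L[d] = box[d]; c.hL[d] = 0.5 * box[d]; }
  c.eps = as<double>(par["epsilon"]);
  c.K = as<double>(par["fene_K"]);
  c.R0 = as<double>(par["fene_R0"]);
  c.R0sq = c.R0 * c.R0;
  c.half_KR0sq = 0.5 * c.K * c.R0sq;
  c.rc = as<double>(par["lj_cutoff"]);
  c.rc2 = c.rc * c.rc;
  c.shift_lj = as<bool>(par["shift_lj"]);
  double src6 = std::pow(1.0 / c.rc, 6.0);
  c.ushift = 4.0 * c.eps * (src6 * src6 - src6);
  c.bonded_lj = as<bool>(par["bonded_lj"]);
  c.skin = as<double>(par["skin"]);
  c.rlist = c.rc + c.skin;
  c.rlist2 = c.rlist * c.rlist;
  c.fclamp = as<double>(par["force_clamp"]);
  c.all_pairs = as<bool>(par["all_pairs"]);
  c.x.resize(3 * c.N); c.v.resize(3 * c.N); c.f.resize(3 * c.N);
  for (int i = 0; i < c.N; ++i)
    for (int d = 0; d < 3; ++d) {
      c.x[3 * i + d] = pos(i, d);
      c.v[3 * i + d] = vel(i, d);
    }
  c.chain.resize(c.N);
  for (int i = 0; i < c.N; ++i) c.chain[i] = chain[i] - 1; // 0-based internally
  c.act.resize(c.nch);
  for (int ch = 0; ch < c.nch; ++ch) c.act[ch] = active_chain[ch] ? 1 : 0;
  return c;
}

static NumericMatrix to_mat(const std::vector<double> &a, int N) {
  NumericMatrix m(N, 3);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) m(i, d) = a[3 * i + d];
  return m;
}

// positions snapshot, wrapped into the box
static NumericMatrix to_mat_wrapped(const std::vector<double> &a, int N,
                                    const double L[3]) {
  NumericMatrix m(N, 3);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) m(i, d) = mimg(a[3 * i + d], L[d]);
  return m;
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, NumericMatrix vel, IntegerVector chain,
                LogicalVector active_chain, List par, double f_act, double bias_k) {
  Ctx c = make_ctx(pos, vel, chain, active_chain, par);
  build_list(c);
  compute_forces(c, f_act, bias_k, 0);
  double ke = 0.0;
  for (int i = 0; i < 3 * c.N; ++i) ke += 0.5 * c.v[i] * c.v[i];
  return List::create(_["forces"] = to_mat(c.f, c.N),
                      _["potential"] = c.pe, _["kinetic"] = ke);
}

// ---------------------------------------------------------------------------
// BAOAB Langevin velocity-Verlet: B (half kick) A (half drift) O (exact
// Ornstein-Uhlenbeck with gamma = m/damping, kBT = m = 1) A (half drift)
// B (half kick).  damping <= 0 or non-finite disables the thermostat, in
// which case the scheme reduces to plain velocity-Verlet.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_simulate(NumericMatrix pos, NumericMatrix vel, IntegerVector chain,
                  LogicalVector active_chain, List par,
                  double nsteps_d, double dump_every_d, double f_act, double bias_k,
                  double seed, bool want_dumps, double thermo_every_d,
                  double step_offset_d) {
  Ctx c = make_ctx(pos, vel, chain, active_chain, par);
  long nsteps = (long)nsteps_d;
  long dump_every = (long)dump_every_d;
  long thermo_every = (long)thermo_every_d;
  long step0 = (long)step_offset_d;
  double dt = as<double>(par["dt"]);
  double damping = as<double>(par["damping"]);
  double gamma = (R_finite(damping) && damping > 0) ? 1.0 / damping : 0.0;
  double c1 = (gamma > 0) ? std::exp(-gamma * dt) : 1.0;
  double c2 = (gamma > 0) ? std::sqrt(1.0 - c1 * c1) : 0.0;
  Xoshiro rng((uint64_t)seed);

  build_list(c);
  compute_forces(c, f_act, bias_k, step0);

  List dumps;
  std::vector<long> dump_steps;
  std::vector<double> th_step, th_ke, th_pe;
  const double hdt = 0.5 * dt;

  auto record_dump = [&](long s) {
    if (!want_dumps) return;
    dumps.push_back(List::create(_["step"] = (double)s,
                                 _["positions"] = to_mat_wrapped(c.x, c.N, c.L),
                                 _["velocities"] = to_mat(c.v, c.N)));
    dump_steps.push_back(s);
  };
  auto record_thermo = [&](long s) {
    double ke = 0.0;
    for (int i = 0; i < 3 * c.N; ++i) ke += 0.5 * c.v[i] * c.v[i];
    th_step.push_back((double)s);
    th_ke.push_back(ke);
    th_pe.push_back(c.pe);
  };

  if (dump_every > 0) record_dump(step0);
  if (thermo_every > 0) record_thermo(step0);

  for (long s = 1; s <= nsteps; ++s) {
    for (int i = 0; i < 3 * c.N; ++i) c.v[i] += hdt * c.f[i];      // B
    for (int i = 0; i < c.N; ++i)                                   // A
      for (int d = 0; d < 3; ++d)
        c.x[3 * i + d] += hdt * c.v[3 * i + d];
    if (gamma > 0)                                                  // O
      for (int i = 0; i < 3 * c.N; ++i) c.v[i] = c1 * c.v[i] + c2 * rng.gauss();
    for (int i = 0; i < c.N; ++i)                                   // A
      for (int d = 0; d < 3; ++d)
        c.x[3 * i + d] += hdt * c.v[3 * i + d];
    if (list_stale(c)) build_list(c);
    compute_forces(c, f_act, bias_k, step0 + s);
    for (int i = 0; i < 3 * c.N; ++i) c.v[i] += hdt * c.f[i];      // B
    if (dump_every > 0 && s % dump_every == 0) record_dump(step0 + s);
    if (thermo_every > 0 && s % thermo_every == 0) record_thermo(step0 + s);
    if (s % 2000 == 0) {
      for (int i = 0; i < 3 * c.N; ++i)
        if (!R_finite(c.x[i]))
          stop("integration blow-up: non-finite coordinate at step %ld", step0 + s);
      Rcpp::checkUserInterrupt();
    }
  }
  double ke = 0.0;
  for (int i = 0; i < 3 * c.N; ++i) ke += 0.5 * c.v[i] * c.v[i];
  return List::create(
      _["positions"] = to_mat_wrapped(c.x, c.N, c.L),
      _["velocities"] = to_mat(c.v, c.N),
      _["dumps"] = dumps, _["dump_steps"] = wrap(dump_steps),
      _["potential"] = c.pe, _["kinetic"] = ke,
      _["thermo"] = DataFrame::create(_["step"] = wrap(th_step), _["kinetic"] = wrap(th_ke),
                                      _["potential"] = wrap(th_pe)));
}

// ---------------------------------------------------------------------------
// Single-linkage clustering of beads under the minimum-image metric
// (union-find over all pairs closer than `cutoff`).  Returns 1-based
// component labels per bead.
// ---------------------------------------------------------------------------
struct DSU {
  std::vector<int> p, r;
  explicit DSU(int n) : p(n), r(n, 0) { for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int a) { while (p[a] != a) { p[a] = p[p[a]]; a = p[a]; } return a; }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (r[a] < r[b]) std::swap(a, b);
    p[b] = a;
    if (r[a] == r[b]) ++r[a];
  }
};

// [[Rcpp::export]]
IntegerVector cpp_cluster_labels(NumericMatrix pos, NumericVector box, double cutoff) {
  int N = pos.nrow();
  if (N == 0) stop("empty state: no beads to cluster");
  double L[3] = {box[0], box[1], box[2]};
  double c2 = cutoff * cutoff;
  DSU dsu(N);
  // cell list at cell size >= cutoff
  int nc[3];
  double cs[3];
  bool cells_ok = N >= 256;
  for (int d = 0; d < 3; ++d) {
    nc[d] = (int)std::floor(L[d] / cutoff);
    if (nc[d] < 3) cells_ok = false;
    cs[d] = L[d] / std::max(nc[d], 1);
  }
  if (!cells_ok) {
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        double dx = mimg(pos(i, 0) - pos(j, 0), L[0]);
        double dy = mimg(pos(i, 1) - pos(j, 1), L[1]);
        double dz = mimg(pos(i, 2) - pos(j, 2), L[2]);
        if (dx * dx + dy * dy + dz * dz <= c2) dsu.unite(i, j);
      }
  } else {
    int ncell = nc[0] * nc[1] * nc[2];
    std::vector<int> head(ncell, -1), nxt(N, -1);
    std::vector<int> ci(N), cj(N), ck(N);
    for (int i = 0; i < N; ++i) {
      int cx = (int)std::floor((pos(i, 0) + 0.5 * L[0]) / cs[0]);
      int cy = (int)std::floor((pos(i, 1) + 0.5 * L[1]) / cs[1]);
      int cz = (int)std::floor((pos(i, 2) + 0.5 * L[2]) / cs[2]);
      if (cx < 0) cx = 0; if (cx >= nc[0]) cx = nc[0] - 1;
      if (cy < 0) cy = 0; if (cy >= nc[1]) cy = nc[1] - 1;
      if (cz < 0) cz = 0; if (cz >= nc[2]) cz = nc[2] - 1;
      ci[i] = cx; cj[i] = cy; ck[i] = cz;
      int cc = (cz * nc[1] + cy) * nc[0] + cx;
      nxt[i] = head[cc];
      head[cc] = i;
    }
    for (int i = 0; i < N; ++i)
      for (int ox = -1; ox <= 1; ++ox)
        for (int oy = -1; oy <= 1; ++oy)
          for (int oz = -1; oz <= 1; ++oz) {
            int cx = (ci[i] + ox + nc[0]) % nc[0];
            int cy = (cj[i] + oy + nc[1]) % nc[1];
            int cz = (ck[i] + oz + nc[2]) % nc[2];
            int cc = (cz * nc[1] + cy) * nc[0] + cx;
            for (int j = head[cc]; j >= 0; j = nxt[j]) {
              if (j <= i) continue;
              double dx = mimg(pos(i, 0) - pos(j, 0), L[0]);
              double dy = mimg(pos(i, 1) - pos(j, 1), L[1]);
              double dz = mimg(pos(i, 2) - pos(j, 2), L[2]);
              if (dx * dx + dy * dy + dz * dz <= c2) dsu.unite(i, j);
            }
          }
  }
  std::vector<int> lab(N, 0);
  int next_lab = 0;
  std::vector<int> seen;
  IntegerVector out(N);
  std::vector<int> map(N, -1);
  for (int i = 0; i < N; ++i) {
    int rr = dsu.find(i);
    if (map[rr] < 0) map[rr] = next_lab++;
    out[i] = map[rr] + 1;
  }
  return out;
}
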