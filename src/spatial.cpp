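// Spatial queries and Brownian radical transport on z-sorted site tables.
//
// Geometry here is one or more straight fibres laid along the z axis, so a
// 1-D index (sites sorted by z, binary search + expanding window) gives
// sublinear nearest-neighbour and fixed-radius queries without an external
// KD-tree dependency.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

static inline double sq(double v) { return v * v; }

// first index with z[i] >= value (z ascending)
static int lower_idx(const NumericVector& z, double value) {
  return (int)(std::lower_bound(z.begin(), z.end(), value) - z.begin());
}

// Nearest site to (qx,qy,qz) among sites sorted by z. prio breaks exact
// distance ties (lower wins). Returns 0-based index, dist via out param.
static int nearest_sorted(double qx, double qy, double qz,
                          const NumericVector& x, const NumericVector& y,
                          const NumericVector& z, const IntegerVector& prio,
                          double& best_d) {
  const int n = x.size();
  int lo = lower_idx(z, qz) - 1; // scan downward from here
  int hi = lo + 1;               // scan upward from here
  best_d = R_PosInf;
  int best = -1;
  const double tol = 1e-9;
  while (lo >= 0 || hi < n) {
    bool take_lo;
    if (lo < 0) take_lo = false;
    else if (hi >= n) take_lo = true;
    else take_lo = (qz - z[lo]) <= (z[hi] - qz);
    int i = take_lo ? lo : hi;
    double dz = z[i] - qz;
    if (best >= 0 && std::fabs(dz) > best_d + tol) break; // no closer z left
    double d = std::sqrt(sq(x[i] - qx) + sq(y[i] - qy) + sq(dz));
    if (d < best_d - tol ||
        (std::fabs(d - best_d) <= tol && best >= 0 && prio[i] < prio[best])) {
      best_d = d;
      best = i;
    } else if (best < 0) {
      best_d = d;
      best = i;
    }
    if (take_lo) --lo; else ++hi;
  }
  return best;
}

// any site within radius r of query point?
static bool within_any_sorted(double qx, double qy, double qz,
                              const NumericVector& x, const NumericVector& y,
                              const NumericVector& z, double r) {
  const int n = x.size();
  int i0 = lower_idx(z, qz - r);
  for (int i = i0; i < n && z[i] <= qz + r; ++i) {
    if (sq(x[i] - qx) + sq(y[i] - qy) + sq(z[i] - qz) <= r * r) return true;
  }
  return false;
}

// first site (by priority order of scan) whose per-site radius sphere
// contains the query; returns 0-based index of the CLOSEST contained site.
static int contained_in_sorted(double qx, double qy, double qz,
                               const NumericVector& x, const NumericVector& y,
                               const NumericVector& z, const NumericVector& r,
                               double rmax) {
  const int n = x.size();
  int i0 = lower_idx(z, qz - rmax);
  int best = -1;
  double best_d = R_PosInf;
  for (int i = i0; i < n && z[i] <= qz + rmax; ++i) {
    double d2 = sq(x[i] - qx) + sq(y[i] - qy) + sq(z[i] - qz);
    if (d2 <= sq(r[i]) && d2 < best_d) { best_d = d2; best = i; }
  }
  return best;
}

// [[Rcpp::export]]
List cpp_nearest_site(NumericMatrix query, NumericVector x, NumericVector y,
                      NumericVector z, IntegerVector prio) {
  const int m = query.nrow();
  IntegerVector idx(m);
  NumericVector dist(m);
  for (int k = 0; k < m; ++k) {
    double d;
    int i = nearest_sorted(query(k, 0), query(k, 1), query(k, 2), x, y, z,
                           prio, d);
    idx[k] = i + 1; // 1-based, 0 if no sites
    dist[k] = d;
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// [[Rcpp::export]]
LogicalVector cpp_within_any(NumericMatrix query, NumericVector x,
                             NumericVector y, NumericVector z, double r) {
  const int m = query.nrow();
  LogicalVector out(m);
  for (int k = 0; k < m; ++k)
    out[k] = within_any_sorted(query(k, 0), query(k, 1), query(k, 2),
                               x, y, z, r);
  return out;
}

// ---- deterministic per-radical RNG (splitmix64 + Box-Muller) -------------

struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t v = (s += 0x9E3779B97F4A7C15ULL);
    v = (v ^ (v >> 30)) * 0xBF58476D1CE4E5B9ULL;
    v = (v ^ (v >> 27)) * 0x94D049BB133111EBULL;
    return v ^ (v >> 31);
  }
  double unif() { // (0,1)
    return (next() >> 11) * (1.0 / 9007199254740992.0) +
           (0.5 / 9007199254740992.0);
  }
};

struct Gauss {
  SplitMix rng;
  double spare;
  bool has_spare;
  explicit Gauss(uint64_t seed) : rng(seed), spare(0), has_spare(false) {}
  double next() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = rng.unif(), u2 = rng.unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(6.283185307179586 * u2);
    has_spare = true;
    return r * std::cos(6.283185307179586 * u2);
  }
};

// Brownian transport of radicals until histone scavenging, backbone
// encounter, or the chemistry time cut. Status: 2 scavenged, 3 reacted,
// 4 timed_out. Each radical gets an independent stream derived from
// (seed, radical index) so removing obstacles never reroutes survivors.
// [[Rcpp::export]]
List cpp_diffuse(NumericMatrix pos,
                 NumericVector bx, NumericVector by, NumericVector bz,
                 NumericVector benc, double benc_max,
                 NumericVector hx, NumericVector hy, NumericVector hz,
                 double hist_r, double d_oh, double dt, double t_chem,
                 double seed) {
  const int n = pos.nrow();
  const bool have_hist = hx.size() > 0;
  const bool have_bb = bx.size() > 0;
  IntegerVector status(n), hit(n);
  NumericVector t_end(n);
  NumericMatrix fin(n, 3);
  const double step_sd = std::sqrt(2.0 * d_oh * dt);
  const uint64_t base = (uint64_t)seed;

  for (int k = 0; k < n; ++k) {
    Gauss g(base * 0x2545F4914F6CDD1DULL + (uint64_t)(k + 1));
    double px = pos(k, 0), py = pos(k, 1), pz = pos(k, 2);
    double t = 0.0;
    int st = 0, hi = 0;
    while (true) {
      if (t >= t_chem) { st = 4; break; }
      if (have_hist &&
          within_any_sorted(px, py, pz, hx, hy, hz, hist_r)) {
        st = 2; break;
      }
      if (have_bb) {
        int i = contained_in_sorted(px, py, pz, bx, by, bz, benc, benc_max);
        if (i >= 0) { st = 3; hi = i + 1; break; }
      }
      px += step_sd * g.next();
      py += step_sd * g.next();
      pz += step_sd * g.next();
      t += dt;
    }
    status[k] = st;
    hit[k] = hi;
    t_end[k] = std::min(t, t_chem);
    fin(k, 0) = px; fin(k, 1) = py; fin(k, 2) = pz;
  }
  return List::create(_["status"] = status, _["hit"] = hit,
                      _["time"] = t_end, _["position"] = fin);
}

// Deterministic per-id uniforms in (0,1): splitmix64 of (seed, id).
// Used for indirect-break Bernoulli trials so that the same radical gets
// the same draw in paired simulation arms.
// [[Rcpp::export]]
NumericVector cpp_hash_unif(IntegerVector ids, double seed) {
  const int n = ids.size();
  NumericVector out(n);
  const uint64_t base = (uint64_t)seed * 0x9E3779B97F4A7C15ULL;
  for (int i = 0; i < n; ++i) {
    SplitMix sm(base ^ ((uint64_t)ids[i] * 0xBF58476D1CE4E5B9ULL));
    out[i] = sm.unif();
  }
  return out;
}
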