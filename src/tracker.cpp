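// Probabilistic streamline tracker over analytic orientation fields.
//
// Each streamline draws from its own counter-based substream (splitmix64
// seeded by (base seed, seed-voxel rank, sample, branch)), so runs are
// bit-identical for a fixed seed and growing the terminus can only truncate
// a trajectory, never alter it — the common-random-number monotonicity the
// hit-fraction contract relies on.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct SplitMix {
  uint64_t state;
  explicit SplitMix(uint64_t s) : state(s) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in (0,1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0) +
                         (1.0 / 18014398509481984.0); }
};

uint64_t substream(uint64_t base, uint64_t a, uint64_t b, uint64_t c) {
  uint64_t s = base;
  s ^= a * 0x9E3779B97F4A7C15ULL;
  s ^= b * 0xC2B2AE3D27D4EB4FULL;
  s ^= c * 0x165667B19E3779F9ULL;
  SplitMix m(s);
  return m.next();
}

struct Vec3 {
  double x, y, z;
  Vec3 operator+(const Vec3& o) const { return {x + o.x, y + o.y, z + o.z}; }
  Vec3 operator-(const Vec3& o) const { return {x - o.x, y - o.y, z - o.z}; }
  Vec3 operator-() const { return {-x, -y, -z}; }
  Vec3 operator*(double s) const { return {x * s, y * s, z * s}; }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  double norm() const { return std::sqrt(dot(*this)); }
};

struct Field {
  IntegerVector dims;          // nx, ny, nz
  NumericMatrix w2v;           // 4x4 world -> voxel (inverse affine)
  NumericMatrix v2w;           // 4x4 voxel -> world
  const double *dir1, *dir2, *w1, *kappa;
  const int *tmask;
  long n;                      // voxels per component

  long voxel_at(const Vec3& p, int* io, int* jo, int* ko) const {
    double i = w2v(0, 0) * p.x + w2v(0, 1) * p.y + w2v(0, 2) * p.z + w2v(0, 3);
    double j = w2v(1, 0) * p.x + w2v(1, 1) * p.y + w2v(1, 2) * p.z + w2v(1, 3);
    double k = w2v(2, 0) * p.x + w2v(2, 1) * p.y + w2v(2, 2) * p.z + w2v(2, 3);
    int ii = (int)std::lround(i), jj = (int)std::lround(j),
        kk = (int)std::lround(k);
    if (io) { *io = ii; *jo = jj; *ko = kk; }
    if (ii < 0 || jj < 0 || kk < 0 ||
        ii >= dims[0] || jj >= dims[1] || kk >= dims[2]) return -1;
    return ii + (long)dims[0] * (jj + (long)dims[1] * kk);
  }
  Vec3 fiber(const double* d, long lin) const {
    return {d[lin], d[lin + n], d[lin + 2 * n]};
  }
};

// von Mises-Fisher draw on the sphere about mu (unit), concentration kappa.
// kappa = +Inf (or <= 0 treated as invalid upstream) collapses to mu.
Vec3 vmf_draw(const Vec3& mu, double kappa, SplitMix& rng) {
  if (!std::isfinite(kappa)) return mu;
  double u = rng.unif();
  double w = 1.0 + std::log(u + (1.0 - u) * std::exp(-2.0 * kappa)) / kappa;
  double phi = 2.0 * M_PI * rng.unif();
  // orthonormal basis perpendicular to mu
  Vec3 a = std::fabs(mu.x) < 0.9 ? Vec3{1, 0, 0} : Vec3{0, 1, 0};
  Vec3 e1 = a - mu * mu.dot(a);
  e1 = e1 * (1.0 / e1.norm());
  Vec3 e2 = {mu.y * e1.z - mu.z * e1.y,
             mu.z * e1.x - mu.x * e1.z,
             mu.x * e1.y - mu.y * e1.x};
  double s = std::sqrt(std::max(0.0, 1.0 - w * w));
  return mu * w + e1 * (s * std::cos(phi)) + e2 * (s * std::sin(phi));
}

// Draw a direction at voxel lin: pick a fiber by weight, perturb by vMF,
// orient within 90 degrees of prev (if has_prev). Returns false if no fiber.
bool draw_direction(const Field& f, long lin, const Vec3& prev, bool has_prev,
                    SplitMix& rng, Vec3* out) {
  Vec3 d1 = f.fiber(f.dir1, lin), d2 = f.fiber(f.dir2, lin);
  bool h1 = d1.norm() > 0.5, h2 = d2.norm() > 0.5;
  if (!h1 && !h2) return false;
  Vec3 mu;
  if (h1 && h2) mu = (rng.unif() < f.w1[lin]) ? d1 : d2;
  else mu = h1 ? d1 : d2;
  Vec3 d = vmf_draw(mu, f.kappa[lin], rng);
  d = d * (1.0 / d.norm());
  if (has_prev && d.dot(prev) < 0) d = -d;
  *out = d;
  return true;
}

enum Reason { HIT = 0, LEFT_MASK, MAX_STEPS, CURV_STOP, NO_FIBER };

// Walk one streamline. Returns termination reason; optionally records points.
Reason walk(const Field& f, const int* terminus, Vec3 pos, int init_sign,
            double step, int max_steps, double cos_limit, SplitMix& rng,
            std::vector<Vec3>* path) {
  Vec3 prev{0, 0, 0};
  bool has_prev = false;
  if (path) path->push_back(pos);
  for (int s = 0; s < max_steps; ++s) {
    long lin = f.voxel_at(pos, nullptr, nullptr, nullptr);
    if (lin < 0 || !f.tmask[lin]) return LEFT_MASK;
    if (terminus[lin]) return HIT;
    Vec3 d;
    if (!draw_direction(f, lin, prev, has_prev, rng, &d)) return NO_FIBER;
    if (!has_prev && init_sign < 0) d = -d;
    if (has_prev && d.dot(prev) < cos_limit) return CURV_STOP;
    pos = pos + d * step;
    if (path) path->push_back(pos);
    prev = d;
    has_prev = true;
  }
  // classify the final point before giving up
  long lin = f.voxel_at(pos, nullptr, nullptr, nullptr);
  if (lin >= 0 && f.tmask[lin] && terminus[lin]) return HIT;
  return MAX_STEPS;
}

Field make_field(IntegerVector dims, NumericMatrix v2w, NumericMatrix w2v,
                 NumericVector dir1, NumericVector dir2, NumericVector w1,
                 NumericVector kappa, IntegerVector tmask) {
  Field f;
  f.dims = dims; f.v2w = v2w; f.w2v = w2v;
  f.dir1 = REAL(dir1); f.dir2 = REAL(dir2);
  f.w1 = REAL(w1); f.kappa = REAL(kappa);
  f.tmask = INTEGER(tmask);
  f.n = (long)dims[0] * dims[1] * dims[2];
  return f;
}

const char* reason_name(Reason r) {
  switch (r) {
    case HIT: return "terminus";
    case LEFT_MASK: return "left_mask";
    case MAX_STEPS: return "max_steps";
    case CURV_STOP: return "curvature_stop";
    default: return "no_fiber";
  }
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_sample_directions(NumericVector d1, NumericVector d2,
                                    double w1, double kappa,
                                    NumericVector prev, bool has_prev,
                                    int n, double seed) {
  NumericMatrix out(n, 3);
  Vec3 f1{d1[0], d1[1], d1[2]}, f2{d2[0], d2[1], d2[2]};
  Vec3 pv{0, 0, 0};
  if (has_prev) pv = {prev[0], prev[1], prev[2]};
  bool h1 = f1.norm() > 0.5, h2 = f2.norm() > 0.5;
  for (int i = 0; i < n; ++i) {
    SplitMix rng(substream((uint64_t)seed, 0, (uint64_t)i + 1, 7));
    if (!h1 && !h2) { out(i, 0) = NA_REAL; continue; }
    Vec3 mu = (h1 && h2) ? ((rng.unif() < w1) ? f1 : f2) : (h1 ? f1 : f2);
    Vec3 d = vmf_draw(mu, kappa, rng);
    d = d * (1.0 / d.norm());
    if (has_prev && d.dot(pv) < 0) d = -d;
    out(i, 0) = d.x; out(i, 1) = d.y; out(i, 2) = d.z;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_propagate(IntegerVector dims, NumericMatrix v2w, NumericMatrix w2v,
                   NumericVector dir1, NumericVector dir2, NumericVector w1,
                   NumericVector kappa, IntegerVector tmask,
                   IntegerVector terminus, NumericVector seed_pt,
                   int init_sign, double step, int max_steps,
                   double curv_limit_deg, double seed) {
  Field f = make_field(dims, v2w, w2v, dir1, dir2, w1, kappa, tmask);
  double cos_limit = std::cos(curv_limit_deg * M_PI / 180.0);
  SplitMix rng(substream((uint64_t)seed, 1, 1, 1));
  int sign = init_sign;
  if (sign == 0) sign = (rng.unif() < 0.5) ? 1 : -1;
  std::vector<Vec3> path;
  Reason r = walk(f, INTEGER(terminus), Vec3{seed_pt[0], seed_pt[1],
                  seed_pt[2]}, sign, step, max_steps, cos_limit, rng, &path);
  NumericMatrix pts(path.size(), 3);
  for (size_t i = 0; i < path.size(); ++i) {
    pts(i, 0) = path[i].x; pts(i, 1) = path[i].y; pts(i, 2) = path[i].z;
  }
  return List::create(_["points"] = pts,
                      _["termination_reason"] = reason_name(r));
}

// [[Rcpp::export]]
NumericVector cpp_track_fractions(IntegerVector dims, NumericMatrix v2w,
                                  NumericMatrix w2v, NumericVector dir1,
                                  NumericVector dir2, NumericVector w1,
                                  NumericVector kappa, IntegerVector tmask,
                                  IntegerVector terminus,
                                  IntegerMatrix seed_vox, double step,
                                  int max_steps, double curv_limit_deg,
                                  int samples, bool jitter, bool bidirectional,
                                  double seed) {
  Field f = make_field(dims, v2w, w2v, dir1, dir2, w1, kappa, tmask);
  double cos_limit = std::cos(curv_limit_deg * M_PI / 180.0);
  int nseed = seed_vox.nrow();
  NumericVector out(nseed);
  const int* term = INTEGER(terminus);
  for (int v = 0; v < nseed; ++v) {
    int hits = 0;
    for (int s = 0; s < samples; ++s) {
      SplitMix jrng(substream((uint64_t)seed, (uint64_t)v + 1,
                              (uint64_t)s + 1, 2));
      double ox = 0, oy = 0, oz = 0;
      if (jitter) {
        ox = jrng.unif() - 0.5; oy = jrng.unif() - 0.5; oz = jrng.unif() - 0.5;
      }
      double i = seed_vox(v, 0) + ox, j = seed_vox(v, 1) + oy,
             k = seed_vox(v, 2) + oz;
      Vec3 pos{v2w(0, 0) * i + v2w(0, 1) * j + v2w(0, 2) * k + v2w(0, 3),
               v2w(1, 0) * i + v2w(1, 1) * j + v2w(1, 2) * k + v2w(1, 3),
               v2w(2, 0) * i + v2w(2, 1) * j + v2w(2, 2) * k + v2w(2, 3)};
      bool hit = false;
      if (bidirectional) {
        SplitMix r1(substream((uint64_t)seed, (uint64_t)v + 1,
                              (uint64_t)s + 1, 3));
        hit = walk(f, term, pos, 1, step, max_steps, cos_limit, r1,
                   nullptr) == HIT;
        if (!hit) {
          SplitMix r2(substream((uint64_t)seed, (uint64_t)v + 1,
                                (uint64_t)s + 1, 4));
          hit = walk(f, term, pos, -1, step, max_steps, cos_limit, r2,
                     nullptr) == HIT;
        }
      } else {
        SplitMix r1(substream((uint64_t)seed, (uint64_t)v + 1,
                              (uint64_t)s + 1, 3));
        int sign = (r1.unif() < 0.5) ? 1 : -1;
        hit = walk(f, term, pos, sign, step, max_steps, cos_limit, r1,
                   nullptr) == HIT;
      }
      if (hit) ++hits;
    }
    out[v] = (double)hits / samples;
  }
  return out;
}
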