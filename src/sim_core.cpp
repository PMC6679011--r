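#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Self-contained counter-seeded RNG (xoshiro256++ seeded via splitmix64) so
// that trace simulation is reproducible from an explicit integer seed and
// independent of R's global RNG state.
namespace {

struct Xoshiro256pp {
  uint64_t s[4];

  explicit Xoshiro256pp(uint64_t seed) {
    // splitmix64 expansion of the seed into the full state
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
    zigset();
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on (0, 1)
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  inline uint32_t next32() { return (uint32_t)(next() >> 32); }

  // standard normal via the Marsaglia-Tsang ziggurat (128 layers)
  uint32_t kn[128];
  double wn[128], fn[128];

  void zigset() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn, vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1); kn[1] = 0;
    wn[0] = q / m1; wn[127] = dn / m1;
    fn[0] = 1.0; fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1); tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn); wn[i] = dn / m1;
    }
  }

  inline double norm() {
    for (;;) {
      int32_t hz = (int32_t)next32();
      uint32_t iz = (uint32_t)hz & 127u;
      uint32_t ahz = hz < 0 ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
      if (ahz < kn[iz]) return hz * wn[iz];
      // tail / wedge corrections
      const double r = 3.442619855899;
      double x = hz * wn[iz];
      if (iz == 0) {
        double y;
        do {
          x = -std::log(unif()) / r;
          y = -std::log(unif());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -r - x;
      }
      if (fn[iz] + unif() * (fn[iz - 1] - fn[iz]) < std::exp(-0.5 * x * x))
        return x;
    }
  }

  // Poisson by Knuth multiplication for small means, normal approx beyond
  inline double pois(double lambda) {
    if (lambda <= 0.0) return 0.0;
    if (lambda > 50.0) {
      double x = std::floor(lambda + std::sqrt(lambda) * norm() + 0.5);
      return x < 0.0 ? 0.0 : x;
    }
    const double L = std::exp(-lambda);
    double p = 1.0;
    int k = 0;
    do { ++k; p *= unif(); } while (p > L);
    return (double)(k - 1);
  }
};

inline double wrap(double x, double half, double box, bool &crossed) {
  while (x >= half) { x -= box; crossed = true; }
  while (x < -half) { x += box; crossed = true; }
  return x;
}

} // namespace

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_simulate_trace(int n_steps, double dt,
                                 IntegerVector n_particles,
                                 NumericVector step_sd,
                                 NumericVector box, double w, double s,
                                 double brightness, double background,
                                 bool shot_noise,
                                 bool use_triplet, double trip_T, double trip_tau,
                                 bool reservoir,
                                 int seed,
                                 Nullable<NumericMatrix> init_pos) {
  const int n_comp = n_particles.size();
  int n_tot = 0;
  for (int c = 0; c < n_comp; ++c) n_tot += n_particles[c];

  Xoshiro256pp rng((uint64_t)(uint32_t)seed * 0x9e3779b97f4a7c15ULL + 0x1234567ULL);

  if (box.size() != 3) stop("box must have 3 edge lengths (x, y, z)");
  std::vector<double> px(n_tot), py(n_tot), pz(n_tot), sd_of(n_tot);
  std::vector<unsigned char> bright_state(n_tot, 1);
  const double bx = box[0], by = box[1], bz = box[2];
  const double hx = bx / 2.0, hy = by / 2.0, hz2 = bz / 2.0;

  {
    int k = 0;
    for (int c = 0; c < n_comp; ++c)
      for (int i = 0; i < n_particles[c]; ++i, ++k) sd_of[k] = step_sd[c];
  }

  if (init_pos.isNotNull()) {
    NumericMatrix ip(init_pos);
    if (ip.nrow() != n_tot || ip.ncol() != 3)
      stop("init_pos must be an n_particles x 3 matrix (x, y, z in um)");
    for (int k = 0; k < n_tot; ++k) {
      px[k] = ip(k, 0); py[k] = ip(k, 1); pz[k] = ip(k, 2);
    }
  } else {
    for (int k = 0; k < n_tot; ++k) {
      px[k] = (rng.unif() - 0.5) * bx;
      py[k] = (rng.unif() - 0.5) * by;
      pz[k] = (rng.unif() - 0.5) * bz;
    }
  }

  // triplet telegraph: stationary dark fraction trip_T, relaxation trip_tau;
  // per-step transition uses the exact two-state propagator
  double p_dark_given_dark = 0.0, p_dark_given_bright = 0.0;
  if (use_triplet) {
    const double decay = std::exp(-dt / trip_tau);
    p_dark_given_dark = trip_T + (1.0 - trip_T) * decay;
    p_dark_given_bright = trip_T * (1.0 - decay);
    for (int k = 0; k < n_tot; ++k)
      bright_state[k] = (rng.unif() < trip_T) ? 0 : 1;
  }

  const double inv_w2 = 2.0 / (w * w);
  const double zw = s * w;
  const double inv_z2 = 2.0 / (zw * zw);
  const double q_cut = 18.0; // exp(-18) ~ 1.5e-8 of peak: negligible signal

  NumericVector out(n_steps);
  for (int t = 0; t < n_steps; ++t) {
    double signal = background;
    for (int k = 0; k < n_tot; ++k) {
      const double sd = sd_of[k];
      if (sd > 0.0) {
        bool cx = false, cy = false, cz = false;
        px[k] = wrap(px[k] + sd * rng.norm(), hx, bx, cx);
        py[k] = wrap(py[k] + sd * rng.norm(), hy, by, cy);
        pz[k] = wrap(pz[k] + sd * rng.norm(), hz2, bz, cz);
        if (reservoir && (cx || cy || cz)) {
          // crossing particles sit >= 3 detection radii out (box contract),
          // i.e. are invisible; re-drawing their transverse coordinates
          // emulates exchange with an open reservoir instead of the
          // particle returning as a correlated periodic image
          if (!cx) px[k] = (rng.unif() - 0.5) * bx;
          if (!cy) py[k] = (rng.unif() - 0.5) * by;
          if (!cz) pz[k] = (rng.unif() - 0.5) * bz;
        }
      }
      if (use_triplet) {
        const double pd = bright_state[k] ? p_dark_given_bright : p_dark_given_dark;
        bright_state[k] = (rng.unif() < pd) ? 0 : 1;
        if (!bright_state[k]) continue;
      }
      const double q = (px[k] * px[k] + py[k] * py[k]) * inv_w2 +
                       pz[k] * pz[k] * inv_z2;
      if (q < q_cut) signal += brightness * std::exp(-q);
    }
    out[t] = shot_noise ? rng.pois(signal) : signal;
  }
  return out;
}

// sampler draws exposed for statistical validation of the ziggurat
//' @noRd
// [[Rcpp::export]]
NumericVector cpp_rng_normals(int n, int seed) {
  Xoshiro256pp rng((uint64_t)(uint32_t)seed * 0x9e3779b97f4a7c15ULL + 0x1234567ULL);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.norm();
  return out;
}

//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int current = 0;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++current;
    labels[i] = current;
    stack.push_back(i);
    while (!stack.empty()) {
      const R_xlen_t v = stack.back();
      stack.pop_back();
      const int z = (int)(v % nz);
      const int y = (int)((v / nz) % ny);
      const int x = (int)(v / ((R_xlen_t)nz * ny));
      for (int dx = -1; dx <= 1; ++dx) {
        const int xx = x + dx;
        if (xx < 0 || xx >= nx) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dz = -1; dz <= 1; ++dz) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            const int zz = z + dz;
            if (zz < 0 || zz >= nz) continue;
            const R_xlen_t u = (R_xlen_t)zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
            if (mask[u] && labels[u] == 0) {
              labels[u] = current;
              stack.push_back(u);
            }
          }
        }
      }
    }
  }
  labels.attr("n_components") = current;
  return labels;
}
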