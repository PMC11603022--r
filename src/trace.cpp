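#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Self-contained counter-independent RNG (xoshiro256++ seeded via
// splitmix64) so traces are bit-reproducible across platforms for a
// given integer seed, independent of R's RNG state.
namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() {  // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_spare = false;
  double spare = 0.0;
  inline double norm() {  // Marsaglia polar
    if (have_spare) { have_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f; have_spare = true;
    return u * f;
  }
  inline int poisson(double lambda) {  // Knuth; normal approx for large lambda
    if (lambda <= 0.0) return 0;
    if (lambda > 30.0) {
      double x = lambda + std::sqrt(lambda) * norm();
      return x < 0.0 ? 0 : (int)(x + 0.5);
    }
    double L = std::exp(-lambda), p = 1.0;
    int k = 0;
    do { ++k; p *= unif(); } while (p > L);
    return k - 1;
  }
};

inline double wrap(double x, double half, double box) {
  if (x >= half) return x - box;
  if (x < -half) return x + box;
  return x;
}

}  // namespace

// Brownian-dynamics photon trace through a 3D Gaussian observation
// volume. Positions advance by Gaussian steps with variance 2*D*dt per
// axis with periodic wrapping in a cubic box; expected counts per bin
// are brightness * exp(-2(x^2+y^2)/w0^2 - 2 z^2/(kappa w0)^2) * dt,
// realised as Poisson counts.
// [[Rcpp::export]]
List simulate_trace_cpp(NumericMatrix pos0, NumericVector D,
                        NumericVector qg, NumericVector qr,
                        double w0, double kappa, double dt,
                        int nbins, double box, double seed) {
  const int n = pos0.nrow();
  Xoshiro rng((uint64_t)seed);
  std::vector<double> x(n), y(n), z(n), sig(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2);
    sig[i] = std::sqrt(2.0 * D[i] * dt);
  }
  const double half = box / 2.0;
  const double inv_w2 = 2.0 / (w0 * w0);
  const double zr = kappa * w0;
  const double inv_z2 = 2.0 / (zr * zr);
  IntegerVector cg(nbins), cr(nbins);
  for (int b = 0; b < nbins; ++b) {
    double lam_g = 0.0, lam_r = 0.0;
    for (int i = 0; i < n; ++i) {
      x[i] = wrap(x[i] + sig[i] * rng.norm(), half, box);
      y[i] = wrap(y[i] + sig[i] * rng.norm(), half, box);
      z[i] = wrap(z[i] + sig[i] * rng.norm(), half, box);
      double e = (x[i] * x[i] + y[i] * y[i]) * inv_w2 + z[i] * z[i] * inv_z2;
      if (e < 20.0) {  // exp(-20) ~ 2e-9: below shot noise
        double w = std::exp(-e);
        lam_g += qg[i] * w;
        lam_r += qr[i] * w;
      }
    }
    cg[b] = rng.poisson(lam_g * dt);
    cr[b] = rng.poisson(lam_r * dt);
  }
  return List::create(_["g"] = cg, _["r"] = cr);
}

// Uniform initial positions in the box, from the same RNG family.
// [[Rcpp::export]]
NumericMatrix uniform_positions_cpp(int n, double box, double seed) {
  Xoshiro rng((uint64_t)seed);
  NumericMatrix pos(n, 3);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j)
      pos(i, j) = (rng.unif() - 0.5) * box;
  return pos;
}
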