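#ifndef FLUCBRIDGE_RNG_H
#define FLUCBRIDGE_RNG_H

#include <cstdint>
#include <cmath>

// Self-contained, seedable generator: one instance per simulation call so no
// global RNG state is touched. xoshiro256++ seeded via splitmix64, with a
// Marsaglia-Tsang ziggurat for standard normals (128 layers).
class FbRng {
public:
  explicit FbRng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s_[i] = splitmix64(x);
    zig_init();
    // warm up
    for (int i = 0; i < 8; ++i) next_u64();
  }

  uint64_t next_u64() {
    const uint64_t result = rotl(s_[0] + s_[3], 23) + s_[0];
    const uint64_t t = s_[1] << 17;
    s_[2] ^= s_[0];
    s_[3] ^= s_[1];
    s_[1] ^= s_[2];
    s_[0] ^= s_[3];
    s_[2] ^= t;
    s_[3] = rotl(s_[3], 45);
    return result;
  }

  // uniform in (0,1), 53-bit
  double unif() {
    double u;
    do {
      u = (next_u64() >> 11) * (1.0 / 9007199254740992.0);
    } while (u <= 0.0);
    return u;
  }

  double exp1() { return -std::log(unif()); }

  double normal() {
    for (;;) {
      int32_t hz = (int32_t)(next_u64() >> 32);
      uint32_t iz = (uint32_t)hz & 127u;
      uint32_t ahz = hz < 0 ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
      if (ahz < kn_[iz]) return hz * wn_[iz];
      double x = hz * wn_[iz];
      if (iz == 0) {
        // tail beyond r
        const double r = 3.442619855899;
        double xx, y;
        do {
          xx = -std::log(unif()) / r;
          y = -std::log(unif());
        } while (y + y < xx * xx);
        return hz > 0 ? r + xx : -(r + xx);
      }
      if (fn_[iz] + unif() * (fn_[iz - 1] - fn_[iz]) < std::exp(-0.5 * x * x))
        return x;
      // otherwise loop with a fresh hz
    }
  }

  // Poisson via inversion for small mean, normal-approximation-free PTRS-less
  // fallback by splitting large means (rates here are modest).
  int poisson(double lambda) {
    if (lambda <= 0.0) return 0;
    int total = 0;
    while (lambda > 30.0) {
      // split: Poisson(lambda) = Poisson(30) + Poisson(lambda-30)
      total += poisson_inv(30.0);
      lambda -= 30.0;
    }
    return total + poisson_inv(lambda);
  }

private:
  uint64_t s_[4];
  uint32_t kn_[128];
  double wn_[128], fn_[128];

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }

  static uint64_t rotl(const uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  int poisson_inv(double lambda) {
    double p = std::exp(-lambda), F = p, u = unif();
    int k = 0;
    while (u > F) {
      ++k;
      p *= lambda / k;
      F += p;
      if (k > 2000) break; // unreachable for lambda <= 30
    }
    return k;
  }

  void zig_init() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn_[0] = (uint32_t)((dn / q) * m1);
    kn_[1] = 0;
    wn_[0] = q / m1;
    wn_[127] = dn / m1;
    fn_[0] = 1.0;
    fn_[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn_[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn_[i] = std::exp(-0.5 * dn * dn);
      wn_[i] = dn / m1;
    }
  }
};

#endif
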