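#ifndef PQA_RNG_H
#define PQA_RNG_H

#include <cstdint>
#include <cmath>

// Counter-seeded PRNG used by the transport engine. Each history derives its
// own stream from (master seed, history index) so results are reproducible
// and independent of execution order.

static inline uint64_t pqa_splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

// Marsaglia-Tsang ziggurat tables for standard normal sampling
struct PqaZig {
  double wn[128], fn[128];
  uint32_t kn[128];
  PqaZig() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
};

inline const PqaZig &pqa_zig() {
  static const PqaZig z;
  return z;
}

struct PqaRng {
  uint64_t s0, s1;

  void seed(uint64_t master, uint64_t stream) {
    uint64_t x = master ^ (stream * 0x9e3779b97f4a7c15ULL + 0x632be59bd9b4e019ULL);
    s0 = pqa_splitmix64(x);
    s1 = pqa_splitmix64(x);
  }

  // xoroshiro128+
  inline uint64_t next() {
    uint64_t a = s0, b = s1;
    uint64_t r = a + b;
    b ^= a;
    s0 = ((a << 24) | (a >> 40)) ^ b ^ (b << 16);
    s1 = (b << 37) | (b >> 27);
    return r;
  }

  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  inline double norm() {  // ziggurat (Marsaglia-Tsang)
    const PqaZig &z = pqa_zig();
    for (;;) {
      int32_t hz = (int32_t)(next() >> 32);
      uint32_t iz = (uint32_t)hz & 127u;
      if ((uint32_t)(hz < 0 ? -hz : hz) < z.kn[iz]) return hz * z.wn[iz];
      // edge / tail handling
      double x = hz * z.wn[iz];
      if (iz == 0) {
        const double r = 3.442619855899;
        double y;
        do {
          x = -std::log(unif()) / r;
          y = -std::log(unif());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -r - x;
      }
      if (z.fn[iz] + unif() * (z.fn[iz - 1] - z.fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};

#endif
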