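#ifndef SALRMIX_RNG_H
#define SALRMIX_RNG_H

#include <cstdint>

// xoshiro256++ seeded through splitmix64: a small, fast generator with an
// explicit 64-bit seed so runs are reproducible independently of R's RNG.
struct Xoshiro256 {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }

  explicit Xoshiro256(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
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

  // uniform in [0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53; }

  // uniform integer in {0, ..., n-1}; n <= 2^32
  uint32_t unif_int(uint32_t n) {
    // Lemire's multiply-shift rejection method (unbiased)
    uint64_t x = next() >> 32;
    uint64_t m = x * (uint64_t)n;
    uint32_t l = (uint32_t)m;
    if (l < n) {
      uint32_t t = (uint32_t)(-(int32_t)n) % n;
      while (l < t) {
        x = next() >> 32;
        m = x * (uint64_t)n;
        l = (uint32_t)m;
      }
    }
    return (uint32_t)(m >> 32);
  }
};

#endif
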