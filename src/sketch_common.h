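#ifndef SKETCHNAV_COMMON_H
#define SKETCHNAV_COMMON_H

#include <cstdint>
#include <cmath>
#include <vector>
#include <limits>

// Seedable 64-bit mixing hash (splitmix64 finaliser).  All sketch randomness
// derives from (token, seed) through this function so that sketches are
// reproducible bit-for-bit across sessions and platforms.
static inline uint64_t sx_mix64(uint64_t z) {
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t sx_hash64(uint64_t token, uint64_t seed) {
  return sx_mix64(sx_mix64(token + 0x9E3779B97F4A7C15ULL) ^
                  (seed * 0xD1B54A32D192ED03ULL + 0x8BB84B93962EACC9ULL));
}

// Counter-based RNG stream; the state advances through the splitmix64 update.
struct SxRng {
  uint64_t s;
  explicit SxRng(uint64_t seed) : s(seed) {}
  uint64_t next() {
    s += 0x9E3779B97F4A7C15ULL;
    return sx_mix64(s);
  }
  // uniform on (0, 1]: log() is always finite
  double unif() {
    return (double)((next() >> 11) + 1) * (1.0 / 9007199254740993.0);
  }
  // uniform integer in [0, n)
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

// Registers cross into R as doubles; keep 52 bits so every value is an exact
// integer-valued double.
static const uint64_t SX_REG_BITS = 52;
static inline double sx_reg52(uint64_t h) { return (double)(h >> 12); }

// Lazily initialised Fisher-Yates state, reusable across elements via epoch
// stamping (avoids O(m) reset per element).
struct SxLazyPerm {
  std::vector<int> val;
  std::vector<uint32_t> stamp;
  uint32_t epoch;
  void init(int m) {
    val.assign(m, 0);
    stamp.assign(m, 0);
    epoch = 0;
  }
  void reset() { ++epoch; }
  int get(int i) const { return stamp[i] == epoch ? val[i] : i; }
  void set(int i, int v) {
    stamp[i] = epoch;
    val[i] = v;
  }
};

// Fixed-shape segment trees used by the early-stopping rules of the
// order-statistics sketches (max over current registers for min-sketches,
// min for the max-stable SetSketch).
struct SxMaxTree {
  int n, m;
  std::vector<double> t;
  void init(int m_, double fill) {
    m = m_;
    n = 1;
    while (n < m) n <<= 1;
    t.assign(2 * n, -std::numeric_limits<double>::infinity());
    for (int i = 0; i < m; ++i) t[n + i] = fill;
    for (int i = n - 1; i >= 1; --i) t[i] = t[2 * i] > t[2 * i + 1] ? t[2 * i] : t[2 * i + 1];
  }
  void update(int i, double v) {
    i += n;
    t[i] = v;
    for (i >>= 1; i >= 1; i >>= 1) {
      double w = t[2 * i] > t[2 * i + 1] ? t[2 * i] : t[2 * i + 1];
      if (w == t[i]) break;
      t[i] = w;
    }
  }
  double top() const { return t[1]; }
};

struct SxMinTree {
  int n, m;
  std::vector<double> t;
  void init(int m_, double fill) {
    m = m_;
    n = 1;
    while (n < m) n <<= 1;
    t.assign(2 * n, std::numeric_limits<double>::infinity());
    for (int i = 0; i < m; ++i) t[n + i] = fill;
    for (int i = n - 1; i >= 1; --i) t[i] = t[2 * i] < t[2 * i + 1] ? t[2 * i] : t[2 * i + 1];
  }
  void update(int i, double v) {
    i += n;
    t[i] = v;
    for (i >>= 1; i >= 1; i >>= 1) {
      double w = t[2 * i] < t[2 * i + 1] ? t[2 * i] : t[2 * i + 1];
      if (w == t[i]) break;
      t[i] = w;
    }
  }
  double top() const { return t[1]; }
};

#endif
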