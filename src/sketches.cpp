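#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include "sketch_common.h"
using namespace Rcpp;

// Salts separating independent hash universes derived from one user seed.
static const uint64_t SALT_CONTENT = 0xA24BAED4963EE407ULL;
static const uint64_t SALT_OPH_VAL = 0x9FB21C651E98DF25ULL;
static const uint64_t SALT_OPH_DIR = 0x27220A95FE5577B3ULL;
static const uint64_t SALT_OPH_ROT = 0x5851F42D4C957F2DULL;

// ---------------------------------------------------------------------------
// ProbMinHash3a: order-statistics accelerated weighted MinHash.
//
// Conceptually every element x with normalised weight w(x) draws one
// Exp(w(x)) value per register and each register keeps the element attaining
// the minimum; the register collision probability between two sketches is
// then exactly the probability Jaccard index J_p.  The acceleration generates
// each element's m exponential draws in ascending order (order-statistic
// spacings) assigned to a uniformly random permutation of the registers
// (incremental Fisher-Yates) and stops as soon as the running value exceeds
// the largest current register minimum, tracked by a max segment tree.  The
// joint distribution of the registers is identical to the naive scheme.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector sketch_pmh3a_cpp(NumericVector tokens, IntegerVector counts,
                               int m, double seed_) {
  const int n = tokens.size();
  const uint64_t seed = (uint64_t)(int64_t)seed_;
  double total = 0;
  for (int i = 0; i < n; ++i) total += counts[i];

  std::vector<double> vals((size_t)m, std::numeric_limits<double>::infinity());
  std::vector<uint64_t> toks((size_t)m, ~0ULL);
  SxMaxTree bound;
  bound.init(m, std::numeric_limits<double>::infinity());
  SxLazyPerm perm;
  perm.init(m);

  for (int e = 0; e < n; ++e) {
    const uint64_t tok = (uint64_t)(int64_t)tokens[e];
    const double w = counts[e] / total;
    SxRng rng(sx_hash64(tok, seed));
    perm.reset();
    double x = 0.0;
    for (int i = 0; i < m; ++i) {
      x += -std::log(rng.unif()) / (w * (double)(m - i));
      if (x >= bound.top()) break;
      int j = i + rng.below(m - i);
      int slot = perm.get(j);
      perm.set(j, perm.get(i));
      if (x < vals[slot] || (x == vals[slot] && tok < toks[slot])) {
        vals[slot] = x;
        toks[slot] = tok;
        bound.update(slot, x);
      }
    }
  }

  NumericVector out(m);
  for (int i = 0; i < m; ++i)
    out[i] = sx_reg52(sx_hash64(toks[i], seed ^ SALT_CONTENT));
  return out;
}

// ---------------------------------------------------------------------------
// SuperMinHash over the support set: element d visits registers in a random
// permutation order j = 0,1,... and proposes value j + U(0,1); registers keep
// the minimum.  Register collision probability equals the plain Jaccard J.
// Early stop once j exceeds the largest current register value.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector sketch_superminhash_cpp(NumericVector tokens, int m, double seed_) {
  const int n = tokens.size();
  const uint64_t seed = (uint64_t)(int64_t)seed_;
  std::vector<double> q((size_t)m, std::numeric_limits<double>::infinity());
  SxMaxTree bound;
  bound.init(m, std::numeric_limits<double>::infinity());
  SxLazyPerm perm;
  perm.init(m);

  for (int e = 0; e < n; ++e) {
    const uint64_t tok = (uint64_t)(int64_t)tokens[e];
    SxRng rng(sx_hash64(tok, seed));
    perm.reset();
    for (int j = 0; j < m; ++j) {
      if ((double)j >= bound.top()) break;
      double r = rng.unif();
      int kk = j + rng.below(m - j);
      int slot = perm.get(kk);
      perm.set(kk, perm.get(j));
      double v = (double)j + r;
      if (v < q[slot]) {
        q[slot] = v;
        bound.update(slot, v);
      }
    }
  }
  return NumericVector(q.begin(), q.end());
}

// ---------------------------------------------------------------------------
// One Permutation Hashing with densification.  A single hash pass assigns
// every element to bin floor(m*u) with a 52-bit value hash; each bin keeps
// its minimum.  Empty bins are filled by
//   optimal: random-direction borrowing through a 2-universal re-hash of
//            (bin, attempt), copying the source value verbatim;
//   faster:  fixed-direction (cyclic right) rotation, with the copied value
//            re-randomised by the rotation offset so that two sketches
//            collide on a filled-from bin only when they borrowed the same
//            value over the same offset.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector sketch_oph_cpp(NumericVector tokens, int m, double seed_, bool faster) {
  const int n = tokens.size();
  if (n < 1) stop("OPH sketch requires a non-empty support");
  const uint64_t seed = (uint64_t)(int64_t)seed_;
  std::vector<uint64_t> val((size_t)m, ~0ULL);
  std::vector<char> occ((size_t)m, 0);

  for (int e = 0; e < n; ++e) {
    const uint64_t tok = (uint64_t)(int64_t)tokens[e];
    uint64_t h = sx_hash64(tok, seed);
    double u = (double)h * (1.0 / 18446744073709551616.0);
    int bin = (int)(u * m);
    if (bin >= m) bin = m - 1;
    uint64_t hv = sx_hash64(tok, seed ^ SALT_OPH_VAL) >> 12;
    if (!occ[bin] || hv < val[bin]) {
      val[bin] = hv;
      occ[bin] = 1;
    }
  }

  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    if (occ[i]) {
      out[i] = (double)val[i];
    } else if (!faster) {
      for (uint64_t c = 0;; ++c) {
        int j = (int)(sx_hash64(((uint64_t)i << 32) ^ c, seed ^ SALT_OPH_DIR) % (uint64_t)m);
        if (occ[j]) {
          out[i] = (double)val[j];
          break;
        }
      }
    } else {
      for (int t = 1; t <= m; ++t) {
        int j = (i + t) % m;
        if (occ[j]) {
          out[i] = (double)(sx_hash64(val[j] + (uint64_t)t, seed ^ SALT_OPH_ROT) >> 12);
          break;
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// SetSketch: m registers, each the maximum over elements of a truncated
// geometric-stable value  h(d,i) = clamp(1 + floor(log_b(1/X_{d,i})), 0, q+1)
// with X_{d,i} ~ Exp(a) i.i.d., so P(K_i <= k | n elements) = exp(-n a b^-k).
// Element values are generated in descending order (ascending X order
// statistics) over a random register permutation, with early stop once the
// candidate cannot exceed the smallest current register (min segment tree).
// Register values of a union are the element-wise max by construction.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector sketch_setsketch_cpp(NumericVector tokens, int m, double seed_,
                                   double b, double a, int q) {
  const int n = tokens.size();
  const uint64_t seed = (uint64_t)(int64_t)seed_;
  const double logb = std::log(b);
  std::vector<double> K((size_t)m, 0.0);
  SxMinTree bound;
  bound.init(m, 0.0);
  SxLazyPerm perm;
  perm.init(m);

  for (int e = 0; e < n; ++e) {
    const uint64_t tok = (uint64_t)(int64_t)tokens[e];
    SxRng rng(sx_hash64(tok, seed));
    perm.reset();
    double x = 0.0;
    for (int i = 0; i < m; ++i) {
      x += -std::log(rng.unif()) / (a * (double)(m - i));
      double v = std::floor(1.0 - std::log(x) / logb);
      if (v > (double)(q + 1)) v = (double)(q + 1);
      if (v <= bound.top()) break;  // cannot raise any register
      int j = i + rng.below(m - i);
      int slot = perm.get(j);
      perm.set(j, perm.get(i));
      if (v > K[slot]) {
        K[slot] = v;
        bound.update(slot, v);
      }
    }
  }
  return NumericVector(K.begin(), K.end());
}
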