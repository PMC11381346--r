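#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>
#include "sketch_common.h"
using namespace Rcpp;

// Token packing.  Nucleotide k-mers are packed 2 bits/base (A=0,C=1,G=2,T=3)
// and canonicalised to min(forward, reverse complement); amino-acid k-mers are
// packed positionally in base 20 over the canonical residue order.  Both stay
// below 2^53 for the supported k ranges so tokens round-trip exactly through
// R doubles.

static const char AA_ORDER[21] = "ACDEFGHIKLMNPQRSTVWY";

static void nt_code_table(int8_t* code) {
  for (int i = 0; i < 256; ++i) code[i] = -1;
  code[(unsigned char)'A'] = 0;
  code[(unsigned char)'C'] = 1;
  code[(unsigned char)'G'] = 2;
  code[(unsigned char)'T'] = 3;
}

static void aa_code_table(int8_t* code) {
  for (int i = 0; i < 256; ++i) code[i] = -1;
  for (int i = 0; i < 20; ++i) code[(unsigned char)AA_ORDER[i]] = (int8_t)i;
}

// [[Rcpp::export]]
List kmer_count_cpp(CharacterVector seqs, int k, bool aminoacid) {
  int8_t code[256];
  if (aminoacid) aa_code_table(code); else nt_code_table(code);

  std::vector<uint64_t> toks;
  const uint64_t shift = 2ULL * (uint64_t)(k - 1);
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2ULL * k)) - 1ULL);
  uint64_t p20 = 1;  // 20^(k-1) for the amino-acid rolling window
  for (int i = 0; i < k - 1; ++i) p20 *= 20ULL;

  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char* seq = CHAR(STRING_ELT(seqs, s));
    uint64_t fwd = 0, rc = 0;
    int run = 0;  // length of current window of admissible residues
    for (const char* p = seq; *p; ++p) {
      int c = code[(unsigned char)*p];
      if (c < 0) {  // excluded residue breaks the window, never spans it
        run = 0;
        fwd = 0;
        rc = 0;
        continue;
      }
      if (aminoacid) {
        if (run >= k) fwd = (fwd % p20) * 20ULL + (uint64_t)c;
        else fwd = fwd * 20ULL + (uint64_t)c;
        ++run;
        if (run >= k) toks.push_back(fwd);
      } else {
        fwd = ((fwd << 2) | (uint64_t)c) & mask;
        rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
        ++run;
        if (run >= k) toks.push_back(fwd < rc ? fwd : rc);
      }
    }
  }

  std::sort(toks.begin(), toks.end());
  std::vector<double> utoks;
  std::vector<int> counts;
  for (size_t i = 0; i < toks.size();) {
    size_t j = i;
    while (j < toks.size() && toks[j] == toks[i]) ++j;
    utoks.push_back((double)toks[i]);
    counts.push_back((int)(j - i));
    i = j;
  }
  return List::create(_["tokens"] = NumericVector(utoks.begin(), utoks.end()),
                      _["counts"] = IntegerVector(counts.begin(), counts.end()),
                      _["total"] = (double)toks.size());
}
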