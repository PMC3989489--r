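#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <cstdint>
using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Distinct canonical k-mer multiplicity spectrum.
// k <= 31 so a k-mer fits in a 64-bit word (2 bits per base).
// k-mers containing any non-ACGT symbol are skipped.
// [[Rcpp::export]]
List kmer_spectrum_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::unordered_map<uint64_t, uint32_t> tab;
  tab.reserve(1 << 20);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char *p = CHAR(STRING_ELT(seqs, s));
    uint64_t fwd = 0, rev = 0;
    int valid = 0;
    for (; *p; ++p) {
      int b = base2bits(*p);
      if (b < 0) { valid = 0; fwd = rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
      if (++valid >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        ++tab[canon];
      }
    }
  }
  // histogram: multiplicity -> number of distinct canonical k-mers
  std::map<uint32_t, double> hist;
  double total = 0.0;
  for (auto &kv : tab) {
    hist[kv.second] += 1.0;
    total += (double)kv.second;
  }
  IntegerVector mult((int)hist.size());
  NumericVector nk((int)hist.size());
  int i = 0;
  for (auto &kv : hist) { mult[i] = (int)kv.first; nk[i] = kv.second; ++i; }
  return List::create(_["multiplicity"] = mult,
                      _["n_kmers"] = nk,
                      _["total_occurrences"] = total);
}
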