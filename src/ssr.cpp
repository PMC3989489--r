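#include <Rcpp.h>
using namespace Rcpp;

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// unit is primitive iff it is not a whole-number repetition of a shorter unit
static bool primitive_unit(const char *s, int u) {
  for (int d = 1; d < u; ++d) {
    if (u % d != 0) continue;
    bool rep = true;
    for (int i = d; i < u && rep; ++i)
      if (s[i] != s[i % d]) rep = false;
    if (rep) return false;
  }
  return true;
}

// Maximal perfect tandem repeats with unit length 1-6.
// min_repeats has one entry per unit length 1..6.
// A region reportable under several unit lengths is emitted only for the
// smallest (primitive) unit; only whole units are counted (end = start + u*reps).
// [[Rcpp::export]]
DataFrame find_ssrs_cpp(CharacterVector seqs, IntegerVector min_repeats) {
  if (min_repeats.size() != 6) stop("min_repeats must have 6 entries");
  std::vector<int> out_seq, out_start, out_end, out_ulen, out_reps;
  std::vector<std::string> out_motif;
  for (R_xlen_t si = 0; si < seqs.size(); ++si) {
    const char *s = CHAR(STRING_ELT(seqs, si));
    int n = (int)LENGTH(STRING_ELT(seqs, si));
    for (int u = 1; u <= 6; ++u) {
      int need = min_repeats[u - 1];
      int i = u;
      while (i < n) {
        if (!is_acgt(s[i]) || !is_acgt(s[i - u]) || s[i] != s[i - u]) { ++i; continue; }
        int run_start = i;                 // first index with s[i] == s[i-u]
        while (i < n && is_acgt(s[i]) && s[i] == s[i - u]) ++i;
        int m = i - run_start;             // run of periodicity matches
        int start = run_start - u;
        int reps = (m + u) / u;            // whole units in the periodic region
        if (reps >= need && primitive_unit(s + start, u)) {
          out_seq.push_back((int)si + 1);
          out_start.push_back(start);
          out_end.push_back(start + u * reps);
          out_ulen.push_back(u);
          out_reps.push_back(reps);
          out_motif.push_back(std::string(s + start, s + start + u));
        }
      }
    }
  }
  return DataFrame::create(_["seq_index"] = out_seq,
                           _["start"] = out_start,
                           _["end"] = out_end,
                           _["motif"] = out_motif,
                           _["motif_length"] = out_ulen,
                           _["repeat_count"] = out_reps,
                           _["stringsAsFactors"] = false);
}
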