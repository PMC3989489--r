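#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

static inline int b2i(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
    case 'A': c = 'T'; break; case 'T': c = 'A'; break;
    case 'C': c = 'G'; break; case 'G': c = 'C'; break;
    case 'a': c = 't'; break; case 't': c = 'a'; break;
    case 'c': c = 'g'; break; case 'g': c = 'c'; break;
    default: break;
    }
  }
  return r;
}

struct SeedHit { int t; int diag; int qpos; int tpos; };

struct Chain { int t; int qlo, qhi, tlo, thi, dmin, dmax; };

struct AlnRec {
  int t, qs, qe, ts, te;
  int matches, mismatches, qgb, qgc, tgb, tgc;
};

// Banded global alignment of A vs B (linear gap cost): match +1, mismatch -2,
// gap -3 (so substitutions are strictly preferred over gap pairs). Returns the trimmed local window maximizing a per-column score
// (match +1, mismatch/gap-base -1), with PSL-style counts.
static bool banded_align(const std::string &A, const std::string &B,
                         int lo, int hi, AlnRec &rec) {
  int n = (int)A.size(), m = (int)B.size();
  if (n == 0 || m == 0) return false;
  if (lo > std::min(0, m - n)) lo = std::min(0, m - n);
  if (hi < std::max(0, m - n)) hi = std::max(0, m - n);
  int width = hi - lo + 1;
  if ((double)(n + 1) * width > 2e8) return false;
  const int NEG = -1000000000;
  std::vector<int> prev(width, NEG), cur(width, NEG);
  std::vector<uint8_t> tb((size_t)(n + 1) * width, 0);
  // row 0
  for (int j = std::max(0, lo); j <= std::min(m, hi); ++j) {
    prev[j - lo] = -3 * j;
    tb[(size_t)0 * width + (j - lo)] = 2; // left
  }
  for (int i = 1; i <= n; ++i) {
    int jmin = std::max(0, i + lo), jmax = std::min(m, i + hi);
    std::fill(cur.begin(), cur.end(), NEG);
    for (int j = jmin; j <= jmax; ++j) {
      int col = j - i - lo;
      int best = NEG; uint8_t dir = 0;
      if (j > 0) {
        int d = prev[col]; // (i-1, j-1) has same j-i offset index
        if (d > NEG) {
          int sc = d + (b2i(A[i - 1]) >= 0 && A[i - 1] == B[j - 1] ? 1 : -2);
          if (sc > best) { best = sc; dir = 0; }
        }
      }
      if (j - i + 1 <= hi) { // up: from (i-1, j), consumes query base
        int d = prev[col + 1];
        if (d > NEG && d - 3 > best) { best = d - 3; dir = 1; }
      }
      if (j - i - 1 >= lo && j > 0) { // left: from (i, j-1), consumes target base
        int d = cur[col - 1];
        if (d > NEG && d - 3 > best) { best = d - 3; dir = 2; }
      }
      if (i > 0 && j == 0) { // first column: all-up path
        best = -3 * i; dir = 1;
      }
      cur[col] = best;
      tb[(size_t)i * width + col] = dir;
    }
    std::swap(prev, cur);
  }
  // traceback from (n, m)
  std::vector<uint8_t> ops; ops.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    uint8_t d = tb[(size_t)i * width + (j - i - lo)];
    if (i == 0) d = 2;
    else if (j == 0) d = 1;
    ops.push_back(d);
    if (d == 0) { --i; --j; }
    else if (d == 1) { --i; }
    else { --j; }
  }
  std::reverse(ops.begin(), ops.end());
  // local trim: best contiguous window by per-column score
  int besttot = 0, curtot = 0, curstart = 0, b1 = 0, b2 = -1;
  int qi = 0, ti = 0;
  std::vector<int> qat(ops.size() + 1), tat(ops.size() + 1);
  for (size_t c = 0; c < ops.size(); ++c) {
    qat[c] = qi; tat[c] = ti;
    int v;
    if (ops[c] == 0) {
      v = (A[qi] == B[ti]) ? 1 : -1;
      ++qi; ++ti;
    } else if (ops[c] == 1) { v = -1; ++qi; }
    else { v = -1; ++ti; }
    if (curtot <= 0) { curtot = v; curstart = (int)c; }
    else curtot += v;
    if (curtot > besttot) { besttot = curtot; b1 = curstart; b2 = (int)c; }
  }
  qat[ops.size()] = qi; tat[ops.size()] = ti;
  if (b2 < b1) return false;
  rec.qs = qat[b1]; rec.ts = tat[b1];
  rec.qe = qat[b2 + 1]; rec.te = tat[b2 + 1];
  rec.matches = rec.mismatches = rec.qgb = rec.qgc = rec.tgb = rec.tgc = 0;
  int lastop = -1;
  for (int c = b1; c <= b2; ++c) {
    if (ops[c] == 0) {
      if (A[qat[c]] == B[tat[c]]) ++rec.matches; else ++rec.mismatches;
    } else if (ops[c] == 1) {
      ++rec.qgb; if (lastop != 1) ++rec.qgc;
    } else {
      ++rec.tgb; if (lastop != 2) ++rec.tgc;
    }
    lastop = ops[c];
  }
  return rec.matches > 0;
}

// Seed-and-extend local alignment of queries against targets, both strands,
// with PSL-semantics records.
// [[Rcpp::export]]
DataFrame seed_align_cpp(CharacterVector qnames, CharacterVector qseqs,
                         CharacterVector tnames, CharacterVector tseqs,
                         int seed_len, int band, int max_chain_gap,
                         double min_identity, int min_score,
                         double evalue_max, double lambda, double kparam,
                         int max_seed_occ) {
  int nq = qseqs.size(), nt = tseqs.size();
  std::vector<std::string> T(nt);
  double total_tlen = 0.0;
  for (int t = 0; t < nt; ++t) { T[t] = as<std::string>(tseqs[t]); total_tlen += T[t].size(); }
  // target seed index
  const uint64_t mask = (1ULL << (2 * seed_len)) - 1;
  std::unordered_map<uint64_t, std::vector<std::pair<int,int> > > idx;
  idx.reserve(1 << 18);
  for (int t = 0; t < nt; ++t) {
    const std::string &s = T[t];
    uint64_t h = 0; int valid = 0;
    for (int p = 0; p < (int)s.size(); ++p) {
      int b = b2i(s[p]);
      if (b < 0) { valid = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)b) & mask;
      if (++valid >= seed_len) idx[h].push_back(std::make_pair(t, p - seed_len + 1));
    }
  }
  std::vector<std::string> o_q, o_t, o_strand;
  std::vector<int> o_qsize, o_qs, o_qe, o_tsize, o_ts, o_te;
  std::vector<int> o_match, o_mis, o_qgb, o_qgc, o_tgb, o_tgc, o_score;
  std::vector<double> o_ident, o_eval;

  for (int q = 0; q < nq; ++q) {
    std::string qfwd = as<std::string>(qseqs[q]);
    int qlen = (int)qfwd.size();
    for (int strand = 0; strand < 2; ++strand) {
      std::string Q = strand == 0 ? qfwd : revcomp_str(qfwd);
      // collect seed hits
      std::vector<SeedHit> hits;
      uint64_t h = 0; int valid = 0;
      for (int p = 0; p < (int)Q.size(); ++p) {
        int b = b2i(Q[p]);
        if (b < 0) { valid = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)b) & mask;
        if (++valid >= seed_len) {
          auto it = idx.find(h);
          if (it == idx.end()) continue;
          if ((int)it->second.size() > max_seed_occ) continue;
          int qpos = p - seed_len + 1;
          for (auto &tp : it->second)
            hits.push_back({tp.first, qpos - tp.second, qpos, tp.second});
        }
      }
      if (hits.empty()) continue;
      std::sort(hits.begin(), hits.end(), [](const SeedHit &a, const SeedHit &b) {
        if (a.t != b.t) return a.t < b.t;
        if (a.diag != b.diag) return a.diag < b.diag;
        return a.qpos < b.qpos;
      });
      // cluster by (target, diagonal band)
      std::vector<Chain> chains;
      for (size_t ii = 0; ii < hits.size(); ++ii) {
        const SeedHit &hh = hits[ii];
        if (!chains.empty()) {
          Chain &c = chains.back();
          if (c.t == hh.t && hh.diag - c.dmax <= band) {
            c.qlo = std::min(c.qlo, hh.qpos); c.qhi = std::max(c.qhi, hh.qpos);
            c.tlo = std::min(c.tlo, hh.tpos); c.thi = std::max(c.thi, hh.tpos);
            c.dmin = std::min(c.dmin, hh.diag); c.dmax = std::max(c.dmax, hh.diag);
            continue;
          }
        }
        chains.push_back({hh.t, hh.qpos, hh.qpos, hh.tpos, hh.tpos, hh.diag, hh.diag});
      }
      // merge colinear chains on the same target
      std::sort(chains.begin(), chains.end(), [](const Chain &a, const Chain &b) {
        if (a.t != b.t) return a.t < b.t;
        return a.qlo < b.qlo;
      });
      std::vector<Chain> merged;
      for (auto &c : chains) {
        bool joined = false;
        if (!merged.empty()) {
          Chain &p = merged.back();
          if (p.t == c.t && c.qlo - p.qhi <= max_chain_gap &&
              c.tlo - p.thi <= max_chain_gap && c.tlo + seed_len > p.tlo &&
              std::abs((double)c.dmin - p.dmax) <= 2 * band + max_chain_gap) {
            p.qlo = std::min(p.qlo, c.qlo); p.qhi = std::max(p.qhi, c.qhi);
            p.tlo = std::min(p.tlo, c.tlo); p.thi = std::max(p.thi, c.thi);
            p.dmin = std::min(p.dmin, c.dmin); p.dmax = std::max(p.dmax, c.dmax);
            joined = true;
          }
        }
        if (!joined) merged.push_back(c);
      }
      std::vector<AlnRec> found;
      for (auto &c : merged) {
        const std::string &Ts = T[c.t];
        int qs = c.qlo, ts = c.tlo;
        int qe = c.qhi + seed_len, te = c.thi + seed_len;
        // ungapped x-drop extension along the seed diagonal
        { int i = qs - 1, j = ts - 1, cur = 0, best = 0, bi = qs, bj = ts;
          while (i >= 0 && j >= 0) {
            cur += (Q[i] == Ts[j] && b2i(Q[i]) >= 0) ? 1 : -2;
            if (cur > best) { best = cur; bi = i; bj = j; }
            if (cur < best - 12) break;
            --i; --j;
          }
          qs = bi; ts = bj; }
        { int i = qe, j = te, cur = 0, best = 0, bi = qe, bj = te;
          while (i < (int)Q.size() && j < (int)Ts.size()) {
            cur += (Q[i] == Ts[j] && b2i(Q[i]) >= 0) ? 1 : -2;
            if (cur > best) { best = cur; bi = i + 1; bj = j + 1; }
            if (cur < best - 12) break;
            ++i; ++j;
          }
          qe = bi; te = bj; }
        std::string A = Q.substr(qs, qe - qs);
        std::string B = Ts.substr(ts, te - ts);
        int pad = (c.dmax - c.dmin) + 8;
        AlnRec rec;
        if (!banded_align(A, B, -pad, pad, rec)) continue;
        rec.t = c.t;
        rec.qs += qs; rec.qe += qs; rec.ts += ts; rec.te += ts;
        found.push_back(rec);
      }
      // deduplicate identical spans
      std::sort(found.begin(), found.end(), [](const AlnRec &a, const AlnRec &b) {
        if (a.t != b.t) return a.t < b.t;
        if (a.qs != b.qs) return a.qs < b.qs;
        if (a.qe != b.qe) return a.qe < b.qe;
        return a.ts < b.ts;
      });
      for (size_t ii = 0; ii < found.size(); ++ii) {
        const AlnRec &r = found[ii];
        if (ii > 0) {
          const AlnRec &p = found[ii - 1];
          if (p.t == r.t && p.qs == r.qs && p.qe == r.qe && p.ts == r.ts && p.te == r.te)
            continue;
        }
        int aligned = r.matches + r.mismatches + r.qgb + r.tgb;
        double ident = aligned > 0 ? 100.0 * r.matches / aligned : 0.0;
        int score = r.matches - r.mismatches - r.qgc - r.tgc;
        double sraw = r.matches - 2.0 * r.mismatches - 5.0 * (r.qgc + r.tgc)
          - 2.0 * (r.qgb + r.tgb);
        double ex = lambda * sraw;
        double ev = ex > 700 ? 0.0 : kparam * (double)qlen * total_tlen * std::exp(-ex);
        if (score < min_score || ident < min_identity || ev > evalue_max) continue;
        int oqs = r.qs, oqe = r.qe;
        if (strand == 1) { oqs = qlen - r.qe; oqe = qlen - r.qs; }
        o_q.push_back(as<std::string>(qnames[q]));
        o_t.push_back(as<std::string>(tnames[r.t]));
        o_strand.push_back(strand == 0 ? "+" : "-");
        o_qsize.push_back(qlen); o_qs.push_back(oqs); o_qe.push_back(oqe);
        o_tsize.push_back((int)T[r.t].size()); o_ts.push_back(r.ts); o_te.push_back(r.te);
        o_match.push_back(r.matches); o_mis.push_back(r.mismatches);
        o_qgb.push_back(r.qgb); o_qgc.push_back(r.qgc);
        o_tgb.push_back(r.tgb); o_tgc.push_back(r.tgc);
        o_score.push_back(score); o_ident.push_back(ident); o_eval.push_back(ev);
      }
    }
  }
  return DataFrame::create(
    _["q_name"] = o_q, _["q_size"] = o_qsize, _["q_start"] = o_qs, _["q_end"] = o_qe,
    _["t_name"] = o_t, _["t_size"] = o_tsize, _["t_start"] = o_ts, _["t_end"] = o_te,
    _["strand"] = o_strand,
    _["matches"] = o_match, _["mismatches"] = o_mis,
    _["q_gap_count"] = o_qgc, _["q_gap_bases"] = o_qgb,
    _["t_gap_count"] = o_tgc, _["t_gap_bases"] = o_tgb,
    _["score"] = o_score, _["identity"] = o_ident, _["evalue"] = o_eval,
    _["stringsAsFactors"] = false);
}

// Pairwise end-to-end overlaps between fragments via shared-seed diagonal
// voting. offset is the position of fragment b's first base in a's coordinates
// (negative when b starts before a); for strand '-', coordinates refer to the
// reverse complement of b.
// [[Rcpp::export]]
DataFrame find_overlaps_cpp(CharacterVector seqs, int seed_len,
                            int min_overlap, double min_identity,
                            int max_seed_occ, int min_votes) {
  int n = seqs.size();
  std::vector<std::string> F(n), R(n);
  for (int i = 0; i < n; ++i) { F[i] = as<std::string>(seqs[i]); R[i] = revcomp_str(F[i]); }
  const uint64_t mask = (1ULL << (2 * seed_len)) - 1;
  std::unordered_map<uint64_t, std::vector<std::pair<int,int> > > idx;
  idx.reserve(1 << 18);
  for (int t = 0; t < n; ++t) {
    const std::string &s = F[t];
    uint64_t h = 0; int valid = 0;
    for (int p = 0; p < (int)s.size(); ++p) {
      int b = b2i(s[p]);
      if (b < 0) { valid = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)b) & mask;
      if (++valid >= seed_len) idx[h].push_back(std::make_pair(t, p - seed_len + 1));
    }
  }
  std::vector<int> o_a, o_b, o_off, o_len, o_match;
  std::vector<std::string> o_strand;
  std::vector<double> o_ident;
  const int64_t DIAG0 = 1 << 21;
  for (int a = 0; a < n; ++a) {
    for (int strand = 0; strand < 2; ++strand) {
      const std::string &A = strand == 0 ? F[a] : R[a];
      // votes: (partner b, diag) -> count ; diag = posA - posB
      std::unordered_map<uint64_t, int> votes;
      uint64_t h = 0; int valid = 0;
      for (int p = 0; p < (int)A.size(); ++p) {
        int b = b2i(A[p]);
        if (b < 0) { valid = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)b) & mask;
        if (++valid >= seed_len) {
          auto it = idx.find(h);
          if (it == idx.end()) continue;
          if ((int)it->second.size() > max_seed_occ) continue;
          int apos = p - seed_len + 1;
          for (auto &tp : it->second) {
            if (tp.first <= a) continue; // each unordered pair once
            int64_t diag = (int64_t)apos - tp.second;
            uint64_t key = ((uint64_t)tp.first << 23) | (uint64_t)(diag + DIAG0);
            ++votes[key];
          }
        }
      }
      // best identity per partner over voted diagonals
      std::unordered_map<int, std::tuple<int,int,int> > best; // b -> (offset? we store via tuple)
      for (auto &kv : votes) {
        if (kv.second < min_votes) continue;
        int bfrag = (int)(kv.first >> 23);
        int64_t diag = (int64_t)(kv.first & ((1 << 23) - 1)) - DIAG0;
        // A[i] ~ B[i - offset] where offset = diag with B = partner's fwd seq
        // (the partner is always indexed on its forward strand; when strand==1
        //  A is revcomp(a), so offset refers to revcomp(a) coords -- convert below)
        const std::string &B = F[bfrag];
        int offset = (int)diag; // b start position in A coords = offset? A[p]==B[p-offset] -> B index 0 at A coord offset
        int lo = std::max(0, offset);
        int hi = std::min((int)A.size(), offset + (int)B.size());
        int ov = hi - lo;
        if (ov < min_overlap) continue;
        int mt = 0;
        for (int i = lo; i < hi; ++i)
          if (A[i] == B[i - offset] && b2i(A[i]) >= 0) ++mt;
        auto it2 = best.find(bfrag);
        if (it2 == best.end() || mt > std::get<2>(it2->second))
          best[bfrag] = std::make_tuple(offset, ov, mt);
      }
      for (auto &kv : best) {
        int offset = std::get<0>(kv.second);
        int ov = std::get<1>(kv.second);
        int mt = std::get<2>(kv.second);
        double ident = (double)mt / ov;
        if (ident < min_identity) continue;
        int off_out = offset, a_out = a + 1, b_out = kv.first + 1;
        std::string str_out = strand == 0 ? "+" : "-";
        if (strand == 1) {
          // express offset in a's forward coords: A = revcomp(a);
          // revcomp(b) starts at position len(A) - (offset + len(B)) ... keep the
          // convention: offset of revcomp(b) within forward a:
          off_out = (int)F[a].size() - (offset + (int)F[kv.first].size());
        }
        o_a.push_back(a_out); o_b.push_back(b_out); o_strand.push_back(str_out);
        o_off.push_back(off_out); o_len.push_back(ov); o_match.push_back(mt);
        o_ident.push_back(ident);
      }
    }
  }
  return DataFrame::create(_["a"] = o_a, _["b"] = o_b, _["strand"] = o_strand,
                           _["offset"] = o_off, _["length"] = o_len,
                           _["matches"] = o_match, _["identity"] = o_ident,
                           _["stringsAsFactors"] = false);
}

// Depth-weighted majority consensus over fragments placed at offsets.
// [[Rcpp::export]]
List consensus_cpp(CharacterVector seqs, IntegerVector offsets, NumericVector weights) {
  int n = seqs.size();
  int L = 0;
  std::vector<std::string> S(n);
  for (int i = 0; i < n; ++i) {
    S[i] = as<std::string>(seqs[i]);
    if (offsets[i] < 0) stop("offsets must be normalized to be >= 0");
    L = std::max(L, offsets[i] + (int)S[i].size());
  }
  std::vector<double> w(5 * (size_t)L, 0.0);
  std::vector<int> depth(L, 0);
  for (int i = 0; i < n; ++i) {
    int off = offsets[i];
    double wt = weights[i];
    for (int p = 0; p < (int)S[i].size(); ++p) {
      int b = b2i(S[i][p]);
      int col = off + p;
      if (b < 0) w[5 * (size_t)col + 4] += wt;
      else w[5 * (size_t)col + b] += wt;
      ++depth[col];
    }
  }
  std::string cons(L, 'N');
  int het = 0;
  const char bases[4] = {'A', 'C', 'G', 'T'};
  for (int col = 0; col < L; ++col) {
    double bw = -1.0; int bi = -1; int distinct = 0;
    for (int b = 0; b < 4; ++b) {
      double ww = w[5 * (size_t)col + b];
      if (ww > 0) ++distinct;
      if (ww > bw) { bw = ww; bi = b; } // tie keeps smaller index: A<C<G<T
    }
    if (bw > 0) cons[col] = bases[bi];
    if (distinct >= 2) ++het;
  }
  return List::create(_["sequence"] = cons,
                      _["depth"] = IntegerVector(depth.begin(), depth.end()),
                      _["het_sites"] = het);
}

// Edge support filter for the overlap graph: an edge (a,b) is kept when some
// third fragment c overlaps both a and b with a composed placement that agrees
// with the direct edge (within tol bases, same orientation), or when either
// endpoint has no other overlap. Spurious near-threshold overlaps between
// unrelated fragments are almost never transitively consistent.
// [[Rcpp::export]]
LogicalVector overlap_support_cpp(int n, IntegerVector ea, IntegerVector eb,
                                  IntegerVector esign, IntegerVector eoff,
                                  IntegerVector flen, int tol) {
  int m = ea.size();
  // adjacency with transformed (neighbor, offset, sign) in the source's
  // forward frame
  std::vector<std::vector<std::array<int,3> > > adj(n + 1);
  std::vector<int> deg(n + 1, 0);
  for (int k = 0; k < m; ++k) {
    int a = ea[k], b = eb[k], s = esign[k], o = eoff[k];
    adj[a].push_back({b, o, s});
    int orev = (s == 1) ? -o : o + flen[b - 1] - flen[a - 1];
    adj[b].push_back({a, orev, s});
    ++deg[a]; ++deg[b];
  }
  LogicalVector keep(m);
  for (int k = 0; k < m; ++k) {
    int a = ea[k], b = eb[k], s_ab = esign[k], o_ab = eoff[k];
    if (deg[a] <= 1 || deg[b] <= 1) { keep[k] = true; continue; }
    bool ok = false;
    for (auto &ac : adj[a]) {
      int c = ac[0];
      if (c == b || c == a) continue;
      int o_ac = ac[1], s_ac = ac[2];
      for (auto &cb : adj[c]) {
        if (cb[0] != b) continue;
        int o_cb = cb[1], s_cb = cb[2];
        // compose a->c->b
        int s_comp = s_ac * s_cb;
        int o_comp = (s_ac == 1)
          ? o_ac + o_cb
          : o_ac + flen[c - 1] - o_cb - flen[b - 1];
        if (s_comp == s_ab && std::abs(o_comp - o_ab) <= tol) { ok = true; break; }
      }
      if (ok) break;
    }
    keep[k] = ok;
  }
  return keep;
}

// Agglomerative layout with cluster-level identity verification.
// Edges are processed strongest-first (identity, then overlap length); a merge
// of two clusters is accepted only when the aggregate identity over ALL
// overlapping member-pair columns (given the placement implied by the edge)
// still reaches min_identity. Chance near-threshold overlaps between diverged
// copies are thereby rejected once the copies have grown, while genuinely
// similar copies (aggregate identity above threshold) collapse.
// [[Rcpp::export]]
List agglomerate_layout_cpp(CharacterVector seqs,
                            IntegerVector ea, IntegerVector eb,
                            IntegerVector esign, IntegerVector eoff,
                            NumericVector eident, IntegerVector elen,
                            double min_identity, int tol) {
  int n = seqs.size();
  std::vector<std::string> F(n), R(n);
  std::vector<int> len(n);
  for (int i = 0; i < n; ++i) {
    F[i] = as<std::string>(seqs[i]);
    R[i] = revcomp_str(F[i]);
    len[i] = (int)F[i].size();
  }
  int m = ea.size();
  std::vector<int> order(m);
  for (int k = 0; k < m; ++k) order[k] = k;
  std::sort(order.begin(), order.end(), [&](int x, int y) {
    if (eident[x] != eident[y]) return eident[x] > eident[y];
    if (elen[x] != elen[y]) return elen[x] > elen[y];
    if (ea[x] != ea[y]) return ea[x] < ea[y];
    return eb[x] < eb[y];
  });
  std::vector<int> root(n), nori(n, 1);
  std::vector<double> noff(n, 0.0);
  // members per root, sorted by offset
  std::vector<std::vector<int> > members(n);
  std::vector<int> maxlen(n);
  for (int i = 0; i < n; ++i) { root[i] = i; members[i].push_back(i); maxlen[i] = len[i]; }
  int conflicts = 0, rejected = 0;

  auto base_at = [&](int node, double col) -> char {
    int p = (int)(col - noff[node]);
    if (p < 0 || p >= len[node]) return 0;
    return nori[node] == 1 ? F[node][p] : R[node][p];
  };

  for (int kk = 0; kk < m; ++kk) {
    int k = order[kk];
    int a = ea[k] - 1, b = eb[k] - 1;
    int s = esign[k], o = eoff[k];
    int ra = root[a], rb = root[b];
    // placement of oriented-b implied by the edge, in ra's frame
    int b_ori = nori[a] * s;
    double b_off = (nori[a] == 1) ? noff[a] + o
                                  : noff[a] + len[a] - o - len[b];
    if (ra == rb) {
      if (nori[b] != b_ori || std::abs(noff[b] - b_off) > tol) ++conflicts;
      continue;
    }
    // transform T mapping rb-frame placements into ra-frame
    int ot = b_ori * nori[b];
    double D = 0, C = 0;
    if (ot == 1) D = b_off - noff[b];
    else C = b_off + noff[b] + len[b];
    // iterate the smaller cluster; invert T if needed
    int src = rb, dst = ra;
    bool inverted = false;
    if (members[ra].size() < members[rb].size()) {
      src = ra; dst = rb; inverted = true;
      if (ot == 1) D = -D; // flip transform is self-inverse
    }
    // aggregate identity between clusters under the implied placement
    long matches = 0, total = 0;
    const std::vector<int> &big = members[dst];
    for (int y : members[src]) {
      int yori = ot == 1 ? nori[y] : -nori[y];
      double yoff = ot == 1 ? D + noff[y] : C - noff[y] - len[y];
      double lo = yoff - maxlen[dst];
      // first big member with offset >= lo (members sorted by offset)
      int l = 0, h = (int)big.size();
      while (l < h) {
        int mid = (l + h) / 2;
        if (noff[big[mid]] < lo) l = mid + 1; else h = mid;
      }
      for (int t = l; t < (int)big.size(); ++t) {
        int u = big[t];
        if (noff[u] >= yoff + len[y]) break;
        double clo = std::max(yoff, noff[u]);
        double chi = std::min(yoff + len[y], noff[u] + len[u]);
        for (double c2 = clo; c2 < chi; ++c2) {
          int py = (int)(c2 - yoff);
          char cy = (py < 0 || py >= len[y]) ? 0
            : (yori == 1 ? F[y][py] : R[y][py]);
          char cu = base_at(u, c2);
          if (!cy || !cu) continue;
          ++total;
          if (cy == cu) ++matches;
        }
      }
    }
    if (total == 0 || (double)matches < min_identity * total - 1e-9) {
      ++rejected;
      continue;
    }
    // accept: move src members into dst with the transform applied
    std::vector<int> moved = members[src];
    for (int y : moved) {
      int yori = ot == 1 ? nori[y] : -nori[y];
      double yoff = ot == 1 ? D + noff[y] : C - noff[y] - len[y];
      nori[y] = yori; noff[y] = yoff; root[y] = dst;
    }
    std::sort(moved.begin(), moved.end(), [&](int x, int y) {
      if (noff[x] != noff[y]) return noff[x] < noff[y];
      return x < y;
    });
    std::vector<int> merged;
    merged.reserve(big.size() + moved.size());
    size_t i1 = 0, i2 = 0;
    while (i1 < big.size() || i2 < moved.size()) {
      bool takeBig;
      if (i1 >= big.size()) takeBig = false;
      else if (i2 >= moved.size()) takeBig = true;
      else takeBig = noff[big[i1]] <= noff[moved[i2]];
      merged.push_back(takeBig ? big[i1++] : moved[i2++]);
    }
    members[dst] = merged;
    members[src].clear();
    maxlen[dst] = std::max(maxlen[dst], maxlen[src]);
  }
  // relabel components in order of first node appearance
  std::vector<int> comp(n, 0);
  int ncomp = 0;
  for (int i = 0; i < n; ++i) {
    int r = root[i];
    if (comp[r] == 0) comp[r] = ++ncomp;
    comp[i] = comp[r];
  }
  return List::create(_["component"] = IntegerVector(comp.begin(), comp.end()),
                      _["ori"] = IntegerVector(nori.begin(), nori.end()),
                      _["offset"] = NumericVector(noff.begin(), noff.end()),
                      _["conflicts"] = conflicts,
                      _["rejected_merges"] = rejected);
}
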