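#include <Rcpp.h>
#include <cstdint>
#include <cstdlib>
#include <vector>
#include <string>
#include <map>
#include <array>
#include <algorithm>
using namespace Rcpp;

// A, C, G, T -> 0..3; anything else (incl. N) -> 4 and never matches.
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

// Bit-parallel pattern preprocessing for Myers' algorithm (Hyyro's block variant).
struct PatternBits {
  int m = 0, W = 0;
  std::vector<uint64_t> peq; // 4 * W words; N rows stay 0 (N is always a mismatch)
  void build(const std::string& s) {
    m = (int)s.size();
    W = (m + 63) / 64;
    peq.assign((size_t)4 * W, 0ULL);
    for (int i = 0; i < m; ++i) {
      int c = base_code(s[i]);
      if (c < 4) peq[(size_t)c * W + (i >> 6)] |= (1ULL << (i & 63));
    }
  }
};

// Global (Needleman-Wunsch, unit cost) Levenshtein distance between the
// preprocessed pattern and `text`. Returns the exact distance if it is <= k,
// otherwise -1 (with an early abandon on a per-column lower bound).
static int myers_nw(const PatternBits& P, const std::string& text, int k,
                    std::vector<uint64_t>& Pv, std::vector<uint64_t>& Mv) {
  const int m = P.m, W = P.W;
  const int n = (int)text.size();
  if (m == 0) return n <= k ? n : -1;
  if (n == 0) return m <= k ? m : -1;
  Pv.assign(W, ~0ULL);
  Mv.assign(W, 0ULL);
  int score = m;
  const uint64_t last_hb = 1ULL << ((m - 1) & 63);
  for (int j = 0; j < n; ++j) {
    const int c = base_code(text[j]);
    int hin = 1; // NW: the top row costs one insertion per text column
    int hout = 0;
    for (int b = 0; b < W; ++b) {
      uint64_t Eq = (c < 4) ? P.peq[(size_t)c * W + b] : 0ULL;
      const uint64_t pv = Pv[b], mv = Mv[b];
      const uint64_t Xv = Eq | mv;
      if (hin < 0) Eq |= 1ULL;
      const uint64_t Xh = (((Eq & pv) + pv) ^ pv) | Eq;
      uint64_t Ph = mv | ~(Xh | pv);
      uint64_t Mh = pv & Xh;
      const uint64_t hb = (b == W - 1) ? last_hb : (1ULL << 63);
      hout = (Ph & hb) ? 1 : ((Mh & hb) ? -1 : 0);
      Ph <<= 1; Mh <<= 1;
      if (hin < 0) Mh |= 1ULL; else if (hin > 0) Ph |= 1ULL;
      Pv[b] = Mh | ~(Xv | Ph);
      Mv[b] = Ph & Xv;
      hin = hout;
    }
    score += hout;
    // each remaining column can lower the score by at most 1
    if (score - (n - 1 - j) > k) return -1;
  }
  return score <= k ? score : -1;
}

// [[Rcpp::export]]
int edit_dist_cpp(std::string a, std::string b) {
  PatternBits P;
  P.build(a);
  std::vector<uint64_t> Pv, Mv;
  int k = (int)std::max(a.size(), b.size());
  return myers_nw(P, b, k, Pv, Mv);
}

// Pairwise similarity edges within one batch. seqs/rcseqs are the batch reads
// and their reverse complements; i_from..i_to (1-based, inclusive) restricts the
// first index so callers can chunk the triangular loop across workers.
// Returns 1-based batch index pairs (a < b), similarity percent and whether the
// reverse complement orientation was used.
// [[Rcpp::export]]
List pair_edges_cpp(CharacterVector seqs, CharacterVector rcseqs,
                    double len_gate, double min_sim, double rc_trigger,
                    int i_from, int i_to) {
  const int n = seqs.size();
  std::vector<std::string> S(n), R(n);
  std::vector<int> len(n);
  for (int i = 0; i < n; ++i) {
    S[i] = std::string(CHAR(STRING_ELT(seqs, i)));
    R[i] = std::string(CHAR(STRING_ELT(rcseqs, i)));
    len[i] = (int)S[i].size();
  }
  std::vector<int> ea, eb, erc;
  std::vector<double> es;
  std::vector<uint64_t> Pv, Mv;
  PatternBits Pf, Pr;
  const int lo = std::max(1, i_from) - 1;
  const int hi = std::min(i_to, n - 1); // first index runs to n-1 (1-based)
  for (int i = lo; i < hi; ++i) {
    Pf.build(S[i]);
    Pr.build(R[i]);
    for (int j = i + 1; j < n; ++j) {
      const int L = std::max(len[i], len[j]);
      if ((double)std::abs(len[i] - len[j]) / L >= len_gate) continue;
      // D <= k_trig  <=>  similarity >= rc_trigger
      const int k_trig = (int)std::floor(L * (100.0 - rc_trigger) / 100.0 + 1e-9);
      const int k_edge = (int)std::floor(L * (100.0 - min_sim) / 100.0 + 1e-9);
      const int d1 = myers_nw(Pf, S[j], k_trig, Pv, Mv);
      if (d1 >= 0) { // same-strand similarity >= rc_trigger: RC never consulted
        const double sim = 100.0 * (1.0 - (double)d1 / L);
        if (sim >= min_sim) {
          ea.push_back(i + 1); eb.push_back(j + 1); es.push_back(sim); erc.push_back(0);
        }
      } else {       // below the trigger: rescue with the reverse complement
        const int d2 = myers_nw(Pr, S[j], k_edge, Pv, Mv);
        if (d2 >= 0) {
          const double sim = 100.0 * (1.0 - (double)d2 / L);
          if (sim >= min_sim) {
            ea.push_back(i + 1); eb.push_back(j + 1); es.push_back(sim); erc.push_back(1);
          }
        }
      }
    }
  }
  return List::create(_["a"] = wrap(ea), _["b"] = wrap(eb),
                      _["similarity"] = wrap(es), _["rc"] = wrap(erc));
}

// Oriented similarity of each read against each consensus, with a length gate.
// Gated-out pairs get NA. rc[i,j] = 1 when the reverse complement orientation
// was the one scored (only consulted when same-strand similarity < rc_trigger).
// [[Rcpp::export]]
List cross_sim_cpp(CharacterVector reads, CharacterVector cons, CharacterVector cons_rc,
                   double len_gate, double rc_trigger) {
  const int nr = reads.size(), nc = cons.size();
  NumericMatrix sim(nr, nc);
  IntegerMatrix rc(nr, nc);
  std::fill(sim.begin(), sim.end(), NA_REAL);
  std::vector<std::string> Rd(nr);
  std::vector<int> rl(nr);
  for (int i = 0; i < nr; ++i) {
    Rd[i] = std::string(CHAR(STRING_ELT(reads, i)));
    rl[i] = (int)Rd[i].size();
  }
  std::vector<uint64_t> Pv, Mv;
  PatternBits Pf, Pr;
  for (int j = 0; j < nc; ++j) {
    std::string cj(CHAR(STRING_ELT(cons, j)));
    std::string cjr(CHAR(STRING_ELT(cons_rc, j)));
    const int lc = (int)cj.size();
    Pf.build(cj);
    Pr.build(cjr);
    for (int i = 0; i < nr; ++i) {
      const int L = std::max(rl[i], lc);
      if ((double)std::abs(rl[i] - lc) / L >= len_gate) continue;
      const int k_trig = (int)std::floor(L * (100.0 - rc_trigger) / 100.0 + 1e-9);
      const int d1 = myers_nw(Pf, Rd[i], k_trig, Pv, Mv);
      if (d1 >= 0) {
        sim(i, j) = 100.0 * (1.0 - (double)d1 / L);
      } else {
        const int d2 = myers_nw(Pr, Rd[i], L, Pv, Mv);
        sim(i, j) = 100.0 * (1.0 - (double)d2 / L);
        rc(i, j) = 1;
      }
    }
  }
  return List::create(_["similarity"] = sim, _["rc"] = rc);
}

// ---- star-alignment consensus ------------------------------------------------

// Banded global alignment of `rd` to the backbone with traceback; tallies the
// per-backbone-column symbol and insertion segments between columns.
// Exact whenever the final distance fits in the band (the band is grown and the
// alignment redone otherwise).
static void align_tally(const std::string& bb, const std::string& rd,
                        std::vector<std::array<int, 6>>& counts,
                        std::vector<int>& ins_n,
                        std::vector<std::map<std::string, int>>& ins_seg,
                        std::vector<int>& dp, std::vector<uint8_t>& tr) {
  const int m = (int)bb.size(), n = (int)rd.size();
  const int rmax = std::max(m, n);
  const int INF = 1 << 28;
  int r = std::max(32, std::abs(n - m) + rmax / 10);
  int width = 0;
  for (;;) {
    if (r > rmax) r = rmax;
    width = 2 * r + 1;
    dp.assign((size_t)(m + 1) * width, INF);
    tr.assign((size_t)(m + 1) * width, 0);
    dp[r] = 0;                                  // (0, 0)
    for (int j = 1; j <= std::min(n, r); ++j) { // top row: insertions only
      dp[j + r] = j;
      tr[j + r] = 3;
    }
    for (int i = 1; i <= m; ++i) {
      const int jlo = std::max(0, i - r), jhi = std::min(n, i + r);
      const size_t row = (size_t)i * width, prow = (size_t)(i - 1) * width;
      for (int j = jlo; j <= jhi; ++j) {
        const int k = j - i + r;
        int best = INF;
        uint8_t mv = 0;
        if (j > 0) { // diagonal
          const int d = dp[prow + k] + (bb[i - 1] == rd[j - 1] &&
                                        base_code(bb[i - 1]) < 4 ? 0 : 1);
          if (d < best) { best = d; mv = 1; }
        }
        if (k + 1 < width) { // up: backbone char deleted in the read
          const int d = dp[prow + k + 1] + 1;
          if (d < best) { best = d; mv = 2; }
        }
        if (k - 1 >= 0 && j > 0) { // left: read char inserted
          const int d = dp[row + k - 1] + 1;
          if (d < best) { best = d; mv = 3; }
        }
        dp[row + k] = best;
        tr[row + k] = mv;
      }
    }
    const int D = dp[(size_t)m * width + (n - m + r)];
    if (D <= r || r >= rmax) break;
    r = std::min(2 * r, rmax);
  }
  // traceback
  int i = m, j = n;
  std::string cur;
  const int rr = (width - 1) / 2;
  while (i > 0 || j > 0) {
    const uint8_t mv = tr[(size_t)i * width + (j - i + rr)];
    if (mv == 3) {
      cur.push_back(rd[j - 1]);
      --j;
    } else {
      if (!cur.empty()) {
        std::reverse(cur.begin(), cur.end());
        ins_seg[i][cur] += 1;
        ins_n[i] += 1;
        cur.clear();
      }
      if (mv == 1) {
        const int c = base_code(rd[j - 1]);
        counts[i - 1][c < 4 ? c : 5] += 1;
        --i; --j;
      } else { // mv == 2
        counts[i - 1][4] += 1;
        --i;
      }
    }
  }
  if (!cur.empty()) {
    std::reverse(cur.begin(), cur.end());
    ins_seg[0][cur] += 1;
    ins_n[0] += 1;
  }
}

// One round of star alignment + per-column majority vote against a backbone.
// Gap plurality deletes a column; an insertion is emitted when a strict
// majority of reads inserts at that junction (most frequent segment, ties to
// the lexicographically smallest).
// [[Rcpp::export]]
std::string consensus_round_cpp(std::string backbone, CharacterVector reads) {
  const int m = (int)backbone.size();
  const int depth = reads.size();
  if (m == 0 || depth == 0) return backbone;
  std::vector<std::array<int, 6>> counts(m);
  for (auto& a : counts) a.fill(0);
  std::vector<int> ins_n(m + 1, 0);
  std::vector<std::map<std::string, int>> ins_seg(m + 1);
  std::vector<int> dp;
  std::vector<uint8_t> tr;
  for (int t = 0; t < depth; ++t) {
    std::string rd(CHAR(STRING_ELT(reads, t)));
    align_tally(backbone, rd, counts, ins_n, ins_seg, dp, tr);
  }
  static const char* BASES = "ACGT";
  std::string out;
  out.reserve(m + m / 10);
  auto emit_ins = [&](int jn) {
    if (2 * ins_n[jn] > depth) {
      const std::string* best = nullptr;
      int bc = 0;
      for (const auto& kv : ins_seg[jn]) {
        if (kv.second > bc) { bc = kv.second; best = &kv.first; }
      }
      if (best) out += *best;
    }
  };
  emit_ins(0);
  for (int i = 0; i < m; ++i) {
    int bi = 0;
    for (int c = 1; c < 4; ++c) {
      if (counts[i][c] > counts[i][bi]) bi = c;
    }
    if (counts[i][4] > counts[i][bi]) {
      // gap plurality: column deleted
    } else if (counts[i][bi] == 0) {
      out.push_back('N'); // only N votes observed
    } else {
      out.push_back(BASES[bi]);
    }
    emit_ins(i + 1);
  }
  return out;
}
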