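// miRanda-style complementarity Smith-Waterman.
//
// The reversed miRNA (3'->5') is aligned against the target (5'->3') with
// complementarity scoring: A:T and G:C count as match, G:T (target G vs
// miRNA U and vice versa) as wobble, anything else (N included) as mismatch.
// Per-position substitution scores are multiplied by seed_scale when the
// miRNA base sits at positions seed_start..seed_end from the miRNA 5' end.
// Affine gaps: a gap of length k costs gap_open + k * gap_extend (costs
// passed as negative scores).  All local optima scoring >= threshold are
// reported greedily best-first, previously reported target spans masked, so
// per-miRNA sites never overlap.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

namespace {

inline bool is_comp(char t, char m) {
  return (t == 'A' && m == 'T') || (t == 'T' && m == 'A') ||
         (t == 'G' && m == 'C') || (t == 'C' && m == 'G');
}
inline bool is_wobble(char t, char m) {
  return (t == 'G' && m == 'T') || (t == 'T' && m == 'G');
}

struct Hit {
  double score;
  int ts, te;      // target span, 0-based half-open
  int qs, qe;      // miRNA 5'-based positions covered, 1-based inclusive
  std::string at, am;  // gapped alignment strings (target 5'->3', miRNA 3'->5')
};

struct Params {
  double match, wobble, mismatch, gap_open, gap_extend, seed_scale;
  int seed_start, seed_end;
};

// One Smith-Waterman pass over target[lo, hi) vs the reversed miRNA.
// Returns true and fills `best` when the optimum reaches `threshold`.
bool sw_pass(const std::string& target, const std::string& rq, int mlen,
             int lo, int hi, const Params& P, double threshold, Hit& best) {
  const int n = hi - lo, m = (int)rq.size();
  if (n < 1) return false;
  const double NEG = -1e30;
  // DP matrices, (n+1) x (m+1), row-major
  std::vector<double> H((n + 1) * (m + 1), 0.0),
                      E((n + 1) * (m + 1), NEG),   // gap in miRNA (consumes target)
                      F((n + 1) * (m + 1), NEG);   // gap in target (consumes miRNA)
  std::vector<unsigned char> TB((n + 1) * (m + 1), 0),  // H origin: 1 diag, 2 E, 3 F
                             TE((n + 1) * (m + 1), 0),  // E origin: 1 from H
                             TF((n + 1) * (m + 1), 0);  // F origin: 1 from H

  // per-column substitution context
  std::vector<double> scale(m + 1);
  for (int j = 1; j <= m; ++j) {
    int pos5 = mlen - j + 1;  // miRNA position from 5' end
    scale[j] = (pos5 >= P.seed_start && pos5 <= P.seed_end) ? P.seed_scale : 1.0;
  }

  double bestScore = 0.0;
  int bi = -1, bj = -1;
  const double go = P.gap_open + P.gap_extend;  // first gap position

  for (int i = 1; i <= n; ++i) {
    const char tb = target[lo + i - 1];
    for (int j = 1; j <= m; ++j) {
      const char mb = rq[j - 1];
      double s;
      if (is_comp(tb, mb)) s = P.match;
      else if (is_wobble(tb, mb)) s = P.wobble;
      else s = P.mismatch;
      s *= scale[j];

      const int idx = i * (m + 1) + j;
      const int up = (i - 1) * (m + 1) + j;
      const int left = i * (m + 1) + (j - 1);
      const int diag = (i - 1) * (m + 1) + (j - 1);

      double e_open = H[up] + go, e_ext = E[up] + P.gap_extend;
      E[idx] = std::max(e_open, e_ext);
      TE[idx] = (e_open >= e_ext) ? 1 : 0;

      double f_open = H[left] + go, f_ext = F[left] + P.gap_extend;
      F[idx] = std::max(f_open, f_ext);
      TF[idx] = (f_open >= f_ext) ? 1 : 0;

      double d = H[diag] + s;
      double h = 0.0; unsigned char tb_code = 0;
      if (d > h) { h = d; tb_code = 1; }
      if (E[idx] > h) { h = E[idx]; tb_code = 2; }
      if (F[idx] > h) { h = F[idx]; tb_code = 3; }
      H[idx] = h; TB[idx] = tb_code;

      // strictly greater keeps the first (smallest end) among ties
      if (h > bestScore) { bestScore = h; bi = i; bj = j; }
    }
  }
  if (bestScore < threshold || bi < 0) return false;

  // traceback from (bi, bj) in H state
  std::string at, am;
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    const int idx = i * (m + 1) + j;
    if (TB[idx] == 0 || H[idx] <= 0.0) break;
    if (TB[idx] == 1) {
      at.push_back(target[lo + i - 1]);
      am.push_back(rq[j - 1]);
      --i; --j;
    } else if (TB[idx] == 2) {  // run of gaps in miRNA
      while (true) {
        at.push_back(target[lo + i - 1]);
        am.push_back('-');
        const bool open = TE[i * (m + 1) + j] == 1;
        --i;
        if (open) break;
      }
    } else {  // run of gaps in target
      while (true) {
        at.push_back('-');
        am.push_back(rq[j - 1]);
        const bool open = TF[i * (m + 1) + j] == 1;
        --j;
        if (open) break;
      }
    }
  }
  std::reverse(at.begin(), at.end());
  std::reverse(am.begin(), am.end());

  best.score = bestScore;
  best.ts = lo + i;          // i, j now index the cell before the alignment
  best.te = lo + bi;
  best.qs = mlen - bj + 1;   // miRNA 5'-based positions covered
  best.qe = mlen - j;
  best.at = at;
  best.am = am;
  return true;
}

}  // namespace

// [[Rcpp::export(name = ".sw_scan_cpp")]]
DataFrame sw_scan_cpp(std::string target, std::string mirna,
                      double match, double wobble, double mismatch,
                      double gap_open, double gap_extend,
                      double seed_scale, int seed_start, int seed_end,
                      double threshold) {
  Params P{match, wobble, mismatch, gap_open, gap_extend,
           seed_scale, seed_start, seed_end};
  const int mlen = (int)mirna.size();
  std::string rq(mirna.rbegin(), mirna.rend());  // reversed miRNA, 3'->5'

  std::vector<Hit> hits;
  // interval stack for greedy masking: solve, mask the best span, recurse
  std::vector<std::pair<int, int>> stack;
  stack.push_back({0, (int)target.size()});
  while (!stack.empty()) {
    auto iv = stack.back();
    stack.pop_back();
    Hit h;
    if (sw_pass(target, rq, mlen, iv.first, iv.second, P, threshold, h)) {
      hits.push_back(h);
      if (h.ts - iv.first >= 1) stack.push_back({iv.first, h.ts});
      if (iv.second - h.te >= 1) stack.push_back({h.te, iv.second});
    }
  }
  // greedy best-first report order; ties by leftmost target start
  std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
    if (a.score != b.score) return a.score > b.score;
    return a.ts < b.ts;
  });

  const int k = (int)hits.size();
  NumericVector score(k);
  IntegerVector ts(k), te(k), qs(k), qe(k);
  CharacterVector at(k), am(k);
  for (int i = 0; i < k; ++i) {
    score[i] = hits[i].score;
    ts[i] = hits[i].ts; te[i] = hits[i].te;
    qs[i] = hits[i].qs; qe[i] = hits[i].qe;
    at[i] = hits[i].at; am[i] = hits[i].am;
  }
  return DataFrame::create(_["score"] = score,
                           _["t_start"] = ts, _["t_end"] = te,
                           _["q_start"] = qs, _["q_end"] = qe,
                           _["aln_target"] = at, _["aln_mirna"] = am,
                           _["stringsAsFactors"] = false);
}
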