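// Iterative masked local alignment block extraction.
//
// Repeatedly finds the best Smith-Waterman local alignment (affine gaps)
// between a query and an ortholog promoter, decomposes its traceback path
// into gap-free segments, keeps the maximal-scoring sub-block of each
// segment when it is long enough and identical enough, masks the aligned
// regions in both sequences, and repeats until no alignment reaches the
// score threshold. Masked or non-ACGT positions (e.g. N) never match.

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static inline bool is_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

struct Block {
  int qs, qe, ss, se, nmatch;
};

// [[Rcpp::export(name = ".sw_blocks_cpp")]]
DataFrame sw_blocks_cpp(std::string query, std::string subject,
                        double match = 1.0, double mismatch = -1.0,
                        double gap_open = -2.0, double gap_extend = -1.0,
                        double min_score = 15.0, int min_block = 8,
                        double min_identity = 0.7, int max_iter = 50) {
  const int n = (int)query.size(), m = (int)subject.size();
  std::vector<bool> mq(n, false), ms(m, false);
  std::vector<Block> blocks;

  const double NEG = -1e6;
  std::vector<double> H((n + 1) * (m + 1)), E((n + 1) * (m + 1)),
      F((n + 1) * (m + 1));
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  for (int iter = 0; iter < max_iter; ++iter) {
    // forward pass
    double best = 0.0;
    int bi = -1, bj = -1;
    for (int j = 0; j <= m; ++j) {
      H[idx(0, j)] = 0; E[idx(0, j)] = NEG; F[idx(0, j)] = NEG;
    }
    for (int i = 1; i <= n; ++i) {
      H[idx(i, 0)] = 0; E[idx(i, 0)] = NEG; F[idx(i, 0)] = NEG;
      for (int j = 1; j <= m; ++j) {
        double s;
        char a = query[i - 1], b = subject[j - 1];
        if (mq[i - 1] || ms[j - 1] || !is_base(a) || !is_base(b))
          s = NEG;
        else
          s = (a == b) ? match : mismatch;
        double e = std::max(H[idx(i, j - 1)] + gap_open,
                            E[idx(i, j - 1)] + gap_extend);
        double f = std::max(H[idx(i - 1, j)] + gap_open,
                            F[idx(i - 1, j)] + gap_extend);
        double h = H[idx(i - 1, j - 1)] + s;
        h = std::max(std::max(h, e), std::max(f, 0.0));
        E[idx(i, j)] = e;
        F[idx(i, j)] = f;
        H[idx(i, j)] = h;
        if (h > best) { best = h; bi = i; bj = j; }
      }
    }
    if (best < min_score) break;

    // traceback, collecting diagonal (gap-free) segments
    // state 0 = H, 1 = E (gap in query), 2 = F (gap in subject)
    int i = bi, j = bj, state = 0;
    // current diagonal run, recorded back-to-front
    std::vector<int> run_qi, run_sj;          // 1-based positions
    std::vector<int> run_match;               // 1 if match else 0
    const double eps = 1e-9;
    std::vector<std::vector<int>> seg_qi, seg_sj, seg_match;
    auto flush_run = [&]() {
      if (!run_qi.empty()) {
        seg_qi.push_back(run_qi); seg_sj.push_back(run_sj);
        seg_match.push_back(run_match);
        run_qi.clear(); run_sj.clear(); run_match.clear();
      }
    };
    int q_lo = bi, q_hi = bi, s_lo = bj, s_hi = bj;
    while (i > 0 && j > 0) {
      if (state == 0) {
        double h = H[idx(i, j)];
        if (h <= 0 + eps) break;
        char a = query[i - 1], b = subject[j - 1];
        double s = (mq[i - 1] || ms[j - 1] || !is_base(a) || !is_base(b))
                       ? NEG
                       : ((a == b) ? match : mismatch);
        if (std::abs(h - (H[idx(i - 1, j - 1)] + s)) < eps) {
          run_qi.push_back(i); run_sj.push_back(j);
          run_match.push_back(a == b && is_base(a) ? 1 : 0);
          q_lo = std::min(q_lo, i); s_lo = std::min(s_lo, j);
          --i; --j;
        } else if (std::abs(h - E[idx(i, j)]) < eps) {
          flush_run(); state = 1;
        } else if (std::abs(h - F[idx(i, j)]) < eps) {
          flush_run(); state = 2;
        } else {
          break;  // h == 0 start
        }
      } else if (state == 1) {
        // gap in query: came from (i, j-1)
        double e = E[idx(i, j)];
        s_lo = std::min(s_lo, j);
        if (std::abs(e - (H[idx(i, j - 1)] + gap_open)) < eps) state = 0;
        --j;
      } else {
        double f = F[idx(i, j)];
        q_lo = std::min(q_lo, i);
        if (std::abs(f - (H[idx(i - 1, j)] + gap_open)) < eps) state = 0;
        --i;
      }
    }
    flush_run();

    // keep best-scoring sub-block of each gap-free segment
    for (size_t sgi = 0; sgi < seg_qi.size(); ++sgi) {
      std::vector<int>& qi = seg_qi[sgi];
      std::vector<int>& sj = seg_sj[sgi];
      std::vector<int>& mt = seg_match[sgi];
      int L = (int)qi.size();
      // segments were recorded back-to-front: reverse
      std::reverse(qi.begin(), qi.end());
      std::reverse(sj.begin(), sj.end());
      std::reverse(mt.begin(), mt.end());
      // Kadane for max-scoring contiguous sub-run
      double cur = 0, bestv = -1;
      int cs = 0, b0 = -1, b1 = -1;
      for (int t = 0; t < L; ++t) {
        double sc = mt[t] ? match : mismatch;
        if (cur <= 0) { cur = sc; cs = t; }
        else cur += sc;
        if (cur > bestv) { bestv = cur; b0 = cs; b1 = t; }
      }
      if (b0 < 0) continue;
      int len = b1 - b0 + 1;
      int nmatch = 0;
      for (int t = b0; t <= b1; ++t) nmatch += mt[t];
      if (len >= min_block && (double)nmatch / len >= min_identity) {
        Block bl;
        bl.qs = qi[b0]; bl.qe = qi[b1];
        bl.ss = sj[b0]; bl.se = sj[b1];
        bl.nmatch = nmatch;
        blocks.push_back(bl);
      }
    }

    // mask the whole aligned region in both sequences
    for (int t = q_lo; t <= q_hi; ++t) mq[t - 1] = true;
    for (int t = s_lo; t <= s_hi; ++t) ms[t - 1] = true;
  }

  int nb = (int)blocks.size();
  IntegerVector qs(nb), qe(nb), ss(nb), se(nb), nm(nb);
  NumericVector ident(nb);
  for (int b = 0; b < nb; ++b) {
    qs[b] = blocks[b].qs; qe[b] = blocks[b].qe;
    ss[b] = blocks[b].ss; se[b] = blocks[b].se;
    nm[b] = blocks[b].nmatch;
    ident[b] = (double)blocks[b].nmatch / (blocks[b].qe - blocks[b].qs + 1);
  }
  return DataFrame::create(_["q_start"] = qs, _["q_end"] = qe,
                           _["s_start"] = ss, _["s_end"] = se,
                           _["n_match"] = nm, _["identity"] = ident);
}
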