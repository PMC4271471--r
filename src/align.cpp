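#include "seedex.h"
#include <algorithm>
#include <climits>

using namespace Rcpp;

// Banded affine-gap extension anchored at the origin (a seed edge).
//
// DP states: H (match/mismatch or closed gap), V (gap consuming query),
// G (gap consuming reference). A gap of length g costs
// gap_open + g * gap_extend. The band restricts |i - j| <= half_width,
// measured from the seed diagonal (the origin).
//
// global (glocal) mode: the extension must consume the whole query side;
// the reference endpoint is free. If the query end lies outside the band's
// reach past the reference end, the remaining query is consumed by
// continuing a gap in column j = N (handled exactly by the tail scan).
// local mode: the extension ends at its maximum-scoring cell; if no cell
// scores > 0 the extension is empty.

static const int NEG = INT_MIN / 4;

ExtResult extend_side(const std::string& a, const std::string& b,
                      bool global_mode, int half_width,
                      int match, int mismatch, int gap_open, int gap_extend) {
  ExtResult res = {0, 0, 0, 0, 0, 0, 0};
  const int M = (int)a.size(), N = (int)b.size();
  if (M == 0 && (!global_mode || true)) {
    // nothing to consume on the query side; empty extension is optimal for
    // glocal (free reference end) and scores 0 for local.
    return res;
  }
  int W = half_width;
  if (W > std::max(M, N)) W = std::max(M, N);  // band already covers everything
  const int width = 2 * W + 1;

  std::vector<int> Hprev(width, NEG), Hcur(width, NEG);
  std::vector<int> Vprev(width, NEG), Vcur(width, NEG);
  std::vector<int> Gcur(width, NEG);
  // pointer matrices: hp 0=origin/unset, 1=diag, 2=V, 3=G
  std::vector<unsigned char> hp((size_t)(M + 1) * width, 0);
  std::vector<unsigned char> vopen((size_t)(M + 1) * width, 0);
  std::vector<unsigned char> gopen((size_t)(M + 1) * width, 0);

  // local-mode best cell, and glocal endpoint candidates
  int best_loc = 0, bi = 0, bj = 0;              // local (empty allowed)
  long best_gl = LONG_MIN; int gi = -1, gj = -1; // glocal
  int g_state = 0;  // 0 = plain H endpoint, 1 = tail opening new gap, 2 = tail extending V

  // row 0
  {
    int hi = std::min(N, W);
    Hprev[W + 0] = 0;  // c = j - (0 - W) = j + W; j=0 -> c=W
    int Gp = NEG;
    for (int j = 1; j <= hi; ++j) {
      int c = j + W;
      int open = Hprev[c - 1] > NEG ? Hprev[c - 1] + gap_open + gap_extend : NEG;
      int ext = Gp > NEG ? Gp + gap_extend : NEG;
      int g = std::max(open, ext);
      Gp = g;
      Hprev[c] = g;
      hp[c] = 3;
      gopen[c] = (open >= ext) ? 1 : 0;
    }
    if (global_mode && M == 0) { /* handled above */ }
    if (global_mode && N <= W && M > 0) {
      // tail candidates from (0, N)
      int c = N + W;
      if (c < width && Hprev[c] > NEG) {
        long t1 = (long)Hprev[c] + gap_open + (long)gap_extend * M;
        if (t1 > best_gl) { best_gl = t1; gi = 0; gj = N; g_state = 1; }
      }
    }
    if (M == 0) {
      // local with M == 0 already returned; defensive
      res.score = 0;
      return res;
    }
  }

  for (int i = 1; i <= M; ++i) {
    int lo = std::max(0, i - W), hi = std::min(N, i + W);
    std::fill(Vcur.begin(), Vcur.end(), NEG);
    std::fill(Hcur.begin(), Hcur.end(), NEG);
    std::fill(Gcur.begin(), Gcur.end(), NEG);
    size_t rowbase = (size_t)i * width;
    for (int j = lo; j <= hi; ++j) {
      int c = j - (i - W);
      // V from (i-1, j): parent column index c+1
      int v = NEG; unsigned char vo = 0;
      if (c + 1 < width) {
        int open = Hprev[c + 1] > NEG ? Hprev[c + 1] + gap_open + gap_extend : NEG;
        int ext = Vprev[c + 1] > NEG ? Vprev[c + 1] + gap_extend : NEG;
        if (open >= ext) { v = open; vo = 1; } else { v = ext; vo = 0; }
      }
      Vcur[c] = v;
      vopen[rowbase + c] = vo;
      // G from (i, j-1): column index c-1 in current row
      int g = NEG; unsigned char go_ = 0;
      if (c - 1 >= 0 && j - 1 >= lo) {
        int open = Hcur[c - 1] > NEG ? Hcur[c - 1] + gap_open + gap_extend : NEG;
        int ext = Gcur[c - 1] > NEG ? Gcur[c - 1] + gap_extend : NEG;
        if (open >= ext) { g = open; go_ = 1; } else { g = ext; go_ = 0; }
      }
      Gcur[c] = g;
      gopen[rowbase + c] = go_;
      // diagonal from (i-1, j-1): parent column index c
      int d = NEG;
      if (j >= 1 && Hprev[c] > NEG)
        d = Hprev[c] + (a[i - 1] == b[j - 1] ? match : mismatch);
      int h = d; unsigned char p = 1;
      if (v > h) { h = v; p = 2; }
      if (g > h) { h = g; p = 3; }
      if (h <= NEG) { p = 0; h = NEG; }
      Hcur[c] = h;
      hp[rowbase + c] = p;
      if (!global_mode && h > best_loc) { best_loc = h; bi = i; bj = j; }
    }
    // glocal tail candidates from column j = N
    if (global_mode && i < M && N >= lo && N <= hi) {
      int c = N - (i - W);
      long rest = (long)gap_extend * (M - i);
      if (Hcur[c] > NEG) {
        long t1 = (long)Hcur[c] + gap_open + rest;
        if (t1 > best_gl) { best_gl = t1; gi = i; gj = N; g_state = 1; }
      }
      if (Vcur[c] > NEG) {
        long t2 = (long)Vcur[c] + rest;
        if (t2 > best_gl) { best_gl = t2; gi = i; gj = N; g_state = 2; }
      }
    }
    std::swap(Hprev, Hcur);
    std::swap(Vprev, Vcur);
  }
  // after the loop Hprev holds row M
  if (global_mode) {
    int lo = std::max(0, M - W), hi = std::min(N, M + W);
    for (int j = lo; j <= hi; ++j) {
      int c = j - (M - W);
      if (Hprev[c] > NEG && (long)Hprev[c] > best_gl) {
        best_gl = Hprev[c]; gi = M; gj = j; g_state = 0;
      }
    }
    if (gi < 0) stop("internal error: no reachable glocal endpoint");
  } else {
    if (best_loc <= 0) return res;  // empty extension
  }

  // traceback
  int i = global_mode ? gi : bi;
  int j = global_mode ? gj : bj;
  res.score = global_mode ? (int)best_gl : best_loc;
  res.qlen = global_mode ? M : bi;
  res.rlen = j;
  int state = 0;  // 0 = H, 1 = V, 2 = G
  if (global_mode && g_state != 0) {
    res.cols += M - gi;            // trailing query-gap columns past the band
    if (g_state == 1) { res.gap_opens += 1; state = 0; }
    else state = 1;
  }
  while (i > 0 || j > 0 || state != 0) {
    size_t idx = (size_t)i * width + (size_t)(j - (i - W));
    if (state == 0) {
      unsigned char p = hp[idx];
      if (p == 1) {
        res.cols += 1;
        if (a[i - 1] == b[j - 1]) res.matches += 1; else res.mismatches += 1;
        --i; --j;
      } else if (p == 2) {
        state = 1;
      } else if (p == 3) {
        state = 2;
      } else {
        break;  // origin
      }
    } else if (state == 1) {
      unsigned char o = vopen[idx];
      res.cols += 1;
      --i;
      if (o) { res.gap_opens += 1; state = 0; }
    } else {
      unsigned char o = gopen[idx];
      res.cols += 1;
      --j;
      if (o) { res.gap_opens += 1; state = 0; }
    }
  }
  return res;
}

HitCore banded_extend_core(const std::string& q, const std::string& r,
                           int q_off, int r_off, int k,
                           bool global_mode, int half_width,
                           int match, int mismatch, int gap_open, int gap_extend) {
  if (q_off < 0 || r_off < 0 || q_off + k > (int)q.size() || r_off + k > (int)r.size())
    stop("seed does not fit inside the sequences");
  if (q.compare(q_off, k, r, r_off, k) != 0)
    stop("internal consistency error: seed windows do not match");
  std::string ar = q.substr(q_off + k);
  std::string br = r.substr(r_off + k);
  std::string al(q.rbegin() + (q.size() - q_off), q.rend());
  std::string bl(r.rbegin() + (r.size() - r_off), r.rend());
  ExtResult R = extend_side(ar, br, global_mode, half_width,
                            match, mismatch, gap_open, gap_extend);
  ExtResult L = extend_side(al, bl, global_mode, half_width,
                            match, mismatch, gap_open, gap_extend);
  HitCore h;
  h.score = L.score + R.score + k * match;
  h.q_start = q_off - L.qlen;
  h.q_end = q_off + k + R.qlen;
  h.r_start = r_off - L.rlen;
  h.r_end = r_off + k + R.rlen;
  h.matches = k + L.matches + R.matches;
  h.mismatches = L.mismatches + R.mismatches;
  h.gap_opens = L.gap_opens + R.gap_opens;
  h.aln_len = k + L.cols + R.cols;
  return h;
}

// [[Rcpp::export]]
NumericVector cpp_banded_extend(std::string q, std::string r,
                                int q_off, int r_off, int k,
                                bool global_mode, int half_width,
                                int match, int mismatch,
                                int gap_open, int gap_extend) {
  if (half_width < 0) stop("half_width must be >= 0");
  HitCore h = banded_extend_core(q, r, q_off, r_off, k, global_mode, half_width,
                                 match, mismatch, gap_open, gap_extend);
  NumericVector out = NumericVector::create(
      _["score"] = h.score, _["q_start"] = h.q_start, _["q_end"] = h.q_end,
      _["r_start"] = h.r_start, _["r_end"] = h.r_end, _["matches"] = h.matches,
      _["mismatches"] = h.mismatches, _["gap_opens"] = h.gap_opens,
      _["aln_len"] = h.aln_len);
  return out;
}
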