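#include "seedex.h"
#include <algorithm>
#include <cstring>

using namespace Rcpp;

char iupac_complement(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C';
    case 'T': return 'A'; case 'U': return 'A';
    case 'R': return 'Y'; case 'Y': return 'R';
    case 'S': return 'S'; case 'W': return 'W';
    case 'K': return 'M'; case 'M': return 'K';
    case 'B': return 'V'; case 'V': return 'B';
    case 'D': return 'H'; case 'H': return 'D';
    case 'N': return 'N';
    default: return 0;
  }
}

std::string revcomp(const std::string& s) {
  std::string out(s.size(), 0);
  for (size_t i = 0; i < s.size(); ++i) {
    char c = iupac_complement(s[s.size() - 1 - i]);
    if (c == 0)
      stop("non-IUPAC character in sequence: '%c'", s[s.size() - 1 - i]);
    out[i] = c;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_STRING; continue; }
    out[i] = revcomp(as<std::string>(x[i]));
  }
  return out;
}

// Seeds for one query strand against the index. Every candidate is verified
// by direct window comparison, which both guards against key rounding at
// large k and enforces seed soundness.
// [[Rcpp::export]]
DataFrame cpp_seed_query(std::string qseq, int k,
                         NumericVector nr_keys, IntegerVector cell_size,
                         IntegerVector gateway, IntegerVector sorted_seq,
                         IntegerVector sorted_off, CharacterVector frag_seqs) {
  std::vector<int> q_off, r_ord, r_off;
  int n = (int)qseq.size();
  for (int o = 0; o + k <= n; ++o) {
    bool amb = false;
    uint64_t key = 0;
    for (int t = 0; t < k; ++t) {
      int c = base2(qseq[o + t]);
      if (c < 0) { amb = true; break; }
      key = (key << 2) | (uint64_t)c;
    }
    if (amb) continue;
    double dk = (double)key;
    NumericVector::iterator it =
        std::lower_bound(nr_keys.begin(), nr_keys.end(), dk);
    if (it == nr_keys.end() || *it != dk) continue;
    int idx = (int)(it - nr_keys.begin());
    int cs = cell_size[idx], gw = gateway[idx];
    for (int t = 0; t < cs; ++t) {
      int so = sorted_off[gw + t], sq = sorted_seq[gw + t];
      const char* fs = CHAR(STRING_ELT(frag_seqs, sq - 1));
      if (strncmp(fs + so, qseq.c_str() + o, k) != 0) continue;
      q_off.push_back(o);
      r_ord.push_back(sq);
      r_off.push_back(so);
    }
  }
  return DataFrame::create(_["query_offset"] = q_off,
                           _["ref_ordinal"] = r_ord,
                           _["ref_offset"] = r_off,
                           _["stringsAsFactors"] = false);
}

// Two-pass surrounding-area filter on a sorted seed list.
// Pass 1 removes every seed whose successor (next in sorted order, same
// group) is not inside its surrounding area; pass 2 removes every pass-1
// survivor whose successor in the remaining, re-linked list is inside its
// surrounding area. A seed with no successor counts as "not in area".
std::vector<char> reduce_seeds_core(const std::vector<int>& grp,
                                    const std::vector<int>& ref_off,
                                    const std::vector<int>& diag,
                                    int z, int w) {
  int n = (int)grp.size();
  std::vector<char> keep(n, 0);
  auto in_area = [&](int a, int b) {
    if (grp[a] != grp[b]) return false;
    int dd = diag[b] - diag[a];
    if (dd < 0) dd = -dd;
    if (dd > z) return false;
    int dr = ref_off[b] - ref_off[a];
    return dr > 0 && dr <= w;
  };
  std::vector<int> surv;
  for (int i = 0; i < n; ++i)
    if (i + 1 < n && in_area(i, i + 1)) surv.push_back(i);
  for (size_t s = 0; s < surv.size(); ++s) {
    bool next_in = (s + 1 < surv.size()) && in_area(surv[s], surv[s + 1]);
    if (!next_in) keep[surv[s]] = 1;
  }
  return keep;
}

// [[Rcpp::export]]
LogicalVector cpp_reduce_keep(IntegerVector grp, IntegerVector ref_off,
                              IntegerVector diag, int z, int w) {
  std::vector<int> g(grp.begin(), grp.end());
  std::vector<int> r(ref_off.begin(), ref_off.end());
  std::vector<int> d(diag.begin(), diag.end());
  std::vector<char> keep = reduce_seeds_core(g, r, d, z, w);
  LogicalVector out(keep.size());
  for (size_t i = 0; i < keep.size(); ++i) out[i] = (bool)keep[i];
  return out;
}

// Seed + reduce + extend for a batch of queries against one index.
// Returns raw hit rows; coordinates are 0-based half-open on the searched
// strand / fragment, lifted to parent coordinates by the R layer.
// [[Rcpp::export]]
DataFrame cpp_search_batch(CharacterVector queries, CharacterVector frag_seqs,
                           NumericVector nr_keys, IntegerVector cell_size,
                           IntegerVector gateway, IntegerVector sorted_seq,
                           IntegerVector sorted_off,
                           int k, int z, int w, bool global_mode,
                           int half_width, int match, int mismatch,
                           int gap_open, int gap_extend, bool both_strands) {
  std::vector<int> o_query, o_strand, o_frag;
  std::vector<int> o_qs, o_qe, o_rs, o_re;
  std::vector<int> o_score, o_matches, o_mismatches, o_gapopens, o_alnlen;

  int nfrag = frag_seqs.size();
  std::vector<std::string> frags(nfrag);
  for (int i = 0; i < nfrag; ++i) frags[i] = as<std::string>(frag_seqs[i]);

  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string fwd = as<std::string>(queries[qi]);
    for (int strand = 0; strand < (both_strands ? 2 : 1); ++strand) {
      std::string qseq = strand == 0 ? fwd : revcomp(fwd);
      int n = (int)qseq.size();
      if (n < k) continue;
      // seeds
      std::vector<int> s_qoff, s_rord, s_roff;
      for (int o = 0; o + k <= n; ++o) {
        bool amb = false;
        uint64_t key = 0;
        for (int t = 0; t < k; ++t) {
          int c = base2(qseq[o + t]);
          if (c < 0) { amb = true; break; }
          key = (key << 2) | (uint64_t)c;
        }
        if (amb) continue;
        double dk = (double)key;
        NumericVector::iterator it =
            std::lower_bound(nr_keys.begin(), nr_keys.end(), dk);
        if (it == nr_keys.end() || *it != dk) continue;
        int idx = (int)(it - nr_keys.begin());
        int cs = cell_size[idx], gw = gateway[idx];
        for (int t = 0; t < cs; ++t) {
          int so = sorted_off[gw + t], sq = sorted_seq[gw + t];
          if (frags[sq - 1].compare(so, k, qseq, o, k) != 0) continue;
          s_qoff.push_back(o);
          s_rord.push_back(sq);
          s_roff.push_back(so);
        }
      }
      int ns = (int)s_qoff.size();
      if (ns == 0) continue;
      // sort by (ref_ordinal, ref_offset, diagonal)
      std::vector<int> ord(ns);
      for (int i = 0; i < ns; ++i) ord[i] = i;
      std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
        if (s_rord[a] != s_rord[b]) return s_rord[a] < s_rord[b];
        if (s_roff[a] != s_roff[b]) return s_roff[a] < s_roff[b];
        return (s_roff[a] - s_qoff[a]) < (s_roff[b] - s_qoff[b]);
      });
      std::vector<int> g(ns), ro(ns), dg(ns);
      for (int i = 0; i < ns; ++i) {
        g[i] = s_rord[ord[i]];
        ro[i] = s_roff[ord[i]];
        dg[i] = s_roff[ord[i]] - s_qoff[ord[i]];
      }
      std::vector<char> keep = reduce_seeds_core(g, ro, dg, z, w);
      for (int i = 0; i < ns; ++i) {
        if (!keep[i]) continue;
        int si = ord[i];
        const std::string& ref = frags[s_rord[si] - 1];
        HitCore h = banded_extend_core(qseq, ref, s_qoff[si], s_roff[si], k,
                                       global_mode, half_width, match,
                                       mismatch, gap_open, gap_extend);
        if (!global_mode && h.score <= 0) continue;
        o_query.push_back(qi + 1);
        o_strand.push_back(strand);
        o_frag.push_back(s_rord[si]);
        o_qs.push_back(h.q_start);
        o_qe.push_back(h.q_end);
        o_rs.push_back(h.r_start);
        o_re.push_back(h.r_end);
        o_score.push_back(h.score);
        o_matches.push_back(h.matches);
        o_mismatches.push_back(h.mismatches);
        o_gapopens.push_back(h.gap_opens);
        o_alnlen.push_back(h.aln_len);
      }
    }
  }
  return DataFrame::create(
      _["query"] = o_query, _["strand"] = o_strand, _["frag"] = o_frag,
      _["q_start"] = o_qs, _["q_end"] = o_qe, _["r_start"] = o_rs,
      _["r_end"] = o_re, _["score"] = o_score, _["matches"] = o_matches,
      _["mismatches"] = o_mismatches, _["gap_opens"] = o_gapopens,
      _["aln_len"] = o_alnlen, _["stringsAsFactors"] = false);
}
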