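#pragma once

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>

// 2-bit base codes: A=0, C=1, G=2, T=3; -1 for anything else.
static inline int base2(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

char iupac_complement(char c);  // throws on non-IUPAC input
std::string revcomp(const std::string& s);

// One-sided banded extension, anchored at the origin (a seed edge).
// a = query residues in extension direction, b = reference residues.
struct ExtResult {
  int score;      // best extension score (0 = empty extension)
  int qlen;       // query residues consumed
  int rlen;       // reference residues consumed
  int matches;
  int mismatches;
  int gap_opens;
  int cols;       // alignment columns (incl. gap columns)
};

ExtResult extend_side(const std::string& a, const std::string& b,
                      bool global_mode, int half_width,
                      int match, int mismatch, int gap_open, int gap_extend);

// Full two-sided extension around a seed; coordinates are 0-based offsets
// into q and r. Returns score and hit geometry.
struct HitCore {
  int score;
  int q_start, q_end;   // half-open
  int r_start, r_end;   // half-open
  int matches, mismatches, gap_opens, aln_len;
};

HitCore banded_extend_core(const std::string& q, const std::string& r,
                           int q_off, int r_off, int k,
                           bool global_mode, int half_width,
                           int match, int mismatch, int gap_open, int gap_extend);

// Two-pass surrounding-area seed filter on a sorted seed list.
// grp identifies (query, reference, strand) groups; arrays must already be
// sorted by (grp, ref_off, diag). Returns the survivor mask.
std::vector<char> reduce_seeds_core(const std::vector<int>& grp,
                                    const std::vector<int>& ref_off,
                                    const std::vector<int>& diag,
                                    int z, int w);
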