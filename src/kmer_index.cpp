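#include "seedex.h"
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Keys are 2-bit packed, most significant base first, held in uint64 and
// surfaced to R as doubles (exact for k <= 26; the seeding stage verifies
// every candidate seed by direct window comparison, so larger k stays sound).

static uint64_t encode_window(const char* s, int k, bool& ambiguous) {
  uint64_t v = 0;
  ambiguous = false;
  for (int i = 0; i < k; ++i) {
    int c = base2(s[i]);
    if (c < 0) { ambiguous = true; return 0; }
    v = (v << 2) | (uint64_t)c;
  }
  return v;
}

// [[Rcpp::export]]
double cpp_encode_kmer(std::string window, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  if ((int)window.size() != k) stop("window length must equal k");
  bool amb;
  uint64_t v = encode_window(window.c_str(), k, amb);
  if (amb) return NA_REAL;
  return (double)v;
}

// Sliding-window k-mer extraction starting at `start`, stepping by p.
// Windows containing non-ACGT letters are dropped.
// [[Rcpp::export]]
List cpp_extract_kmers(std::string seq, int k, int p, int start) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  if (p < 1) stop("p must be >= 1");
  if (start < 0) stop("start must be >= 0");
  int n = (int)seq.size();
  std::vector<double> keys;
  std::vector<int> offs;
  for (int o = start; o + k <= n; o += p) {
    bool amb;
    uint64_t v = encode_window(seq.c_str() + o, k, amb);
    if (amb) continue;
    keys.push_back((double)v);
    offs.push_back(o);
  }
  return List::create(_["keys"] = NumericVector(keys.begin(), keys.end()),
                      _["offsets"] = IntegerVector(offs.begin(), offs.end()));
}

// Build the read-only q-gram index: stable co-sort of (key, value) pairs,
// deduplicated key array, per-key redundancy counts, gateway = exclusive
// prefix sum of the PRE-masking counts, then counts above the repeat
// threshold overwritten with zero.
// [[Rcpp::export]]
List cpp_build_index(NumericVector keys, IntegerVector val_seq,
                     IntegerVector val_off, double repeat_threshold) {
  int n = keys.size();
  if (val_seq.size() != n || val_off.size() != n)
    stop("keys and values must have equal length");
  if (!(repeat_threshold >= 1)) stop("repeat_threshold must be >= 1");
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return keys[a] < keys[b]; });

  NumericVector skeys(n);
  IntegerVector sseq(n), soff(n);
  for (int i = 0; i < n; ++i) {
    skeys[i] = keys[ord[i]];
    sseq[i] = val_seq[ord[i]];
    soff[i] = val_off[ord[i]];
  }

  std::vector<double> nr;
  std::vector<int> count;
  for (int i = 0; i < n; ) {
    int j = i;
    while (j < n && skeys[j] == skeys[i]) ++j;
    nr.push_back(skeys[i]);
    count.push_back(j - i);
    i = j;
  }
  int m = (int)nr.size();
  IntegerVector gateway(m), cell(m);
  int acc = 0;
  for (int i = 0; i < m; ++i) {
    gateway[i] = acc;
    acc += count[i];
    cell[i] = ((double)count[i] > repeat_threshold) ? 0 : count[i];
  }
  return List::create(
      _["sorted_keys"] = skeys, _["sorted_seq"] = sseq, _["sorted_off"] = soff,
      _["nonredundant_keys"] = NumericVector(nr.begin(), nr.end()),
      _["cell_size"] = cell, _["gateway"] = gateway);
}

// Binary search for each query key (leftmost exact match); absence yields
// cell_size 0 (gateway slot reported as NA).
// [[Rcpp::export]]
List cpp_lookup(NumericVector nr_keys, IntegerVector cell_size,
                IntegerVector gateway, NumericVector query_keys) {
  int nq = query_keys.size();
  IntegerVector gw(nq), cs(nq);
  for (int i = 0; i < nq; ++i) {
    double k = query_keys[i];
    if (NumericVector::is_na(k)) { gw[i] = NA_INTEGER; cs[i] = 0; continue; }
    NumericVector::iterator it =
        std::lower_bound(nr_keys.begin(), nr_keys.end(), k);
    if (it != nr_keys.end() && *it == k) {
      int idx = (int)(it - nr_keys.begin());
      gw[i] = gateway[idx];
      cs[i] = cell_size[idx];
    } else {
      gw[i] = NA_INTEGER;
      cs[i] = 0;
    }
  }
  return List::create(_["gateway"] = gw, _["cell_size"] = cs);
}
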