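---
title: "Methods: seed-and-extend search with a read-only q-gram index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-and-extend search with a read-only q-gram index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedex)
```

## The problem

Metagenomic studies map millions of short reads against large collections of
reference genomes, usually to assign each read to a taxon via its best
matching genome. Many reads come from organisms with no sequenced genome, so
the aligner must detect *weak* similarity (to a congeneric relative) rather
than near-identity, and it must do so without an expensive precomputed
database, because reference collections are large and frequently updated.

seedex implements a classic two-phase answer on the CPU. Phase one finds
**seeds** — exact k-mer correspondences between a read and a reference —
through a *read-only q-gram index* built fresh for every reference batch.
Phase two thins the seeds geometrically and extends one representative per
seed cluster by **banded affine-gap dynamic programming**, in either a
glocal (full-query) or a local mode, reporting hits with identities,
similarity scores and Karlin–Altschul E-values.

## The read-only q-gram index

The index is deliberately *not* a hash table. Reference k-mers (sampled
every `p` bases, packed 2 bits per base into an unsigned 64-bit key) and
their positions are stably co-sorted by key, giving a *data array*. From it
we derive an *index array*: the strictly increasing deduplicated key list,
each key's occurrence count (`cell_size`), and the exclusive prefix sum of
those counts (`gateway`). A key's positions are exactly the value-array
slice `[gateway, gateway + cell_size)`; a binary search over the
deduplicated keys answers any query. Batched queries compute a write-index
array — another exclusive prefix sum, over the per-query `cell_size` — so
every query's matches land in a contiguous, precomputed slice of one result
array. Every step (sort, prefix sum, scatter) is a standard data-parallel
primitive, which is what makes the structure attractive; this package runs
them sequentially on one CPU core but keeps the construction.

Memory scales with the number of stored k-mers, never with the key range,
so `k` may be as large as 31 (the 64-bit packing limit). Two details
matter:

* **Repeat masking.** After the gateway is computed, any `cell_size`
  larger than `repeat_threshold` (default 1000) is overwritten with zero:
  over-represented k-mers produce floods of uninformative seeds. Masking
  *after* the prefix sum keeps every unmasked key's slice valid.
* **Key precision at the R boundary.** Inside the C++ core keys live in
  `uint64`; at the R surface they are `double`s, exact up to `k = 26`.
  The seeding stage therefore verifies every candidate seed by direct
  window comparison before emitting it — a guard that simultaneously
  enforces the seed-soundness invariant for all `k` and costs a dozen
  byte comparisons per candidate.

Ambiguous windows (any non-ACGT letter) have no 2-bit code point and are
dropped at extraction time, on both the reference and the query side.

## Seed thinning: the surrounding area

A read aligning to a genome region produces a run of seeds on nearly the
same diagonal; extending each one would repeat the same alignment many
times. The *surrounding area* of a seed covers seeds of the same query,
reference fragment and strand that lie within `z` diagonals and at most `w`
bases ahead along the reference. After sorting seeds by reference location,
two linear passes thin them:

1. remove every seed whose successor is **not** in its surrounding area —
   this deletes isolated seeds and each cluster's last member;
2. over the remaining, re-linked list, remove every seed whose successor
   **is** in its surrounding area — collapsing each surviving run to its
   final member.

A chain of n ≥ 2 successor-linked seeds thus yields exactly one
representative and isolated seeds vanish. "Next" in pass 2 means the
successor in the list *remaining after pass 1*: using original successors
would never remove a survivor whose neighbour was already deleted, and the
filter would not collapse clusters at all.

One caveat is worth stating precisely, because the tests exercise it: the
two passes inspect only immediate successors. When two seed clusters
interleave tightly — the survivor of one cluster landing inside the
surrounding area of the next cluster's survivor — pass 2 merges them into
a single representative, and conversely two survivors that are *not*
consecutive in the list can remain mutually adjacent. On well-separated
clusters (the situation the filter is designed for, and what real seed
patterns look like) neither occurs; on dense adversarial configurations a
transitive-closure clustering and the two-pass scan can disagree. The
package implements the two-pass scan exactly; the test suite checks it
against an independent transcription of the same passes, and flags the
closure-disagreement cases rather than hiding them.

Defaults `z = 16`, `w = 64` were fixed once as plausible cluster
tolerances for substitution-dominated divergence at the default `k = 16`,
`p = 4`; all four are user-adjustable and none comes from a published
value.

## Banded extension

Each representative seed anchors two independent extensions, rightward
from the seed's end and leftward from its start, both confined to DP cells
within `half_width` diagonals of the seed diagonal (default `z + k`,
coupling the band to the largest indel displacement a cluster can have by
construction; `half_width = 0` degenerates to a gapless diagonal scan).
Gaps are affine: a gap of length g costs `gap_open + g * gap_extend`. The
seed interior contributes `k * match` and is never realigned.

The two modes differ only in the endpoint rule:

* **glocal** (the `"global"` mode, default): each extension must consume
  the query to its end on that side, while the reference endpoint floats
  freely within the band. The full query is always covered — the property
  that makes best-hit taxonomic assignment discriminating, since a short
  high-identity island cannot masquerade as a full-read match. When the
  band cannot reach the query end past the reference's edge, the remaining
  query is consumed by continuing a gap along the final reference column;
  this boundary case is handled exactly (both gap-opening and
  gap-extending continuations are scored), so the banded score with a
  full-width band equals the unbanded optimum.
* **local**: each extension stops at its maximum-scoring cell and may be
  empty; negative-scoring flanks are trimmed. Local scores therefore
  dominate glocal scores on the same pair, which is why local mode reports
  at least as many hits and glocal assigns at least as accurately.

Ties in the DP are broken deterministically (diagonal over vertical over
horizontal; gap opening over extension at equal score), so runs are
byte-reproducible. Identity is matched columns over alignment columns,
gap columns included.

E-values use the Karlin–Altschul form
`E = K m n exp(-lambda S)` with `m` the query length and `n` the total
residue count of the reference set in the run (not the batch — batching
must not change reported statistics). The default parameters
(`match = +1`, `mismatch = -3`, `gap_open = -5`, `gap_extend = -2`,
`lambda = 1.28`, `K = 0.46`) are megablast-style conventions, configurable
and not tied to any published calibration; for gapped scores they are an
approximation, as lambda and K strictly describe the ungapped ensemble.
Hits are kept when `evalue <= 1e-3` and the alignment spans at least 30
columns (both inclusive, both configurable).

## Batching, splitting, and why the results do not depend on them

References longer than `L` (default 64 Mb, comfortably above any
prokaryotic genome) are split into fragments of length `L` overlapping by
`overlap` (default `max(2000, 2 *` longest query`)`, so no single-read
alignment can span more than one internal boundary). Three decisions make
the final hit set independent of batching and splitting:

* the k-mer sampling grid is phased to *parent* coordinates, so a split
  reference contributes exactly the k-mers its unsplit parent would;
* hits whose reference interval abuts an internal fragment edge are
  dropped: they are truncation artifacts, and the overlap guarantees the
  untruncated alignment is recovered intact from the neighbouring
  fragment (for any hit shorter than the overlap);
* duplicate hits arising inside overlaps are collapsed after lifting
  fragment coordinates back to the parent, and E-values always use the
  global database length.

One index is built per reference batch and discarded afterwards — there is
deliberately no on-disk index format.

## The synthetic benchmark

`generate_community()` emulates the structure of the simulated
metagenomic evaluation: labelled genomes with known genus structure and
reads of known origin. One random ancestor per genus (independent
ancestors by default; optionally derived from a shared root at
`inter_rate`), `genomes_per_genus` genomes per ancestor at i.i.d.
per-base substitution rate `intra_rate` (default 0.05 — congeneric
genomes then sit near 90% identity, a realistic within-genus figure), and
reads sampled uniformly over genomes, positions and strands. Reads are
verbatim by default (`error_rate = 0`), matching a protocol that retrieves
fragments directly from the reference sequences; a substitution-only error
model is available. Mutation is substitution-only by design — fragment
retrieval introduces no indels — so indel robustness is exercised by the
alignment tests, not the community generator.

Evaluation mirrors the protocol: search, delete hits to the read's own
source genome, take the best non-self hit per read (score, then E-value,
then lexicographic reference id, then reference start — the last two are
pure determinism tie-breaks), and score the **CGA ratio**: correct genus
assignments over total reported hits. `threshold_sweep()` repeats the
evaluation after discarding hits below identity thresholds (0.95, 0.90,
0.85, 0.80) or below 50% query coverage, reporting the unfiltered point
plus one per threshold.

What the generator does *not* model — real taxonomy structure, shared
genes between genera, repeats, indel sequencing errors, non-uniform
abundance — bounds what passing benchmarks show: they certify the search
machinery and the protocol wiring, not performance on real communities.

## Problem sizes used by the shipped benchmarks

The test-suite and the acceptance script run the protocol at desk scale,
chosen once to keep a full run in minutes on one core: self-recovery uses
1000 reads of 100 bases against ten independent 100-kb genomes
(error-free and at 5% substitution error); the miniature protocol uses
5 genera × 3 genomes of 100 kb with 2500 reads per read length (100 and
800 bases), both alignment modes, five generator seeds. At those sizes
error-free self-recovery is exact (100% of reads at their true
coordinates with identity 1.0), ~98% of 5%-error reads are still reported
(essentially all to the true genome), and the sweep's hit counts decrease
monotonically with the identity threshold.

## Known limitations

* Contiguous k-mer seeds only — no spaced seeds, no minimizers; two
  substitutions 15 bases apart already erase every seed at `k = 16`
  (lower `k` or `p` to trade speed for sensitivity).
* The two-pass seed filter can merge interleaved clusters (see above);
  consequences are limited to occasionally extending one representative
  where two clusters overlap geometrically.
* Karlin–Altschul parameters are fixed constants, not estimated per
  scoring scheme or composition.
* No paired-end awareness, no SAM output, and no attempt to reproduce
  GPU execution — the algorithms are kept in their data-parallel form but
  run on one CPU core.
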