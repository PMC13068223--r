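---
title: "From rolling-circle concatemer reads to polished plasmid sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From rolling-circle concatemer reads to polished plasmid sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concatemeR)
```

## The problem

Rolling-circle amplification (RCA) of a circular plasmid produces long
linear DNA in which the plasmid appears as head-to-tail tandem repeats.
Nanopore sequencing of that DNA yields noisy long reads, each covering one
molecule: several complete turns of one plasmid plus partial turns at the
read ends, starting at an arbitrary phase of the circle and on an arbitrary
strand. Because every repeat in one read is an independent observation of
the same molecule, the repeats can be collapsed into a per-read consensus
far more accurate than any raw read; and because all consensus reads of one
plasmid share its length, a pool of plasmids can be demultiplexed purely by
read length, with no barcoding, as long as the plasmid lengths differ by at
least about 1%. concatemeR implements this whole chain — splint-free repeat
detection, per-read consensus, length demultiplexing, circular-aware
polishing, and evaluation — together with a truth-annotated simulator, so
the statistical behaviour of every stage can be verified end to end without
any sequencing data.

## Splint-free repeat detection

Classic concatemer pipelines locate repeat boundaries by searching for a
known splint (adapter) sequence. Plasmids amplified directly by RCA contain
no splint, so the package instead copies a 200-base **anchor** from inside
the read itself (after skipping `anchor_offset = 250` bases of typically
low-quality read start) and finds all of its approximate recurrences by a
semi-global edit-distance scan (at most 30% of the anchor length in edits,
non-overlapping hits selected greedily by score). The anchor recurs once
per repeat; hit spacing estimates the repeat length and the hit positions
are the split points. Reads with fewer than two hits carry less than one
observable repeat and are skipped. If the full subreads between boundaries
deviate from their median length by more than `tolerance_fraction = 0.05`,
splitting is considered faulty — an internal tandem duplication inside the
plasmid makes the anchor recur at sub-unit spacing — and the read is
excluded rather than risking a collapsed consensus.

The parameters that matter here, with their defaults:

| parameter | default | meaning |
|---|---|---|
| `anchor_offset` | 250 bases | read-start bases skipped before the anchor |
| `anchor_length` | 200 bases | anchor size; recurrences mark boundaries |
| `max_error_fraction` | 0.30 | anchor-match edit budget, fraction of anchor |
| `tolerance_fraction` | 0.05 | full-subread length-consistency band |
| `partial_min_fraction` | 0.20 | terminal flank kept if ≥ this × repeat length |

The anchor-match budget of 30% leaves room for ~10% raw error on both the
anchor copy and the target occurrence while keeping chance matches of a
200-mer negligible. All coordinates in the package are 1-based and closed,
the R convention.

## Per-read consensus

Full subreads are combined by center-star progressive alignment: the
subread whose length is closest to the median is the center, all full
subreads are pairwise-aligned to it, and each column is called by
plurality. The rough consensus is then polished once more using **all**
subreads — including the terminal partial flanks, which carry real signal
but are never counted in the subread coverage reported for ranking.

The polisher is a quality-aware pileup caller shared by every polishing
step in the package. Each evidence read is aligned to the template (global
in the evidence, local in the template; unit edit costs); per template
column the plurality symbol among {A, C, G, T, deletion} wins, and an
inserted run is emitted where the top inserted string outweighs the
spanning evidence that saw no insertion. Three details matter for
correctness:

* **Tie-breaks are conservative.** A tied vote keeps the template symbol:
  the polisher never changes the template without majority evidence.
* **Indel placements are left-normalized.** Equivalent-cost alignments can
  attach the same insertion or deletion at several positions inside a
  repeated context, and forward- versus reverse-oriented evidence would
  otherwise split the vote between the two ends of a run. Every indel is
  shifted to its leftmost equivalent position before voting.
* **Homopolymer runs are resolved jointly.** For each template run of one
  base (≥ 4 bases), each spanning evidence read contributes its observed
  run length (aligned bases of the run base plus pure-base insertions at
  the run); the emitted length is the weighted median. When the median is
  an interval, the template's own length is kept if it lies inside it.
  A winning insertion of *foreign* bases inside the run disables the joint
  call for that run — that pattern means the template fused two runs by a
  deletion, and the column-wise machinery handles it correctly.

Under `weighting = "uniform"` every read votes with weight 1; under
`"quality"` a read votes with `1 - 10^(-Q/10)` where Q is its
probability-space mean quality (per-base error probabilities averaged, then
converted back to the Phred scale — the reading of "estimated error rate"
that makes Q20+Q40 average to Q23, not Q30). Evidence `N` bases never vote.
An evidence read whose edit distance to the template exceeds 40% of its own
length is dropped; if all evidence is dropped the polish fails explicitly.
The 40% threshold is taken against the evidence length rather than the
template length because legitimate evidence (partial flanks, split pieces)
can be much shorter than the template.

## Length demultiplexing

Consensus-read lengths are binned in a histogram with relative bin width
0.005; bins holding at least `cutoff_percent` of all reads that are local
maxima become peaks, and adjacent above-threshold bins merge into one peak
at the mean member length. `cutoff_percent` is interpreted as percent of
the total read count in the run — a floor on minor-species abundance,
which is the only reading under which a pooled setting of 2 makes sense —
and is exposed as a flag (10 is the single-plasmid default, 2 the pooled
default). Members are reads within 1% of the peak center. Two species
whose lengths differ by about 2% or more separate cleanly; at 0.5%
separation their bins are adjacent and merge into one peak — the
documented resolution limit of demultiplexing by length.

## Circular polishing of one plasmid per peak

Within a peak, consensus reads are ranked by (subread coverage, mean
subread Q) and the top `iterations` of them (default 100) are polished
independently; the evidence is the peak's top `n_subreads` subreads by mean
Q (default 500). Each template is **padded** by appending the first half of
its own sequence, so no alignment is truncated at the arbitrary circular
origin; it is then polished twice — a uniform-weight round followed by a
quality-weighted round — and cut back to unit length at the coordinate-map
image of the unpadded template end.

Two geometric details are easy to get wrong:

* **Evidence phase.** A full-length subread is one complete turn starting
  at an arbitrary phase; if its phase is offset from the template origin by
  more than half a unit it cannot align contiguously to the 1.5-unit padded
  template. Aligning naive half-unit pieces instead works, but dilutes
  coverage near the origin between its two images in the padded template
  (position *p* and *p + U*), leaving the head columns nearly unprotected.
  The package therefore rotates every full-length subread to the template
  origin before alignment (locating the origin in the subread with a
  200-base probe from the template start, in both orientations); only
  partial flanks and subreads whose origin probe spans their own seam are
  split into half-unit pieces, which always place contiguously.
* **The cut.** Indels during polishing can shift the image of the unpadded
  end by a base or two, so the cut is refined within ±2 bases to the
  position where the trimmed-away pad best replicates the output start —
  the self-consistency a correct circular cut must satisfy.

One representative per peak is chosen as the modal sequence among the
iteration outputs after canonicalization (lexicographically minimal
rotation over both strands, Booth's algorithm); ties resolve toward the
highest-ranked template's output. Reporting a representative is an
addition beyond simply emitting all iterations, and all iterations are
still written.

## Evaluation against a circular reference

A query is aligned against the doubled reference in both orientations; the
best alignment is decomposed into at most two segments in reference
coordinates (the primary alignment plus the wrap-around secondary), whose
counts are summed. Identity is `100 × matches / (matches + mismatches +
indels)`; its Phred conversion is `Q = -10 log10(1 - identity/100)` (so
99.86% ↔ Q28.54, displayed Q28; a perfect alignment is capped at Q93). A
sequence is **full-length error-free** iff its length equals the reference
length exactly and the circular alignment contains zero mismatches and
zero indels — rotation- and strand-invariant by construction. Alignments
below 60% identity are rejected as unalignable, a threshold low enough to
keep genuine low-quality subreads (80–90%) while discarding junk.
Per-position error profiles attribute each insertion to the reference
position it follows (circularly) and count at most one insertion event per
query and position.

## The simulator: what it emulates, and what not

`make_plasmid()` draws a random circular sequence at a chosen GC fraction
and can embed homopolymer runs verbatim at fixed positions (e.g. 8 Cs and
16 Gs) for stress tests. `simulate_concatemer_read()` traverses the circle
from a uniform phase on a uniform strand for a chosen number of template
bases, then applies independent per-base substitution, insertion and
deletion errors. Defaults are `sub = 0.4%`, `ins = 0.3%`, `del = 0.3%` —
1% total, consistent with raw subread accuracies around 99% — and are
configurable, not asserted facts about any particular basecaller. Inside
homopolymer runs of ≥ 6 bases the indel rates are multiplied by
`homopolymer_indel_boost` (default 3) and inserted bases extend the run,
emulating systematic run-length miscalls; emitted qualities are a constant
`round(-10 log10(total error rate))` everywhere, deliberately *not*
lowered inside boosted runs, because systematic nanopore errors are
quality-blind. Read lengths follow a log-normal distribution whose mode
can sit well below the molecule length, reproducing the short-read bias of
nanopore sequencers against long RCA molecules.

The simulator does not emulate signal-level artifacts, chimeric reads,
barcodes, quality-informative errors, or context-dependent error hotspots
beyond homopolymers. Consequently, passing tests demonstrate the
statistical machinery — boundary detection, voting, demultiplexing,
circular bookkeeping — under a faithful error *structure*, but say nothing
about basecaller-specific biases on real flow-cell data.

## The two homopolymer regimes

With run-length errors calibrated so that about half the evidence misreads
a 16-base run, two regimes emerge. Under **balanced** noise (insertions
and deletions equally boosted) the weighted median still recovers the true
length, so polishing rescues templates with wrong run lengths and the
polished error-free fraction is at least the template fraction — tested as
a property. Under **deletion-dominant** noise (the realistic nanopore
regime; deletion rate boosted to ~4.8%/base so P(run read short) ≈ 0.55)
the pooled median itself flips one base short: the error-free output
fraction drops below 1 and every residual error localizes to the run,
while positions outside the runs remain error-free. Both regimes are
exercised in the test suite; the deletion-biased one is the package's
stress benchmark. Note that in this regime polishing can be worse than a
lucky individual template: with quality-blind systematic error there is no
signal left that could outvote the biased majority — which is precisely
why long homopolymers remain the residual failure mode of this class of
methods, whatever the polisher.

## Numerical and design choices

* Alignment uses unit edit costs (Levenshtein) throughout, implemented in
  C++ as banded dynamic programming with automatic band widening, so a
  15 kb query against a 30 kb doubled reference stays within memory and
  seconds. Bands are provably sufficient before a result is accepted.
* The rough-consensus backend is center-star progressive alignment behind
  the `rough_consensus()` contract; a partial-order-alignment backend
  could replace it without touching anything downstream.
* The polish pass is this package's own pileup caller by design, at
  contract level (plurality + run-length median + coordinate map), rather
  than a reimplementation of any specific window/POA polisher; the
  accuracy behaviour it reproduces is coverage-driven.
* Determinism: every stochastic step takes an explicit seed; derived seeds
  for pipeline stages are computed from the master seed and kept within
  32-bit range. Ranking ties break lexicographically by read id, vote ties
  toward the template, so whole-pipeline outputs are byte-identical under
  a fixed seed.
* Degenerate inputs: a single full subread is its own rough consensus;
  a single-member peak is polished as-is; fewer than 5 evidence subreads
  warns but proceeds; empty FASTQ files yield empty streams.
* Problem sizes in the tests and the acceptance script — a 3 kb plasmid
  with 300 reads for parameter recovery, a 160-read pool of 5/6/9/15 kb
  plasmids for demultiplexing, 40–80 reads for the accuracy and
  homopolymer studies — were chosen as the smallest runs at which the
  binomial/multinomial assertions have comfortable statistical margins.

## Known limitations

* Plasmids of identical length but different sequence cannot be separated
  by length demultiplexing; that is a limitation of the method itself.
* Very long plasmids are covered by few full repeats per read, so subread
  coverage — and with it consensus accuracy — drops with plasmid length.
* Long homopolymers under deletion-dominant systematic error can defeat
  run-length voting (see above); the residual error is a ±1 run-length
  miscall localized to the run.
* The evaluator uses a single alignment path (doubled-reference edit
  alignment) for both completeness and accuracy, rather than reconciling
  two different aligners' views.
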