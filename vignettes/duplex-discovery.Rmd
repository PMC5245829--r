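---
title: "Small RNA duplex discovery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small RNA duplex discovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(dinomir)
```

## The problem

Dinoflagellates regulate much of their gene expression
post-transcriptionally, and circadian systems such as the bioluminescent
*Lingulodinium polyedrum* are a natural place to ask whether miRNAs
contribute: translation of proteins such as the luciferin binding
protein (LBP) is clock-controlled while transcript levels are not. A
stranded small-RNA library can answer two questions at once — are there
small RNAs with the structural signature of Dicer products, and do any
of them sit antisense to circadian-regulated transcripts?

`dinomir` implements that analysis as a reusable pipeline. Its single
structural criterion for a miRNA candidate is the geometry of a Dicer
product: two small RNAs that anneal antiparallel leaving exactly 2-nt
single-stranded 3′ overhangs at both ends, with at most 3 mismatches and
at most 1 single-base bulge in the paired region.

## Pipeline stages and their parameters

### Cleaning cascade

`run_cascade()` executes, in order: 3′ adapter trimming, rRNA
subtraction, tRNA subtraction, polyA-read removal, size selection, a
second rRNA/tRNA pass, and organelle (mitochondrial/plastid)
subtraction. Each stage's surviving count and percent-of-initial
(half-up, one decimal — the convention of published accounting tables)
are recorded.

Parameter defaults, with rationale:

* **adapter** — the TruSeq small-RNA 3′ adapter
  (`TGGAATTCTCGGGTGCCAAGG`). Library kits differ, so this is a required
  config value with a documented default. Trimming prefers a full
  internal adapter occurrence (leftmost) and otherwise accepts an
  adapter prefix of ≥3 nt at the read's 3′ end; reads reduced to nothing
  are rejected.
* **polya_max_run = 6** — reads containing a run of more than 6
  consecutive `A` anywhere are removed. The run is internal, not merely
  a 3′ tail: polyadenylated degradation products can be ligated in
  either register.
* **size_min/size_max = 18/26 nt** — the canonical small-RNA window,
  inclusive at both ends.
* **max_mismatches = 0** — reference subtraction removes a read iff it
  occurs as a contiguous substring of a reference sequence on either
  strand. Reads this short make a k-mer/substring test equivalent to an
  aligner in practice; a tolerance of 1 approximates a short-read
  aligner's mismatch allowance and is config-exposed. `N` never matches
  at tolerance 0 unless the reference also carries `N`.
* The **second rRNA/tRNA pass** re-runs subtraction after trimming and
  size selection, which can expose matches hidden by the adapter.

Quality-based filtering is deliberately out of scope: the cascade takes
already quality-filtered reads.

### Collapse and abundance filter

`collapse_reads()` tallies identical sequences (strand-literal — the
library is directional, so a read and its reverse complement are
different observations) and `filter_min_count()` keeps sequences seen in
at least 5 raw reads. The boundary is inclusive: "fewer than 5" is
removed, count 5 survives.

### Contig filter

mRNA degradation fragments tile their source transcript, so they chain
into long contigs whose members all lie in one direction; genuine
guide/star pairs at most assemble with each other, in opposite
orientations. `assemble_contigs()` performs greedy agglomeration:
repeatedly merge the pair of units with the longest exact overlap
(suffix–prefix of ≥14 nt, or containment), trying both orientations,
until no qualifying overlap remains. Ties pick the lexicographically
smallest merged sequence, which makes assembly deterministic. Only
100%-identity merges are allowed — mismatch-tolerant assembly would blur
the "defined ends" evidence the filter relies on.

`filter_long_unidirectional()` then removes the member reads of every
contig that is strictly longer than the median contig length (or an
explicit threshold) *and* single-direction. Design choices worth
stating:

* Singleton (unassembled) reads are never removed: they carry no length
  evidence beyond themselves, and removing them would empty the
  candidate pool.
* The median is computed over multi-member contig lengths and is
  config-overridable, since a fixed threshold is sometimes preferable
  when the contig population is small (with very few contigs the median
  can land *on* a fragment chain, which then survives the strict
  inequality — the test suite exercises exactly this edge).
* The threshold is strict (`>`): a contig exactly at the median is kept.
* Reads in retained (short or bidirectional) contigs stay in the
  candidate pool alongside the unassembled reads.

### Duplex search

`pair_duplex()` is the core primitive. For reads `a` and `b` it removes
exactly 2 bases from each 3′ end (the overhangs, unconstrained in
sequence), reverse-complements one pairing region and scores the
remaining gapless-or-one-bulge global alignment:

* Watson–Crick pairs only; G:T (G:U) wobble counts as a mismatch,
  consistent with searching in DNA space; `N` pairs with nothing.
* A bulge is one unpaired base on either strand strictly inside the
  pairing region. A terminal gap would change the overhang length, so it
  is not a bulge. Consequently valid partners differ in length by at
  most 1.
* When several bulge placements tie on mismatch count, the leftmost (in
  alignment coordinates along the first argument) is reported; mismatch
  and bulge *counts* are symmetric in the argument order.
* The alignment is an exhaustive minimum over bulge placements, not a
  heuristic: candidate sets after filtering are small, so correctness is
  cheap.

`find_duplexes()` partitions candidates by length and tests each
sequence only against lengths L−1, L and L+1 — the only geometrically
possible partners — emitting each unordered pair once. Self-pairing is
tested rather than excluded. An independent brute-force enumeration
(every pair, every bulge placement) is kept in the test suite and the
acceptance script as an oracle; the search must match it exactly.

One boundary case deserves a note: a homopolymer `A` read and a
homopolymer `T` read of the same length *do* form a perfect duplex —
poly(T) is precisely the perfect-partner construction
`revcomp(a[1:(n-2)]) + overhang` applied to poly(A). The package treats
complementarity physically; any intuition that "A aligned to A after
reverse complement" is a mismatch gets the sign of the test wrong.

### Transcript profiling

`map_reads()` reports every occurrence of a read (sense) and of its
reverse complement (antisense) on a transcript — exact matching by
default, ≤2 mismatches configurable — and `profile_transcript()`
aggregates count-weighted totals, per-strand coverage and antisense
mappings inside a declared 3′ UTR. Weighting by collapsed copy counts is
the default (totals then equal raw mapped reads); unweighted mode counts
unique sequences. The full cleaned, collapsed read set is profiled, not
just the duplex candidates: sense-only fragment coverage is itself the
diagnostic signature.

`classify_pattern()` encodes the three empirical coverage patterns: `A`
— literally zero antisense reads (degradation-fragment signature); `C` —
antisense fraction above 20%; `B` — anything in between. The A/B
boundary is exact zero by definition of the pattern; only the B/C
threshold is tunable.

`build_pfm()` aligns near-identical read families without gaps by
anchoring each sequence on its leftmost occurrence of the longest
substring common to the whole set, then counts bases per column.
Majority consensus, ties alphabetical. A full multiple alignment would
be overkill for families that differ at a handful of positions.

## The synthetic library

`generate_library()` emulates a stranded TruSeq-style small-RNA library
with complete ground truth. The default configuration *is* the package's
reference validation scenario:

* **20 duplex loci**, lengths allocated over 18–26 nt by largest
  remainder from a unimodal weight vector with mode 22 (so the planted
  length distribution, and hence the modal candidate length, is exact at
  any locus count), guide:star copy ratio **50:1** with star depth 5 —
  the star strand must clear the 5-copy abundance filter or the pipeline
  could never recover the pair, and 5 is the smallest depth that does.
* **5000 mRNA degradation fragments** (1000 per bundled transcript),
  tiled left-to-right with adjacent overlaps ≥14 nt so that the contig
  filter — not the duplex filter — is what removes them.
* **20% contaminants** of the total library (8% rRNA, 5% tRNA, 4%
  organelle, 3% polyA), apportioned by largest remainder so class counts
  are deterministic. Organelle contaminants are drawn at 18–26 nt so
  they survive size selection and are removed at their own stage;
  rRNA/tRNA contaminants may be longer since their stages precede size
  selection. Contaminant draws that would contain a polyA run are
  redrawn, so each class is removed at exactly its designated stage.
* Every read gets the full 3′ adapter appended and constant high
  qualities (cleaning is not quality-aware by design).

What the simulator does *not* model: sequencing errors, quality decay,
ligation bias, expression-level heterogeneity across loci, and partial
adapter read-through. Passing recovery tests therefore demonstrates the
pipeline's logic — stage ordering, boundary conditions, geometry — on
idealized composition, not robustness to platform noise.

Bundled reference fixtures (`inst/extdata/synthetic_*.fa`) are random
sequences generated by `data-raw/make_fixtures.R` under constraints (no
polyA runs, no shared 14-mers between entries) so tests run offline and
cannot cross-match; they are synthetic, not biological sequences.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open throughout; FASTA/FASTQ I/O is
  1-based only at the file boundary.
* The internal alphabet is DNA (`U` → `T` on input): probe and search
  operations live in DNA space, and one canonical alphabet avoids double
  bookkeeping.
* Percentages use half-up rounding to one decimal.
* Empty inputs: an empty library yields a report with all counts 0 and
  percents defined as 0.0; empty collapsed sets propagate as empty
  results rather than errors; a transcript with no mapped reads has an
  undefined pattern (error) rather than a default.
* Collapse ordering (count descending, then sequence lexicographic),
  assembly tie-breaks and largest-remainder allocation make every
  analysis stage fully deterministic; the only randomness in the package
  is the simulator's, driven by a single seed.

## Problem sizes used in validation

The shipped tests and the acceptance script run the full pipeline on the
default synthetic library (~12,600 reads), check the duplex search
against exhaustive enumeration on 200 random candidates, and verify
geometry invariants on 10,000 random pairs — sizes chosen so the whole
suite completes in well under a minute while every code path, including
the greedy assembler on ~350-unit inputs, is exercised.

## Known limitations

* The greedy longest-overlap-first assembler is a filter, not a genome
  assembler: with heavily branching overlap graphs the merge order can
  influence contig boundaries (ties are broken deterministically, but
  greediness itself is a heuristic). For the unidirectional-chain
  signature it targets, this is immaterial.
* Reference subtraction and mapping are exact/near-exact substring
  tests; they do not model gapped alignment, which an aligner-based
  subtraction would tolerate.
* The duplex criterion is purely structural. No precursor folding, free
  energy, conservation or target support is computed, so candidates are
  exactly that — candidates.
* Guide/star ratio recovery assumes collapse counts reflect abundance;
  PCR duplicates would inflate both strands alike.
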