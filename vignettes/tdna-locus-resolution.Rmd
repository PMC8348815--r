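---
title: "Resolving T-DNA insertion loci from long reads: models and methods"
author: "tdnalocus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving T-DNA insertion loci from long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Agrobacterium-mediated transformation integrates the T-DNA segment of a
binary vector into the plant nuclear genome. Real insertion alleles are
rarely the textbook single copy: loci carry multi-unit arrays of complete
and truncated T-DNA copies in tandem and inverted configurations, stretches
of vector backbone (BVB), captured organellar DNA, filler sequence, and in
some lines the insertion is entangled with chromosome-scale rearrangements
— arm translocations with T-DNA at one fusion and a clean compensating
fusion at the other, or large inverted duplications. Short flanking
sequence tags see one junction at a time and systematically miss these
configurations. Noisy long reads (ONT) span whole loci, but at 85–92%
accuracy every analysis step must tolerate errors, and inverted T-DNA
repeats additionally produce a characteristic sequencing-quality collapse
in the second repeat arm that can render half of an array unalignable on
any single read.

`tdnalocus` implements a read-level workflow for this problem: identify
insert-bearing reads, tile each read with catalog annotations, cluster
reads into loci, reconstruct the unit chain of each locus from individual
reads, classify the genome-level event, characterize every junction, and —
independently of the insertion analysis — flag candidate reference
misassemblies from alignment-end pileups.

## The aligner and its statistics

All sequence comparison runs through one seed-and-extend local aligner
(`find_local_hits()`), standing in for BLASTn:

* scoring: match +2, mismatch −3, affine gaps with open −5 and extend −2
  per base (a gap of length $L$ costs $-5 - 2L$);
* seeding: exact $k$-mers ($k = 12$ by default, valid range 8–21; k-mers
  containing N are skipped) chained greedily on near-constant diagonals
  (tolerance 100 bp); chains split by seed droughts are re-merged when
  their diagonals agree within the band, so gradual indel drift cannot
  fragment one long alignment into overlapping pieces;
* extension: banded affine Smith–Waterman whose band follows the
  interpolated chain diagonals, half-width $\max(150, \min(400,
  \text{span}/5))$. The band tracks the anchor diagonals, so the
  indel-driven diagonal drift of a long noisy read stays inside it. We
  deliberately run the full banded matrix rather than an X-drop
  termination: the band already bounds cost, and X-drop can split an
  alignment at an error burst.
* exactness at small scale: whenever query × subject is at most ~2.1 M
  cells the band covers the whole matrix, so the result *is* the
  Smith–Waterman optimum. The test suite verifies score equality against
  an independent full-matrix implementation on hundreds of random and
  mutated pairs, plus strand symmetry and determinism (ties broken by
  subject id, subject start, query start).

E-values use the Karlin–Altschul form $E = K m n e^{-\lambda S}$. The
ungapped $\lambda$ is computed numerically from the score distribution
under uniform base composition (the root of $E[e^{\lambda S}] = 1$, about
0.634 for the default scheme); $K$ is a declared constant (0.1). These
E-values exist to reproduce the published detection cutoffs (identity ≥
80%, $E \le 10^{-50}$ for T-DNA read identification), not as publishable
statistics. Because an 80% identity cutoff is meaningless on very short
spans, hits shorter than 50 columns are discarded — the publication states
only the identity and E-value cutoffs, so this floor is our own,
configurable choice.

## Tiling, gaps and the quality track

Read annotation follows the published greedy rule exactly: hits are
accepted in order of decreasing score, and a hit is discarded iff its
read-interval overlap with a previously accepted segment exceeds 10 bp (an
overlap of exactly 10 bp is allowed). Score ties are broken by longer
alignment, then smaller read start, then subject id — the source text
specifies only "decreasing score", so the tie-break is ours, chosen for
determinism; permutation invariance is property-tested. Unannotated read
parts longer than 1 kbp become *gaps*; per-read quality is summarized in
200 nt windows stepped by 100 nt, and a gap whose windows average at or
below Phred 10 while being flanked by T-DNA segments is flagged as a
candidate second arm of an inverted repeat (the observed collapse is to
about Phred 7; the threshold sits above it with margin and is
configurable).

## Locus resolution

Reads sharing a genome::insert changeover (projected onto the reference)
within 1 kbp are single-linkage clustered into a locus; the merge window is
our choice — far below any inter-locus distance that occurs in practice
(distinct loci on one chromosome are megabases apart), far above ONT
breakpoint jitter (single bases). Within a locus:

1. each read's tiled segments become an oriented unit chain; interior
   unannotated gaps become `UNKNOWN_LOWQ` units;
2. chains are oriented consistently (each chain is compared to the
   most-resolved chain in both orientations with an order-preserving
   unit-alignment score); orientation canonicalization is an involution —
   flipping every read leaves the reported structure unchanged;
3. the chain resolving the most units, preferring reads that span from
   genomic flank to genomic flank, becomes the backbone;
4. a low-quality gap explained by the eroded edge of an adjacent truncated
   unit is absorbed into that unit; an unexplained gap that aligns with a
   whole, well-annotated T-DNA/BVB unit in another read — typically one
   sequenced in the opposite direction, where the other arm collapsed —
   is replaced by that unit. This is the inverted-repeat rescue: combining
   reads of both directions yields the full array even though no single
   read annotates both arms;
5. where reads disagree on a unit's extent, the largest extent supported
   by any single read wins — implementing the "largest possible T-DNA"
   rule literally rather than as a coverage-weighted vote;
6. flank anchors are median changeover positions over supporting reads,
   and every junction anchor observed in any supporting read is kept in
   the locus's anchor table (the backbone need not traverse, say, the far
   border of an 80 kbp duplication).

Border status: the vector convention places position 1 at the left end of
the 25 bp LB repeat, making position 4 the start of the transferred DNA.
A unit edge within 3 bp of the repeat's outer end is called intact
(`lb_slack = 3`; border nicking leaves few terminal bases variable), else
truncated; edges between two insert units are internal, and internal edges
where two units meet at their RB-proximal ends are flagged as RB::RB
fusions.

Event classification: flanks on different chromosomes →
`TRANSLOCATION_FUSION`; no insert units with discontinuous genomic flanks →
`TDNA_FREE_FUSION`; same chromosome with opposite-orientation terminal
genomic units → `INVERTED_DUPLICATION`; a single T-DNA unit →
`CANONICAL_INSERTION`; two or more insert units → `COMPLEX_ARRAY`; a chain
containing a plastome-derived unit additionally emits `CPDNA_INSERTION`.
Fusion events joining the same chromosome pair with complementary arms are
paired as reciprocal partners — the pairing rule is this package's
construction (how compensating fusions were matched was not specified at
the source).

Zygosity: in a fully selected segregating T2 family two thirds of the
chromosomes in the pool carry the insertion, so the wild-type allele is
expected in ~1/3 of spanning reads. With at least 10 spanning reads, a
wild-type fraction below 0.15 is called `HOMOZYGOUS`, within [0.15, 0.60]
`SEGREGATING` (centered on the 1/3 expectation), anything else
`UNDETERMINED`.

## Junction analysis

Each junction is examined in a window extending 100 bp into either
assigned side (window size our choice: large enough for the short-filler
class, small enough to keep short-match searches specific); for captured
organellar inserts, the entire insert between the two genomic arms sits
inside the window. The cascade:

* **stage 1** aligns the window to the whole catalog at moderate
  stringency ($E \le 10^{-5}$; an E of 10 on a 200 bp query would flood the
  window with noise, so the published "default parameters" are tightened
  here, configurably). The maximal middle part not covered by the
  continuation of the two assigned flanks is the filler.
* **stage 2** re-searches a non-empty filler with short-match sensitivity
  at the published acceptance $E \le 10$. We run an exact local alignment
  of the filler against every catalog sequence on both strands — strictly
  more sensitive than a word-size-5 seeded search, whose word size we
  retain as configuration metadata.
* **stage 3** extends the filler by 10 bases up- and downstream within the
  window and repeats stage 2. A filler copied from sequence adjacent to
  the junction becomes detectable exactly through this extension, because
  the extended query forms one contiguous match with the neighborhood.

Microhomology is the longest exact suffix–prefix overlap of the two joined
ends, computed on the *reference* context of the two assigned origins so
that read errors cannot corrupt it; mismatch-tolerant homology is not
scored (the exact-overlap definition is the junction-analysis convention).

## Reference integrity

Alignment ends are counted in 100 bp bins (`bin(p) = floor(p/100)`, each
alignment contributing its start and its end−1); bins at or above a
threshold seed candidate regions, and seeds closer than 30 kbp merge by
single linkage. The threshold default is the 99.9th percentile of non-zero
bin counts — the published criterion is qualitative ("outstanding high
numbers"), so the default is scale-free across depths and overridable by
an absolute count. Coverage is binned at 1 kbp (depth = aligned bases /
bin size, so depth × bin size sums to total aligned bases), and CNV calls
are deliberately simple run-length thresholding (≥ 50 kbp runs beyond fold
change 1.4 / 0.6 against the genome median) — the published copy-number
evidence was visual inspection of coverage plots, so change-point methods
are out of scope. For a duplication carried on the mutant haplotype of a
selected pool, the expected fold change is $\tfrac13 \cdot 1 + \tfrac23
\cdot 2 = 5/3 \approx 1.67$; tests assert a GAIN call with fold change in
[1.4, 1.9] around that expectation.

## The simulator

`make_genome()` / `plant_events()` / `simulate_reads()` generate the study
conditions: by default five 150 kbp chromosomes stand in for the nuclear
genome (every relevant threshold — 50 kbp flanks, 30 kbp grouping, 50 kbp
CNV floor — is still exercisable; flank-extraction tests use a 200 kbp
chromosome), plus a 20 kbp plastome and a vector with LB/RB repeats at
declared coordinates. Events are planted exactly as specified and recorded
in a truth set: per-base origin block maps, reference junction anchors,
unit chains, fillers, microhomologies, inverted-repeat arm pairs, and
per-read error counts — sufficient to score every pipeline output without
re-simulation. Planted microhomology is engineered by making the wild-type
flank end equal the insert's first bases, which is how microhomology
presents in real junctions.

Reads: log-normal lengths (median 15 kbp, sdlog 0.9 — a realistic ONT
heavy tail that still yields a few array-spanning reads at 30×; truncated
to [1, 100] kbp), uniform starts, strands at random; i.i.d. per-base
errors (mismatch 0.04, insertion 0.03, deletion 0.04) at mean Phred 13.
When a read traverses a planted inverted repeat having covered at least
100 bp of the first arm, the arm encountered *second in its own direction*
is emitted at mean Phred 7 with a tripled substitution rate — the quality
drop is positional, directly encoding the observed phenomenon rather than
simulating pore physics. The model is deliberately i.i.d. (no
homopolymer-aware errors, no chimeras or adapters): sufficient to stress
the 80%-identity detection, the tiling and the rescue logic. Passing tests
therefore demonstrate robustness to error *rate*, not to every error
*structure* of real flow cells.

## Problem sizes and replicate designs

The validation suite runs seven fixture scenarios at 30× simulated
coverage on 150 kbp chromosomes (one or two per scenario): canonical
insertion with a 13 bp target-site deletion; head-to-head two-unit array
with the quality drop; an eight-unit array with distinct per-unit
truncations plus a BVB fragment (distinct extents keep repeat units
distinguishable when partial chains must be merged); a reciprocal
translocation with T-DNA at one fusion; an 80 kbp inverted duplication
(the published case, scaled ~10×); a 652 bp captured plastome fragment;
and a T-DNA-free fusion with 4 bp microhomology. Replicate experiments use
interval-level read sampling where only sampling noise matters: zygosity
calling (100 replicate loci at depth 30 — the call depends on allele
counts, not base content) and misjoin ranking (reads never spanning a
concatenation pile ~2 × depth alignment ends into one 100 bp bin against a
Poisson background well below 1). Simulator calibration counts the errors written
into each read against the generator's edit script, with the mean
re-aligned identity as a sequence-level cross-check (parsimonious
re-alignment merges adjacent indels into mismatches, so alignment columns
alone would bias the rates).

## Degenerate inputs and numerical choices

Empty FASTA records, quality/sequence length mismatches and missing FASTQ
separators are format errors naming the record; characters outside
`{A,C,G,T,N}` are mapped to N with a warning. All internal coordinates are
0-based half-open; human-readable reports convert to 1-based at the
boundary. Loci supported by a single read are reported with a
`LOW_SUPPORT` flag rather than suppressed (single reads resolved genuine
features in the source data); irreconcilable chain sets are flagged
`UNRESOLVED` with all candidates kept. A target-site "deletion" that comes
out negative (junction overlap) is clamped to 0. Structures built only
from merged partial chains carry a `MERGED` (and possibly `PARTIAL`) flag.

## Known limitations

* The aligner is exact only where the band covers the matrix; a true
  optimum whose path leaves the seed-chain band would be missed (not
  observed in testing at these error rates).
* Chain merging across arrays whose units are indistinguishable (identical
  extents and orientations) is ambiguous without spanning reads; the
  fixtures plant distinguishable truncations, and real arrays typically
  provide them.
* The zygosity caller assumes the selected-pool expectation; other
  selection regimes need re-parameterized thresholds.
* CNV calling reports plateaus, not breakpoint-resolved segments.
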