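---
title: "Detecting and dating TE-derived transcription factor binding sites"
author: "TEcisReg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating TE-derived transcription factor binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

TEcisReg analyses how transposable-element (TE) families supplied
transcription-factor binding sites, starting from two inputs a regulatory
genomics lab already has: called ChIP-seq peak summits and a RepeatMasker
annotation of the reference genome. This vignette explains each model and
procedure, its assumptions, the tunable parameters, and the choices made
where the underlying methodology leaves details open. It also describes
what the synthetic-data generator does and does not emulate, so that the
scope of the package's passing tests is clear.

## Coordinate conventions

Everything inside the package is 0-based half-open. The conversion happens
once, at the I/O boundary: RepeatMasker `.out` rows (1-based inclusive,
strand `C` for minus) are converted on read, UCSC chains are already
0-based, narrowPeak summits are `start + offset`. A summit at a copy's
`end` coordinate is outside the copy. Minus-strand copy alignments are
normalized so consensus coordinates always refer to the consensus forward
orientation; downstream binning is therefore strand-agnostic.

## Family-level enrichment

For each TE group (subfamily, family or class) the genomic fraction is the
union of its copies' bases divided by the length of the non-excluded
chromosomes. Chromosome exclusion exists because ChIP-seq from a
female-derived cell line should not be compared against a genome that
includes chrY; the exclusion set is a property of the `GenomeIndex` and is
applied to both numerator and denominator. Overlapping copies of one group
count once per base; each annotation row is treated as one copy and
fragments of one insertion event are not merged — the annotation is taken
at face value, which is also what per-base fraction arithmetic assumes.

The test per (group × factor) is an exact two-tailed binomial test with
`n` = all of the factor's summits (TE-resident and not), `k` = summits
inside the group's copies, and `p` = the group's genomic fraction. The
two-sided p-value uses the minimum-likelihood convention: the sum of
P(X = i) over every outcome whose point probability is at most
P(X = k)·(1 + 1e-7). Correction is Bonferroni with the multiplier equal to
the number of (group × factor) tests actually run, reported alongside each
result. A summit inside several overlapping copies is assigned
deterministically — smallest copy start, then lexicographically smallest
copy id — because reproducibility matters more than any of the equally
arbitrary alternatives.

`fold` is reported as (k/n)/p. Note that published fold-enrichment numbers
for this kind of analysis are sometimes computed against other baselines;
the package states its definition and sticks to it.

## Consensus projection and binding profiles

A summit inside a copy is mapped to its consensus coordinate through the
gapless blocks of the copy's alignment (`.align`). Within a block the
mapping is linear; a summit falling in a genomic insertion (a consensus
gap) is assigned the nearest downstream (larger) consensus coordinate and
flagged — flagged events stay in the bin counts but should be excluded
from base-resolution motif statistics. Summits outside all blocks are
counted as unmappable.

Profiles use 100 bins: `bin = floor(pos * 100 / L)` clipped to 99. The raw
per-bin event counts are normalized by copy coverage: for every consensus
site, the number of subfamily copies (bound or not) whose alignment covers
that site, averaged within each bin; the normalized value is
events-per-copy-per-bin scaled by 1e5. This is the truncation correction:
LINE-family copy sets are heavily 5′-truncated, so raw counts rise toward
the 3′ end even under uniform binding, while the normalized profile stays
flat. Coverage is averaged (not summed) within bins so that the normalized
unit does not depend on bin width.

Positional uniformity is tested on ten segments of ten bins. With more
than 100 events the Pearson statistic is compared to χ² with df = 9. With
30–100 events an exact test is wanted but a 1×10 goodness-of-fit has no
standard Fisher construction; the package uses an exact Monte-Carlo
multinomial test (100 000 resamples under a fixed, recorded seed;
p = (1 + #{T\* ≥ T}) / (R + 1)), which preserves the exactness intent while
staying tractable. Fewer than 30 events: not tested, tagged. The
Bonferroni multiplier is again the number of profiles actually tested,
computed from the data at hand rather than assumed.

Peak regions for motif scanning are contiguous runs of bins whose
normalized value exceeds 3× the profile median (configurable); where the
median is zero, half the maximum is used. This replaces a manual marking
step with a reproducible rule.

## Motif scanning

Scanning is FIMO-like: the log2 likelihood ratio of the PWM against the
background is summed over the window, both strands are scanned, and the
p-value is the exact probability that a background k-mer scores at least
as high. Exactness comes from dynamic programming on a discretized score
lattice (step 1e-3 bits): each position's four scores are rounded to the
lattice, and the full score distribution is built by convolution — the
same construction FIMO uses. Windows containing `N` are skipped. The
reverse strand gets its own null distribution, so non-symmetric
backgrounds are handled correctly. Hits below `alpha` (default 1e-4) are
reported. Tests verify the lattice tail probabilities against exhaustive
enumeration of all 4^k k-mers up to k = 8.

## Conservation, accessibility and chromatin state

Meta-profiles average a signal track over ±400 bp around each summit and
then apply a centered 10-bp moving average, truncated at the ends. Tracks
are per-base (conservation) or windowed (20-bp DHS); a windowed value
applies to every base in its window. Sites near a chromosome end
contribute their available bases.

The control set is drawn as uniform random genomic positions, keeping
those inside TEs — the same construction as sampling a million positions
and retaining the TE-resident subset. The group comparison is Welch's
unequal-variance two-tailed t-test on per-site means over the ±400 bp
window. Two decisions were open and are documented here: "t-test" alone
does not specify equal or unequal variance (Welch is the safer default),
and per-site means rather than pooled per-base values are compared (sites
are the sampling unit; pooled bases would be pseudo-replicated).

Read-coverage matrices (±4 kb) subsample reads without replacement to a
fixed target under a seed before accumulating coverage, mirroring
normalization to a fixed read count. Chromatin-state assignment requires
the segmentation to partition the genome, assigns each summit its
segment's state, and rolls states up to promoter/enhancer/other through a
user-supplied map — state semantics belong to whoever trained the
segmentation, so the map is configuration, not code.

## Cross-species dating

Liftover is implemented directly on chain files: the highest-scoring chain
overlapping the query is selected, every base is mapped through its
gapless blocks, and the lift succeeds if at least `minRatio` (default
0.95, approximating the liftOver tool's minMatch default) of the bases map
and the image is one contiguous interval on the query. Failures are
classified (no chain / partial / split). The implementation is
cross-checked in the test suite against rtracklayer's liftOver on the same
chain files.

Each binding event's 10-bp summit region is lifted to every species;
species without chain data are `no_data` and never determine a call. The
origin call is the most distantly related species with a detected
ortholog, resolved by tree topology (the species whose most recent common
ancestor with the reference is closest to the root); the origin clade is
that ancestor's label. "Most distant" is topological rather than based on
divergence-time metadata because only a labeled topology is required as
input. A per-subfamily maximal-clade table caps calls: an apparent mapping
outside a subfamily's known species range is flagged inconsistent and
clamped, which protects against spurious deep alignments. Missing chains
can only make calls younger, never older — a property the test suite
checks under deliberate chain ablation.

Age distributions are 1%-wide histograms of per-copy divergence from the
consensus, for all copies or for bound events weighted by their host
copy's divergence.

## Colocalization and density

Colocalization asks whether TE copies bound by factor A are enriched for
binding by factor B within a copy category. The baseline is B's average
binding probability in the category (bound copies / total copies); the
test is a one-sample χ² goodness-of-fit (df = 1, no continuity correction)
of the A-bound copies' B/not-B split against that baseline. Categories
with ≤10 A-binding events are skipped; a pooled row aggregates the tested
categories. Published per-factor bound-copy percentages of this kind can
differ slightly depending on whether the average is taken genome-wide or
per category; the package computes the category baseline from the copy
table it is given, so both conventions are reproducible by changing the
category column.

Density scans slide a 100-kb window in 50-kb steps (10-kb steps for a
finer pass) over the non-excluded genome and count distinct bound copies
whose midpoint falls in each window, per kilobase. Midpoint membership
avoids double counting across overlapping windows and makes window counts
over a non-overlapping tiling sum exactly to the number of bound copies.
Windows truncated at a chromosome end use their truncated width. The top
locus merges contiguous windows in the top 1% of densities around the
argmax window.

## The synthetic study generator

`simulateBundle()` emits a complete, self-consistent toy study with a
ground-truth manifest. Its default configuration *is* the study design the
package is validated against: two chromosomes of 2 Mb; eight subfamilies
spanning the four TE classes with ~3000 copies covering about half of the
genome; per-subfamily divergence (means 3–25%, realized by per-base
substitution), 5′-truncation (up to 85–90% truncation probability for the
LINE-like subfamilies), and lineage-dated insertion clades on an 8-species
amniote-like tree; binding motifs planted at fixed consensus intervals
(an estrogen-response-element palindrome, plus FoxA1-, GATA3- and
AP2γ-like motifs) with the motif bases protected from substitution;
~2000 summits over five factors, a configurable fraction placed at planted
motif instances (with ±2 bp jitter), the rest uniform background; p300
summits co-placed on ERα-bound copies to plant copy-level colocalization;
conservation uplift (+0.4 over a noisy ~0.02 baseline) at bound TE
summits; and one 100-kb hot locus carrying 60 extra motif-bound copies.
These scales keep a full pipeline run under two minutes on one CPU while
leaving every statistic comfortably powered.

Chains are generated from the true multi-species coordinate bookkeeping —
a copy is aligned in exactly the species descending from its insertion
clade, background sequence in all species — not from sequence alignment,
so liftover behaviour is exact by construction. Divergence is
substitution-only; an optional indel mode inserts short genomic gaps to
exercise the projection gap rule. `auditBundle()` re-parses every emitted
file with the package's own readers and verifies the manifest, including
the chain mappability pattern on a sample of copies.

What the generator does not emulate, and what passing tests therefore do
not show about real data: read-level noise and peak-calling artifacts
(summits are generated directly); interspersed nested insertions and
fragmented RepeatMasker hits of one element; alignment errors in real
chain files; non-uniform background binding (real background summits
cluster in open chromatin); and sequence-driven motif gain/loss (planted
motifs are protected from substitution, which mimics purifying selection
rather than neutral decay).

## Numerical choices and degenerate inputs

* Binomial p-values use `dbinom` sums with the 1 + 1e-7 relative tolerance
  in the minimum-likelihood rule; results are clamped to (0, 1].
* The motif lattice step is 1e-3 bits; coarser steps bias p-values near
  decision boundaries, finer steps cost memory linearly.
* Zero-probability PWM cells map to a −100-bit floor rather than −∞.
* Zero-variance group comparisons return p = 1 (equal means) or p → 0,
  flagged degenerate, instead of erroring.
* Profiles with zero copy coverage in a bin report `NA` normalized values
  and keep the raw counts.
* Summit offsets of −1 in narrowPeak fall back to the interval midpoint
  with a warning; dropped non-TE repeat records (satellites, simple
  repeats, small RNAs) are counted in a message.
* All stochastic steps (Monte-Carlo uniformity test, random TE sites, read
  subsampling, the generator) take explicit seeds; the pipeline records
  its seeds in a machine-readable run record.

## Problem sizes in the test suite

The test suite validates against a scaled-down generator configuration
(two 250-kb chromosomes, ~300 copies, ~420 summits) so that the complete
suite runs in about two minutes; the acceptance script uses the full
default scale. Scaling down changes power, not correctness: tests assert
only effects that remain comfortably detectable at the smaller scale, and
the planted-recovery checks at default scale are repeated by
`scripts/acceptance.R`.

## Known limitations

* Fragment merging of one insertion event split by RepeatMasker into
  several rows is not attempted; family fractions are unaffected but
  copy-level statistics (colocalization, density) treat fragments as
  separate copies.
* The liftover models single-chain mappings only; a binding site whose
  ortholog is split across chains (e.g. by a rearrangement breakpoint) is
  reported as `split` rather than recovered.
* The uniformity test's exact branch is Monte-Carlo, so its p-values have
  resolution 1/(R+1).
* Clade dating is presence/absence-based; it cannot distinguish a true
  insertion from an independent deletion in all outgroup lineages.
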