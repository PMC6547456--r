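---
title: "Methods: origin calling, selection signatures and turnover analysis"
author: "oriturn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: origin calling, selection signatures and turnover analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oriturn)
```

This vignette documents the statistical models, the tunable parameters,
the synthetic-data generator, and the numerical and design choices behind
`oriturn`. Every empirical claim made here is one the package's own test
suite or acceptance script computes; nothing is quoted from external
datasets.

## Coordinates and containers

All coordinates, everywhere, are 0-based half-open (BED convention).
Records from 1-based inclusive sources pass through `from_one_based()`
exactly once, at parse time. A `genome_ref` is the single coordinate
authority: chromosome sequences (A/C/G/T/N), lengths and a mappability
mask of sorted, non-overlapping half-open intervals. Reads are represented
by their 5' position only (`read_track`); SNS profiles are
counts-per-window quantities, so fragment length carries no additional
information for any statistic computed here. Homology between two
assemblies is a list of ungapped, co-linear, equal-length segment pairs
(`homology_map`) — a deliberate simplification of chain/net alignments
that is exact for interval arithmetic at the resolution used (tens of kb),
at the cost of not modelling within-segment indels.

## Origin calling

Reads are binned into windows of `window_size` (default 500 bp; window
`i` covers `[i*w, (i+1)*w)`). Windows with mappable fraction below 0.5 are
excluded from testing but keep their counts, so total read count is
conserved. The background model is fitted by method of moments on included
windows after trimming the top 1% of counts, so that origin signal does
not inflate the background estimate: with mean m and variance v of the
trimmed counts, the model is negative binomial with Var = mu + phi mu^2,
phi = (v − m)/m^2, falling back to Poisson when v <= m. Trimming 1% while
origins occupy a few percent of windows biases the background slightly
downward; on null data the resulting p-values remain conservative in
aggregate because of count discreteness, which the error-control test
verifies directly.

Each included window gets an upper-tail p-value P(X >= count) with the
expectation scaled by the window's mappable bp. "Controlled multiple error
rate of 1%" is operationalized as Benjamini–Hochberg FDR control at
alpha = 0.01 across all included windows genome-wide; Bonferroni
(family-wise) control is available via `caller_config(method =
"bonferroni")` since the underlying scan method's exact criterion is not
restated in the literature the package follows. Runs of significant
windows separated by at most `merge_gap` windows (default 1) merge into
one origin whose boundaries are the outer window edges.

The SNS peak of an origin is the integer bp in `[start, end)` maximizing
the Gaussian-kernel density of read 5' positions, bandwidth sqrt(500) ≈
22.4 bp, evaluated on a grid covering the origin plus three bandwidths;
ties break leftmost. Reads within three bandwidths outside the origin
contribute to the smoothed density so the estimate is not biased at origin
edges. Whether the read accumulation profile should use 5' ends or whole
fragments is not specified by the upstream method; 5' ends are used, which
only shifts the peak by a constant under any fixed fragment-length
distribution. Intensity is RPKM = reads / (kb × total reads / 10^6).
`subsample_to_depth()` equalizes sequencing depth between datasets before
any cross-species comparison — enrichment-based callers are more
sensitive at higher coverage, so the pipeline driver performs this step
unconditionally rather than silently trusting the inputs.

## The synthetic-data generator

The generator defines the study conditions under which every downstream
claim is tested. Defaults (see `sim_config()`):

| parameter | default | rationale |
|---|---|---|
| `origin_density` | 55 / Mb | mid-range of vertebrate SNS maps (34–84 / Mb) |
| `min_spacing` | 3 kb | origins are resolvable, non-overlapping peaks |
| `background_rate` | 28 reads/kb | the depth datasets are equalized to |
| `peak_sd` | 100 bp | read displacement spread around the initiation site |
| `origin_width` | log-normal, median 800 bp | observed origin sizes ~0.7–0.9 kb |
| `intensity` | log-normal(0, 1) | long tail so "top 25% most active" is meaningful |
| `skew_amplitude` | 0.2, extent 2 kb | skews invert at origins and extend over >2 kb |
| `snp_rate` | 0.027 / bp | ~84M SNPs over a ~3.1 Gb genome |
| `daf_weights` | 0.762 / 0.143 / 0.095 | rare (<1%) / intermediate / common (>10%) SNP shares |
| `common_depletion` | 0.25 | planted selective deficit in the 40-bp core |
| `core_width` | 40 bp | the constrained core region around the SNS peak |
| `conserved_fraction` | 0.30 | functionally conserved share of top origins in CGS |

Design choices worth recording:

* **Read displacement law.** The true SNS fragment law around initiation
  sites is uncharacterized; reads are displaced from the origin center by
  a rounded normal truncated to the chromosome. Only symmetry and
  unimodality matter for the peak-recovery properties being tested, and
  both are explicit in this choice.
* **Skew planting.** Sequence within ±2 kb of each origin center is
  redrawn so both S_GC and S_AT equal +a upstream and −a downstream,
  decaying linearly to zero over the next 1 kb; local GC content is
  preserved, and overlapping windows resolve to the nearest origin.
* **DAF mixture.** Point masses smoothed by Beta distributions populate
  the rare (<0.01) and common (>0.10) classes with realistic shares; the
  analysis only relies on both classes being populated. Common variants
  (and indels) inside the core are thinned by `common_depletion`; rare
  variants are untouched, reproducing the mutation-rate-neutral,
  selection-driven pattern.
* **Homology.** Genome B is a block shuffle of genome A (blocks of
  `cgs_block` bp, a fraction inverted), with exact ungapped homology
  inside conserved segments — conservation logic is interval arithmetic,
  not alignment, so an evolved sequence would add noise without adding
  coverage. Among top-quartile A origins whose peak maps through the
  segment map, an exact fraction `conserved_fraction` (not a Bernoulli
  draw) receives a B origin at the mapped position: the generator defines
  a truth set, and fixing the fraction makes the planted parameter the
  estimand rather than a random variable. Additional unrelated B origins
  are placed at `b_origin_density` (10/Mb), which adds a small
  (<1.5-point) chance-overlap inflation that stays within the stated
  recovery tolerance.

What the generator does **not** emulate: sequencing error, mappability
biases correlated with composition, diploid genotypes, gapped alignment,
and realistic molecular evolution. Passing tests therefore demonstrate
that the estimators recover planted truth under the stated statistical
structure, not that any particular biological dataset satisfies that
structure.

## Sequence features

Nucleotide profiles report, per offset, the fraction of anchors carrying
each base (N excluded from the denominator; the four profiles sum to 1).
Skew profiles pool base counts over anchors per offset bin — a pooled
estimator is stable at low per-anchor coverage where a mean of per-anchor
ratios is not; a trailing partial bin is dropped rather than reported from
fewer bases. Origins are unoriented, so anchors are never strand-flipped
for skew. The inversion locator interpolates the zero crossing linearly
between the two bins flanking the sign change nearest offset zero and also
reports the positive and negative extrema.

The G4 scanner matches G₃N₁₋₇G₃N₁₋₇G₃N₁₋₇G₃ per strand with leftmost,
non-overlapping, greedy semantics (the minus strand is scanned on the
reverse complement and mapped back); ambiguous N bases never match. The
test suite proves the scanner equal to an exhaustive position-by-position
enumeration on 1,000 random 200-bp sequences, both strands. Whether
overlapping matches should be counted is unknowable from the upstream
description; non-overlapping leftmost is standard scanner semantics and is
what the oracle encodes. Each motif is summarized by its middle
nucleotide, `start + floor(length/2)`.

## Selection signatures

Variants are classed rare (DAF < 0.01), common (DAF > 0.10) — strict
inequalities, boundary values fall in "intermediate" — or
"unknown-frequency" when DAF is absent (species whose polymorphism panels
are too small to distinguish frequencies). SNP mutation classes are
GC→AT, AT→GC and GC-conservative, separating directional effects of
GC-biased gene conversion from selection.

The core-depletion statistic is the ratio of class-specific variant
density in `peak ± 20 bp` to the density in flanks 100–500 bp on each
side. The flank window is a package choice (the upstream analysis says
only "flanking regions") and is exposed as an argument. The 95% CI is a
percentile bootstrap over anchors — origins, not variants, are resampled,
because variant counts within one origin are dependent. The acceptance
suite plants a 25% depletion on ~5,000 origins and checks both the point
recovery and the CI's empirical coverage (≥93/100 replicates), with the
rare-variant profile simultaneously flat within sampling error.

## Background compositional clustering

Random 40-bp segments (matched in number to the origins, uniform over
positions where the whole segment is mappable) are summarized by
overlapping 5-mer counts on the given strand (windows containing N are
skipped; strand-symmetrized counting is intentionally not the default
since cores are unoriented but the genome strand is arbitrary either way).
The count matrix is factorized by hand-written multiplicative-update NMF
(Frobenius loss, seeded uniform initialization, 200 iterations); the
update rule guarantees a non-increasing reconstruction error, which is
asserted per run. K-means (10 starts, best inertia) on the segment
loadings yields the background clusters. Six axes and six clusters are the
defaults, matching the "rule of thumb" outcome reported upstream; both are
arguments, since the rule itself is not reproducible.

New segments (origin cores) are projected onto the fixed basis by
non-negative least squares (multiplicative updates with a deterministic
flat initialization) and assigned by a maximum-a-posteriori rule under a
spherical Gaussian per cluster with empirical priors — the MAP details
are unstated upstream, so the simplest generative reading was chosen and
is documented; ties break to the larger prior, then the lower index.
Motif enrichment is evaluated cluster-wise: occurrences per bp (both
strands, overlapping matches counted) in cores over the same rate in the
cluster's random segments, with a Fisher count test; clusters with <20
background segments are flagged unstable, and an infinite fold (motif
absent from the background) is flagged rather than silently capped.
De-novo motif discovery is out of scope: the package evaluates a supplied
list of short literal motifs (defaults CG, CCC, GAG, ACAC — the classes
reported as origin-enriched), because the background-adjusted enrichment
logic, not the discovery tool, is the analysis contribution.

## Conservation and turnover

The concentration curve tiles chromosomes with 100-kb windows from the
chromosome start (last partial window dropped), sorts by read count and
accumulates read fractions; `concentration_share(curve, 0.05)` gives the
share of activity in the richest 5% of windows, ≈5% under uniform reads
(the suite checks ±0.5 points).

Top-quartile selection keeps origins at or above the 75th RPKM
percentile, ties included. "Functionally conserved" is operationalized as:
the origin overlaps a conserved segment (≥1 bp) and its mapped interval
overlaps (≥1 bp) an origin in the sister species; an origin conserved via
several sister origins counts once. Both thresholds are arguments rather
than constants in spirit, but 1 bp is the default because the upstream
definition is schematic. Mapping is orientation-aware offset arithmetic
within the containing segment, clipping intervals that span segment
boundaries; the suite checks the hand-computed minus-strand fixtures and
the round trip through the reversed map.

The randomization baseline draws 10 random sets preserving, per
chromosome, the origin count and the empirical size distribution, placed
uniformly in mappable sequence. Fold enrichment is observed/mean(random).
The CI treats the observed fraction as one more draw with spread
estimated from the random sets (t-quantile, inflated by sqrt(1 + 1/n));
under null placement this covers fold = 1 at roughly the nominal rate,
verified over 10 independent null experiments. TSS conservation extends
each oriented TSS 5'-ward by a length drawn from the origin size
distribution (minus-strand TSSs extend toward larger coordinates) and
applies the identical logic.

Score profiles consume any per-base bedGraph track (e.g. phylogenetic
conservation scores computed elsewhere); bases without coverage are
excluded from bin means, and minus-strand anchors are flipped so negative
offsets are always 5'.

## Pipeline, determinism and problem sizes

`run_pipeline()` chains simulate → call → features → selection →
composition → conserve into a report directory with a manifest of md5
checksums. Every stage derives its seed deterministically from the global
seed, so two runs with the same configuration are byte-identical (the
suite compares checksums file by file). A stage is skipped when its
outputs exist and match the manifest; a corrupted or missing output
triggers recomputation of exactly that stage, and failed stages keep
their partial outputs under a `.partial` suffix. The command-line surface
of the package is its exported functions plus this driver; a YAML file
can stand in for the configuration objects.

Test problem sizes were chosen so the full suite exercises every claim at
meaningful statistical resolution on a single CPU: 50 Mb null genomes for
error-rate control (20 replicates), ~500 origins for peak recovery,
~5,000 origins × 100 replicates for depletion-CI coverage, ~2,000
origins for conservation recovery, 3 Mb end-to-end pipeline fixtures for
determinism.

## Known limitations

* The NB background is fitted marginally; systematic covariates
  (GC-dependent coverage, replication timing) are not modelled.
* Homology maps are ungapped and co-linear; real chain/net alignments
  with within-segment indels must be segmented before import.
* The MAP assignment degrades for segments in the extreme tails of a
  cluster's composition (a spherical Gaussian underestimates tail
  density); assignments remain ≥95% correct on well-separated regimes.
* `unknown-frequency` variants cannot contribute to depletion estimates;
  for species without frequency panels only total SNP density profiles
  are meaningful.
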