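---
title: "CNV discovery from SNP-array cohorts: models and conventions"
author: "cohortCNV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CNV discovery from SNP-array cohorts: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortCNV)
```

This vignette is the package's own account of the science it implements:
the signal model, the hidden Markov segmentation, the population-level
region construction, the read-depth cross-check, and — just as important —
the numerical conventions and design choices taken where the underlying
methodology leaves room.

## The signal model

A genotyping array reports two normalised quantities per SNP and sample:

* **LRR (Log R Ratio)** — log2-scale total probe intensity relative to a
  diploid reference. Its expectation shifts with local copy number:
  strongly negative for homozygous deletions, about −0.67 for one copy,
  0 for two, and about +0.40 / +0.68 for three / four copies. These
  defaults (`hmmModel()$lrrMean`) follow the canonical per-state shifts
  observed on SNP arrays and are fully configurable.
* **BAF (B allele frequency)** — normalised allelic intensity ratio in
  [0, 1]. Under copy number *c* it clusters at *b/c* for B-allele count
  *b* = 0…*c*; the cluster weights are Binomial(*c*, *p*) with *p* the
  **PFB** (population frequency of the B allele) at that marker. A
  hemizygous deletion therefore shows BAF only near 0 and 1; a
  triplication adds clusters at 1/3 and 2/3.

Both tracks are stored in a `SignalSet`, a `RangedSummarizedExperiment`
whose rows are the markers of a `MarkerMap` (a sorted `GRanges` carrying
PFB) and whose two assays are `lrr` and `baf`. `NA` is the missing-data
sentinel throughout: a marker missing in one sample contributes zero
log-likelihood to that sample's decoding (it is skipped, not imputed),
which matches how per-sample signal files drop markers.

### Coordinates

Internally every interval is **1-based closed**, the GRanges/IRanges
convention, so all overlap arithmetic is delegated to the interval
algebra the Bioconductor stack already provides. BED input/output
converts at the edges (`readBedIntervals()` accepts both the 0-based
half-open BED dialect and a 1-based dialect and records which one it
read); GFF3 is natively 1-based closed.

## Quality control

Marker-level filters are applied to the genotype matrix before calling:
call rate < 0.90, minor allele frequency < 0.05, and a Hardy–Weinberg
exact test. The HWE test is the exact conditional test: with allele
counts fixed, every attainable heterozygote count has probability

$$P(n_{AB}) = \frac{n!\,n_A!\,n_B!\,2^{n_{AB}}}{n_{AA}!\,n_{AB}!\,n_{BB}!\,(2n)!},$$

and the two-sided p-value sums the probabilities no larger than the
observed one. The implementation accumulates the ratio recurrence
$P(h{+}2)/P(h) = 4\,n_{AA}(h)\,n_{BB}(h)/\big((h{+}1)(h{+}2)\big)$ in log
space; the test suite checks it exhaustively against an independent
log-factorial enumeration for every table with up to 50 genotypes. No
genome-wide HWE cutoff is inherent to the test itself; the default
`hwePMin = 1e-6` is the common whole-genome convention and is
configurable. The plain (non mid-p) exact test is used.

Sample-level signal QC computes three statistics whose thresholds are the
standard gates (0.3 / 0.02 / 0.05), but whose concrete formulas are this
package's documented conventions, chosen because they are computable from
the signal alone and respond to the artefacts the gates target:

* `lrr_sd` — the standard deviation of the sample's non-missing autosomal
  LRR (noise level);
* `baf_drift` — the fraction of markers with BAF in the off-cluster zones
  [0.2, 0.25] ∪ [0.75, 0.8] (poor allelic clustering; uniform BAF
  contamination gives ≈ 0.10);
* `waviness_factor` — the standard deviation of per-1-Mb-bin median LRR,
  signed by the correlation of the bin medians with bin GC content when a
  GC track is supplied (long-range genomic waves; a sinusoid of amplitude
  *A* over full periods gives ≈ *A*/√2).

Samples with fewer than 100 informative markers are flagged unreliable
and fail. Per-filter marker-removal counts are reported both
non-exclusively (a marker counts against every filter it fails) and
exclusively, because the two tallies genuinely differ whenever filters
overlap.

## The six-state HMM

States are CN0, CN1, CN2, CN2-LOH, CN3, CN4. Copy-neutral LOH is modelled
— it stabilises BAF interpretation by giving the decoder a diploid state
without a heterozygote cluster — but is never emitted as a CNV call.

**Emissions.** Each state contributes a Gaussian LRR term and a BAF
mixture term. The BAF mixture is over the state's genotype clusters
(uniform for CN0), each a Gaussian truncated to [0, 1] with
`bafClusterSd = 0.03`, plus a uniform outlier component of weight 0.01.
PFB values are clamped to [0.01, 0.99] (and `computePfb()` clamps on
construction) so no genotype-cluster weight ever vanishes.

**Transitions.** The self-transition probability after an inter-marker
gap of *d* bp is $1 - (1 - s_i)\,(1 - e^{-d/D})$ with per-state
long-distance stay probability $s_i$ (0.999 for CN2, 0.95 otherwise) and
decay length $D$ = 100 kb. Adjacent markers therefore almost never
switch state, distant markers switch at the saturation rate, and the
off-diagonal mass is split among the other states proportionally to
fixed base weights that favour returning to CN2. The initial
distribution puts 99.4% of its mass on CN2.

**Decoding.** Viterbi in log space, ties broken toward the lower state
index. The test suite verifies the decoder against brute-force
enumeration of all $6^n$ paths on instances up to 8 markers across 100
seeds. Maximal single-state non-diploid runs of at least
`minSnps = 3` markers become calls; each call's confidence is the summed
per-marker emission log-likelihood advantage over CN2, which is positive
for every emitted call on the synthetic cohorts.

Numerical notes: a fully missing marker emits 0 in every state, so it
lengthens a run without adding evidence; calls span the first through
last *marker position* of the run (no midpoint extrapolation).

## CNVR construction

Per-sample calls are clustered per chromosome into maximal connected
components under ≥ 1 bp pairwise overlap — abutting calls do **not**
merge, the strictest reading of "overlapping". Clusters supported by
fewer than two distinct samples are removed (two calls from the same
sample do not rescue a cluster), and trimming happens *after* that
filter, on the surviving clusters' full call sets.

The consensus boundary rule interprets the 2.5% cumulative-frequency
prescription as quantiles of the **base-coverage mass distribution**: with
per-base coverage $c(x)$ over the cluster's union extent and total mass
$M = \sum_x c(x)$, the trimmed start is the smallest base with ≥ 0.025·M
mass strictly before it and the trimmed end the largest base with
≥ 0.025·M strictly after it. An alternative reading — quantiles of the
distribution of member-call endpoints — was considered and rejected
because it ignores how much of each call actually covers the region. The
sweep implementation works on breakpoints only and is checked against a
naive per-base accumulation oracle on 1,000 random clusters. Ceiling
rounding keeps boundaries on integer bases; for degenerate extents of a
few bases where trimming would invert the interval, the raw extent is
returned unchanged. Region labels CNVR1…CNVRn follow (chromosome, start)
order; the whole merge → filter → trim → classify chain is deterministic
and invariant to input call order.

Event classes: *gain* if every supporting copy number exceeds 2, *loss*
if every one is below 2, *both* otherwise.

## Read-depth validation

Validation consumes per-window read counts (400 bp windows, read assigned
to the window containing its start; the final partial window is kept).
GC correction bins windows into 50 equal-width GC bins and rescales each
window by (global mean)/(bin mean), leaving bins with fewer than 20
windows uncorrected, then restores the total mass exactly. The
cross-window similarity recalibration step that some depth callers
apply between counting and GC correction is represented by
`similarityCorrect()`, an explicit identity hook: it requires genome
self-alignment resources far beyond this package's scope and has no
effect unless the user plugs in a correction function.

Copy number per window is `round(2·corrected/median)` (half away from
zero, capped at 10); runs of ≥ 5 non-diploid windows, bridging single
diploid windows, become depth regions whose copy number is the majority
non-diploid value. A CNVR is *confirmed* when it overlaps a depth region
of compatible polarity by ≥ 1 bp — "perfect overlap" is not given a
stricter published definition, so the 1-bp rule is the default and a
reciprocal-overlap fraction is exposed as a parameter. Pooled sequencing
designs are represented as one track per pool whose local copy number is
the pool-average; confirmation therefore uses polarity, not magnitude.

## Overlap analytics

Concordance with a reference catalogue counts query CNVRs touched by
≥ 1 bp and sums the merged intersection length per query region; both are
also reported as percentages of the query count and total length.
Enrichment uses the one-sided hypergeometric upper tail
(`phyper(k-1, K, N-K, n, lower.tail = FALSE)`), Bonferroni-corrected over
the number of *tested* terms (those with at least one selected gene). The
associated-gene percentage uses the term size *K* as denominator — the
selection-size alternative was considered; *K* is what "percentage of the
term's genes that are in the selection" means and is the documented
choice. Ortholog mapping and live ontology databases are out of scope;
the annotation is a user-supplied gene→term table.

## The synthetic cohort generator

`simConfig()` defaults define the simulated study conditions: 90 samples,
exponential marker spacing with mean 3,080 bp (exponential rather than
uniform so that realistic gaps exercise the distance-dependent
transitions), LRR noise SD 0.2, BAF cluster SD 0.03, per-marker allele
frequencies uniform on [0.05, 0.95] defining both PFB and HWE genotypes,
12 multi-carrier events (2–8 carriers) plus 2 single-carrier events to
exercise singleton filtering, and copy numbers drawn from
{0, 1, 3, 4} with weights {0.10, 0.40, 0.35, 0.15}. The default test
genome is two 10-Mb chromosomes (~6,500 markers) — large enough for
full waviness periods and Poisson-stable depth tracks, small enough that
the complete pipeline runs in well under five minutes. Depth tracks use
30× coverage, 150-bp reads, a smooth sinusoidal GC profile and a linear
GC bias. QC failure injections (LRR waves, uniform BAF contamination,
inflated LRR noise) are parameterised to straddle the QC thresholds so
both pass and fail outcomes are covered; with the adopted waviness
definition a wave of amplitude 0.3 clearly fails and 0.03 clearly passes
the 0.05 gate. All generators are pure functions of (configuration,
seed).

**What the simulation does and does not emulate.** It reproduces the
signal-level behaviour the caller relies on (state-dependent LRR shifts,
PFB-weighted BAF clusters, distance structure, Poisson depth with GC
bias) but not linkage disequilibrium, probe-specific effects, batch
structure, segmental-duplication artefacts, or breakpoints between
markers. Passing tests therefore demonstrate algorithmic correctness
under the stated generative model, not field performance on any
particular array product.

**A desk-scale interaction worth knowing.** On fixtures with only ~10³
markers, a homozygous deletion (LRR ≈ −3.5) can occupy several percent
of a carrier's markers and legitimately push that sample's LRR SD past
the 0.3 QC gate — a regime that full-size maps (5×10⁵ markers, < 0.1%
CNV markers) never enter. Integration fixtures that exercise the
QC→calling path therefore implant CN ∈ {1, 3, 4}; CN0 emission and
decoding are covered by calling-level tests.

Recovery against truth: an expected multi-carrier region counts as
recovered when a called CNVR of matching polarity covers at least half
of it; a called CNVR is a true positive when it overlaps any implanted
event of compatible polarity. Read-depth recovery is scored per true
segment as the Jaccard index against the **union** of the
compatible-polarity depth regions overlapping it: per-window rounding at
realistic depth occasionally mis-rounds two adjacent windows inside a
long event, splitting one true segment into two called regions that
jointly cover it, and the union is the standard recovery measure in that
situation.

## Reporting conventions

Every percentage and mean in reports is computed by `summaryPercent()`:
100·num/den (or num/den), rounded **half away from zero** to 2 decimals,
with a strict zero-denominator error. The pipeline asserts on every run
that each printed percentage is recomputable from its own printed
numerator and denominator. One caveat this surfaces: a ratio quoted to
two decimals from already-rounded inputs can differ by 0.01 from the
same ratio computed on unrounded values, so `summaryPercent()` on
printed inputs is the defined arithmetic, not an approximation of it.

## Limitations

* Sex chromosomes are out of scope (autosomal calling only), as is
  trio/family-aware calling and GC-model adjustment of LRR itself.
* Equivalence with any specific external caller's output is not claimed;
  the HMM parameter defaults are this package's own and behavioural
  fidelity is demonstrated on synthetic truth.
* CNVR construction offers no frequency-stratified classes and no
  cross-cohort genotyping.
* The depth validator consumes window counts; alignment, duplicate
  marking and recalibration happen upstream.
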