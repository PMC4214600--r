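---
title: "Methods: inferring Hedgehog-dependent target genes in the second heart field"
author: "shfgrn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring Hedgehog-dependent target genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shfgrn)
```

## Scope and model

The package infers candidate *direct* targets of Hedgehog/GLI signaling
in second-heart-field (SHF) progenitors by intersecting two independent
genome-scale measurements: GLI3 chromatin occupancy (ChIP-seq peak
intervals) and a pathway loss-of-function expression contrast (mutant vs
wild-type arrays). Neither measurement alone identifies direct targets —
binding without response may be non-functional, response without binding
may be indirect. The pipeline therefore (i) builds a
differential-expression signature, (ii) assigns peaks to genes by TSS
proximity, (iii) intersects the two gene sets and quantifies enrichments
with Fisher-exact statistics, and (iv) scans candidate enhancer sequences
for adjacent GLI and T-box consensus sites, the configuration
characteristic of enhancers integrating Hedgehog and TBX5 inputs.

Every stage can run on simulated inputs with planted ground truth, so the
whole chain is testable end to end.

## Differential-expression signature

### Probe filtering

Probes enter the test only if they (1) pass their quality flag on every
array, (2) show cross-sample spread in the top half of all probes'
spread, and (3) map to an annotated gene. Spread is measured as the
inter-quartile range of `log2(1 + x)`: on the raw scale an IQR filter is
dominated by overall intensity and silently discards genuinely regulated
low-intensity genes, while on the log scale it measures relative
variation, which is what distinguishes an expressed, varying probe from
background. The spread threshold (the median over all probes) is recorded
in the dataset's metadata and reused on re-application, which makes the
filter idempotent — re-filtering an already-filtered dataset is a no-op
rather than a repeated halving.

### Normalization

`normalizeExpression()` is a simplified variance-stabilizing transform in
three monotone steps: per-array median-ratio calibration (array effects
in the intensity model are multiplicative, and a ratio calibration cannot
push non-negative intensities negative, where a generalized log is steep
and noise-amplifying), the generalized log
`glog2(x) = log2((x + sqrt(x^2 + c^2))/2)`, and an affine median/IQR
match across the transformed columns. The offset `c` defaults to 1% of
the median calibrated intensity: large enough to keep the transform
defined at zero, small enough that expressed intensities sit on an
essentially pure log2 scale, so differences between arrays approach log2
ratios. A full maximum-likelihood variance-stabilization fit is
deliberately out of scope; arrays whose spread is zero are rejected as
uncalibratable. Raw intensities are preserved alongside, because fold
changes are reported on the linear scale of raw group means (standard
practice for these arrays, and independent of the transform's behavior
near zero).

### The SAM statistic and its null

Per probe, `d = (mean_case − mean_ctrl)/(s + s0)` with the pooled
standard error `s` and an exchangeability ("fudge") factor `s0` chosen
from a grid of quantiles of `s` to minimize the coefficient of variation
of the windowed spread of `d` across the range of `s` — the standard
recipe that stops near-zero-variance probes from dominating the ranking.
With `s0 = 0` and no multiplicity, `d` is exactly the classical
equal-variance two-sample t statistic (a tested equivalence).

The null distribution comes from relabeling samples. With 4 case and 3
control arrays there are only `choose(7,3) = 35` distinct assignments, so
all of them are enumerated; designs with more distinct assignments than
requested permutations are subsampled without replacement. Permutation
p-values pool permuted statistics across probes
(granularity `1/(B·m)`), the convention that makes small p-values
attainable at all with seven samples.

### False-discovery estimation

A subtlety dominates the q-value design: because the distinct-assignment
null *contains the observed labeling*, every truly regulated gene
contributes its own observed statistic to the pooled null. Any q-value
computed from the pooled p-values therefore has a hard floor of about
`(number of genes)/(B × number of probes)` — roughly 0.02 at both the
simulated and the original array dimensions — and a threshold of
q < 0.005 would be unreachable *by construction*, regardless of effect
size. The package instead estimates, at each gene's `|d|` threshold, the
expected number of false calls as the median across the *non-identity*
relabelings of the count of permuted statistics beyond the threshold,
plus a `1/B` smoothing floor so that no threshold ever claims an exactly
zero null rate; the estimated FDR is `π0 × V / R` with the
middle-quartile `π0` estimate, and each gene's q is the minimum estimated
FDR over all thresholds that include it. The median marginalizes the
identity relabeling out (a plain pooled mean is over-conservative because
partially-informative relabelings of regulated genes retain some signal),
while the smoothing floor prevents the opposite failure — a top-ranked
null gene whose median count is zero would otherwise receive q = 0 and
be called on null data. Both properties are exercised by the test suite:
zero signature genes across repeated null simulations, and ≥ 90% recall
of genes planted at |log2FC| ≥ 2 under the default 4-vs-3 design.

### Thresholds

The signature keeps genes with q ≤ 0.005 and linear fold change ≥ 2 in
either direction; a stringent candidate screen additionally demands exact
Wilcoxon rank-sum p < 0.15, empirical permutation-t FDR < 0.1 and
|FC| > 3, sorted by |log2FC|. Probe statistics collapse to genes via each
gene's extreme-`|d|` probe; with 1.3 probes per gene and seven samples
this is a deliberately simple rule, and both probe- and gene-level counts
are reported by the pipeline.

## Peak-to-gene annotation

Peaks link to every gene whose TSS lies within 100 kbp of the peak
midpoint on the same chromosome; a peak with no TSS in its window links
to the nearest TSS on its chromosome instead, so every peak on a
gene-bearing chromosome yields at least one link. The anchor is the peak
midpoint by default (the summit offset is honored when present); the
nearest-TSS fallback is restricted to the peak's own chromosome; ties
among equidistant TSSs are all reported, ordered by gene id. Distances
are signed in gene orientation (positive downstream of the TSS) but the
window test is unsigned. Coordinates are BED-convention 0-based
half-open externally and Bioconductor 1-based closed internally, with
conversion only at the file boundary. The annotation is validated against
an exhaustive all-pairs oracle and obeys translation invariance and
window monotonicity.

## Enrichment statistics

All enrichments run through one 2×2 engine: exact hypergeometric
p-values (two-sided: total probability of tables no more probable than
the observed one; one-sided: upper tail) and the *unconditional
cross-product* odds ratio `a·d/(b·c)` — not the conditional maximum
likelihood estimate — because the cross-product is what reproduces
published odds ratios from published counts. Zero denominators are
reported as `Inf`/`NaN` markers; a Haldane–Anscombe 0.5 correction is
available but off by default. The gene universe N is always an explicit
argument (defaulting to the supplied genome's gene count) and never
inferred silently. Sidedness defaults to two-sided for phenotype
penetrance tables and one-sided (over-representation) for set
enrichments, and is recorded in every result. The luciferase synergy
index is descriptive: the excess of the combined fold induction over the
additive expectation `fold_A + fold_B − 1`, labeled super-additive when
positive, with no hypothesis test attached because fold inductions carry
no replicate structure here.

## Motif scanning and co-site pairing

Scanning matches IUPAC consensus sets directly rather than log-odds
matrices (no position weight matrices are bundled). Every window at or
below the mismatch allowance is reported on both strands, with
minus-strand hits given in plus-strand coordinates; an `N` in the
sequence never matches. Default allowances are 0 mismatches for the 8-bp
T-box site and 2 for the 12-bp GLI consensus — the known functional GLI
site at the Foxf1a enhancer differs from the ChIP-derived consensus at
two positions, so 2 is the smallest allowance that recovers it.
Heterotypic pairs are scored by edge-to-edge gap under half-open
coordinates (overlap counts as 0); since reported "adjacent" sites sit
~32 bp apart edge-to-edge, the default pairing window is 50 bp.
Enrichment against background uses per-sequence presence/absence with a
Fisher test; absent an explicit background, one is generated by a
per-sequence first-order Markov (dinucleotide-preserving) shuffle.

## The synthetic-data generator

The generator emulates the study design so that every downstream stage
has known truth: a genome of TSSs with configurable family labels
("TF", "FOX"); log-normal probe intensities (log2-scale gene means
N(8, 1.5), probe affinity offsets, per-measurement noise SD 0.4,
per-array multiplicative jitter SD 0.1 log2 units) for 4 case vs 3
control arrays; ~1.3 probes per gene with a small unannotated fraction
and injected QC failures; planted log2 fold changes on a chosen set of
genes (default 40 down, 10 up at |log2FC| ∈ [2,3], about 6% of tested
genes — the proportion differentially expressed in the study this
emulates); peak sets placed near target TSSs at a controlled fraction;
and uniform-ACGT sequences carrying exact GLI/T-box cassettes at a
controlled spacing and strand, with all planted coordinates recorded.

What it does *not* emulate: additive scanner background (intensities are
purely multiplicative, which is why the median-ratio calibration is the
right simplified normalization here), probe cross-hybridization, spatial
array artifacts, fragment-level ChIP coverage or read-level noise, and
sequence composition bias (a GC-bias knob exists in spirit but the
default background is uniform). Passing recovery tests therefore
demonstrates the statistical machinery is correct and calibrated under
the stated generative model — not that real arrays or real chromatin
behave this simply.

All randomness flows through one seeded generator per call; a seed is a
required argument of every simulator, and the pipeline derives per-stage
seeds from one master seed, making full runs byte-reproducible (a tested
invariant, with the configuration hash stamped into every report).

## Numerical and design choices

* "Top half of the IQR" filtering is read as: spread ≥ median spread
  over all probes, the standard IQR-filter idiom.
* Expression fold change uses raw linear group means, not
  back-transformed normalized values.
* Nearest-TSS fallback is same-chromosome only.
* The pairing gap is edge-to-edge; "within 30 bp" phrasings are covered
  by the 50-bp default window.
* Degenerate inputs: zero-spread arrays, all-zero contingency tables,
  motifs longer than their sequences and empty post-filter datasets are
  hard errors with diagnostics; empty signatures and empty peak sets are
  legal and flow through as empty results.
* Published 1-based inclusive site coordinates are converted to 0-based
  half-open internally; both renderings appear in reports.

## Problem sizes

The test suite and the acceptance script size their simulations for
seconds-to-minutes runtimes while keeping the study's proportions: 1000
genes (~6% planted DE) for recovery runs, 350–400 genes for repeated
null-calibration runs over ≥ 50 seeds, 200 peaks × 500 genes for the
annotation oracle, exhaustive Fisher-table enumeration to N = 30 with a
random sweep to N = 50, and 1-kb sequences for scanner oracles. These
sizes are package choices; all are configurable upward.

## Limitations

Gene-body annotation uses a downstream-of-TSS proxy (the genome model
carries TSSs, not full gene models), so "intragenic" classification is
approximate. The probe-to-gene collapse by extreme `|d|` is simple and
slightly anti-conservative for genes with many probes. The q-value
estimator is calibrated under the generator's assumptions and the
enumerated-permutation regime; designs with hundreds of samples would
warrant sampled permutations and a pooled-p Storey estimator instead.
Consensus scanning cannot rank sites by binding energy; it is a
presence/geometry tool, not a thermodynamic model.
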