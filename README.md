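# shfgrn

Inference of direct Hedgehog/GLI target genes in cardiac progenitors by
integrating transcription-factor chromatin occupancy with loss-of-function
transcriptional profiling.

## The problem

Atrioventricular septal defects arise when the second heart field (SHF) —
the progenitor population that builds the atrial septum — fails to receive
or transduce Hedgehog signaling. The GLI transcription factors act as the
pathway's transcriptional effectors, and T-box factors such as TBX5
co-regulate some of the same enhancers. Identifying which genes GLI
factors regulate *directly* requires combining two genome-scale readouts:

1. **Where GLI3 binds** — ChIP-seq peaks, annotated to candidate target
   genes by proximity to transcription start sites (TSSs);
2. **Which genes respond to pathway loss** — a differential-expression
   signature from mutant-versus-wild-type expression arrays.

Genes in both sets are candidate direct targets; enrichment statistics
quantify whether the overlap, and the transcription-factor content of the
overlap, exceed chance. A consensus-motif scan for adjacent GLI and T-box
sites then nominates enhancers where the two pathways converge. This
package implements that pipeline as reusable, tested components, together
with a synthetic-data generator that plants known structure at every stage
so recovery can be measured exactly.

## The statistics at the core

* **SAM-type permutation test.** Per probe,
  `d = (mean_case − mean_ctrl) / (s + s0)` with pooled standard error `s`
  and exchangeability factor `s0` chosen to decouple `|d|`'s spread from
  `s`. The null comes from the distinct case/control relabelings (all 35
  for the default 4-vs-3 design). Permutation p-values pool permuted
  statistics across probes; the q-value at each gene's `|d|` threshold is
  `π0 ×` (smoothed median across non-identity relabelings of the count of
  permuted statistics beyond the threshold) / (genes called), minimized
  over thresholds that include the gene. The signature keeps genes with
  `q ≤ 0.005` and linear fold change ≥ 2 in either direction.
* **Peak-to-gene annotation.** Each peak links to every TSS within
  100 kbp of its midpoint on the same chromosome; a peak with none links
  to its chromosome's nearest TSS instead.
* **Fisher-exact enrichment.** For sets A and B in a universe of N genes,
  the 2×2 table `a = |A∩B|`, `b = |A|−a`, `c = |B|−a`, `d = N−|A|−|B|+a`
  is scored with the exact hypergeometric p and the unconditional
  cross-product odds ratio `OR = a·d / (b·c)`.
* **Motif co-occurrence.** IUPAC consensus scanning (built-in GLI
  `CGTGGGTGGTCC` and T-box `AGGTGTGG`), with heterotypic site pairs
  reported when edge-to-edge separation is at most 50 bp.

## Worked example

Published contingency tables re-tested directly:

```r
library(shfgrn)
enrichmentFETCounts(112, 3296, 560, 22000)
#> 2x2 table [a=112 b=3184 | c=448 d=18256], N=22000
#> cross-product OR = 1.43, one-sided Fisher exact p = 0.0006975

fet2x2(3, 0, 0, 4)   # 3/3 affected embryos vs 0/4 wild types
#> 2x2 table [a=3 b=0 | c=0 d=4], N=7
#> cross-product OR = Inf, two-sided Fisher exact p = 0.02857
```

The first call rebuilds the signature-versus-bound-gene overlap table from
its published set sizes: the odds ratio of 1.43 (≈1.4) says genes near
GLI3 peaks are ~1.4× more likely to be Hedgehog-responsive than chance,
with p well below 0.01. The second reproduces the penetrance test for
compound-heterozygote embryos (p = 1/35 ≈ 0.03).

An end-to-end run on simulated data with planted structure:

```r
rep <- runPipeline(defaultPipelineConfig(seed = 7))
#> [simulate] 1000 genes, 1339 probes, 80 peaks, 40 sequences
#> [expression] 614/1339 probes kept; 537 genes tested; signature 51 genes; stringent 45
#> [annotate] 80 peaks -> 138 neighbor genes (202 links)
#> [integrate] 38 target genes from 62 peaks
#> [motifs] 21 GLI sites, 21 TBX sites, 21 co-site pairs
str(rep$recovery)
#> $ planted_de       : int 50
#> $ signature_recall : num 1
#> $ planted_cotargets: int 38
#> $ target_precision : num 1
#> $ target_recall    : num 1
```

All 50 planted differentially expressed genes are recovered in the
signature at this seed, and the target set equals the planted
DE-and-peak-linked genes exactly. `rep$enrichment` carries the overlap and
family enrichment tables; with 10% of genes labeled "TF", the planted
target set shows `family_TF` OR = 2.75 here.

## Package tour

| Stage | Functions |
| --- | --- |
| synthetic data | `simulateGenome`, `simulateExpression`, `simulatePeaks`, `plantMotifPairs` |
| expression | `filterProbes`, `normalizeExpression`, `samTest`, `selectSignature`, `stringentCandidates`, `clusterSamples`, `genesetEnrichment` |
| peaks | `readPeakBed`, `writePeakBed`, `annotatePeaks`, `classifyPeaks`, `intersectPeakSets` |
| integration | `intersectSignature`, `fet2x2`, `enrichmentFET`, `familyEnrichment`, `synergyIndex` |
| motifs | `scanConsensus`, `findAdjacentPairs`, `motifEnrichment`, `builtinMotif` |
| orchestration | `runPipeline`, `defaultPipelineConfig` |

See the methods vignette (`vignettes/methods.Rmd`) for the modeling
assumptions, parameter choices and limitations.
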