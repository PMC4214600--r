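#' Fisher's exact test on a 2x2 table with cross-product odds ratio
#'
#' Exact hypergeometric p-value for the table
#' \preformatted{          in B   not in B
#'   in A      a       b
#'   not in A  c       d}
#' Two-sided p is the sum of probabilities of all tables (at the observed
#' margins) no more probable than the observed one; one-sided p is the
#' upper tail of `a`. The odds ratio is the unconditional cross-product
#' `a*d / (b*c)` — not the conditional MLE that `fisher.test()` reports —
#' with `Inf` when `b*c = 0` and `a*d > 0` and `NaN` when both products are
#' zero; `haldane = TRUE` instead adds 0.5 to every cell for the odds ratio
#' only.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @param sided `"two"` (default, as for phenotype tables) or `"one"`
#'   (over-representation of `a`).
#' @param haldane Apply the Haldane-Anscombe 0.5 correction to the odds
#'   ratio.
#' @param label Optional description stored in the result.
#' @return An [EnrichmentResult-class].
#' @examples
#' fet2x2(3, 0, 0, 4)   # p = 1/35
#' @export
fet2x2 <- function(a, b, c, d, sided = c("two", "one"), haldane = FALSE,
                   label = "") {
  sided <- match.arg(sided)
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("all-zero table")
  orr <- if (haldane) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else if (b * c == 0) {
    if (a * d > 0) Inf else NaN
  } else (a * d) / (b * c)
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  x <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(x, r1, r2, c1)
  p <- if (sided == "one") {
    sum(probs[x >= a])
  } else {
    ## relative tolerance absorbs floating-point ties between
    ## equally-probable tables
    sum(probs[probs <= probs[x == a] * (1 + 1e-7)])
  }
  new("EnrichmentResult",
      counts = stats::setNames(as.numeric(counts), c("a", "b", "c", "d")),
      oddsRatio = orr, pValue = min(p, 1), sided = sided, label = label)
}

#' Set-overlap enrichment between two gene sets
#'
#' Builds the 2x2 table `a = |A intersect B|`, `b = |A| - a`,
#' `c = |B| - a`, `d = N - |A| - |B| + a` over an explicit universe of size
#' `N` and delegates to [fet2x2()]. `enrichmentFET` takes gene-id vectors;
#' `enrichmentFETCounts` takes the printed set sizes directly (as when
#' re-testing published counts).
#'
#' @param setA,setB Character vectors of gene ids.
#' @param universeN Universe size `N` (an explicit input, never inferred).
#' @param sided Sidedness; enrichment tests default to one-sided
#'   over-representation.
#' @param label Optional description.
#' @return An [EnrichmentResult-class].
#' @examples
#' enrichmentFETCounts(112, 3296, 560, 22000)  # cross-product OR ~ 1.4
#' @export
enrichmentFET <- function(setA, setB, universeN, sided = "one", label = "") {
  setA <- unique(setA); setB <- unique(setB)
  enrichmentFETCounts(length(intersect(setA, setB)), length(setA),
                      length(setB), universeN, sided = sided, label = label)
}

#' @param nOverlap,nA,nB Overlap and set sizes.
#' @rdname enrichmentFET
#' @export
enrichmentFETCounts <- function(nOverlap, nA, nB, universeN, sided = "one",
                                label = "") {
  if (nOverlap > min(nA, nB) || max(nA, nB) > universeN)
    stop("inconsistent set sizes")
  d <- universeN - nA - nB + nOverlap
  if (d < 0)
    stop("universe too small: |A| + |B| - overlap exceeds N")
  fet2x2(nOverlap, nA - nOverlap, nB - nOverlap, d, sided = sided,
         label = label)
}

#' Intersect a peak-gene annotation with a DE signature
#'
#' Genes present both in the differential-expression signature and among
#' the peak-annotated genes — the candidate direct-target set. Peak and
#' gene counts are reported separately: a peak may contribute to several
#' genes and a gene may collect several peaks.
#'
#' @param links An [annotatePeaks()] link table (`peak_id`, `gene_id`).
#' @param sig A [GeneSignature-class] or character vector of gene ids.
#' @return A [TargetSet-class].
#' @export
intersectSignature <- function(links, sig) {
  if (is(sig, "GeneSignature")) sig <- signatureGenes(sig)
  stopifnot(all(c("peak_id", "gene_id") %in% colnames(links)))
  common <- intersect(unique(links$gene_id), sig)
  if (!length(common) && nrow(links) > 0 && length(sig) > 0)
    warning("no gene ids shared between links and signature - ",
            "possible gene-id namespace mismatch")
  sub <- links[links$gene_id %in% common, c("peak_id", "gene_id"),
               drop = FALSE]
  rownames(sub) <- NULL
  new("TargetSet", genes = sort(unique(sub$gene_id)),
      peaks = sort(unique(sub$peak_id)), links = sub)
}

#' Gene-family enrichment of a target set
#'
#' Tests whether target genes are over-represented among genes carrying a
#' family label (e.g. `"TF"` for transcription factors, `"FOX"` for
#' Forkhead-family genes) with a one-sided Fisher exact test over an
#' explicit universe.
#'
#' @param targets A [TargetSet-class] or character vector of gene ids.
#' @param familyMap A [GenomeModel-class] (labels taken from its gene
#'   table) or a named list mapping gene id to a character vector of
#'   labels.
#' @param universe Character vector of universe gene ids.
#' @param label The family label to test (must occur in the map).
#' @param sided Sidedness, default one-sided.
#' @return An [EnrichmentResult-class].
#' @export
familyEnrichment <- function(targets, familyMap, universe, label,
                             sided = "one") {
  if (is(targets, "TargetSet")) targets <- targetGenes(targets)
  famGenes <- if (is(familyMap, "GenomeModel")) {
    geneFamilies(familyMap, label)
  } else {
    has <- vapply(familyMap, function(f) label %in% f, logical(1))
    names(familyMap)[has]
  }
  allLabels <- if (is(familyMap, "GenomeModel")) {
    unique(unlist(geneTable(familyMap)$families, use.names = FALSE))
  } else unique(unlist(familyMap, use.names = FALSE))
  if (!label %in% allLabels)
    stop("family label '", label, "' not present in the family map")
  universe <- unique(universe)
  enrichmentFET(intersect(targets, universe),
                intersect(famGenes, universe), length(universe),
                sided = sided, label = paste0("family:", label))
}

#' Super-additivity index for reporter fold inductions
#'
#' Descriptive summary of co-activation: with single-factor fold
#' inductions `foldA` and `foldB` (relative to a baseline of 1), the
#' additive expectation for the combination is `foldA + foldB - 1`; the
#' excess of the observed combined induction over that expectation is
#' positive when the two factors act synergistically. This is an index,
#' not a hypothesis test.
#'
#' @param foldA,foldB,foldAB Non-negative fold inductions.
#' @return List with `excess_over_additive` and `is_super_additive`.
#' @examples
#' synergyIndex(91.9, 3.9, 171.6)  # excess 76.8
#' @export
synergyIndex <- function(foldA, foldB, foldAB) {
  if (any(c(foldA, foldB, foldAB) < 0))
    stop("fold inductions must be >= 0")
  excess <- foldAB - (foldA + foldB - 1)
  list(excess_over_additive = excess, is_super_additive = excess > 0)
}

#' Collect enrichment results into a report table
#'
#' @param results A named list of [EnrichmentResult-class] objects.
#' @return `data.frame` with `comparison`, `a`, `b`, `c`, `d`, `N`,
#'   `odds_ratio`, `p`, `sided`.
#' @export
enrichmentTable <- function(results) {
  rows <- lapply(names(results), function(nm) {
    x <- results[[nm]]
    k <- enrichmentCounts(x)
    data.frame(comparison = nm, a = k["a"], b = k["b"], c = k["c"],
               d = k["d"], N = sum(k), odds_ratio = oddsRatio(x),
               p = pValue(x), sided = x@sided, stringsAsFactors = FALSE,
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Write a target set as TSV
#'
#' One row per target gene with its comma-separated contributing peak ids;
#' fold change and q-value columns are appended when a DE result table is
#' supplied.
#'
#' @param targets A [TargetSet-class].
#' @param path Output path.
#' @param deTable Optional [samTest()] table for fc/q annotation.
#' @export
writeTargetSet <- function(targets, path, deTable = NULL) {
  l <- targetLinks(targets)
  peaksByGene <- vapply(split(l$peak_id, l$gene_id), function(p)
    paste(sort(unique(p)), collapse = ","), character(1))
  df <- data.frame(gene_id = names(peaksByGene), peak_ids = peaksByGene,
                   stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(deTable)) {
    i <- match(df$gene_id, deTable$gene_id)
    df$fc <- deTable$fc[i]
    df$q <- deTable$q[i]
  }
  .writeTsv(df, path)
  invisible(path)
}
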