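#' @include AllClasses.R
NULL

#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @export
setGeneric("tssRanges", function(x) standardGeneric("tssRanges"))
#' @export
setGeneric("geneFamilies", function(x, label) standardGeneric("geneFamilies"))
#' @export
setGeneric("signatureGenes", function(x) standardGeneric("signatureGenes"))
#' @export
setGeneric("signatureDirection", function(x) standardGeneric("signatureDirection"))
#' @export
setGeneric("oddsRatio", function(x) standardGeneric("oddsRatio"))
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @export
setGeneric("enrichmentCounts", function(x) standardGeneric("enrichmentCounts"))
#' @export
setGeneric("consensus", function(x) standardGeneric("consensus"))
#' @export
setGeneric("motifId", function(x) standardGeneric("motifId"))
#' @export
setGeneric("motifLength", function(x) standardGeneric("motifLength"))
#' @export
setGeneric("targetGenes", function(x) standardGeneric("targetGenes"))
#' @export
setGeneric("targetPeaks", function(x) standardGeneric("targetPeaks"))
#' @export
setGeneric("targetLinks", function(x) standardGeneric("targetLinks"))
#' @export
setGeneric("plantedDE", function(x) standardGeneric("plantedDE"))
#' @export
setGeneric("plantedPeakTargets", function(x) standardGeneric("plantedPeakTargets"))
#' @export
setGeneric("plantedMotifPairs", function(x) standardGeneric("plantedMotifPairs"))

#' Accessors for GenomeModel
#'
#' `chromLengths()` returns the named chromosome lengths; `geneTable()` the
#' gene DataFrame; `geneIds()` the gene identifiers; `tssRanges()` the TSSs
#' as width-1 [GenomicRanges::GRanges] (with seqlengths set);
#' `geneFamilies(x, label)` the ids of genes carrying a family label.
#'
#' @param x A [GenomeModel-class].
#' @param label A family label, e.g. `"TF"`.
#' @name GenomeModel-accessors
#' @aliases chromLengths geneTable geneIds tssRanges geneFamilies
NULL

#' @rdname GenomeModel-accessors
#' @export
setMethod("chromLengths", "GenomeModel", function(x) x@chromLengths)

#' @rdname GenomeModel-accessors
#' @export
setMethod("geneTable", "GenomeModel", function(x) x@genes)

#' @rdname GenomeModel-accessors
#' @export
setMethod("geneIds", "GenomeModel", function(x) as.character(x@genes$gene_id))

#' @rdname GenomeModel-accessors
#' @export
setMethod("tssRanges", "GenomeModel", function(x) {
  g <- x@genes
  gr <- GRanges(g$chrom, IRanges(start = g$tss + 1L, width = 1L),
                strand = g$strand,
                seqlengths = x@chromLengths[unique(g$chrom)])
  mcols(gr)$gene_id <- g$gene_id
  names(gr) <- g$gene_id
  gr
})

#' @rdname GenomeModel-accessors
#' @export
setMethod("geneFamilies", "GenomeModel", function(x, label) {
  hit <- vapply(x@genes$families, function(f) label %in% f, logical(1))
  as.character(x@genes$gene_id[hit])
})

setMethod("show", "GenomeModel", function(object) {
  cat("GenomeModel:", length(object@chromLengths), "chromosome(s),",
      nrow(object@genes), "genes\n")
  fam <- sort(unique(unlist(object@genes$families, use.names = FALSE)))
  if (length(fam))
    cat("  family labels:", paste(fam, collapse = ", "), "\n")
})

#' Accessors for GeneSignature
#'
#' @param x A [GeneSignature-class].
#' @name GeneSignature-accessors
NULL

#' @rdname GeneSignature-accessors
#' @export
setMethod("signatureGenes", "GeneSignature", function(x) x@genes)

#' @rdname GeneSignature-accessors
#' @export
setMethod("signatureDirection", "GeneSignature", function(x) {
  stats::setNames(x@direction, x@genes)
})

setMethod("length", "GeneSignature", function(x) length(x@genes))

setMethod("show", "GeneSignature", function(object) {
  cat(sprintf("GeneSignature: %d genes (%d down, %d up) at q<=%g, |FC|>=%g\n",
              length(object@genes), sum(object@direction == "down"),
              sum(object@direction == "up"), object@qMax, object@minAbsFC))
})

#' Accessors for EnrichmentResult
#'
#' @param x An [EnrichmentResult-class].
#' @name EnrichmentResult-accessors
NULL

#' @rdname EnrichmentResult-accessors
#' @export
setMethod("oddsRatio", "EnrichmentResult", function(x) x@oddsRatio)

#' @rdname EnrichmentResult-accessors
#' @export
setMethod("pValue", "EnrichmentResult", function(x) x@pValue)

#' @rdname EnrichmentResult-accessors
#' @export
setMethod("enrichmentCounts", "EnrichmentResult", function(x) x@counts)

setMethod("show", "EnrichmentResult", function(object) {
  k <- object@counts
  if (nzchar(object@label)) cat(object@label, "\n")
  cat(sprintf("2x2 table [a=%g b=%g | c=%g d=%g], N=%g\n",
              k["a"], k["b"], k["c"], k["d"], sum(k)))
  cat(sprintf("cross-product OR = %s, %s-sided Fisher exact p = %.4g\n",
              format(object@oddsRatio, digits = 3), object@sided,
              object@pValue))
})

#' Accessors for Motif
#'
#' @param x A [Motif-class].
#' @name Motif-accessors
NULL

#' @rdname Motif-accessors
#' @export
setMethod("consensus", "Motif", function(x) x@consensus)

#' @rdname Motif-accessors
#' @export
setMethod("motifId", "Motif", function(x) x@motifId)

#' @rdname Motif-accessors
#' @export
setMethod("motifLength", "Motif", function(x) nchar(x@consensus))

setMethod("show", "Motif", function(object) {
  cat(sprintf("Motif %s: %s (%d bp)\n", object@motifId, object@consensus,
              nchar(object@consensus)))
})

#' Accessors for TargetSet
#'
#' @param x A [TargetSet-class].
#' @name TargetSet-accessors
NULL

#' @rdname TargetSet-accessors
#' @export
setMethod("targetGenes", "TargetSet", function(x) x@genes)

#' @rdname TargetSet-accessors
#' @export
setMethod("targetPeaks", "TargetSet", function(x) x@peaks)

#' @rdname TargetSet-accessors
#' @export
setMethod("targetLinks", "TargetSet", function(x) x@links)

setMethod("show", "TargetSet", function(object) {
  cat(sprintf("TargetSet: %d genes from %d contributing peaks\n",
              length(object@genes), length(object@peaks)))
})

#' Accessors for SyntheticTruth
#'
#' @param x A [SyntheticTruth-class].
#' @name SyntheticTruth-accessors
NULL

#' @rdname SyntheticTruth-accessors
#' @export
setMethod("plantedDE", "SyntheticTruth", function(x) x@deGenes)

#' @rdname SyntheticTruth-accessors
#' @export
setMethod("plantedPeakTargets", "SyntheticTruth", function(x) x@peakTargets)

#' @rdname SyntheticTruth-accessors
#' @export
setMethod("plantedMotifPairs", "SyntheticTruth", function(x) x@motifPairs)

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d DE genes, %d peak targets, %d motif pairs\n",
              nrow(object@deGenes), nrow(object@peakTargets),
              nrow(object@motifPairs)))
})
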