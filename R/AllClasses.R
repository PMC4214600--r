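#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges CharacterList
#' @importFrom GenomicRanges GRanges start end width strand seqnames
#' @importFrom GenomeInfoDb seqlengths seqlevels
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames
#'   rowData colData
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Genome model: chromosome sizes plus a gene/TSS table
#'
#' A `GenomeModel` is the coordinate universe used throughout the pipeline:
#' named chromosome lengths and one row per gene carrying its transcription
#' start site (TSS), strand and zero or more family labels (for example
#' `"TF"` for transcription factors or `"FOX"` for Forkhead-family genes).
#' It is the universe for every enrichment test and the anchor set for
#' peak-to-gene annotation.
#'
#' @slot chromLengths Named numeric vector of chromosome lengths in bp.
#' @slot genes A [S4Vectors::DataFrame] with columns `gene_id`, `chrom`,
#'   `tss` (0-based bp), `strand` (`"+"`/`"-"`) and `families`
#'   (a [IRanges::CharacterList] of labels).
#'
#' @seealso [simulateGenome()], [readGeneTable()], [tssRanges()]
#' @export
setClass("GenomeModel",
  representation(chromLengths = "numeric", genes = "DataFrame"))

setValidity("GenomeModel", function(object) {
  cl <- object@chromLengths
  g <- object@genes
  msgs <- character()
  if (length(cl) == 0L || is.null(names(cl)) || anyNA(names(cl)) ||
      any(names(cl) == ""))
    msgs <- c(msgs, "chromLengths must be a non-empty named vector")
  if (any(cl <= 0)) msgs <- c(msgs, "chromosome lengths must be positive")
  need <- c("gene_id", "chrom", "tss", "strand", "families")
  if (!all(need %in% colnames(g)))
    msgs <- c(msgs, paste("genes must have columns:", paste(need, collapse = ", ")))
  else if (nrow(g) > 0L) {
    if (anyDuplicated(g$gene_id)) msgs <- c(msgs, "gene_ids must be unique")
    if (!all(g$chrom %in% names(cl)))
      msgs <- c(msgs, "every gene chrom must be a known chromosome")
    else if (any(g$tss < 0 | g$tss >= cl[as.character(g$chrom)]))
      msgs <- c(msgs, "every tss must satisfy 0 <= tss < chromosome length")
    if (!all(g$strand %in% c("+", "-")))
      msgs <- c(msgs, "strand must be '+' or '-'")
    fam <- unlist(g$families, use.names = FALSE)
    if (length(fam) && (anyNA(fam) || any(fam == "")))
      msgs <- c(msgs, "family labels must be non-empty strings")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenomeModel
#'
#' @param chromLengths Named numeric vector of chromosome lengths (bp).
#' @param genes data.frame or DataFrame with columns `gene_id`, `chrom`,
#'   `tss`, `strand` and either a `families` list-column or a
#'   `families` character column of comma-separated labels (empty string =
#'   no labels).
#' @return A [GenomeModel-class] object.
#' @export
GenomeModel <- function(chromLengths, genes) {
  genes <- as(genes, "DataFrame")
  if (!"families" %in% colnames(genes)) {
    genes$families <- CharacterList(rep(list(character()), nrow(genes)))
  } else if (!is(genes$families, "CharacterList")) {
    f <- genes$families
    if (is.character(f)) {
      f <- lapply(f, function(x) {
        x <- strsplit(x, ",", fixed = TRUE)[[1]]
        x[nzchar(x)]
      })
    }
    genes$families <- CharacterList(f)
  }
  genes$chrom <- as.character(genes$chrom)
  genes$gene_id <- as.character(genes$gene_id)
  genes$strand <- as.character(genes$strand)
  new("GenomeModel", chromLengths = chromLengths, genes = genes)
}

#' Differential-expression container built on SummarizedExperiment
#'
#' Probe-by-sample intensities with the probe-to-gene map in `rowData`
#' (`probe_id`, `gene_id`; `NA` gene_id marks an unannotated probe), a
#' per-probe-per-array QC pass/fail matrix in the `"qc"` assay, and the
#' case/control group label in `colData(x)$group`. The measurement scale is
#' tracked in `metadata(x)$scale` (`"raw"` for non-negative intensities,
#' `"glog2"` after normalization); the raw matrix is preserved in the
#' `"raw"` assay across normalization so fold changes can be computed on the
#' linear scale.
#'
#' @seealso [ExpressionDataset()], [simulateExpression()], [filterProbes()],
#'   [normalizeExpression()], [samTest()]
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
  msgs <- character()
  if (!"exprs" %in% assayNames(object))
    msgs <- c(msgs, "assay 'exprs' is required")
  if (!all(c("probe_id", "gene_id") %in% colnames(rowData(object))))
    msgs <- c(msgs, "rowData must have probe_id and gene_id")
  if (!"group" %in% colnames(colData(object)))
    msgs <- c(msgs, "colData must have a 'group' column")
  else if (!all(object$group %in% c("case", "control")))
    msgs <- c(msgs, "groups must be 'case' or 'control'")
  sc <- metadata(object)$scale
  if (is.null(sc) || !sc %in% c("raw", "glog2"))
    msgs <- c(msgs, "metadata(x)$scale must be 'raw' or 'glog2'")
  if ("exprs" %in% assayNames(object)) {
    v <- assay(object, "exprs")
    if (any(!is.finite(v))) msgs <- c(msgs, "expression values must be finite")
    else if (identical(sc, "raw") && any(v < 0))
      msgs <- c(msgs, "raw intensities must be >= 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an ExpressionDataset
#'
#' @param values Numeric matrix, probes x samples (raw intensities unless
#'   `scale` says otherwise).
#' @param probeIds,geneIds Character vectors, one per row; `geneIds` may
#'   contain `NA` for unannotated probes.
#' @param groups Character vector (`"case"`/`"control"`), one per column.
#' @param qc Optional logical matrix (same shape as `values`): `TRUE` =
#'   probe passed QC on that array. Defaults to all-pass.
#' @param scale `"raw"` (default) or `"glog2"`.
#' @return An [ExpressionDataset-class].
#' @export
ExpressionDataset <- function(values, probeIds, geneIds, groups, qc = NULL,
                              scale = "raw") {
  values <- as.matrix(values)
  if (is.null(qc)) qc <- matrix(TRUE, nrow(values), ncol(values))
  stopifnot(length(probeIds) == nrow(values), length(geneIds) == nrow(values),
            length(groups) == ncol(values), all(dim(qc) == dim(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("sample_%02d", seq_len(ncol(values)))
  rownames(values) <- probeIds
  dimnames(qc) <- dimnames(values)
  se <- SummarizedExperiment(
    assays = list(exprs = values, qc = qc),
    rowData = DataFrame(probe_id = as.character(probeIds),
                        gene_id = as.character(geneIds)),
    colData = DataFrame(sample_id = colnames(values),
                        group = as.character(groups),
                        row.names = colnames(values)))
  metadata(se)$scale <- scale
  new("ExpressionDataset", se)
}

#' Differential-expression gene signature
#'
#' The set of genes passing the q-value and fold-change thresholds, with the
#' direction of change in the case (mutant) group and the per-gene
#' statistics that justified inclusion.
#'
#' @slot genes Character vector of member gene ids.
#' @slot direction Character vector parallel to `genes`: `"up"` or `"down"`
#'   in the case group.
#' @slot qMax,minAbsFC The thresholds that were applied.
#' @slot stats data.frame of the member rows from the DE table.
#' @export
setClass("GeneSignature",
  representation(genes = "character", direction = "character",
                 qMax = "numeric", minAbsFC = "numeric", stats = "data.frame"))

setValidity("GeneSignature", function(object) {
  msgs <- character()
  if (length(object@genes) != length(object@direction))
    msgs <- c(msgs, "genes and direction must be parallel")
  if (length(object@direction) && !all(object@direction %in% c("up", "down")))
    msgs <- c(msgs, "direction must be 'up' or 'down'")
  if (anyDuplicated(object@genes)) msgs <- c(msgs, "signature genes must be unique")
  if (length(msgs)) msgs else TRUE
})

#' 2x2 Fisher-exact enrichment result
#'
#' Holds the contingency counts `a` (in both sets), `b` (first set only),
#' `c` (second set only), `d` (neither), the unconditional cross-product
#' odds ratio `a*d / (b*c)` (`Inf` when `b*c == 0` and `a*d > 0`), and the
#' exact hypergeometric p-value. `sided` records whether the p-value is the
#' one-sided over-representation tail or the two-sided sum of tables no more
#' probable than the observed one.
#'
#' @seealso [fet2x2()], [enrichmentFET()], [familyEnrichment()]
#' @export
setClass("EnrichmentResult",
  representation(counts = "numeric", oddsRatio = "numeric",
                 pValue = "numeric", sided = "character",
                 label = "character"))

setValidity("EnrichmentResult", function(object) {
  msgs <- character()
  if (length(object@counts) != 4L ||
      !identical(names(object@counts), c("a", "b", "c", "d")))
    msgs <- c(msgs, "counts must be named a,b,c,d")
  if (any(object@counts < 0)) msgs <- c(msgs, "counts must be >= 0")
  if (!object@sided %in% c("one", "two"))
    msgs <- c(msgs, "sided must be 'one' or 'two'")
  if (object@pValue < 0 || object@pValue > 1)
    msgs <- c(msgs, "p-value must be in [0,1]")
  if (isTRUE(object@oddsRatio < 0)) msgs <- c(msgs, "odds ratio must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' IUPAC consensus motif
#'
#' A named binding-site consensus over the IUPAC nucleotide alphabet.
#' Built-in motifs: the GLI-family consensus `CGTGGGTGGTCC` (ChIP-derived)
#' and the canonical T-box site `AGGTGTGG`; see [builtinMotif()].
#'
#' @slot motifId Identifier, e.g. `"GLI"`.
#' @slot consensus IUPAC string.
#' @export
setClass("Motif", representation(motifId = "character", consensus = "character"))

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

setValidity("Motif", function(object) {
  msgs <- character()
  cons <- object@consensus
  if (length(cons) != 1L || !nzchar(cons))
    msgs <- c(msgs, "consensus must be a single non-empty string")
  else {
    letters <- strsplit(toupper(cons), "")[[1]]
    if (!all(letters %in% names(IUPAC_SETS)))
      msgs <- c(msgs, "consensus must use IUPAC nucleotide codes")
  }
  if (length(msgs)) msgs else TRUE
})

#' @param motifId Identifier for the motif.
#' @param consensus IUPAC consensus string.
#' @rdname Motif-class
#' @export
Motif <- function(motifId, consensus) {
  new("Motif", motifId = motifId, consensus = toupper(consensus))
}

#' Built-in consensus motifs
#'
#' `"GLI"` is the 12-mer GLI-family binding consensus derived from GLI3
#' ChIP-chip (`CGTGGGTGGTCC`); `"TBX"` is the canonical 8-bp T-box
#' (TBX5) recognition sequence (`AGGTGTGG`).
#'
#' @param name `"GLI"` or `"TBX"`.
#' @return A [Motif-class].
#' @examples
#' builtinMotif("GLI")
#' @export
builtinMotif <- function(name = c("GLI", "TBX")) {
  name <- match.arg(name)
  switch(name,
    GLI = Motif("GLI", "CGTGGGTGGTCC"),
    TBX = Motif("TBX", "AGGTGTGG"))
}

#' Ground truth of a synthetic bundle
#'
#' Records what was planted by the simulators so downstream recovery can be
#' measured: the differentially expressed genes and their log2 fold changes,
#' which peaks were targeted at which genes, and the coordinates of planted
#' motif pairs per sequence.
#'
#' @slot deGenes data.frame (`gene_id`, `log2fc`).
#' @slot peakTargets data.frame (`peak_id`, `gene_id`).
#' @slot motifPairs data.frame (`seq_id`, `start_a`, `end_a`, `start_b`,
#'   `end_b`, `strand`, `gap`), 0-based half-open coordinates.
#' @export
setClass("SyntheticTruth",
  representation(deGenes = "data.frame", peakTargets = "data.frame",
                 motifPairs = "data.frame"))

SyntheticTruth <- function(deGenes = data.frame(gene_id = character(),
                                                log2fc = numeric()),
                           peakTargets = data.frame(peak_id = character(),
                                                    gene_id = character()),
                           motifPairs = data.frame()) {
  new("SyntheticTruth", deGenes = deGenes, peakTargets = peakTargets,
      motifPairs = motifPairs)
}

#' Signature x bound-gene target set
#'
#' Genes present both in the differential-expression signature and among
#' peak-annotated genes, with the contributing peak ids (a peak may
#' contribute to several genes and a gene may collect several peaks).
#'
#' @slot genes Character vector of target gene ids.
#' @slot peaks Character vector of all contributing peak ids (unique).
#' @slot links data.frame (`peak_id`, `gene_id`) restricted to the targets.
#' @seealso [intersectSignature()]
#' @export
setClass("TargetSet",
  representation(genes = "character", peaks = "character",
                 links = "data.frame"))

setValidity("TargetSet", function(object) {
  l <- object@links
  msgs <- character()
  if (!all(c("peak_id", "gene_id") %in% colnames(l)))
    msgs <- c(msgs, "links must have peak_id and gene_id")
  else {
    if (!setequal(object@genes, unique(l$gene_id)))
      msgs <- c(msgs, "every target gene must have >= 1 contributing link")
    if (!setequal(object@peaks, unique(l$peak_id)))
      msgs <- c(msgs, "peaks must equal the contributing peak ids")
  }
  if (length(msgs)) msgs else TRUE
})
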