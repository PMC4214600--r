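# Plain-text readers/writers for the pipeline's exchange formats.
# BED is handled in peaks.R; FASTA goes through Biostrings.

#' Write / read the tab-separated gene table
#'
#' Columns: `gene_id`, `chrom`, `tss` (0-based), `strand`, `families`
#' (comma-separated labels, empty when none).
#'
#' @param genome A [GenomeModel-class].
#' @param path File path.
#' @return `writeGeneTable` returns `path` invisibly; `readGeneTable`
#'   returns a [GenomeModel-class].
#' @export
writeGeneTable <- function(genome, path) {
  g <- geneTable(genome)
  df <- data.frame(gene_id = g$gene_id, chrom = g$chrom, tss = g$tss,
                   strand = g$strand,
                   families = vapply(g$families, paste, character(1),
                                     collapse = ","),
                   stringsAsFactors = FALSE)
  .writeTsv(df, path)
  invisible(path)
}

#' @param chromLengths Optional named vector of chromosome lengths; when
#'   omitted each chromosome length is inferred as `max(tss) + 1` (a lower
#'   bound, sufficient for annotation but not for peak simulation).
#' @rdname writeGeneTable
#' @export
readGeneTable <- function(path, chromLengths = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(families = "character"))
  if (is.null(chromLengths)) {
    chromLengths <- tapply(df$tss, df$chrom, function(x) max(x) + 1)
    chromLengths <- stats::setNames(as.numeric(chromLengths),
                                    names(chromLengths))
  }
  GenomeModel(chromLengths, df)
}

#' Write / read chromosome sizes
#'
#' Two-column headerless TSV: chromosome name, length in bp (the same shape
#' as a UCSC "chrom.sizes" file).
#'
#' @param chromLengths Named numeric vector.
#' @param path File path.
#' @export
writeChromSizes <- function(chromLengths, path) {
  utils::write.table(
    data.frame(names(chromLengths), as.numeric(chromLengths)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeChromSizes
#' @export
readChromSizes <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2]]), df[[1]])
}

#' Write / read an expression matrix with its sample sheet
#'
#' The matrix file has columns `probe_id`, `gene_id` (empty for
#' unannotated probes) and one column per sample; the sample sheet has
#' `sample_id` and `group` (`case`/`control`). An optional QC file mirrors
#' the matrix shape with 1 = pass, 0 = fail.
#'
#' @param ds An [ExpressionDataset-class].
#' @param matrixPath,samplesPath,qcPath File paths (`qcPath` optional).
#' @export
writeExpressionMatrix <- function(ds, matrixPath, samplesPath,
                                  qcPath = NULL) {
  rd <- rowData(ds)
  df <- data.frame(probe_id = rd$probe_id,
                   gene_id = ifelse(is.na(rd$gene_id), "", rd$gene_id),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(assay(ds, "exprs")))
  .writeTsv(df, matrixPath)
  .writeTsv(data.frame(sample_id = colnames(ds),
                       group = ds$group, stringsAsFactors = FALSE),
            samplesPath)
  if (!is.null(qcPath)) {
    qdf <- cbind(data.frame(probe_id = rd$probe_id),
                 as.data.frame(assay(ds, "qc") * 1L))
    .writeTsv(qdf, qcPath)
  }
  invisible(matrixPath)
}

#' @param scale Measurement scale of the stored values (`"raw"` default).
#' @rdname writeExpressionMatrix
#' @export
readExpressionMatrix <- function(matrixPath, samplesPath, qcPath = NULL,
                                 scale = "raw") {
  df <- utils::read.delim(matrixPath, stringsAsFactors = FALSE,
                          check.names = FALSE,
                          colClasses = c(gene_id = "character"))
  ss <- utils::read.delim(samplesPath, stringsAsFactors = FALSE)
  sampleCols <- setdiff(colnames(df), c("probe_id", "gene_id"))
  if (!setequal(sampleCols, ss$sample_id))
    stop("sample sheet does not match matrix columns")
  values <- as.matrix(df[, ss$sample_id, drop = FALSE])
  qc <- NULL
  if (!is.null(qcPath)) {
    qdf <- utils::read.delim(qcPath, stringsAsFactors = FALSE,
                             check.names = FALSE)
    qc <- as.matrix(qdf[, ss$sample_id, drop = FALSE]) > 0
  }
  ExpressionDataset(values, df$probe_id,
                    ifelse(df$gene_id == "", NA_character_, df$gene_id),
                    ss$group, qc = qc, scale = scale)
}

#' Read / write FASTA sequence sets
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] that enforce the pipeline's contracts:
#' ids must be unique, records non-empty, and input is folded to upper
#' case so scanning is case-insensitive.
#'
#' @param path FASTA file path.
#' @return `readFastaSeqs`: a [Biostrings::DNAStringSet].
#' @export
readFastaSeqs <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  ## keep only the id token, as scanners and truth tables use bare ids
  names(s) <- sub("\\s.*$", "", names(s))
  if (anyDuplicated(names(s)))
    stop("duplicate sequence ids in ", path)
  if (any(Biostrings::width(s) == 0L))
    stop("empty sequence record in ", path)
  Biostrings::DNAStringSet(toupper(as.character(s)))
}

#' @param seqs A [Biostrings::DNAStringSet] (or named character vector).
#' @rdname readFastaSeqs
#' @export
writeFastaSeqs <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a synthetic-truth object as JSON
#'
#' @param truth A [SyntheticTruth-class].
#' @param path Output path.
#' @export
writeTruthJson <- function(truth, path) {
  jsonlite::write_json(
    list(de_genes = plantedDE(truth),
         peak_targets = plantedPeakTargets(truth),
         motif_pairs = plantedMotifPairs(truth)),
    path, dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(path)
}
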