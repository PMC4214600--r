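# Peak-interval handling. Peaks are GRanges (1-based closed internally, as
# usual for Bioconductor); BED files are 0-based half-open and converted at
# the boundary. mcols carry peak_id, score and optional summit_offset.

.peakIds <- function(peaks) {
  if (!is.null(mcols(peaks)$peak_id)) return(as.character(mcols(peaks)$peak_id))
  if (!is.null(names(peaks)) && !anyNA(names(peaks))) return(names(peaks))
  sprintf("peak_%05d", seq_along(peaks))
}

# 0-based midpoint of each peak: (start0 + end0) %/% 2. With anchor =
# "summit", uses start0 + summit_offset where available.
.peakAnchors <- function(peaks, anchor = c("midpoint", "summit")) {
  anchor <- match.arg(anchor)
  start0 <- start(peaks) - 1
  end0 <- end(peaks)
  mid <- (start0 + end0) %/% 2
  if (anchor == "summit" && !is.null(mcols(peaks)$summit_offset)) {
    so <- mcols(peaks)$summit_offset
    mid <- ifelse(is.na(so), mid, start0 + so)
  }
  mid
}

#' Read a BED3+ peak file
#'
#' Parses BED (0-based half-open) into a [GenomicRanges::GRanges] with
#' mcols `peak_id` (column 4 when present, otherwise generated), `score`
#' and `strand`. `track`, `browser` and `#` header lines are skipped.
#' Malformed lines and intervals with `start >= end` raise an error naming
#' the offending line number.
#'
#' @param path BED file path.
#' @return A [GenomicRanges::GRanges].
#' @export
readPeakBed <- function(path) {
  lines <- readLines(path)
  lineNo <- seq_along(lines)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]; lineNo <- lineNo[keep]
  if (!length(lines))
    return(GRanges(peak_id = character(), score = numeric()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop("malformed BED line ", lineNo[which(nf < 3L)[1]],
         ": fewer than 3 fields")
  chrom <- vapply(parts, `[[`, character(1), 1L)
  start0 <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3L)))
  bad <- is.na(start0) | is.na(end0)
  if (any(bad))
    stop("malformed BED line ", lineNo[which(bad)[1]],
         ": non-numeric coordinates")
  if (any(start0 >= end0))
    stop("invalid interval at line ", lineNo[which(start0 >= end0)[1]],
         ": start >= end")
  name <- ifelse(nf >= 4L, vapply(parts, function(p) p[min(4L, length(p))],
                                  character(1)), NA_character_)
  score <- suppressWarnings(as.numeric(
    ifelse(nf >= 5L, vapply(parts, function(p) p[min(5L, length(p))],
                            character(1)), NA_character_)))
  strand <- ifelse(nf >= 6L, vapply(parts, function(p) p[min(6L, length(p))],
                                    character(1)), "*")
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GRanges(chrom, IRanges(start = start0 + 1, end = end0),
                strand = strand)
  ids <- ifelse(is.na(name), sprintf("peak_%05d", seq_along(gr)), name)
  mcols(gr)$peak_id <- ids
  mcols(gr)$score <- score
  names(gr) <- ids
  gr
}

#' Write peaks as BED6
#'
#' 0-based half-open output; missing scores become 0, unknown strands `.`.
#'
#' @param peaks A [GenomicRanges::GRanges].
#' @param path Output path.
#' @export
writePeakBed <- function(peaks, path) {
  score <- mcols(peaks)$score
  if (is.null(score)) score <- rep(0, length(peaks))
  score[is.na(score)] <- 0
  str <- as.character(strand(peaks))
  str[str == "*"] <- "."
  df <- data.frame(as.character(seqnames(peaks)),
                   format(start(peaks) - 1, scientific = FALSE, trim = TRUE),
                   format(end(peaks), scientific = FALSE, trim = TRUE),
                   .peakIds(peaks), score, str)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Annotate peaks to genes: 100-kbp window with nearest-TSS fallback
#'
#' Each peak is linked to every gene whose TSS lies within `window` bp of
#' the peak anchor (midpoint by default) on the same chromosome
#' (`rule = "window"`). A peak with no gene in its window is linked to the
#' nearest-TSS gene on its chromosome instead (`rule = "nearest"`; all
#' equidistant genes are linked, ordered by gene id). Peaks on chromosomes
#' with no annotated gene yield no link, with a warning. Distances are
#' signed in gene orientation: positive when the peak lies downstream of
#' the TSS.
#'
#' @param peaks A [GenomicRanges::GRanges].
#' @param genome A [GenomeModel-class].
#' @param window Window half-width in bp (default 100 kbp).
#' @param anchor `"midpoint"` (default) or `"summit"`.
#' @return `data.frame` with `peak_id`, `gene_id`, `distance`, `rule`.
#' @export
annotatePeaks <- function(peaks, genome, window = 1e5,
                          anchor = c("midpoint", "summit")) {
  stopifnot(is(genome, "GenomeModel"), window >= 0)
  anchor <- match.arg(anchor)
  if (!length(peaks))
    return(data.frame(peak_id = character(), gene_id = character(),
                      distance = numeric(), rule = character()))
  g <- geneTable(genome)
  ids <- .peakIds(peaks)
  mid <- .peakAnchors(peaks, anchor)
  chrom <- as.character(seqnames(peaks))
  noGene <- !chrom %in% g$chrom
  if (any(noGene))
    warning(sum(noGene), " peak(s) on chromosome(s) without genes: ",
            paste(unique(chrom[noGene]), collapse = ", "))

  winGR <- GRanges(chrom, IRanges(start = mid + 1 - window,
                                  end = mid + 1 + window))
  tssGR <- GRanges(g$chrom, IRanges(start = g$tss + 1, width = 1L))
  ## chromosome mismatch is already reported above; silence the seqlevel
  ## notice findOverlaps would add on top
  hits <- suppressWarnings(GenomicRanges::findOverlaps(winGR, tssGR))
  pi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  signedDist <- function(pidx, gidx) {
    raw <- mid[pidx] - g$tss[gidx]
    ifelse(g$strand[gidx] == "+", raw, -raw)
  }
  winLinks <- data.frame(peak_id = ids[pi], gene_id = g$gene_id[gi],
                         distance = signedDist(pi, gi),
                         rule = rep("window", length(pi)),
                         stringsAsFactors = FALSE)

  ## nearest-TSS fallback for peaks with no window link (same chromosome)
  need <- setdiff(which(!noGene), unique(pi))
  nearRows <- lapply(need, function(i) {
    on <- which(g$chrom == chrom[i])
    dd <- abs(mid[i] - g$tss[on])
    sel <- on[dd == min(dd)]
    sel <- sel[order(g$gene_id[sel])]
    data.frame(peak_id = ids[i], gene_id = g$gene_id[sel],
               distance = signedDist(rep(i, length(sel)), sel),
               rule = "nearest", stringsAsFactors = FALSE)
  })
  out <- rbind(winLinks, do.call(rbind, c(nearRows, list(NULL))))
  out <- out[order(match(out$peak_id, ids), out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Classify peak locations
#'
#' `promoter` when the peak anchor lies within `promoterWindow` bp of any
#' TSS; otherwise `intragenic-proxy` when the anchor falls within
#' `bodyLength` bp downstream of a TSS in gene orientation (a gene-body
#' proxy, since the genome model carries TSSs only); otherwise
#' `intergenic`. Precedence promoter > intragenic-proxy > intergenic.
#'
#' @param peaks A [GenomicRanges::GRanges].
#' @param genome A [GenomeModel-class].
#' @param promoterWindow Promoter half-width in bp.
#' @param bodyLength Gene-body proxy length in bp.
#' @param anchor `"midpoint"` or `"summit"`.
#' @return Character vector of categories, one per peak (named by peak id).
#' @export
classifyPeaks <- function(peaks, genome, promoterWindow = 2000,
                          bodyLength = 30000,
                          anchor = c("midpoint", "summit")) {
  stopifnot(is(genome, "GenomeModel"))
  anchor <- match.arg(anchor)
  g <- geneTable(genome)
  mid <- .peakAnchors(peaks, anchor)
  chrom <- as.character(seqnames(peaks))
  cat0 <- vapply(seq_along(peaks), function(i) {
    on <- which(g$chrom == chrom[i])
    if (!length(on)) return("intergenic")
    dd <- mid[i] - g$tss[on]
    if (any(abs(dd) <= promoterWindow)) return("promoter")
    down <- ifelse(g$strand[on] == "+", dd, -dd)
    if (any(down > 0 & down <= bodyLength)) return("intragenic-proxy")
    "intergenic"
  }, character(1))
  stats::setNames(cat0, .peakIds(peaks))
}

#' Intersect two peak sets
#'
#' All pairs of peaks from `a` and `b` overlapping by at least
#' `minOverlap` bp (half-open convention: intervals that merely abut do
#' not overlap).
#'
#' @param a,b [GenomicRanges::GRanges] peak sets.
#' @param minOverlap Minimum overlap in bp.
#' @return `data.frame` with `peak_a`, `peak_b`, `overlap` (bp).
#' @export
intersectPeakSets <- function(a, b, minOverlap = 1L) {
  stopifnot(minOverlap >= 1L)
  hits <- GenomicRanges::findOverlaps(a, b, minoverlap = minOverlap,
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(end(a)[qi], end(b)[si]) - pmax(start(a)[qi], start(b)[si]) + 1L
  data.frame(peak_a = .peakIds(a)[qi], peak_b = .peakIds(b)[si],
             overlap = as.integer(ov), stringsAsFactors = FALSE)
}

#' Write peak-gene links as TSV
#'
#' @param links An [annotatePeaks()] result.
#' @param path Output path.
#' @export
writePeakLinks <- function(links, path) {
  .writeTsv(links, path)
  invisible(path)
}

#' @rdname writePeakLinks
#' @export
readPeakLinks <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
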