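# IUPAC consensus scanning and heterotypic site pairing. Coordinates are
# 0-based half-open on the plus strand throughout; minus-strand hits are
# reported in plus-strand coordinates.

.checkNucleotides <- function(letters, where) {
  ok <- letters %in% c("A", "C", "G", "T", "N")
  if (!all(ok))
    stop("non-nucleotide character '", letters[!ok][1], "' in ", where)
}

# Mismatch count of one pattern (character vector of IUPAC codes) against
# every window of a subject letter vector. Subject 'N' never matches.
.windowMismatches <- function(subj, pattern) {
  k <- length(pattern)
  L <- length(subj)
  if (L < k) return(integer())
  n <- L - k + 1L
  mm <- integer(n)
  for (j in seq_len(k)) {
    allowed <- setdiff(IUPAC_SETS[[pattern[j]]], "N")
    mm <- mm + !(subj[j:(j + n - 1L)] %in% allowed)
  }
  mm
}

#' Scan sequences for an IUPAC consensus motif
#'
#' Reports every window whose mismatch count against the consensus is at
#' most `maxMismatch`, on both strands when requested. Matching uses IUPAC
#' degeneracy sets (a window base matches a consensus code when it belongs
#' to the code's set); an `N` in the sequence never matches. Minus-strand
#' sites are found by scanning the reverse-complemented consensus and are
#' reported in plus-strand coordinates (0-based half-open).
#'
#' @param seqs A [Biostrings::DNAStringSet], named character vector, or a
#'   single sequence string (sequences over `ACGTN`, case-insensitive).
#' @param motif A [Motif-class].
#' @param maxMismatch Maximum mismatches allowed (must be < motif length).
#' @param bothStrands Scan the minus strand too (default `TRUE`).
#' @return `data.frame` with `seq_id`, `motif_id`, `start`, `end`,
#'   `strand`, `mismatches`.
#' @examples
#' scanConsensus("AGGTGTGG", builtinMotif("TBX"))
#' @export
scanConsensus <- function(seqs, motif, maxMismatch = 0L,
                          bothStrands = TRUE) {
  stopifnot(is(motif, "Motif"))
  k <- motifLength(motif)
  if (maxMismatch >= k) stop("maxMismatch must be smaller than motif length")
  if (is(seqs, "DNAStringSet") || is(seqs, "DNAString"))
    seqs <- as.character(seqs)
  if (is.null(names(seqs)))
    names(seqs) <- if (length(seqs) == 1L) "seq" else
      sprintf("seq_%04d", seq_along(seqs))
  fwd <- strsplit(toupper(consensus(motif)), "")[[1]]
  rev <- strsplit(.revcomp(consensus(motif)), "")[[1]]
  rows <- lapply(names(seqs), function(id) {
    subj <- strsplit(toupper(seqs[[id]]), "")[[1]]
    .checkNucleotides(subj, paste0("sequence '", id, "'"))
    mm <- .windowMismatches(subj, fwd)
    hit <- which(mm <= maxMismatch)
    out <- data.frame(seq_id = rep(id, length(hit)),
                      start = hit - 1L, strand = rep("+", length(hit)),
                      mismatches = mm[hit], stringsAsFactors = FALSE)
    if (bothStrands) {
      mmR <- .windowMismatches(subj, rev)
      hitR <- which(mmR <= maxMismatch)
      out <- rbind(out, data.frame(seq_id = rep(id, length(hitR)),
                                   start = hitR - 1L,
                                   strand = rep("-", length(hitR)),
                                   mismatches = mmR[hitR],
                                   stringsAsFactors = FALSE))
    }
    out
  })
  out <- do.call(rbind, rows)
  out$end <- out$start + k
  out$motif_id <- rep(motifId(motif), nrow(out))
  out <- out[order(out$seq_id, out$start, out$strand), ]
  rownames(out) <- NULL
  out[, c("seq_id", "motif_id", "start", "end", "strand", "mismatches")]
}

#' Pair heterotypic motif sites by adjacency
#'
#' All pairs of one site from `sitesA` and one from `sitesB` on the same
#' sequence whose edge-to-edge separation is at most `maxGap` bp;
#' overlapping or abutting sites have gap 0. Gap is
#' `max(0, max(startA, startB) - min(endA, endB))` under half-open
#' coordinates. The default window of 50 bp accommodates "adjacent" site
#' configurations reported with ~30 bp between site edges.
#'
#' @param sitesA,sitesB [scanConsensus()] site tables from the same
#'   sequence set.
#' @param maxGap Maximum edge-to-edge gap in bp.
#' @return `data.frame` with the `a`/`b` site coordinates and `gap`,
#'   sorted by `(seq_id, gap)`.
#' @export
findAdjacentPairs <- function(sitesA, sitesB, maxGap = 50L) {
  need <- c("seq_id", "start", "end", "strand")
  stopifnot(all(need %in% colnames(sitesA)),
            all(need %in% colnames(sitesB)))
  empty <- data.frame(seq_id = character(), start_a = integer(),
                      end_a = integer(), strand_a = character(),
                      start_b = integer(), end_b = integer(),
                      strand_b = character(), gap = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(sitesA) || !nrow(sitesB)) return(empty)
  merged <- merge(
    data.frame(seq_id = sitesA$seq_id, start_a = sitesA$start,
               end_a = sitesA$end, strand_a = sitesA$strand),
    data.frame(seq_id = sitesB$seq_id, start_b = sitesB$start,
               end_b = sitesB$end, strand_b = sitesB$strand),
    by = "seq_id")
  if (!nrow(merged)) return(empty)
  merged$gap <- pmax(0L, pmax(merged$start_a, merged$start_b) -
                          pmin(merged$end_a, merged$end_b))
  out <- merged[merged$gap <= maxGap, , drop = FALSE]
  out <- out[order(out$seq_id, out$gap, out$start_a, out$start_b), ]
  rownames(out) <- NULL
  out
}

# First-order Markov resample of one sequence (preserves dinucleotide
# composition in expectation); used as scan background.
.dinucShuffle <- function(seq) {
  s <- strsplit(toupper(seq), "")[[1]]
  L <- length(s)
  if (L < 2L) return(seq)
  bases <- c("A", "C", "G", "T")
  s[!s %in% bases] <- sample(bases, sum(!s %in% bases), replace = TRUE)
  trans <- matrix(0.25, 4, 4, dimnames = list(bases, bases))
  tab <- table(factor(s[-L], bases), factor(s[-1], bases))
  rs <- rowSums(tab)
  for (b in bases) if (rs[b] > 0) trans[b, ] <- tab[b, ] / rs[b]
  out <- character(L)
  out[1] <- sample(bases, 1L)
  for (i in 2:L)
    out[i] <- sample(bases, 1L, prob = trans[out[i - 1L], ])
  paste(out, collapse = "")
}

#' Known-motif enrichment of foreground vs background sequences
#'
#' Scores each sequence for presence/absence of the motif (at the given
#' mismatch allowance, both strands) and tests over-representation in the
#' foreground with a one-sided Fisher exact test on the
#' `(fg with, fg without, bg with, bg without)` table. When no background
#' set is supplied, one is generated by a per-sequence dinucleotide
#' (first-order Markov) shuffle of the foreground.
#'
#' @param fgSeqs Foreground sequences ([Biostrings::DNAStringSet] or named
#'   character vector).
#' @param motif A [Motif-class].
#' @param bgSeqs Optional background sequences.
#' @param maxMismatch Mismatch allowance for the scan.
#' @param bgPerSeq Shuffled background sequences generated per foreground
#'   sequence when `bgSeqs` is omitted.
#' @param seed Seed for background generation.
#' @return An [EnrichmentResult-class]; the counts are
#'   `a` = foreground sequences with a site, `b` = without,
#'   `c` = background with, `d` = background without.
#' @export
motifEnrichment <- function(fgSeqs, motif, bgSeqs = NULL, maxMismatch = 0L,
                            bgPerSeq = 2L, seed = 1L) {
  if (is(fgSeqs, "DNAStringSet")) fgSeqs <- as.character(fgSeqs)
  if (!length(fgSeqs)) stop("foreground set is empty")
  if (any(nchar(fgSeqs) < motifLength(motif)))
    stop("motif is longer than some sequences")
  if (is.null(names(fgSeqs))) names(fgSeqs) <- sprintf("fg_%04d",
                                                       seq_along(fgSeqs))
  if (is.null(bgSeqs)) {
    bgSeqs <- .withSeed(seed, {
      reps <- rep(unname(fgSeqs), each = bgPerSeq)
      vapply(reps, .dinucShuffle, character(1), USE.NAMES = FALSE)
    })
    names(bgSeqs) <- sprintf("bg_%04d", seq_along(bgSeqs))
  } else {
    if (is(bgSeqs, "DNAStringSet")) bgSeqs <- as.character(bgSeqs)
    if (!length(bgSeqs)) stop("background set is empty")
    if (is.null(names(bgSeqs))) names(bgSeqs) <- sprintf("bg_%04d",
                                                         seq_along(bgSeqs))
  }
  hasSite <- function(seqs) {
    sites <- scanConsensus(seqs, motif, maxMismatch = maxMismatch,
                           bothStrands = TRUE)
    names(seqs) %in% sites$seq_id
  }
  fgHit <- hasSite(fgSeqs)
  bgHit <- hasSite(bgSeqs)
  fet2x2(sum(fgHit), sum(!fgHit), sum(bgHit), sum(!bgHit), sided = "one",
         label = paste0("motif:", motifId(motif)))
}

#' Write motif sites as TSV or BED6
#'
#' The BED rendering uses the site's motif id as the feature name and the
#' mismatch count as the score; both renderings keep 0-based half-open
#' coordinates.
#'
#' @param sites A [scanConsensus()] table.
#' @param path Output path.
#' @export
writeMotifSites <- function(sites, path) {
  .writeTsv(sites, path)
  invisible(path)
}

#' @rdname writeMotifSites
#' @export
writeMotifSitesBed <- function(sites, path) {
  df <- data.frame(sites$seq_id, sites$start, sites$end, sites$motif_id,
                   sites$mismatches, sites$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @param pairs A [findAdjacentPairs()] table.
#' @rdname writeMotifSites
#' @export
writeCoSitePairs <- function(pairs, path) {
  .writeTsv(pairs, path)
  invisible(path)
}
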