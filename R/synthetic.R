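#' Simulate a genome model with TSS annotation and gene-family labels
#'
#' Places gene transcription start sites uniformly along each chromosome
#' subject to a minimum inter-TSS spacing, assigns strands at random, and
#' tags genes with family labels (e.g. `"TF"`, `"FOX"`) by independent
#' Bernoulli draws at the requested fractions. The result is the coordinate
#' and gene universe for peak annotation and enrichment testing.
#'
#' @param nChrom Number of chromosomes (named `chr1`, `chr2`, ...).
#' @param nGenes Total number of genes, split evenly across chromosomes.
#' @param chromLen Chromosome length in bp (scalar, or one per chromosome).
#' @param familyFractions Named numeric vector: fraction of genes carrying
#'   each family label (labels assigned independently).
#' @param minSpacing Minimum distance between adjacent TSSs on a
#'   chromosome (bp).
#' @param seed Integer seed; identical seeds give identical genomes.
#' @return A [GenomeModel-class].
#' @examples
#' gm <- simulateGenome(nGenes = 100, chromLen = 2e6,
#'                      familyFractions = c(TF = 0.1), seed = 1)
#' gm
#' @export
simulateGenome <- function(nChrom = 1L, nGenes = 1000L, chromLen = 1e8,
                           familyFractions = c(TF = 0.10, FOX = 0.01),
                           minSpacing = 5000L, seed) {
  stopifnot(nChrom >= 1L, nGenes >= 1L)
  if (length(familyFractions) &&
      (any(familyFractions < 0) || any(familyFractions > 1)))
    stop("family fractions must lie in [0, 1]")
  chromLen <- rep_len(chromLen, nChrom)
  chroms <- paste0("chr", seq_len(nChrom))
  nPer <- diff(round(seq(0, nGenes, length.out = nChrom + 1L)))
  bad <- chromLen < (pmax(nPer, 1L) - 1L) * minSpacing + 1
  if (any(bad))
    stop("chromosome too short to fit ", nPer[which(bad)[1]],
         " genes at spacing ", minSpacing, " bp")
  .withSeed(seed, {
    tss <- unlist(lapply(seq_len(nChrom), function(i) {
      n <- nPer[i]
      if (n == 0L) return(numeric())
      slack <- chromLen[i] - (n - 1) * minSpacing
      floor(sort(stats::runif(n, 0, slack)) + (seq_len(n) - 1) * minSpacing)
    }))
    genes <- DataFrame(
      gene_id = sprintf("gene_%05d", seq_len(nGenes)),
      chrom = rep(chroms, nPer),
      tss = as.numeric(tss),
      strand = sample(c("+", "-"), nGenes, replace = TRUE))
    fam <- lapply(seq_len(nGenes), function(i) character())
    for (lab in names(familyFractions)) {
      hit <- stats::runif(nGenes) < familyFractions[[lab]]
      fam[hit] <- lapply(fam[hit], function(f) c(f, lab))
    }
    genes$families <- CharacterList(fam)
    GenomeModel(stats::setNames(chromLen, chroms), genes)
  })
}

#' Simulate a case/control probe-level expression dataset
#'
#' Generates log-normal probe intensities for a mutant-versus-wild-type
#' two-group array experiment (default 4 case vs 3 control arrays). A
#' chosen number of genes is planted as differentially expressed by shifting
#' their case-group mean by a log2 fold change drawn from `lfcRange`
#' (negative for down-regulated genes). Probes map many-to-one onto genes
#' (default 1.3 probes per gene); a fraction of probes is left unannotated
#' and QC-fail flags are injected at a configurable per-measurement rate.
#' Per-array multiplicative scale jitter is applied so the normalization
#' stage has real calibration work to do.
#'
#' @param genome A [GenomeModel-class] supplying the gene universe.
#' @param nCase,nControl Arrays per group (each must be >= 2).
#' @param deSpec List with `n_down`, `n_up` and `lfc_range` (absolute log2
#'   fold-change range of planted genes).
#' @param noiseSd Per-measurement Gaussian noise SD on the log2 scale.
#' @param probesPerGene Mean probes per annotated gene (>= 1).
#' @param fracUnannotated Fraction of additional probes with no gene.
#' @param qcFailRate Per-measurement probability of a QC-fail flag.
#' @param scaleJitterSd SD of the per-array log2 scale offset.
#' @param seed Integer seed.
#' @return A list with elements `dataset` ([ExpressionDataset-class], raw
#'   scale) and `truth` ([SyntheticTruth-class]).
#' @examples
#' gm <- simulateGenome(nGenes = 50, chromLen = 1e6, seed = 1)
#' sim <- simulateExpression(gm, deSpec = list(n_down = 5, n_up = 0,
#'                                             lfc_range = c(2, 3)), seed = 2)
#' sim$dataset
#' @export
simulateExpression <- function(genome, nCase = 4L, nControl = 3L,
                               deSpec = list(n_down = 0L, n_up = 0L,
                                             lfc_range = c(1, 3)),
                               noiseSd = 0.4, probesPerGene = 1.3,
                               fracUnannotated = 0.03, qcFailRate = 0.01,
                               scaleJitterSd = 0.1, seed) {
  stopifnot(is(genome, "GenomeModel"))
  if (nCase < 2L || nControl < 2L)
    stop("need at least 2 samples per group")
  gid <- geneIds(genome)
  m <- length(gid)
  nDown <- deSpec$n_down %||% 0L
  nUp <- deSpec$n_up %||% 0L
  if (nDown + nUp > m)
    stop("deSpec requests ", nDown + nUp, " DE genes but genome has only ",
         m, " genes")
  lfcRange <- deSpec$lfc_range %||% c(1, 3)
  .withSeed(seed, {
    ## planted truth
    deGenes <- sample(gid, nDown + nUp)
    lfc <- c(if (nDown) -stats::runif(nDown, lfcRange[1], lfcRange[2]),
             if (nUp) stats::runif(nUp, lfcRange[1], lfcRange[2]))
    if (is.null(lfc)) lfc <- numeric(0)
    truthDE <- data.frame(gene_id = deGenes, log2fc = lfc,
                          stringsAsFactors = FALSE)

    ## probe -> gene map: one probe per gene, extras to random genes,
    ## plus unannotated probes
    nExtra <- max(0L, round((probesPerGene - 1) * m))
    probeGene <- c(gid, if (nExtra) sample(gid, nExtra, replace = TRUE))
    nUn <- round(fracUnannotated * length(probeGene))
    probeGene <- c(probeGene, rep(NA_character_, nUn))
    p <- length(probeGene)
    probeIds <- sprintf("probe_%06d", seq_len(p))

    n <- nCase + nControl
    groups <- c(rep("case", nCase), rep("control", nControl))
    sampleIds <- c(sprintf("case_%02d", seq_len(nCase)),
                   sprintf("ctrl_%02d", seq_len(nControl)))

    geneMu <- stats::setNames(stats::rnorm(m, mean = 8, sd = 1.5), gid)
    probeMu <- ifelse(is.na(probeGene),
                      stats::rnorm(p, mean = 8, sd = 1.5),
                      geneMu[probeGene]) +
      stats::rnorm(p, sd = 0.5)                     # probe affinity offset
    shift <- stats::setNames(numeric(m), gid)
    shift[deGenes] <- lfc
    probeShift <- ifelse(is.na(probeGene), 0, shift[probeGene])

    arrayOffset <- stats::rnorm(n, sd = scaleJitterSd)
    log2val <- matrix(probeMu, p, n) +
      outer(probeShift, as.numeric(groups == "case")) +
      matrix(arrayOffset, p, n, byrow = TRUE) +
      matrix(stats::rnorm(p * n, sd = noiseSd), p, n)
    values <- 2^log2val
    colnames(values) <- sampleIds
    qc <- matrix(stats::runif(p * n) >= qcFailRate, p, n)
    ds <- ExpressionDataset(values, probeIds, probeGene, groups, qc = qc)
    list(dataset = ds,
         truth = SyntheticTruth(deGenes = truthDE))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a ChIP-seq peak set with controlled TSS proximity
#'
#' Places a requested fraction of peaks with midpoint within `nearWindow` bp
#' of a (target) gene TSS and the remainder uniformly along the genome; no
#' peak crosses a chromosome boundary. The near-TSS peak-to-gene assignment
#' is recorded in the returned truth object.
#'
#' @param genome A [GenomeModel-class].
#' @param nPeaks Number of peaks.
#' @param fracNearTss Fraction of peaks placed near a TSS.
#' @param nearWindow Half-width (bp) of the near-TSS placement window.
#' @param peakWidth Peak width in bp (must fit inside every chromosome).
#' @param targetGenes Optional gene ids to target; all genes by default.
#' @param seed Integer seed.
#' @return List with `peaks` (a [GenomicRanges::GRanges] with mcols
#'   `peak_id`, `score`, `summit_offset`) and `truth`
#'   ([SyntheticTruth-class]).
#' @export
simulatePeaks <- function(genome, nPeaks, fracNearTss = 0.5,
                          nearWindow = 1000L, peakWidth = 500L,
                          targetGenes = NULL, seed) {
  stopifnot(is(genome, "GenomeModel"), nPeaks >= 0L,
            fracNearTss >= 0, fracNearTss <= 1)
  cl <- chromLengths(genome)
  if (any(peakWidth >= cl))
    stop("peakWidth must be smaller than every chromosome")
  g <- geneTable(genome)
  if (!is.null(targetGenes)) {
    miss <- setdiff(targetGenes, g$gene_id)
    if (length(miss))
      stop("target gene(s) not in genome: ", paste(head(miss, 3), collapse = ", "))
  } else targetGenes <- as.character(g$gene_id)
  if (nPeaks == 0L) {
    gr <- GRanges(seqlengths = cl)
    mcols(gr)$peak_id <- character()
    mcols(gr)$score <- numeric()
    mcols(gr)$summit_offset <- integer()
    return(list(peaks = gr, truth = SyntheticTruth()))
  }
  .withSeed(seed, {
    nNear <- round(fracNearTss * nPeaks)
    half <- peakWidth %/% 2L
    tgt <- if (nNear)
      sample(targetGenes, nNear, replace = nNear > length(targetGenes))
    else character()
    rows <- match(tgt, g$gene_id)
    nearChrom <- as.character(g$chrom[rows])
    off <- if (nearWindow > 0)
      round(stats::runif(nNear, -nearWindow, nearWindow)) else rep(0L, nNear)
    mid <- g$tss[rows] + off
    ## keep whole peak on the chromosome
    mid <- pmin(pmax(mid, half), cl[nearChrom] - (peakWidth - half))
    nearStart <- mid - half

    nFar <- nPeaks - nNear
    farChrom <- sample(names(cl), nFar, replace = TRUE,
                       prob = cl / sum(cl))
    farStart <- floor(stats::runif(nFar, 0, cl[farChrom] - peakWidth))

    chrom <- c(nearChrom, farChrom)
    start0 <- as.numeric(c(nearStart, farStart))
    gr <- GRanges(chrom, IRanges(start = start0 + 1, width = peakWidth),
                  seqlengths = cl)
    mcols(gr)$peak_id <- sprintf("peak_%05d", seq_len(nPeaks))
    mcols(gr)$score <- round(stats::runif(nPeaks, 10, 200), 2)
    mcols(gr)$summit_offset <- rep(half, nPeaks)
    names(gr) <- mcols(gr)$peak_id
    truth <- SyntheticTruth(
      peakTargets = data.frame(peak_id = mcols(gr)$peak_id[seq_len(nNear)],
                               gene_id = tgt, stringsAsFactors = FALSE))
    list(peaks = gr, truth = truth)
  })
}

#' Plant heterotypic motif pairs into random sequences
#'
#' Generates `nSeqs` i.i.d. uniform-ACGT sequences and, in a chosen fraction
#' of them, embeds the exact consensus of `motifA`, a fixed-length random
#' spacer, then the consensus of `motifB` — on a randomly chosen strand, at
#' a random position. Plus-strand coordinates of both planted sites are
#' recorded in the truth object (0-based half-open), emulating an enhancer
#' carrying adjacent GLI and T-box sites.
#'
#' @param nSeqs Number of sequences.
#' @param seqLen Sequence length (bp); must fit the full cassette.
#' @param motifA,motifB [Motif-class] objects (defaults: built-in GLI and
#'   TBX).
#' @param gap Spacer length (bp) between the two sites, edge to edge.
#' @param fracPlanted Fraction of sequences receiving a planted pair.
#' @param seed Integer seed.
#' @return List with `sequences` (a [Biostrings::DNAStringSet]) and `truth`
#'   ([SyntheticTruth-class]) whose `motifPairs` rows give `seq_id`,
#'   `start_a`/`end_a`, `start_b`/`end_b`, `strand` and `gap`.
#' @export
plantMotifPairs <- function(nSeqs, seqLen, motifA = builtinMotif("GLI"),
                            motifB = builtinMotif("TBX"), gap = 30L,
                            fracPlanted = 0.5, seed) {
  stopifnot(nSeqs >= 0L, fracPlanted >= 0, fracPlanted <= 1, gap >= 0L)
  lenA <- motifLength(motifA)
  lenB <- motifLength(motifB)
  cassette <- lenA + gap + lenB
  if (seqLen < cassette)
    stop("seqLen (", seqLen, ") cannot hold motifA + gap + motifB (",
         cassette, " bp)")
  .withSeed(seed, {
    bases <- c("A", "C", "G", "T")
    seqs <- vapply(seq_len(nSeqs), function(i)
      paste(sample(bases, seqLen, replace = TRUE), collapse = ""),
      character(1))
    ids <- sprintf("seq_%04d", seq_len(nSeqs))
    nPlant <- round(fracPlanted * nSeqs)
    planted <- sort(sample(seq_len(nSeqs), nPlant))
    pairs <- vector("list", nPlant)
    for (k in seq_along(planted)) {
      i <- planted[k]
      consA <- .concreteConsensus(consensus(motifA))
      consB <- .concreteConsensus(consensus(motifB))
      spacer <- paste(sample(bases, gap, replace = TRUE), collapse = "")
      minus <- stats::runif(1) < 0.5
      pos <- sample.int(seqLen - cassette + 1L, 1L) - 1L  # 0-based
      cas <- paste0(consA, spacer, consB)
      if (minus) cas <- .revcomp(cas)
      substr(seqs[i], pos + 1L, pos + cassette) <- cas
      if (!minus) {
        sa <- pos; sb <- pos + lenA + gap
        pairs[[k]] <- data.frame(seq_id = ids[i], start_a = sa,
                                 end_a = sa + lenA, start_b = sb,
                                 end_b = sb + lenB, strand = "+",
                                 gap = gap, stringsAsFactors = FALSE)
      } else {
        sb <- pos; sa <- pos + lenB + gap
        pairs[[k]] <- data.frame(seq_id = ids[i], start_a = sa,
                                 end_a = sa + lenA, start_b = sb,
                                 end_b = sb + lenB, strand = "-",
                                 gap = gap, stringsAsFactors = FALSE)
      }
    }
    truth <- SyntheticTruth(motifPairs = if (nPlant) do.call(rbind, pairs)
                            else data.frame())
    sset <- Biostrings::DNAStringSet(seqs)
    names(sset) <- ids
    list(sequences = sset, truth = truth)
  })
}

# Draw one concrete ACGT realization of an IUPAC consensus.
.concreteConsensus <- function(cons) {
  letters <- strsplit(toupper(cons), "")[[1]]
  paste(vapply(letters, function(l) {
    s <- IUPAC_SETS[[l]]
    if (length(s) == 1L) s else sample(s, 1L)
  }, character(1)), collapse = "")
}
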