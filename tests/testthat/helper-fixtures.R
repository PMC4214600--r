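# Fixtures built in code; no data files.

# A hand-laid two-chromosome genome with known TSS positions.
tinyGenome <- function() {
  GenomeModel(
    chromLengths = c(chr1 = 1e6, chr2 = 5e5),
    genes = data.frame(
      gene_id = c("gA", "gB", "gC", "gD"),
      chrom = c("chr1", "chr1", "chr1", "chr2"),
      tss = c(10000, 150000, 400000, 250000),
      strand = c("+", "-", "+", "+"),
      families = c("TF", "", "TF,FOX", ""),
      stringsAsFactors = FALSE))
}

# Raw-scale dataset with full control over values.
makeDataset <- function(values, geneIds = NULL, groups = NULL, qc = NULL,
                        scale = "raw") {
  values <- as.matrix(values)
  if (is.null(geneIds)) geneIds <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(groups))
    groups <- rep(c("case", "control"), length.out = ncol(values))
  ExpressionDataset(values, sprintf("p%03d", seq_len(nrow(values))),
                    geneIds, groups, qc = qc, scale = scale)
}

# GRanges peak set from 0-based half-open coordinates.
makePeaks <- function(chrom, start0, end0, ids = NULL) {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1,
                                                end = end0))
  S4Vectors::mcols(gr)$peak_id <- ids %||%
    sprintf("pk%03d", seq_along(gr))
  gr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force window/nearest annotation oracle (all peak-gene pairs).
oracleAnnotate <- function(peaks, genome, window) {
  g <- as.data.frame(geneTable(genome))
  ids <- S4Vectors::mcols(peaks)$peak_id
  mid <- (GenomicRanges::start(peaks) - 1 + GenomicRanges::end(peaks)) %/% 2
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  out <- NULL
  for (i in seq_along(peaks)) {
    on <- g[g$chrom == chrom[i], , drop = FALSE]
    if (!nrow(on)) next
    dd <- abs(mid[i] - on$tss)
    sel <- which(dd <= window)
    rule <- "window"
    if (!length(sel)) {
      sel <- which(dd == min(dd))
      rule <- "nearest"
    }
    sgn <- ifelse(on$strand[sel] == "+", mid[i] - on$tss[sel],
                  on$tss[sel] - mid[i])
    out <- rbind(out, data.frame(peak_id = ids[i],
                                 gene_id = on$gene_id[sel],
                                 distance = sgn, rule = rule,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out))
    return(data.frame(peak_id = character(), gene_id = character(),
                      distance = numeric(), rule = character()))
  out[order(match(out$peak_id, ids), out$gene_id), ]
}

# Naive sliding-window scanner oracle (per-character loop).
oracleScan <- function(seq, motif, maxMismatch, bothStrands = TRUE) {
  iup <- list(A = "A", C = "C", G = "G", T = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  revcompStr <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
              R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
              B = "V", V = "B", D = "H", H = "D")
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  }
  s <- strsplit(toupper(seq), "")[[1]]
  scanOne <- function(pat, strand) {
    p <- strsplit(pat, "")[[1]]
    k <- length(p)
    res <- NULL
    for (i in seq_len(length(s) - k + 1)) {
      mm <- 0
      for (j in seq_len(k)) {
        base <- s[i + j - 1]
        if (base == "N" || !(base %in% iup[[p[j]]])) mm <- mm + 1
      }
      if (mm <= maxMismatch)
        res <- rbind(res, data.frame(start = i - 1L, end = i - 1L + k,
                                     strand = strand, mismatches = mm,
                                     stringsAsFactors = FALSE))
    }
    res
  }
  out <- scanOne(toupper(consensus(motif)), "+")
  if (bothStrands)
    out <- rbind(out, scanOne(revcompStr(toupper(consensus(motif))), "-"))
  if (is.null(out))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer()))
  out[order(out$start, out$strand), ]
}

# Exact Fisher p from first principles: enumerate all tables with the
# observed margins, probabilities from choose() ratios.
oracleFisherP <- function(a, b, c, d, sided = "two") {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  if (sided == "one") sum(pr[xs >= a])
  else sum(pr[pr <= pr[xs == a] * (1 + 1e-7)])
}

# A simulated analysis-ready bundle at the default study-like scale.
simulateBundle <- function(seed, nGenes = 1000L, nDown = 40L, nUp = 10L) {
  gm <- simulateGenome(nChrom = 2L, nGenes = nGenes, chromLen = 5e7,
                       familyFractions = c(TF = 0.10, FOX = 0.02),
                       seed = seed)
  sim <- simulateExpression(gm, deSpec = list(n_down = nDown, n_up = nUp,
                                              lfc_range = c(2, 3)),
                            seed = seed + 1L)
  list(genome = gm, sim = sim)
}
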