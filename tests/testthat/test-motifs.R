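test_that("scanConsensus finds exact and degenerate sites on both strands", {
  tbx <- builtinMotif("TBX")
  hit <- scanConsensus("AGGTGTGG", tbx)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 0L)
  expect_equal(hit$end, 8L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$mismatches, 0L)

  ## the GLI site sequence GGACCACCCAGC is the reverse complement of the
  ## consensus up to 2 mismatches
  gli <- builtinMotif("GLI")
  hit2 <- scanConsensus("GGACCACCCAGC", gli, maxMismatch = 2)
  expect_equal(nrow(hit2), 1L)
  expect_equal(hit2$strand, "-")
  expect_equal(hit2$mismatches, 2L)
  expect_equal(nrow(scanConsensus("GGACCACCCAGC", gli, maxMismatch = 1)), 0L)

  ## N never matches; non-nucleotide characters are an error
  expect_equal(nrow(scanConsensus("AGGTGTNG", tbx)), 0L)
  expect_error(scanConsensus("AGGTXTGG", tbx), "non-nucleotide")
  ## lowercase input scans identically
  expect_equal(scanConsensus("aggtgtgg", tbx)$start, 0L)
  expect_error(scanConsensus("ACGT", Motif("m", "ACG"), maxMismatch = 3),
               "smaller than motif length")
})

test_that("scanConsensus equals the naive oracle on random sequences", {
  set.seed(56)
  for (i in 1:4) {
    seq <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
    motif <- Motif("m", paste(sample(c("A", "C", "G", "T", "R", "N"), 7,
                                     TRUE), collapse = ""))
    mm <- sample(0:2, 1)
    got <- scanConsensus(seq, motif, maxMismatch = mm)
    want <- oracleScan(seq, motif, mm)
    expect_equal(got[, c("start", "end", "strand", "mismatches")], want,
                 ignore_attr = TRUE)
  }
})

test_that("scanning is strand-symmetric and matches the hit-count expectation", {
  set.seed(57)
  seq <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  motif <- Motif("m", "ACGTRY")
  fwd <- scanConsensus(seq, motif, maxMismatch = 1)
  rc <- scanConsensus(shfgrn:::.revcomp(seq), motif, maxMismatch = 1)
  L <- nchar(seq); k <- 6
  mirror <- data.frame(start = L - rc$end, end = L - rc$start,
                       strand = ifelse(rc$strand == "+", "-", "+"))
  mirror <- mirror[order(mirror$start, mirror$strand), ]
  expect_equal(fwd$start, mirror$start)
  expect_equal(fwd$strand, mirror$strand)

  ## E[hits] = 2 (L - m + 1) p_match for exact matching with degeneracy
  pm <- (1 / 4)^4 * (2 / 4)^2   # ACGT exact, R and Y two-base codes
  counts <- vapply(1:200, function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
    nrow(scanConsensus(s, motif, maxMismatch = 0))
  }, numeric(1))
  expected <- 2 * (500 - 6 + 1) * pm
  expect_equal(mean(counts), expected,
               tolerance = 4 * sd(counts) / sqrt(200) / expected + 0.05)
})

test_that("findAdjacentPairs pairs the printed chr8 TBX/GLI sites at gap 32", {
  tbxSite <- data.frame(seq_id = "chr8", start = 123517714, end = 123517722,
                        strand = "+")
  gliSite <- data.frame(seq_id = "chr8", start = 123517754, end = 123517763,
                        strand = "+")
  pr <- findAdjacentPairs(gliSite, tbxSite)
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$gap, 32)        # within the default 50-bp window
  expect_equal(nrow(findAdjacentPairs(gliSite, tbxSite, maxGap = 30)), 0L)

  ## overlapping sites pair at gap 0
  ov <- findAdjacentPairs(
    data.frame(seq_id = "s", start = 10, end = 22, strand = "+"),
    data.frame(seq_id = "s", start = 18, end = 26, strand = "+"))
  expect_equal(ov$gap, 0)
})

test_that("findAdjacentPairs equals brute force and ignores input order", {
  set.seed(58)
  mkSites <- function(n) data.frame(
    seq_id = sample(c("s1", "s2"), n, TRUE),
    start = st <- sample.int(3000, n), end = st + 8,
    strand = sample(c("+", "-"), n, TRUE))
  A <- mkSites(40); B <- mkSites(40)
  got <- findAdjacentPairs(A, B, maxGap = 25)
  brute <- NULL
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    if (A$seq_id[i] != B$seq_id[j]) next
    gap <- max(0, max(A$start[i], B$start[j]) - min(A$end[i], B$end[j]))
    if (gap <= 25)
      brute <- rbind(brute, data.frame(seq_id = A$seq_id[i],
                                       start_a = A$start[i],
                                       start_b = B$start[j], gap = gap))
  }
  brute <- brute[order(brute$seq_id, brute$gap, brute$start_a,
                       brute$start_b), ]
  expect_equal(got[, c("seq_id", "start_a", "start_b", "gap")], brute,
               ignore_attr = TRUE)

  shuf <- findAdjacentPairs(A[sample(nrow(A)), ], B[sample(nrow(B)), ],
                            maxGap = 25)
  expect_equal(got, shuf)
})

test_that("the planted GLI+TBX pair is the unique co-site call at the truth coordinates", {
  pl <- plantMotifPairs(1, 300, gap = 30, fracPlanted = 1, seed = 59)
  tru <- plantedMotifPairs(pl$truth)
  gli <- scanConsensus(pl$sequences, builtinMotif("GLI"), maxMismatch = 2)
  tbx <- scanConsensus(pl$sequences, builtinMotif("TBX"), maxMismatch = 0)
  pr <- findAdjacentPairs(gli, tbx, maxGap = 50)
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$start_a, tru$start_a)
  expect_equal(pr$start_b, tru$start_b)
  expect_equal(pr$gap, 30)
})

test_that("motifEnrichment separates planted foreground from background", {
  gli <- builtinMotif("GLI")
  pl <- plantMotifPairs(30, 400, gap = 20, fracPlanted = 1, seed = 60)
  bg <- plantMotifPairs(30, 400, gap = 20, fracPlanted = 0, seed = 61)
  r <- motifEnrichment(pl$sequences, gli, bgSeqs = bg$sequences)
  expect_equal(oddsRatio(r), Inf)
  expect_lt(pValue(r), 1e-10)

  ## identical fg and bg with partial hit rates: no enrichment signal
  halfSet <- plantMotifPairs(40, 400, gap = 20, fracPlanted = 0.5,
                             seed = 63)$sequences
  same <- motifEnrichment(halfSet, gli, bgSeqs = halfSet)
  expect_equal(oddsRatio(same), 1)
  expect_gt(pValue(same), 0.3)

  ## half-planted fixture: foreground hit rate ~ 0.5 + chance
  half <- plantMotifPairs(200, 400, gap = 20, fracPlanted = 0.5, seed = 62)
  hits <- scanConsensus(half$sequences, gli, maxMismatch = 0)
  expect_equal(length(unique(hits$seq_id)) / 200, 0.5, tolerance = 0.05)

  expect_error(motifEnrichment(character(), gli), "empty")
  expect_error(motifEnrichment(c(s = "ACGT"), gli), "longer")
})

test_that("FASTA round-trips preserve ids and sequences with validation", {
  seqs <- Biostrings::DNAStringSet(c(one = "ACGTACGT", two = "GGGTTTAAACCC"))
  f <- tempfile(fileext = ".fa")
  writeFastaSeqs(seqs, f)
  back <- readFastaSeqs(f)
  expect_equal(as.character(back), as.character(seqs))

  ## wrapped and lowercase input
  f2 <- tempfile(fileext = ".fa")
  writeLines(c(">w1 description", "acgtac", "gtACGT"), f2)
  w <- readFastaSeqs(f2)
  expect_equal(names(w), "w1")
  expect_equal(as.character(w[[1]]), "ACGTACGTACGT")

  f3 <- tempfile(fileext = ".fa")
  writeLines(c(">dup", "ACGT", ">dup", "GGCC"), f3)
  expect_error(readFastaSeqs(f3), "duplicate")
  f4 <- tempfile(fileext = ".fa")
  writeLines(c(">ok", "ACGT", ">empty", "", ">more", "GG"), f4)
  expect_error(readFastaSeqs(f4), "empty")
})
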