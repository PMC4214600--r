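test_that("simulateGenome places TSSs inside chromosomes with spacing and is deterministic", {
  gm <- simulateGenome(nChrom = 1, nGenes = 1, chromLen = 10000,
                       familyFractions = c(), minSpacing = 0, seed = 1)
  tss <- geneTable(gm)$tss
  expect_true(tss >= 0 && tss < 10000)

  gm2 <- simulateGenome(nChrom = 3, nGenes = 120, chromLen = 2e6, seed = 9)
  g <- as.data.frame(geneTable(gm2))
  expect_true(all(g$tss >= 0 & g$tss < chromLengths(gm2)[g$chrom]))
  sp <- tapply(g$tss, g$chrom, function(x) min(diff(sort(x))))
  expect_true(all(sp >= 5000))

  expect_identical(simulateGenome(nGenes = 50, chromLen = 1e6, seed = 4),
                   simulateGenome(nGenes = 50, chromLen = 1e6, seed = 4))
  expect_error(simulateGenome(nGenes = 1000, chromLen = 1e6,
                              minSpacing = 5000, seed = 1), "too short")
})

test_that("family labels are assigned at the requested binomial rate", {
  gm <- simulateGenome(nGenes = 22000, chromLen = 2e9,
                       familyFractions = c(TF = 0.10), minSpacing = 0,
                       seed = 2)
  nTF <- length(geneFamilies(gm, "TF"))
  ## 2200 +/- 4 binomial SDs
  expect_lt(abs(nTF - 2200), 4 * sqrt(22000 * 0.1 * 0.9))
})

test_that("simulateExpression matches the 4-vs-3 design and plants recoverable fold changes", {
  gm <- simulateGenome(nGenes = 60, chromLen = 2e6, seed = 3)
  sim <- simulateExpression(gm, deSpec = list(n_down = 5, n_up = 0,
                                              lfc_range = c(2, 2)),
                            seed = 30)
  ds <- sim$dataset
  expect_equal(ncol(ds), 7L)            # n = 4 mutants vs n = 3 wild types
  expect_equal(sum(ds$group == "case"), 4L)
  expect_equal(nrow(plantedDE(sim$truth)), 5L)
  expect_true(all(plantedDE(sim$truth)$gene_id %in% geneIds(gm)))

  ## planted log2FC = -2 => linear case/control FC ~ 0.25 on average
  fcs <- vapply(100 + seq_len(40), function(sd) {
    s <- simulateExpression(gm, deSpec = list(n_down = 3, n_up = 0,
                                              lfc_range = c(2, 2)),
                            noiseSd = 0.3, seed = sd)
    v <- SummarizedExperiment::assay(s$dataset, "exprs")
    gene <- SummarizedExperiment::rowData(s$dataset)$gene_id
    pick <- which(gene %in% plantedDE(s$truth)$gene_id)
    case <- s$dataset$group == "case"
    mean(rowMeans(v[pick, case, drop = FALSE]) /
           rowMeans(v[pick, !case, drop = FALSE]))
  }, numeric(1))
  expect_equal(mean(fcs), 0.25, tolerance = 0.1)

  expect_error(simulateExpression(gm, deSpec = list(n_down = 100, n_up = 0),
                                  seed = 1), "only")
  expect_error(simulateExpression(gm, nCase = 1, seed = 1), "at least 2")
})

test_that("null expression data have no group structure beyond noise", {
  gm <- simulateGenome(nGenes = 200, chromLen = 5e6, seed = 5)
  sim <- simulateExpression(gm, deSpec = list(n_down = 0, n_up = 0),
                            seed = 50)
  v <- log2(SummarizedExperiment::assay(sim$dataset, "exprs"))
  case <- sim$dataset$group == "case"
  diffs <- rowMeans(v[, case]) - rowMeans(v[, !case])
  ## per-gene group difference is mean-zero noise
  expect_lt(abs(mean(diffs)), 0.15)
  expect_equal(nrow(plantedDE(sim$truth)), 0L)
})

test_that("simulatePeaks honors placement fractions and chromosome bounds", {
  gm <- tinyGenome()
  exact <- simulatePeaks(gm, 8, fracNearTss = 1, nearWindow = 0,
                         peakWidth = 400, seed = 6)
  mid <- (GenomicRanges::start(exact$peaks) - 1 +
            GenomicRanges::end(exact$peaks)) %/% 2
  tgt <- plantedPeakTargets(exact$truth)
  g <- as.data.frame(geneTable(gm))
  expect_equal(mid, g$tss[match(tgt$gene_id, g$gene_id)])

  gm1 <- simulateGenome(nGenes = 10, chromLen = 1e6, seed = 7)
  unif <- simulatePeaks(gm1, 4000, fracNearTss = 0, peakWidth = 100,
                        seed = 8)
  mid <- (GenomicRanges::start(unif$peaks) - 1 +
            GenomicRanges::end(unif$peaks)) %/% 2
  expect_equal(mean(mid), 5e5, tolerance = 0.05)
  expect_true(all(GenomicRanges::start(unif$peaks) >= 1))
  expect_true(all(GenomicRanges::end(unif$peaks) <= 1e6))

  empty <- simulatePeaks(gm1, 0, seed = 9)
  expect_length(empty$peaks, 0L)
  expect_error(simulatePeaks(gm1, 5, targetGenes = "nope", seed = 1),
               "not in genome")
})

test_that("plantMotifPairs records truthful coordinates that the scanner recovers", {
  gli <- builtinMotif("GLI")
  tbx <- builtinMotif("TBX")

  abut <- plantMotifPairs(6, 200, gli, tbx, gap = 0, fracPlanted = 1,
                          seed = 11)
  expect_true(all(plantedMotifPairs(abut$truth)$gap == 0))

  none <- plantMotifPairs(20, 300, gli, tbx, gap = 10, fracPlanted = 0,
                          seed = 12)
  expect_equal(nrow(plantedMotifPairs(none$truth)), 0L)
  ## chance exact GLI 12-mer hits across 20 x 300 bp: expectation
  ## 2 * n * (L-11) / 4^12 ~ 0.0007, so essentially none
  hits <- scanConsensus(none$sequences, gli, maxMismatch = 0)
  expect_lte(nrow(hits), 1L)

  pl <- plantMotifPairs(10, 400, gli, tbx, gap = 30, fracPlanted = 1,
                        seed = 13)
  tru <- plantedMotifPairs(pl$truth)
  sitesA <- scanConsensus(pl$sequences, gli, maxMismatch = 0)
  sitesB <- scanConsensus(pl$sequences, tbx, maxMismatch = 0)
  for (i in seq_len(nrow(tru))) {
    expect_true(any(sitesA$seq_id == tru$seq_id[i] &
                      sitesA$start == tru$start_a[i]))
    expect_true(any(sitesB$seq_id == tru$seq_id[i] &
                      sitesB$start == tru$start_b[i]))
  }

  expect_error(plantMotifPairs(5, 30, gli, tbx, gap = 30, fracPlanted = 1,
                               seed = 1), "cannot hold")
})

test_that("simulators are seed-deterministic and conserve requested counts", {
  gm <- simulateGenome(nGenes = 80, chromLen = 4e6, seed = 21)
  a <- simulateExpression(gm, deSpec = list(n_down = 7, n_up = 3,
                                            lfc_range = c(1, 2)), seed = 22)
  b <- simulateExpression(gm, deSpec = list(n_down = 7, n_up = 3,
                                            lfc_range = c(1, 2)), seed = 22)
  expect_identical(SummarizedExperiment::assay(a$dataset, "exprs"),
                   SummarizedExperiment::assay(b$dataset, "exprs"))
  expect_identical(plantedDE(a$truth), plantedDE(b$truth))
  expect_equal(sum(plantedDE(a$truth)$log2fc < 0), 7L)
  expect_equal(sum(plantedDE(a$truth)$log2fc > 0), 3L)

  p1 <- simulatePeaks(gm, 25, fracNearTss = 0.6, seed = 23)
  p2 <- simulatePeaks(gm, 25, fracNearTss = 0.6, seed = 23)
  expect_identical(as.data.frame(p1$peaks), as.data.frame(p2$peaks))
  expect_equal(nrow(plantedPeakTargets(p1$truth)), 15L)  # 0.6 * 25

  s1 <- plantMotifPairs(8, 300, gap = 12, fracPlanted = 0.5, seed = 24)
  s2 <- plantMotifPairs(8, 300, gap = 12, fracPlanted = 0.5, seed = 24)
  expect_identical(as.character(s1$sequences), as.character(s2$sequences))
  expect_equal(nrow(plantedMotifPairs(s1$truth)), 4L)
})
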