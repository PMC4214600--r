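test_that("filterProbes applies the three criteria with a faithful report", {
  ## probes with log-scale IQRs 1,2,3,4: median split keeps the top two
  k <- c(1, 2, 3, 4) / 3
  logv <- outer(k, c(-3, -2, -1, 0, 1, 2, 3)) + 10
  ds <- makeDataset(2^logv - 1, groups = rep(c("case", "control"),
                                             c(4, 3)))
  out <- filterProbes(ds)
  expect_equal(SummarizedExperiment::rowData(out$dataset)$probe_id,
               c("p003", "p004"))
  expect_equal(unname(out$report["removed_iqr"]), 2L)

  ## unannotated probes always go; QC failures go first
  qc <- matrix(TRUE, 4, 7); qc[1, 2] <- FALSE
  ds2 <- makeDataset(2^logv - 1, geneIds = c("g1", NA, "g3", "g4"),
                     groups = rep(c("case", "control"), c(4, 3)), qc = qc)
  out2 <- filterProbes(ds2)
  expect_equal(unname(out2$report["removed_qc"]), 1L)
  expect_false("p002" %in%
                 SummarizedExperiment::rowData(out2$dataset)$probe_id)
  expect_equal(unname(out2$report["n_input"] - out2$report["n_retained"]),
               unname(sum(out2$report[c("removed_qc", "removed_iqr",
                                        "removed_unannotated")])))

  ## all-QC-fail input is a hard error with diagnostics
  dsBad <- makeDataset(matrix(5, 3, 4), qc = matrix(FALSE, 3, 4))
  expect_error(filterProbes(dsBad), "qc-fail: 3")
})

test_that("filterProbes is idempotent", {
  gm <- simulateGenome(nGenes = 150, chromLen = 5e6, seed = 31)
  sim <- simulateExpression(gm, deSpec = list(n_down = 10, n_up = 0,
                                              lfc_range = c(2, 3)),
                            seed = 32)
  once <- filterProbes(sim$dataset)
  twice <- filterProbes(once$dataset)
  expect_identical(
    SummarizedExperiment::rowData(once$dataset)$probe_id,
    SummarizedExperiment::rowData(twice$dataset)$probe_id)
  expect_equal(unname(twice$report["n_retained"]),
               unname(once$report["n_retained"]))
})

test_that("normalizeExpression removes array scale and approaches log2 ratios", {
  set.seed(41)
  a <- 2^rnorm(300, 9, 1.3)
  v <- cbind(a, a, a, a)
  ds <- makeDataset(v, groups = c("case", "case", "control", "control"))
  norm <- normalizeExpression(ds)
  tr <- SummarizedExperiment::assay(norm, "exprs")
  expect_equal(tr[, 1], tr[, 3], tolerance = 1e-12)

  ## pure scale factor (array B = 2 x array A) is removed exactly
  v2 <- cbind(a, 2 * a, a, 2 * a)
  norm2 <- normalizeExpression(makeDataset(
    v2, groups = c("case", "case", "control", "control")))
  tr2 <- SummarizedExperiment::assay(norm2, "exprs")
  expect_lt(max(abs(tr2[, 1] - tr2[, 2])), 1e-6)

  ## monotone per array
  expect_true(all(apply(tr, 2, function(col) {
    o <- order(v[, 1]); all(diff(col[o]) >= 0)
  })))

  ## for large intensities, differences approach log2 ratios
  big <- 2^seq(10, 16, length.out = 50)
  vb <- cbind(big, big, big, big) * matrix(1, 50, 4)
  trb <- SummarizedExperiment::assay(
    normalizeExpression(makeDataset(
      vb, groups = c("case", "case", "control", "control"))), "exprs")
  expect_equal(unname(diff(trb[c(1, 50), 1])), log2(big[50] / big[1]),
               tolerance = 1e-3)

  ## degenerate array
  expect_error(normalizeExpression(makeDataset(matrix(7, 5, 4))),
               "zero spread")
  expect_error(normalizeExpression(norm), "raw-scale")
})

test_that("samTest reproduces hand-computed and degenerate statistics", {
  ## case {4,4,4}, ctrl {2,2,2}, s = 0, s0 = 1 => d = 2
  ds <- makeDataset(rbind(c(4, 4, 4, 2, 2, 2)),
                    groups = rep(c("case", "control"), each = 3),
                    scale = "glog2")
  de <- samTest(ds, samParams(s0 = 1))
  expect_equal(de$d, 2)
  expect_equal(de$fc, 4)    # linear ratio of raw group means (2^4 / 2^2)

  ## constant data: every d = 0 and q = 1
  dsEq <- makeDataset(matrix(5, 6, 6),
                      groups = rep(c("case", "control"), each = 3),
                      scale = "glog2")
  deEq <- samTest(dsEq, samParams(s0 = 1))
  expect_true(all(deEq$d == 0))
  expect_true(all(deEq$q == 1))

  expect_error(samTest(makeDataset(matrix(rnorm(12), 3, 4),
                                   groups = c("case", rep("control", 3)),
                                   scale = "glog2")), "at least 2")
})

test_that("samTest with s0 = 0 equals the classical two-sample t statistic", {
  set.seed(42)
  v <- matrix(rnorm(10 * 7, 8), 10, 7)
  grp <- rep(c("case", "control"), c(4, 3))
  ds <- makeDataset(v, scale = "glog2", groups = grp)
  de <- samTest(ds, samParams(s0 = 0))
  tref <- apply(v, 1, function(x)
    t.test(x[grp == "case"], x[grp == "control"],
           var.equal = TRUE)$statistic)
  expect_equal(de$d[match(sprintf("g%03d", 1:10), de$gene_id)],
               unname(tref), tolerance = 1e-10)
})

test_that("sampled permutations agree with full enumeration", {
  ## 5 vs 5 has 252 distinct splits: enumerate fully, then subsample 100
  set.seed(43)
  v <- matrix(rnorm(40 * 10, 8), 40, 10)
  v[1:5, 1:5] <- v[1:5, 1:5] + 2
  ds <- makeDataset(v, groups = rep(c("case", "control"), each = 5),
                    scale = "glog2")
  full <- samTest(ds, samParams(nPerm = 252, s0 = 0.2))
  mc <- samTest(ds, samParams(nPerm = 100, s0 = 0.2, seed = 7))
  ## Monte-Carlo p within a generous binomial envelope of the exact p
  se <- sqrt(full$perm_p * (1 - full$perm_p) / 100)
  expect_true(all(abs(mc$perm_p - full$perm_p) <= 4 * se + 0.02))
})

test_that("selectSignature applies q and fold-change cuts with direction", {
  res <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    fc = c(0.4, 1.5, 3.0, 2.5),
                    log2fc = log2(c(0.4, 1.5, 3.0, 2.5)),
                    q = c(0.004, 0.004, 0.001, 0.5))
  sig <- selectSignature(res)
  expect_setequal(signatureGenes(sig), c("g1", "g3"))
  expect_equal(unname(signatureDirection(sig)["g1"]), "down")
  expect_equal(unname(signatureDirection(sig)["g3"]), "up")

  ## monotonicity: tightening either threshold never grows the signature
  set.seed(44)
  res2 <- data.frame(gene_id = sprintf("g%03d", 1:200),
                     fc = 2^rnorm(200, 0, 1.5), q = runif(200, 0, 0.02))
  res2$log2fc <- log2(res2$fc)
  for (i in 1:20) {
    q1 <- runif(1, 0, 0.02); q2 <- q1 * runif(1)
    f1 <- runif(1, 1, 4); f2 <- f1 * (1 + runif(1))
    expect_true(all(signatureGenes(selectSignature(res2, q2, f1)) %in%
                      signatureGenes(selectSignature(res2, q1, f1))))
    expect_true(all(signatureGenes(selectSignature(res2, q1, f2)) %in%
                      signatureGenes(selectSignature(res2, q1, f1))))
  }
})

test_that("stringentCandidates demands all three tests", {
  res <- data.frame(gene_id = c("g1", "g2", "g3"),
                    fc = c(8, 2.5, 0.1),
                    log2fc = log2(c(8, 2.5, 0.1)),
                    wilcoxon_p = c(0.05, 0.05, 0.01),
                    emp_t_fdr = c(0.05, 0.05, 0.01))
  out <- stringentCandidates(res)
  expect_setequal(out$gene_id, c("g1", "g3"))   # g2 fails only |FC| > 3
  expect_equal(out$gene_id[1], "g3")            # sorted by |log2fc|
  expect_error(stringentCandidates(res[, 1:3]), "wilcoxon_p")
})

test_that("clusterSamples separates duplicated sample blocks perfectly", {
  set.seed(45)
  base <- matrix(rnorm(60 * 2, 8), 60, 2)
  v <- base[, c(1, 1, 1, 2, 2, 2)] + matrix(rnorm(360, sd = 0.01), 60, 6)
  ds <- makeDataset(v, groups = rep(c("case", "control"), each = 3),
                    scale = "glog2")
  cl <- clusterSamples(ds, sprintf("g%03d", 1:60))
  expect_equal(length(unique(cl$labels[1:3])), 1L)
  expect_equal(length(unique(cl$labels[4:6])), 1L)
  expect_false(cl$labels[1] == cl$labels[4])
  expect_error(clusterSamples(ds[, 1], "g001"), "at least 2")
})

test_that("planted case/control structure drives the sample dendrogram 2-cut", {
  b <- simulateBundle(61, nGenes = 300, nDown = 30, nUp = 10)
  ds <- normalizeExpression(filterProbes(b$sim$dataset)$dataset)
  cl <- clusterSamples(ds, plantedDE(b$sim$truth)$gene_id)
  grp <- ds$group
  expect_true(all(table(cl$labels, grp) %in%
                    c(0, table(grp)[["case"]], table(grp)[["control"]])))
})

test_that("genesetEnrichment is a calibrated over-representation test", {
  universe <- sprintf("g%03d", 1:100)
  sig <- universe[1:10]
  res <- genesetEnrichment(sig, list(same = sig, disjoint = universe[51:60]),
                           universe)
  expect_equal(res$p[res$set_id == "disjoint"], 1)
  ## identical set: minimal possible p for its size
  expect_equal(res$p[res$set_id == "same"],
               1 / choose(100, 10) * 1, tolerance = 1e-12)
  expect_error(genesetEnrichment(sig, list(a = sig), character()),
               "non-empty")

  ## random signatures over random sets give uniform-ish p
  set.seed(46)
  ps <- replicate(200, {
    s <- sample(universe, 10)
    gs <- sample(universe, 20)
    genesetEnrichment(s, list(x = gs), universe)$p
  })
  ## discrete hypergeometric p-values are super-uniform under the null:
  ## P(p <= alpha) must not exceed alpha (within Monte-Carlo error)
  for (alpha in c(0.05, 0.1, 0.25, 0.5))
    expect_lte(mean(ps <= alpha),
               alpha + 3 * sqrt(alpha * (1 - alpha) / length(ps)))
  expect_gt(mean(ps), 0.35)
})
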