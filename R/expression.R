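#' Filter probes before differential-expression testing
#'
#' Retains probes that (1) pass the QC flag on every array, (2) have
#' cross-sample spread at or above the median spread over all probes — the
#' "upper half of IQR" filter that removes non-expressed background
#' probes; spread is the inter-quartile range of `log2(1 + x)` so that the
#' criterion is not dominated by overall intensity — and (3) map to an
#' annotated gene.
#' The IQR threshold is recorded in the dataset metadata and reused on
#' re-application, so the operation is idempotent.
#'
#' @param ds A raw-scale [ExpressionDataset-class].
#' @return List with `dataset` (filtered) and `report`, a named vector:
#'   `n_input`, `removed_qc`, `removed_iqr`, `removed_unannotated`,
#'   `n_retained` (removals attributed to the first failing criterion, so
#'   they sum to `n_input - n_retained`).
#' @export
filterProbes <- function(ds) {
  stopifnot(is(ds, "ExpressionDataset"))
  v <- assay(ds, "exprs")
  qcAll <- rowSums(!assay(ds, "qc")) == 0L
  iqr <- apply(log2(1 + v), 1L, stats::IQR)
  thr <- metadata(ds)$iqr_threshold
  if (is.null(thr)) thr <- stats::median(iqr)
  iqrOk <- iqr >= thr
  annot <- !is.na(rowData(ds)$gene_id)
  keep <- qcAll & iqrOk & annot
  report <- c(n_input = nrow(ds),
              removed_qc = sum(!qcAll),
              removed_iqr = sum(qcAll & !iqrOk),
              removed_unannotated = sum(qcAll & iqrOk & !annot),
              n_retained = sum(keep))
  if (!any(keep))
    stop("no probes left after filtering (qc-fail: ", report["removed_qc"],
         ", low-IQR: ", report["removed_iqr"], ", unannotated: ",
         report["removed_unannotated"], ")")
  out <- ds[keep, ]
  metadata(out)$iqr_threshold <- thr
  list(dataset = out, report = report)
}

#' Calibrate arrays and apply a generalized-log transform
#'
#' Simplified variance-stabilizing normalization in three monotone steps.
#' Each array is first scale-calibrated so that its median intensity
#' matches the across-array median (array effects on these arrays are
#' multiplicative, so this is the calibration that cancels them without
#' driving non-negative intensities negative). Values then go through the
#' generalized log `glog2(x) = log2((x + sqrt(x^2 + c^2)) / 2)`, which
#' behaves like `log2` for intensities well above the offset `c` -- so
#' differences approach log2 ratios -- while staying defined at and below
#' zero. Finally each transformed column is affinely calibrated so that
#' its median and inter-quartile range match the across-array median of
#' those statistics on the transformed scale. The offset `c` defaults to
#' 1% of the median calibrated intensity. The raw matrix is preserved in
#' the `"raw"` assay so fold changes stay on the linear scale.
#'
#' @param ds A raw-scale [ExpressionDataset-class].
#' @param glogC Optional explicit glog offset `c` (> 0).
#' @return An [ExpressionDataset-class] on the `"glog2"` scale.
#' @export
normalizeExpression <- function(ds, glogC = NULL) {
  stopifnot(is(ds, "ExpressionDataset"))
  if (!identical(metadata(ds)$scale, "raw"))
    stop("normalizeExpression expects a raw-scale dataset")
  v <- assay(ds, "exprs")
  med <- apply(v, 2L, stats::median)
  spr <- apply(v, 2L, stats::IQR)
  if (any(spr == 0))
    stop("cannot calibrate array(s) with zero spread: ",
         paste(colnames(v)[spr == 0], collapse = ", "))
  medT <- stats::median(med)
  cal <- sweep(v, 2L, medT / med, "*")
  if (is.null(glogC)) {
    pos <- cal[cal > 0]
    glogC <- if (length(pos)) max(0.01 * stats::median(pos), 1e-8) else 1
  }
  stopifnot(glogC > 0)
  tr <- log2((cal + sqrt(cal^2 + glogC^2)) / 2)
  medL <- apply(tr, 2L, stats::median)
  iqrL <- apply(tr, 2L, stats::IQR)
  if (any(iqrL == 0))
    stop("cannot calibrate array(s) with zero spread: ",
         paste(colnames(v)[iqrL == 0], collapse = ", "))
  tr <- sweep(sweep(tr, 2L, medL), 2L, iqrL, "/") * stats::median(iqrL) +
    stats::median(medL)
  out <- ds
  SummarizedExperiment::assay(out, "raw", withDimnames = FALSE) <- v
  SummarizedExperiment::assay(out, "exprs", withDimnames = FALSE) <- tr
  metadata(out)$scale <- "glog2"
  metadata(out)$glog_c <- glogC
  metadata(out)$calibration <- list(raw_median = med, raw_iqr = spr,
                                    target_median = medT,
                                    log_median = medL, log_iqr = iqrL)
  validObject(out)
  out
}

#' Parameters for the SAM permutation test
#'
#' @param nPerm Number of label permutations; when the number of distinct
#'   case/control label assignments is smaller (e.g. 35 for 4 vs 3), all
#'   distinct assignments are enumerated instead.
#' @param s0Grid Quantiles of the per-probe standard errors from which the
#'   exchangeability (fudge) factor s0 is chosen.
#' @param s0 Optional fixed s0 (overrides the grid search; `0` recovers the
#'   classical two-sample t statistic).
#' @param seed Seed for permutation sampling.
#' @return A list understood by [samTest()].
#' @export
samParams <- function(nPerm = 100L, s0Grid = seq(0, 1, by = 0.05),
                      s0 = NULL, seed = 1L) {
  stopifnot(nPerm >= 1L, all(s0Grid >= 0 & s0Grid <= 1))
  list(nPerm = as.integer(nPerm), s0Grid = s0Grid, s0 = s0,
       seed = as.integer(seed))
}

# Difference of group means and pooled standard error per row.
.rowStats <- function(v, case) {
  n1 <- sum(case); n2 <- sum(!case)
  m1 <- rowMeans(v[, case, drop = FALSE])
  m2 <- rowMeans(v[, !case, drop = FALSE])
  v1 <- rowSums((v[, case, drop = FALSE] - m1)^2)
  v2 <- rowSums((v[, !case, drop = FALSE] - m2)^2)
  pooled <- (v1 + v2) / (n1 + n2 - 2)
  list(r = m1 - m2, s = sqrt(pooled * (1 / n1 + 1 / n2)))
}

.safeRatio <- function(r, denom) {
  d <- r / denom
  zero <- denom == 0
  d[zero] <- ifelse(r[zero] == 0, 0, sign(r[zero]) * Inf)
  d
}

# SAM fudge-factor selection: pick the s-quantile minimizing the
# coefficient of variation of the windowed MAD of |d| across s-windows.
.chooseS0 <- function(r, s, grid) {
  if (all(s == 0)) return(0)
  sAlpha <- stats::quantile(s, grid, names = FALSE)
  nbin <- min(100L, max(2L, length(s) %/% 5L))
  bins <- cut(rank(s, ties.method = "first"), nbin, labels = FALSE)
  cvs <- vapply(sAlpha, function(s0) {
    d <- .safeRatio(r, s + s0)
    v <- tapply(d, bins, stats::mad)
    v <- v[is.finite(v)]
    if (length(v) < 2L || mean(v) == 0) return(Inf)
    stats::sd(v) / mean(v)
  }, numeric(1))
  if (all(!is.finite(cvs))) return(stats::median(s))
  sAlpha[which.min(cvs)]
}

# Distinct case-label assignments as a logical matrix (samples x splits).
# Enumerates all C(n, n1) splits when feasible, otherwise samples distinct
# splits without replacement (always including the observed labeling).
.labelSplits <- function(case, nPerm, seed) {
  n <- length(case); n1 <- sum(case)
  total <- choose(n, n1)
  if (total <= nPerm) {
    idx <- utils::combn(n, n1)
    splits <- matrix(FALSE, n, ncol(idx))
    splits[cbind(as.vector(idx), rep(seq_len(ncol(idx)), each = n1))] <- TRUE
  } else {
    splits <- .withSeed(seed, {
      seen <- new.env(parent = emptyenv())
      out <- list(which(case))
      assign(paste(which(case), collapse = ","), TRUE, envir = seen)
      while (length(out) < nPerm) {
        cand <- sort(sample.int(n, n1))
        key <- paste(cand, collapse = ",")
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          out[[length(out) + 1L]] <- cand
        }
      }
      m <- matrix(FALSE, n, length(out))
      for (j in seq_along(out)) m[out[[j]], j] <- TRUE
      m
    })
  }
  splits
}

#' SAM-type permutation differential expression test
#'
#' Computes, per probe, the regularized unpaired two-class statistic
#' `d = (mean_case - mean_control) / (s + s0)` with pooled standard error
#' `s` and exchangeability factor `s0` chosen by the standard SAM recipe
#' (minimal coefficient of variation of windowed `|d|` spread across the
#' `s` range). The permutation null pools the permuted statistics of all
#' probes over all distinct case/control label assignments (all 35 splits
#' are enumerated for the default 4-vs-3 design), giving permutation
#' p-values with granularity `1/(B*m)`; q-values are a SAM-style
#' false-discovery estimate: at each gene's `|d|` threshold, pi0 times the
#' smoothed expected count of permuted statistics beyond the threshold
#' (from the non-identity label splits), over the number of genes called,
#' minimized over all thresholds that include the gene.
#' Statistics are collapsed from probes to genes
#' by taking each gene's extreme-`|d|` probe; fold change is the ratio of
#' linear-scale raw group means of that probe. Also reports the exact
#' Wilcoxon rank-sum p-value and an empirical permutation-t FDR used by the
#' stringent candidate filter.
#'
#' @param ds A normalized [ExpressionDataset-class] (the `"raw"` assay, kept
#'   by [normalizeExpression()], supplies linear-scale fold changes).
#' @param params See [samParams()].
#' @return `data.frame` with one row per gene: `gene_id`, `probe_id` (the
#'   probe that carried the gene's statistic), `n_probes`, `fc`, `log2fc`,
#'   `d`, `perm_p`, `q`, `wilcoxon_p`, `emp_t_fdr`.
#' @references Tusher, Tibshirani and Chu (2001) PNAS 98:5116-5121.
#' @export
samTest <- function(ds, params = samParams()) {
  stopifnot(is(ds, "ExpressionDataset"))
  case <- ds$group == "case"
  if (sum(case) < 2L || sum(!case) < 2L)
    stop("need at least 2 samples in each group")
  v <- assay(ds, "exprs")
  raw <- if ("raw" %in% assayNames(ds)) assay(ds, "raw")
         else if (identical(metadata(ds)$scale, "raw")) v else 2^v

  obs <- .rowStats(v, case)
  s0 <- params$s0 %||% .chooseS0(obs$r, obs$s, params$s0Grid)
  d <- .safeRatio(obs$r, obs$s + s0)
  tstat <- .safeRatio(obs$r, obs$s)

  splits <- .labelSplits(case, params$nPerm, params$seed)
  B <- ncol(splits)
  m <- nrow(v)
  dStar <- matrix(0, m, B)
  tStar <- matrix(0, m, B)
  for (j in seq_len(B)) {
    st <- .rowStats(v, splits[, j])
    dStar[, j] <- .safeRatio(st$r, st$s + s0)
    tStar[, j] <- .safeRatio(st$r, st$s)
  }

  ## pooled permutation p: fraction of all permuted |d*| at least |d_i|
  sortedD <- sort(abs(dStar))
  permP <- (B * m - findInterval(abs(d), sortedD, left.open = TRUE)) / (B * m)
  identityCol <- which(colSums(splits == case) == length(case))[1]
  q <- .samQ(d, dStar, identityCol)

  ## empirical permutation-t FDR at each gene's |t| threshold
  sortedT <- sort(abs(tStar))
  expFP <- (B * m - findInterval(abs(tstat), sortedT, left.open = TRUE)) / B
  called <- m - findInterval(abs(tstat), sort(abs(tstat)), left.open = TRUE)
  empFdr <- pmin(1, expFP / pmax(called, 1L))
  ## enforce monotone non-increasing FDR in |t|
  o <- order(abs(tstat), decreasing = TRUE)
  empFdr[o] <- cummax(empFdr[o])

  wilcox <- apply(v, 1L, function(x)
    suppressWarnings(stats::wilcox.test(x[case], x[!case])$p.value))

  fc <- .safeRatio(rowMeans(raw[, case, drop = FALSE]),
                   rowMeans(raw[, !case, drop = FALSE]))

  gene <- rowData(ds)$gene_id
  keep <- !is.na(gene)
  probeTab <- data.frame(
    gene_id = gene[keep], probe_id = rowData(ds)$probe_id[keep],
    fc = fc[keep], d = d[keep], perm_p = permP[keep], q = q[keep],
    wilcoxon_p = wilcox[keep], emp_t_fdr = empFdr[keep],
    stringsAsFactors = FALSE)
  ## collapse: each gene is represented by its extreme-|d| probe
  ord <- order(probeTab$gene_id, -abs(probeTab$d), probeTab$probe_id)
  probeTab <- probeTab[ord, ]
  nProbes <- table(probeTab$gene_id)
  res <- probeTab[!duplicated(probeTab$gene_id), ]
  res$n_probes <- as.integer(nProbes[res$gene_id])
  res$log2fc <- log2(res$fc)
  rownames(res) <- NULL
  res <- res[, c("gene_id", "probe_id", "n_probes", "fc", "log2fc", "d",
                 "perm_p", "q", "wilcoxon_p", "emp_t_fdr")]
  attr(res, "s0") <- s0
  attr(res, "n_perm") <- B
  res
}

# SAM-style q-values. For the threshold at each gene's |d|, the expected
# number of false calls is estimated from the label-permuted statistics of
# all genes, excluding the observed labeling (which is one of the
# enumerated splits and would otherwise feed every true effect back into
# its own null): the median across the remaining splits of the count of
# permuted statistics beyond the threshold, plus a 1/B smoothing floor so
# that no threshold ever claims an exactly-zero null rate. The estimated
# FDR at the threshold is pi0 * false-call-estimate / observed-calls with
# the SAM middle-quartile pi0; each gene's q is the minimum estimated FDR
# over all thresholds loose enough to include it.
.samQ <- function(d, dStar, identityCol) {
  m <- length(d)
  absd <- abs(d)
  q25 <- stats::quantile(dStar, 0.25)
  q75 <- stats::quantile(dStar, 0.75)
  pi0 <- min(1, sum(d >= q25 & d <= q75) / (0.5 * m))
  sortedObs <- sort(absd)
  called <- m - findInterval(absd, sortedObs, left.open = TRUE)
  perm <- abs(dStar[, -identityCol, drop = FALSE])
  B0 <- max(ncol(perm), 1L)
  counts <- matrix(0L, m, B0)
  for (b in seq_len(ncol(perm))) {
    sb <- sort(perm[, b])
    counts[, b] <- m - findInterval(absd, sb, left.open = TRUE)
  }
  V <- apply(counts, 1L, stats::median) + 1 / B0
  fdr <- pmin(1, pi0 * V / pmax(called, 1L))
  ## q_i = min FDR over thresholds t <= |d_i|
  o <- order(absd, decreasing = TRUE)
  q <- fdr
  q[o] <- rev(cummin(rev(fdr[o])))
  q
}

#' Select the differential-expression signature
#'
#' Genes with q-value at most `qMax` and linear fold change at least
#' `minAbsFC` in either direction (`fc >= minAbsFC` up, or
#' `fc <= 1/minAbsFC` down). Defaults match the study thresholds
#' (q < 0.005, |FC| > 2).
#'
#' @param res A [samTest()] result table.
#' @param qMax,minAbsFC Selection thresholds.
#' @return A [GeneSignature-class] (possibly empty).
#' @export
selectSignature <- function(res, qMax = 0.005, minAbsFC = 2) {
  stopifnot(all(c("gene_id", "fc", "q") %in% colnames(res)), minAbsFC >= 1)
  hit <- res$q <= qMax & (res$fc >= minAbsFC | res$fc <= 1 / minAbsFC)
  hit[is.na(hit)] <- FALSE
  sel <- res[hit, , drop = FALSE]
  new("GeneSignature", genes = sel$gene_id,
      direction = if (nrow(sel)) ifelse(sel$fc >= 1, "up", "down")
                  else character(),
      qMax = qMax, minAbsFC = minAbsFC,
      stats = as.data.frame(sel))
}

#' Stringent three-test candidate filter
#'
#' The tighter screen used to pick genes for experimental validation:
#' Wilcoxon rank-sum p below `wilcoxMax`, empirical permutation-t FDR below
#' `fdrMax`, and absolute linear fold change above `minAbsFC` (defaults
#' p < 0.15, FDR < 0.1, |FC| > 3). Candidates are returned sorted by
#' `|log2fc|` descending.
#'
#' @param res A [samTest()] result table (must carry `wilcoxon_p` and
#'   `emp_t_fdr`).
#' @param wilcoxMax,fdrMax,minAbsFC Thresholds.
#' @return The qualifying rows of `res`.
#' @export
stringentCandidates <- function(res, wilcoxMax = 0.15, fdrMax = 0.1,
                                minAbsFC = 3) {
  if (!all(c("wilcoxon_p", "emp_t_fdr") %in% colnames(res)))
    stop("result table lacks wilcoxon_p / emp_t_fdr")
  hit <- res$wilcoxon_p < wilcoxMax & res$emp_t_fdr < fdrMax &
    (res$fc > minAbsFC | res$fc < 1 / minAbsFC)
  hit[is.na(hit)] <- FALSE
  out <- res[hit, , drop = FALSE]
  out[order(-abs(out$log2fc)), ]
}

#' Hierarchical clustering of samples on a gene set
#'
#' Agglomerative (Ward) clustering of the sample columns restricted to the
#' probes of the given genes, with the 2-group cut — the check that a
#' signature separates mutant from wild-type samples.
#'
#' @param ds An [ExpressionDataset-class].
#' @param genes Gene ids to restrict to (must overlap the dataset).
#' @return List with `hclust` (the dendrogram) and `labels` (named 2-cut
#'   cluster assignment per sample).
#' @export
clusterSamples <- function(ds, genes) {
  stopifnot(is(ds, "ExpressionDataset"))
  if (ncol(ds) < 2L) stop("need at least 2 samples to cluster")
  keep <- !is.na(rowData(ds)$gene_id) & rowData(ds)$gene_id %in% genes
  if (!any(keep)) stop("none of the requested genes are in the dataset")
  v <- assay(ds, "exprs")[keep, , drop = FALSE]
  hc <- stats::hclust(stats::dist(t(v)), method = "ward.D2")
  list(hclust = hc, labels = stats::cutree(hc, k = 2))
}

#' Over-representation (hypergeometric) tests for gene sets
#'
#' One-sided hypergeometric p-value per set for over-representation of the
#' signature among the set members, within an explicit gene universe;
#' p-values are Benjamini-Hochberg adjusted across sets.
#'
#' @param sig A [GeneSignature-class] or character vector of gene ids.
#' @param geneSets Named list of character vectors.
#' @param universe Character vector of universe gene ids (non-empty).
#' @return `data.frame` with `set_id`, `overlap`, `set_size`, `sig_size`,
#'   `universe_size`, `p`, `p_adj`.
#' @export
genesetEnrichment <- function(sig, geneSets, universe) {
  if (is(sig, "GeneSignature")) sig <- signatureGenes(sig)
  universe <- unique(universe)
  if (!length(universe)) stop("universe must be non-empty")
  sig <- intersect(sig, universe)
  K <- length(sig)
  N <- length(universe)
  rows <- lapply(names(geneSets), function(id) {
    set <- intersect(unique(geneSets[[id]]), universe)
    k <- length(intersect(set, sig))
    p <- stats::phyper(k - 1, length(set), N - length(set), K,
                       lower.tail = FALSE)
    data.frame(set_id = id, overlap = k, set_size = length(set),
               sig_size = K, universe_size = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), ]
}

#' Write a differential-expression result table or signature as TSV
#'
#' @param res A [samTest()] table or [GeneSignature-class].
#' @param path Output path.
#' @export
writeDEResult <- function(res, path) {
  if (is(res, "GeneSignature"))
    res <- data.frame(gene_id = res@genes, direction = res@direction,
                      stringsAsFactors = FALSE)
  .writeTsv(res, path)
  invisible(path)
}
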