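#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

.checkSampleSheet <- function(samples) {
  need <- c("sample_id", "treatment", "time_h", "replicate", "plate")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  invisible(samples)
}

#' Filter genes with insufficient counts in vehicle samples
#'
#' Keeps genes with at least one count in at least three vehicle (DMSO)
#' samples at any single time point; everything else is treated as
#' low-count noise. Gene order is preserved.
#'
#' @param counts integer matrix, genes x samples (column names =
#'   `sample_id`).
#' @param samples sample sheet data.frame with columns `sample_id`,
#'   `treatment`, `time_h`, `replicate`, `plate`.
#' @param vehicle vehicle treatment label (default `"DMSO"`).
#' @return the filtered count matrix.
#' @export
filterLowCounts <- function(counts, samples, vehicle = "DMSO") {
  .checkSampleSheet(samples)
  veh <- samples[samples$treatment == vehicle, , drop = FALSE]
  if (!nrow(veh)) stop("no vehicle (", vehicle, ") samples in sample sheet")
  keep <- rep(FALSE, nrow(counts))
  for (t in unique(veh$time_h)) {
    ids <- veh$sample_id[veh$time_h == t]
    ids <- intersect(ids, colnames(counts))
    if (length(ids) < 3) next
    keep <- keep | rowSums(counts[, ids, drop = FALSE] >= 1) >= 3
  }
  counts[keep, , drop = FALSE]
}

#' TMM normalization and log2-CPM expression container
#'
#' Computes trimmed-mean-of-M-values scaling factors (via edgeR, factors
#' normalized to geometric mean 1) and log2 counts-per-million, and wraps
#' counts, log2-CPM and the sample annotations in a
#' `SummarizedExperiment`.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param samples sample sheet (see [filterLowCounts()]); rows are matched
#'   to count columns by `sample_id`.
#' @param priorCount prior count for the log transform (default 2, the
#'   edgeR convention).
#' @return `SummarizedExperiment` with assays `counts` and `logCPM`,
#'   `colData` = sample annotations, and the normalization factors in
#'   `metadata(se)$normFactors`.
#' @export
tmmNormalize <- function(counts, samples, priorCount = 2) {
  .checkSampleSheet(samples)
  if (ncol(counts) < 2) stop("need at least 2 samples")
  if (any(colSums(counts) == 0)) stop("sample with zero total counts")
  samples <- samples[match(colnames(counts), samples$sample_id), ,
                     drop = FALSE]
  if (any(is.na(samples$sample_id)))
    stop("count columns missing from sample sheet")
  dge <- edgeR::DGEList(counts = counts)
  dge <- edgeR::calcNormFactors(dge, method = "TMM")
  logcpm <- edgeR::cpm(dge, log = TRUE, prior.count = priorCount)
  se <- SummarizedExperiment(
    assays = list(counts = counts, logCPM = logcpm),
    colData = DataFrame(samples, row.names = samples$sample_id))
  S4Vectors::metadata(se)$normFactors <- dge$samples$norm.factors
  se
}

## per-gene OLS of log2-CPM on a treatment indicator (+ plate covariate),
## vectorized across genes; optional shrinkage of residual variances toward
## their cross-gene mean (simple compromise estimator with d0 pseudo-df)
.fitContrast <- function(Y, treatIdx, plate, shrink = 0) {
  n <- ncol(Y)
  X <- cbind(intercept = 1, treat = as.numeric(treatIdx))
  plate <- factor(plate)
  if (nlevels(plate) > 1) {
    P <- stats::model.matrix(~plate)[, -1, drop = FALSE]
    X <- cbind(X, P)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    ## a confounded plate column is dropped; a confounded treatment is fatal
    keep <- qrX$pivot[seq_len(qrX$rank)]
    if (!(2 %in% keep)) stop("singular design: treatment confounded")
    X <- X[, sort(keep), drop = FALSE]
    qrX <- qr(X)
  }
  df <- n - ncol(X)
  if (df < 1) stop("no residual degrees of freedom")
  coefs <- t(qr.coef(qrX, t(Y)))
  resid <- t(qr.resid(qrX, t(Y)))
  s2 <- rowSums(resid^2) / df
  d0 <- 0
  if (shrink > 0) {
    d0 <- shrink
    s2 <- (d0 * mean(s2) + df * s2) / (d0 + df)
  }
  XtXinv <- chol2inv(qr.R(qrX))
  cTreat <- XtXinv[2, 2]
  tstat <- coefs[, 2] / sqrt(s2 * cTreat)
  tstat[s2 == 0] <- 0  # flat genes: no evidence either way
  p <- 2 * stats::pt(-abs(tstat), df = df + d0)
  list(logFC = coefs[, 2], t = tstat, p = p, df = df + d0)
}

#' Differential expression versus time-matched vehicle
#'
#' Per-gene linear model of log2-CPM on a treatment indicator with a plate
#' covariate, comparing one treatment against vehicle at one time point;
#' two-sided t-test on the treatment coefficient, Benjamini-Hochberg FDR
#' within the (treatment, time) family.
#'
#' @param se `SummarizedExperiment` from [tmmNormalize()].
#' @param treatment treatment label to test.
#' @param time time point (hours).
#' @param vehicle vehicle label (default `"DMSO"`).
#' @param shrink empirical-Bayes pseudo-degrees-of-freedom pulling
#'   per-gene residual variances toward the cross-gene mean (default 10;
#'   0 gives plain per-gene OLS). Replicate counts are small, so borrowing
#'   variance information across genes is what makes 3-vs-3 contrasts
#'   usable, as in moderated-t pipelines.
#' @return data.frame with columns `gene`, `treatment`, `time`, `logFC`,
#'   `t`, `p`, `fdr`.
#' @export
differentialExpression <- function(se, treatment, time, vehicle = "DMSO",
                                   shrink = 10) {
  cd <- as.data.frame(colData(se))
  sel <- cd$time_h == time & cd$treatment %in% c(treatment, vehicle)
  cd <- cd[sel, , drop = FALSE]
  if (sum(cd$treatment == treatment) < 2 || sum(cd$treatment == vehicle) < 2)
    stop("need >= 2 replicates in both treatment and vehicle at time ", time)
  Y <- assay(se, "logCPM")[, rownames(cd), drop = FALSE]
  fit <- .fitContrast(Y, cd$treatment == treatment, cd$plate, shrink)
  data.frame(gene = rownames(Y), treatment = treatment, time = time,
             logFC = unname(fit$logFC), t = unname(fit$t),
             p = unname(fit$p), fdr = stats::p.adjust(fit$p, "BH"),
             row.names = NULL)
}

#' Differential expression for every non-vehicle treatment and time point
#'
#' @inheritParams differentialExpression
#' @param treatments,times subsets to test; default all non-vehicle
#'   treatments and all times with >= 2 replicates each side.
#' @return row-bound data.frame of [differentialExpression()] slices.
#' @export
deAllConditions <- function(se, treatments = NULL, times = NULL,
                            vehicle = "DMSO", shrink = 10) {
  cd <- as.data.frame(colData(se))
  if (is.null(treatments))
    treatments <- setdiff(unique(cd$treatment), vehicle)
  if (is.null(times)) times <- sort(unique(cd$time_h))
  out <- list()
  for (tr in treatments) for (tm in times) {
    if (sum(cd$treatment == tr & cd$time_h == tm) >= 2 &&
        sum(cd$treatment == vehicle & cd$time_h == tm) >= 2)
      out[[paste(tr, tm)]] <-
        differentialExpression(se, tr, tm, vehicle, shrink)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Select an FDR cutoff anchored on the time-0 behaviour
#'
#' Three strategies, all over a grid of candidate cutoffs (default powers
#' of ten down to 1e-30):
#' \describe{
#'   \item{whitelist}{largest grid cutoff at which every time-0 DEG across
#'     all treatments is a whitelisted gene (immediate early genes - the
#'     only genes expected to respond within ~30 minutes).}
#'   \item{zero_time0}{largest grid cutoff with no time-0 DEGs at all.}
#'   \item{count_matched}{smallest (most stringent) grid cutoff still
#'     yielding at least the reference number of DEGs in each named
#'     condition, used to align separately-run experiments.}
#' }
#'
#' @param deTable DE result table ([deAllConditions()]); for the first two
#'   strategies only time-0 rows are used.
#' @param strategy one of `"whitelist"`, `"zero_time0"`,
#'   `"count_matched"`.
#' @param whitelist character vector of allowed time-0 DEGs (immediate
#'   early genes); see [immediateEarlyGenes()].
#' @param referenceCounts named integer vector, treatment -> required DEG
#'   count (count_matched strategy).
#' @param grid candidate cutoffs, default `10^-(1:30)`.
#' @return the selected cutoff (scalar), with the per-cutoff diagnostics in
#'   attribute `"diagnostics"`.
#' @export
selectFdrCutoff <- function(deTable,
                            strategy = c("whitelist", "zero_time0",
                                         "count_matched"),
                            whitelist = NULL, referenceCounts = NULL,
                            grid = 10^-(1:30)) {
  strategy <- match.arg(strategy)
  if (!length(grid)) stop("empty cutoff grid")
  grid <- sort(grid, decreasing = TRUE)
  if (strategy %in% c("whitelist", "zero_time0")) {
    t0 <- deTable[deTable$time == 0, , drop = FALSE]
    ok <- vapply(grid, function(c) {
      degs <- unique(t0$gene[t0$fdr < c])
      if (strategy == "zero_time0") length(degs) == 0
      else all(degs %in% whitelist)
    }, logical(1))
    if (strategy == "whitelist" && !length(whitelist))
      stop("whitelist strategy requires a non-empty whitelist")
    if (!any(ok)) stop("no grid cutoff satisfies the time-0 condition")
    sel <- grid[which(ok)[1]]  # largest satisfying cutoff
  } else {
    if (is.null(referenceCounts) || is.null(names(referenceCounts)))
      stop("count_matched strategy needs a named referenceCounts vector")
    nGenes <- length(unique(deTable$gene))
    if (any(referenceCounts > nGenes))
      stop("referenceCounts exceed the number of genes")
    ok <- vapply(grid, function(c) {
      all(vapply(names(referenceCounts), function(tr) {
        sub <- deTable[deTable$treatment == tr, , drop = FALSE]
        length(unique(sub$gene[sub$fdr < c])) >= referenceCounts[[tr]]
      }, logical(1)))
    }, logical(1))
    if (!any(ok)) stop("no grid cutoff reaches the reference DEG counts")
    sel <- grid[max(which(ok))]  # smallest (most stringent) satisfying cutoff
  }
  attr(sel, "diagnostics") <- data.frame(cutoff = grid, satisfies = ok)
  sel
}

#' Default immediate early gene whitelist
#'
#' Canonical immediate early genes (editable; pass your own vector to
#' [selectFdrCutoff()] to override) used to anchor the time-0 FDR cutoff:
#' these genes are induced within minutes of a stimulus, so they are the
#' only genes expected to be differentially expressed ~30 minutes after
#' treatment.
#'
#' @return character vector of gene symbols.
#' @export
immediateEarlyGenes <- function() {
  c("FOS", "FOSB", "JUN", "JUNB", "JUND", "EGR1", "EGR2", "EGR3", "IER2",
    "IER3", "ZFP36", "MYC", "KLF4", "KLF6", "ATF3", "DUSP1", "NR4A1",
    "ARC", "GADD45B", "SGK1")
}

#' Call differentially expressed gene sets at a cutoff
#'
#' @param deTable DE result table.
#' @param cutoff FDR cutoff in (0, 1); genes with `fdr < cutoff` are DEGs,
#'   split by the sign of the log fold-change.
#' @return data.frame `gene`, `treatment`, `time`, `direction`
#'   (`up`/`down`), `logFC`, `fdr`, plus the cutoff in attribute
#'   `"cutoff"`.
#' @export
callDegs <- function(deTable, cutoff) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be in (0,1)")
  hit <- deTable[deTable$fdr < cutoff & deTable$logFC != 0, , drop = FALSE]
  out <- data.frame(gene = hit$gene, treatment = hit$treatment,
                    time = hit$time,
                    direction = ifelse(hit$logFC > 0, "up", "down"),
                    logFC = hit$logFC, fdr = hit$fdr, row.names = NULL)
  attr(out, "cutoff") <- cutoff
  out
}

#' Extract one DEG set from a DEG table
#' @param degs output of [callDegs()].
#' @param treatment,time condition selectors.
#' @param direction `"up"`, `"down"` or `"both"`.
#' @return character vector of gene ids.
#' @export
degSet <- function(degs, treatment, time, direction = "both") {
  sel <- degs$treatment == treatment & degs$time == time
  if (direction != "both") sel <- sel & degs$direction == direction
  unique(degs$gene[sel])
}

#' Synergistically expressed genes at one time point
#'
#' A SEG is a gene differentially expressed in the combination but in
#' neither constituent monotherapy at the same time point:
#' \eqn{SEG = DEG_{combo} \setminus (DEG_A \cup DEG_B)}.
#'
#' @param comboDegs,monoADegs,monoBDegs character vectors of DEG ids (any
#'   direction) for combination and monotherapies at one time point and
#'   cutoff.
#' @return list with `segs` (character vector) and `venn`, the seven-region
#'   partition counts named by membership pattern `A-B-combo` (e.g.
#'   `"001"` = combination only, the SEGs).
#' @export
identifySegs <- function(comboDegs, monoADegs, monoBDegs) {
  all3 <- union(union(comboDegs, monoADegs), monoBDegs)
  pat <- paste0(as.integer(all3 %in% monoADegs),
                as.integer(all3 %in% monoBDegs),
                as.integer(all3 %in% comboDegs))
  venn <- vapply(c("100", "010", "001", "110", "101", "011", "111"),
                 function(p) sum(pat == p), integer(1))
  list(segs = all3[pat == "001"], venn = venn)
}

#' Correlation of two monotherapy expression profiles
#'
#' Pearson correlation of per-gene log2 fold-changes over the union of
#' genes differentially expressed in either monotherapy at `unionFdr`. An
#' optional exclusion list (for example a phospholipidosis signature that
#' inflates between-drug similarity) is removed before correlating.
#'
#' @param deA,deB DE result slices (one treatment each) with columns
#'   `gene`, `logFC`, `fdr`.
#' @param unionFdr FDR threshold defining the union gene set (default
#'   0.1).
#' @param exclude optional character vector of genes to drop.
#' @param useLogFC correlate log fold-changes (default). `FALSE` correlates
#'   the `mean_expr` columns instead, if present.
#' @return Pearson r, with the union-set size in attribute `"n"`.
#' @export
monotherapyCorrelation <- function(deA, deB, unionFdr = 0.1, exclude = NULL,
                                   useLogFC = TRUE) {
  common <- intersect(deA$gene, deB$gene)
  a <- deA[match(common, deA$gene), ]
  b <- deB[match(common, deB$gene), ]
  sel <- (a$fdr < unionFdr | b$fdr < unionFdr) & !(common %in% exclude)
  if (sum(sel) < 3) stop("union DEG set has fewer than 3 genes")
  col <- if (useLogFC) "logFC" else "mean_expr"
  r <- stats::cor(a[[col]][sel], b[[col]][sel])
  attr(r, "n") <- sum(sel)
  r
}

#' Association between SEG counts and phenotypic synergy
#'
#' @param segCounts numeric vector of SEG counts per condition/time.
#' @param eob matching Excess Over Bliss values.
#' @return data.frame with Pearson and Spearman coefficients and two-sided
#'   p-values; when either input is constant the coefficients are `NA` and
#'   `degenerate` is `TRUE`.
#' @export
segEobAssociation <- function(segCounts, eob) {
  stopifnot(length(segCounts) == length(eob))
  if (length(eob) < 4) stop("need at least 4 paired observations")
  if (stats::sd(segCounts) == 0 || stats::sd(eob) == 0)
    return(data.frame(method = c("pearson", "spearman"), r = NA_real_,
                      p = NA_real_, degenerate = TRUE))
  pe <- stats::cor.test(segCounts, eob, method = "pearson")
  sp <- suppressWarnings(
    stats::cor.test(segCounts, eob, method = "spearman"))
  data.frame(method = c("pearson", "spearman"),
             r = c(unname(pe$estimate), unname(sp$estimate)),
             p = c(pe$p.value, sp$p.value), degenerate = FALSE)
}
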