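#' Filter and normalize an exon count matrix
#'
#' Keeps exons with at least one read in at least one sample, computes TMM
#' scaling factors on the retained exon matrix and returns exon-level
#' log2-CPM with the exon-to-gene map as row annotations.
#'
#' @param counts exon x sample integer matrix (row names = exon ids).
#' @param exonMap data.frame with columns `exon_id`, `gene_id`,
#'   `exon_index` (unique within each gene).
#' @param samples sample sheet (see [filterLowCounts()]).
#' @return `SummarizedExperiment` with assays `counts` and `logCPM` and
#'   rowData columns `gene_id`, `exon_index`.
#' @export
filterNormalizeExons <- function(counts, exonMap, samples) {
  need <- c("exon_id", "gene_id", "exon_index")
  if (!all(need %in% names(exonMap)))
    stop("exon map needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(exonMap[, c("gene_id", "exon_index")]))
    stop("exon indices must be unique within a gene")
  keep <- rowSums(counts >= 1) >= 1
  counts <- counts[keep, , drop = FALSE]
  exonMap <- exonMap[match(rownames(counts), exonMap$exon_id), , drop = FALSE]
  if (any(is.na(exonMap$exon_id))) stop("exon(s) missing from the exon map")
  se <- tmmNormalize(counts, samples)
  SummarizedExperiment::rowData(se)$gene_id <- exonMap$gene_id
  SummarizedExperiment::rowData(se)$exon_index <- exonMap$exon_index
  se
}

#' Synergistic exon expression contrast
#'
#' For each exon at one time point computes the four-term contrast
#' \deqn{See = \bar{combo} + \bar{DMSO} - \bar{monoA} - \bar{monoB}}
#' on log2-CPM (zero under log-additive combination effects), with a
#' standard error from the pooled within-group variance across the four
#' replicate groups. Groups with fewer than 2 replicates are flagged and
#' their variance contribution replaced by the cross-exon average.
#'
#' @param exonSE `SummarizedExperiment` from [filterNormalizeExons()].
#' @param combo,monoA,monoB treatment labels.
#' @param time time point.
#' @param vehicle vehicle label.
#' @return data.frame `exon_id`, `gene_id`, `exon_index`, `see`, `se`,
#'   `df` (residual degrees of freedom used).
#' @export
synergyContrast <- function(exonSE, combo, monoA, monoB, time,
                            vehicle = "DMSO") {
  cd <- as.data.frame(colData(exonSE))
  Y <- assay(exonSE, "logCPM")
  groups <- list(combo = combo, vehicle = vehicle, monoA = monoA,
                 monoB = monoB)
  ids <- lapply(groups, function(tr) {
    s <- cd$sample_id[cd$treatment == tr & cd$time_h == time]
    if (!length(s)) stop("no samples for ", tr, " at time ", time)
    s
  })
  n <- vapply(ids, length, integer(1))
  means <- lapply(ids, function(s) rowMeans(Y[, s, drop = FALSE]))
  vars <- lapply(ids, function(s) {
    if (length(s) < 2) rep(NA_real_, nrow(Y))
    else apply(Y[, s, drop = FALSE], 1, stats::var)
  })
  if (any(n < 2))
    warning("group(s) with < 2 replicates: variance pooled across exons")
  see <- means$combo + means$vehicle - means$monoA - means$monoB
  num <- Reduce(`+`, Map(function(v, k) ifelse(is.na(v), 0, (k - 1) * v),
                         vars, n))
  df <- sum(pmax(n - 1, 0))
  s2 <- num / max(df, 1)
  bad <- !is.finite(s2) | df == 0
  if (any(bad)) s2[bad] <- mean(s2[!bad])
  seOut <- sqrt(s2 * sum(1 / n))
  rd <- as.data.frame(SummarizedExperiment::rowData(exonSE))
  data.frame(exon_id = rownames(Y), gene_id = rd$gene_id,
             exon_index = rd$exon_index, see = unname(see),
             se = unname(seOut), df = df, row.names = NULL)
}

#' Within-gene exon deviation test
#'
#' Tests, for every exon of a multi-exon gene, whether its synergistic
#' expression departs from the unweighted mean of the gene's other exons:
#' \eqn{dev_i = See_i - \overline{See}_{j \ne i}}, with variance
#' \eqn{Var_i + \sum_{j \ne i} Var_j/(m-1)^2} and a Satterthwaite
#' approximation to the degrees of freedom. Two-sided p-values are
#' Benjamini-Hochberg adjusted across all exons genome-wide; exons with
#' FDR < `fdrCutoff` are called synergistically expressed. Single-exon
#' genes carry no within-gene contrast and are excluded (recorded in
#' attribute `"excluded"`).
#'
#' @param seeTable output of [synergyContrast()].
#' @param fdrCutoff exon-level FDR threshold (default 0.05).
#' @return data.frame `exon_id`, `gene_id`, `exon_index`, `see`,
#'   `deviation`, `t`, `df`, `p`, `fdr`, `called`.
#' @export
exonDeviationTest <- function(seeTable, fdrCutoff = 0.05) {
  counts <- table(seeTable$gene_id)
  multi <- names(counts)[counts >= 2]
  excluded <- setdiff(names(counts), multi)
  tab <- seeTable[seeTable$gene_id %in% multi, , drop = FALSE]
  if (!nrow(tab)) {
    out <- data.frame(exon_id = character(), gene_id = character(),
                      exon_index = integer(), see = numeric(),
                      deviation = numeric(), t = numeric(), df = numeric(),
                      p = numeric(), fdr = numeric(), called = logical())
    attr(out, "excluded") <- excluded
    return(out)
  }
  res <- lapply(split(tab, tab$gene_id), function(g) {
    m <- nrow(g)
    v <- g$se^2
    dev <- tstat <- vv <- dfs <- numeric(m)
    for (i in seq_len(m)) {
      others <- setdiff(seq_len(m), i)
      dev[i] <- g$see[i] - mean(g$see[others])
      w <- rep(1 / (m - 1)^2, m); w[i] <- 1
      vv[i] <- sum(w * v)
      ## Satterthwaite df from the per-exon contrast dfs
      dfs[i] <- vv[i]^2 / sum((w * v)^2 / g$df)
      tstat[i] <- dev[i] / sqrt(vv[i])
    }
    data.frame(exon_id = g$exon_id, gene_id = g$gene_id,
               exon_index = g$exon_index, see = g$see, deviation = dev,
               t = tstat, df = dfs,
               p = 2 * stats::pt(-abs(tstat), df = dfs), row.names = NULL)
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  out$fdr <- stats::p.adjust(out$p, "BH")
  out$called <- out$fdr < fdrCutoff
  attr(out, "excluded") <- excluded
  out
}

#' Simes combination of a gene's exon p-values
#'
#' \eqn{p_{gene} = \min_i \; n \, p_{(i)} / i} over the sorted exon
#' p-values: a test of whether any exon's usage departs from the rest of
#' the gene.
#'
#' @param p numeric vector of exon p-values in \[0, 1\].
#' @return the Simes-combined p-value.
#' @export
simesTest <- function(p) {
  stopifnot(length(p) >= 1, all(p >= 0 & p <= 1))
  n <- length(p)
  min(n * sort(p) / seq_len(n))
}

#' Call synergistically spliced genes
#'
#' Combines each gene's exon deviation p-values with the Simes test, then
#' (by default) Benjamini-Hochberg adjusts the per-gene Simes p-values
#' across genes; genes below `cutoff` are synergistically spliced. Set
#' `adjust = FALSE` to threshold the raw Simes p-values instead.
#'
#' @param exonTable output of [exonDeviationTest()].
#' @param cutoff gene-level threshold (default 0.05).
#' @param adjust apply BH across genes (default TRUE).
#' @return data.frame `gene_id`, `n_exons`, `p_simes`, `fdr`, `called`.
#' @export
simesGeneTest <- function(exonTable, cutoff = 0.05, adjust = TRUE) {
  genes <- split(exonTable$p, exonTable$gene_id)
  pg <- vapply(genes, simesTest, numeric(1))
  fdr <- if (adjust) stats::p.adjust(pg, "BH") else pg
  data.frame(gene_id = names(genes),
             n_exons = vapply(genes, length, integer(1)),
             p_simes = unname(pg), fdr = unname(fdr),
             called = unname(fdr < cutoff), row.names = NULL)
}

#' Overlap between synergistically spliced genes and SEGs
#'
#' @param splicedGenes,segs character vectors over the same gene universe.
#' @return named integer vector: `spliced_only`, `both`, `seg_only`.
#' @export
splicingExpressionOverlap <- function(splicedGenes, segs) {
  c(spliced_only = length(setdiff(splicedGenes, segs)),
    both = length(intersect(splicedGenes, segs)),
    seg_only = length(setdiff(segs, splicedGenes)))
}
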