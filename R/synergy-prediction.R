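#' Rank drug pairs by monotherapy-profile correlation
#'
#' For each pair, computes the Pearson correlation of the two monotherapy
#' log fold-change profiles over the union of genes differentially
#' expressed in either monotherapy (FDR < `unionFdr`), then ranks pairs by
#' descending correlation; ties are broken by pair identifier so the
#' ranking is deterministic.
#'
#' @param panel data.frame with one row per pair: `pair_id`, `drug_a`,
#'   `drug_b`, and optionally `label` / `eob`.
#' @param profiles named list: drug -> DE slice (`gene`, `logFC`, `fdr`).
#' @param unionFdr union-set threshold (default 0.1).
#' @param exclude optional genes to drop before correlating (e.g. a shared
#'   toxicity signature).
#' @return the panel with added `correlation` and `rank` (1 = most
#'   correlated), ordered by rank.
#' @export
rankPairs <- function(panel, profiles, unionFdr = 0.1, exclude = NULL) {
  corr <- vapply(seq_len(nrow(panel)), function(i) {
    monotherapyCorrelation(profiles[[panel$drug_a[i]]],
                           profiles[[panel$drug_b[i]]],
                           unionFdr = unionFdr, exclude = exclude)
  }, numeric(1))
  panel$correlation <- corr
  ord <- order(-corr, panel$pair_id)
  panel <- panel[ord, , drop = FALSE]
  panel$rank <- seq_len(nrow(panel))
  rownames(panel) <- NULL
  panel
}

#' Area under the ROC curve of a score against binary labels
#'
#' Mann-Whitney formulation with tie correction: the probability that a
#' random positive outscores a random negative, counting ties as 1/2
#' (equivalent to trapezoidal ROC integration).
#'
#' @param score numeric score (higher = predicted positive).
#' @param label binary labels (0/1 or logical).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(score, label) {
  label <- as.logical(label)
  if (!any(label) || all(label)) stop("need both positive and negative labels")
  pos <- score[label]; neg <- score[!label]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

#' Area under the precision-recall curve
#'
#' Step-interpolated PR area (average precision): walking down the
#' score-ordered list, each positive contributes the precision at its
#' rank, averaged over the positives. Tied scores are processed in a
#' deterministic order.
#'
#' @inheritParams auroc
#' @return AUPR in (0, 1\].
#' @export
aupr <- function(score, label) {
  label <- as.logical(label)
  if (!any(label) || all(label)) stop("need both positive and negative labels")
  ord <- order(-score)
  lab <- label[ord]
  prec <- cumsum(lab) / seq_along(lab)
  mean(prec[lab])
}

#' Bootstrap Bayes factor between two rankers
#'
#' Resamples the pairs with replacement `nBoot` times (stratified within
#' positives and negatives so every resample retains both classes),
#' computes the metric for both score vectors on each resample, and
#' reports \eqn{BF = (w_1 + t/2)/(w_2 + t/2)} where \eqn{w_k} counts
#' resamples won by ranker k and t the ties. Identical scores give BF = 1
#' exactly; a ranker that wins every resample yields an infinite ratio,
#' reported as capped at `nBoot` with `capped = TRUE`. A BF above ~3 is
#' conventionally read as a meaningful performance difference.
#'
#' @param score1,score2 score vectors over the same pairs.
#' @param label binary labels.
#' @param metric `"auroc"` or `"aupr"`, or a function(score, label).
#' @param nBoot bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @return list with `bf`, `wins1`, `wins2`, `ties`, `capped`.
#' @export
bayesFactor <- function(score1, score2, label, metric = "auroc",
                        nBoot = 1000, seed = 1) {
  stopifnot(length(score1) == length(score2),
            length(score1) == length(label))
  f <- if (is.function(metric)) metric else match.fun(metric)
  label <- as.logical(label)
  if (identical(score1, score2))
    return(list(bf = 1, wins1 = 0L, wins2 = 0L, ties = nBoot,
                capped = FALSE))
  set.seed(seed)
  ip <- which(label); ineg <- which(!label)
  w1 <- w2 <- ties <- 0L
  for (b in seq_len(nBoot)) {
    idx <- c(sample(ip, length(ip), replace = TRUE),
             sample(ineg, length(ineg), replace = TRUE))
    m1 <- f(score1[idx], label[idx])
    m2 <- f(score2[idx], label[idx])
    if (m1 > m2) w1 <- w1 + 1L
    else if (m2 > m1) w2 <- w2 + 1L
    else ties <- ties + 1L
  }
  num <- w1 + ties / 2; den <- w2 + ties / 2
  if (den == 0) list(bf = nBoot, wins1 = w1, wins2 = w2, ties = ties,
                     capped = TRUE)
  else list(bf = num / den, wins1 = w1, wins2 = w2, ties = ties,
            capped = FALSE)
}
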