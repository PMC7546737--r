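#' Per-gene trajectory feature vectors across conditions
#'
#' For each gene, concatenates (block 1) the replicate-mean log2-CPM minus
#' the time-matched vehicle mean, per condition then time, and (block 2)
#' the consecutive-time deltas of block 1 within each condition. With 3
#' conditions and 6 time points the vector holds 3*6 + 3*5 = 33 values;
#' the delta block injects derivative information without changing scale.
#'
#' @param se `SummarizedExperiment` from [tmmNormalize()].
#' @param conditions treatment labels to join (order defines block
#'   layout).
#' @param times time points in increasing order.
#' @param genes optional gene subset (default all rows).
#' @param vehicle vehicle label.
#' @return numeric matrix, genes x (C*T + C*(T-1)), with column names
#'   `cond.tX` / `cond.dtX1-X0`.
#' @export
buildFeatureVectors <- function(se, conditions, times, genes = NULL,
                                vehicle = "DMSO") {
  cd <- as.data.frame(colData(se))
  Y <- assay(se, "logCPM")
  if (!is.null(genes)) Y <- Y[genes, , drop = FALSE]
  groupMean <- function(tr, tm) {
    ids <- cd$sample_id[cd$treatment == tr & cd$time_h == tm]
    if (!length(ids)) stop(sprintf("missing (%s, %g h) samples", tr, tm))
    rowMeans(Y[, ids, drop = FALSE])
  }
  blocks1 <- list(); blocks2 <- list()
  for (co in conditions) {
    vals <- vapply(times, function(tm) groupMean(co, tm) - groupMean(vehicle, tm),
                   numeric(nrow(Y)))
    if (nrow(Y) == 1) vals <- matrix(vals, nrow = 1)
    rownames(vals) <- rownames(Y)
    colnames(vals) <- paste0(co, ".t", times)
    blocks1[[co]] <- vals
    d <- vals[, -1, drop = FALSE] - vals[, -ncol(vals), drop = FALSE]
    colnames(d) <- paste0(co, ".d", times[-1], "-", times[-length(times)])
    blocks2[[co]] <- d
  }
  cbind(do.call(cbind, blocks1), do.call(cbind, blocks2))
}

## k-means++ seeding: spread initial centers by squared-distance sampling
.kmeansPP <- function(X, k) {
  n <- nrow(X)
  centers <- X[sample.int(n, 1), , drop = FALSE]
  while (nrow(centers) < k) {
    d2 <- apply(X, 1, function(r) min(colSums((t(centers) - r)^2)))
    if (all(d2 == 0)) {
      centers <- rbind(centers, X[sample.int(n, 1), , drop = FALSE])
    } else {
      centers <- rbind(centers, X[sample.int(n, 1, prob = d2), , drop = FALSE])
    }
  }
  centers
}

#' Best-of-restarts k-means
#'
#' Runs k-means `nRestarts` times and keeps the partition with the
#' smallest total within-cluster sum of squares. The default local search
#' is Lloyd with k-means++ initialization; `algorithm = "Hartigan-Wong"`
#' uses the Hartigan-Wong updates with random initialization instead. With
#' many restarts the two converge to the same optimum on well-separated
#' data.
#'
#' @param X feature matrix ([buildFeatureVectors()]).
#' @param k number of clusters.
#' @param nRestarts restarts (default 10000; reduce for exploratory
#'   runs).
#' @param maxIter per-restart iteration cap (default 1000).
#' @param seed RNG seed for the whole restart stream.
#' @param algorithm `"Lloyd"` (k-means++ init) or `"Hartigan-Wong"`.
#' @return object of class `ClusterModel`: list with `k`, `cluster`
#'   (named assignments), `centers`, `totWithinss`, `nRestarts`,
#'   `bestRestart`, `seed`, `algorithm`.
#' @export
kmeansRestarts <- function(X, k, nRestarts = 10000, maxIter = 1000,
                           seed = 1, algorithm = c("Lloyd", "Hartigan-Wong")) {
  algorithm <- match.arg(algorithm)
  stopifnot(k >= 1, nRestarts >= 1)
  if (k > nrow(unique(as.data.frame(X))))
    stop("k exceeds the number of distinct feature vectors")
  set.seed(seed)
  best <- NULL; bestIdx <- NA_integer_
  for (i in seq_len(nRestarts)) {
    fit <- tryCatch({
      if (algorithm == "Lloyd")
        stats::kmeans(X, centers = .kmeansPP(X, k), iter.max = maxIter,
                      algorithm = "Lloyd")
      else
        stats::kmeans(X, centers = k, iter.max = maxIter,
                      algorithm = "Hartigan-Wong")
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit) || any(fit$size == 0)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) {
      best <- fit; bestIdx <- i
    }
  }
  if (is.null(best)) stop("no restart produced a valid partition")
  out <- list(k = k, cluster = stats::setNames(best$cluster, rownames(X)),
              centers = best$centers, totWithinss = best$tot.withinss,
              nRestarts = nRestarts, bestRestart = bestIdx, seed = seed,
              algorithm = algorithm)
  class(out) <- "ClusterModel"
  out
}

#' @export
print.ClusterModel <- function(x, ...) {
  cat(sprintf(
    "k-means model: k = %d, WCSS = %.4g (best of %d %s restarts, seed %d)\n",
    x$k, x$totWithinss, x$nRestarts, x$algorithm, x$seed))
  cat("cluster sizes:", paste(table(x$cluster), collapse = ", "), "\n")
  invisible(x)
}

#' Recompute a model's within-cluster sum of squares from scratch
#' @param model a `ClusterModel`.
#' @param X the feature matrix it was fitted on.
#' @return total WCSS (should equal `model$totWithinss`).
#' @export
recomputeWCSS <- function(model, X) {
  sum(vapply(seq_len(nrow(X)), function(i)
    sum((X[i, ] - model$centers[model$cluster[i], ])^2), numeric(1)))
}

#' Elbow-based choice of k
#'
#' Computes the best-of-restarts WCSS over a range of k and suggests the
#' elbow by maximum curvature of the log-WCSS profile (the interior k with
#' the largest positive second difference of log WCSS): past the true
#' cluster number the relative gain per extra cluster collapses, which is
#' a curvature spike on the log scale regardless of the absolute
#' separation between clusters. The full curve is always returned for
#' manual inspection.
#'
#' @inheritParams kmeansRestarts
#' @param kRange candidate k values (default 1:20).
#' @return list with `curve` (data.frame `k`, `wcss`) and `k` (suggested).
#' @export
selectK <- function(X, kRange = 1:20, nRestarts = 100, maxIter = 1000,
                    seed = 1, algorithm = "Lloyd") {
  if (!length(kRange)) stop("empty k range")
  kRange <- sort(as.integer(kRange))
  wcss <- vapply(seq_along(kRange), function(i)
    kmeansRestarts(X, kRange[i], nRestarts, maxIter, seed + i,
                   algorithm)$totWithinss, numeric(1))
  curve <- data.frame(k = kRange, wcss = wcss)
  if (length(kRange) <= 2) return(list(curve = curve, k = kRange[1]))
  lw <- log(pmax(wcss, max(wcss) * 1e-12))
  d2 <- lw[seq_len(length(lw) - 2)] - 2 * lw[seq(2, length(lw) - 1)] +
    lw[seq(3, length(lw))]
  list(curve = curve, k = kRange[which.max(d2) + 1L])
}
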