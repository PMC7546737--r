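#' Sign a TF-target network from expression
#'
#' For each directed edge whose TF and target are both measured, computes
#' the Spearman correlation of their expression across all samples and a
#' two-sided p-value (t approximation on the rank correlation). P-values
#' are Benjamini-Hochberg adjusted across edges; edges at or above the FDR
#' threshold are removed and each survivor carries the sign of its
#' correlation. Edges with unmeasured nodes are dropped and counted.
#'
#' @param edges data.frame with columns `tf`, `target` (directed edge
#'   list).
#' @param se `SummarizedExperiment` with a `logCPM` assay (the expression
#'   used for signing).
#' @param fdr edge retention threshold (default 0.05).
#' @return a [SignedNetwork-class] whose edge table adds `rho` and `fdr`.
#' @export
signNetwork <- function(edges, se, fdr = 0.05) {
  Y <- assay(se, "logCPM")
  if (ncol(Y) < 4)
    stop("need >= 4 samples for rank-correlation signing")
  measured <- rownames(Y)
  keep <- edges$tf %in% measured & edges$target %in% measured
  droppedNodes <- sum(!keep)
  edges <- edges[keep, , drop = FALSE]
  if (!nrow(edges)) stop("no edge has both nodes measured")
  R <- t(apply(Y[unique(c(edges$tf, edges$target)), , drop = FALSE], 1, rank))
  n <- ncol(Y)
  rA <- R[edges$tf, , drop = FALSE]
  rB <- R[edges$target, , drop = FALSE]
  rho <- vapply(seq_len(nrow(edges)), function(i) {
    suppressWarnings(stats::cor(rA[i, ], rB[i, ]))
  }, numeric(1))
  rho[is.na(rho)] <- 0  # constant expression: no association
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  q <- stats::p.adjust(p, "BH")
  sel <- q < fdr & rho != 0
  out <- data.frame(tf = edges$tf[sel], target = edges$target[sel],
                    sign = ifelse(rho[sel] > 0, 1L, -1L),
                    rho = rho[sel], fdr = q[sel], row.names = NULL)
  SignedNetwork(out, dropped = droppedNodes + sum(!sel))
}

#' Guarded one-sided Fisher enrichment test
#'
#' Hypergeometric upper-tail probability of the observed overlap between
#' two gene sets within a universe. The guard rule returns p = 1 without
#' testing when either set has fewer than 3 genes or the overlap fewer
#' than 2 genes (tiny tables carry no usable signal and would otherwise
#' flood the FDR family).
#'
#' @param setA,setB character vectors (subsets of `universe`).
#' @param universe background gene universe.
#' @param minSet,minOverlap guard thresholds (defaults 3 and 2).
#' @return list with `p`, `overlap`, `guarded`.
#' @export
guardedFisher <- function(setA, setB, universe, minSet = 3, minOverlap = 2) {
  setA <- intersect(unique(setA), universe)
  setB <- intersect(unique(setB), universe)
  k <- length(intersect(setA, setB))
  if (length(setA) < minSet || length(setB) < minSet || k < minOverlap)
    return(list(p = 1, overlap = k, guarded = TRUE))
  N <- length(universe)
  p <- stats::phyper(k - 1, length(setA), N - length(setA), length(setB),
                     lower.tail = FALSE)
  list(p = p, overlap = k, guarded = FALSE)
}

#' Four regulon-direction enrichment comparisons for one TF
#'
#' Tests the TF's positively and negatively regulated target sets against
#' the up- and downregulated DEG sets (four guarded one-sided Fisher
#' tests). Direction semantics: enrichment of the positive regulon in
#' upregulated genes is evidence the positive effector function is
#' activated, and so on (see [callDifferentialActivity()]).
#'
#' @param regulon list with `pos` and `neg` target vectors
#'   (see [regulons()]).
#' @param up,down DEG sets.
#' @param universe background universe.
#' @return data.frame with one row per comparison: `effector`
#'   (`pos`/`neg`), `direction` (`up`/`down`), `p`, `overlap`, `guarded`.
#' @export
regulonFisher <- function(regulon, up, down, universe) {
  rows <- expand.grid(effector = c("pos", "neg"),
                      direction = c("up", "down"),
                      stringsAsFactors = FALSE)
  res <- Map(function(eff, dir) {
    guardedFisher(regulon[[eff]], if (dir == "up") up else down, universe)
  }, rows$effector, rows$direction)
  rows$p <- vapply(res, `[[`, numeric(1), "p")
  rows$overlap <- vapply(res, `[[`, numeric(1), "overlap")
  rows$guarded <- vapply(res, `[[`, logical(1), "guarded")
  rows
}

## enumerate the four comparisons for every TF at every time of a treatment
.activityPvalues <- function(network, degs, treatment, times, universe) {
  regs <- regulons(network)
  out <- list()
  for (tm in times) {
    up <- degSet(degs, treatment, tm, "up")
    down <- degSet(degs, treatment, tm, "down")
    for (tf in names(regs)) {
      r <- regulonFisher(regs[[tf]], up, down, universe)
      r$tf <- tf; r$time <- tm
      out[[paste(tf, tm)]] <- r
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Differential TF activity for one treatment
#'
#' Runs the four regulon-direction comparisons for every TF at every time
#' point of a treatment, pools all resulting p-values into a single
#' Benjamini-Hochberg family for the treatment, and maps significant
#' comparisons to effector states: positive regulon enriched in up genes
#' means the positive effector function is activated; positive in down,
#' inactivated; negative in up, inactivated; negative in down, activated.
#' An effector found both activated and inactivated is nonsensical and
#' removed. Concordance: both effectors in the same direction is
#' `concordant`, opposite `discordant`, one only `unique`, none `none`.
#'
#' @param network a [SignedNetwork-class].
#' @param degs DEG table from [callDegs()].
#' @param treatment treatment label.
#' @param times time points to assess (default all in `degs`).
#' @param universe background gene universe.
#' @param fdr significance threshold on the pooled FDR (default 0.05).
#' @return a [RegulonActivity-class]; its table carries the four p-values
#'   and FDRs per (tf, time) as columns `p_<effector>_<direction>` /
#'   `fdr_<effector>_<direction>`.
#' @export
callDifferentialActivity <- function(network, degs, treatment, times = NULL,
                                     universe, fdr = 0.05) {
  if (is.null(times)) times <- sort(unique(degs$time))
  if (!length(times))
    return(new("RegulonActivity", table = data.frame(
      tf = character(), treatment = character(), time = numeric(),
      pos_state = character(), neg_state = character(),
      concordance = character())))
  pv <- .activityPvalues(network, degs, treatment, times, universe)
  pv$fdr <- stats::p.adjust(pv$p, "BH")  # pooled family: TFs x times x 4
  rows <- list()
  for (key in split(seq_len(nrow(pv)), paste(pv$tf, pv$time, sep = "\r"))) {
    sub <- pv[key, ]
    tf <- sub$tf[1]; tm <- sub$time[1]
    get <- function(eff, dir)
      sub[sub$effector == eff & sub$direction == dir, ]
    state <- function(eff) {
      actDir <- if (eff == "pos") "up" else "down"
      inactDir <- if (eff == "pos") "down" else "up"
      act <- get(eff, actDir)$fdr < fdr
      inact <- get(eff, inactDir)$fdr < fdr
      if (act && inact) "removed_nonsensical"
      else if (act) "activated"
      else if (inact) "inactivated"
      else "not_DA"
    }
    ps <- state("pos"); ns <- state("neg")
    da <- c("activated", "inactivated")
    conc <- if (ps %in% da && ns %in% da) {
      if (ps == ns) "concordant" else "discordant"
    } else if (ps %in% da || ns %in% da) "unique" else "none"
    row <- data.frame(tf = tf, treatment = treatment, time = tm,
                      pos_state = ps, neg_state = ns, concordance = conc)
    for (eff in c("pos", "neg")) for (dir in c("up", "down")) {
      g <- get(eff, dir)
      row[[paste0("p_", eff, "_", dir)]] <- g$p
      row[[paste0("fdr_", eff, "_", dir)]] <- g$fdr
    }
    rows[[paste(tf, tm)]] <- row
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  tab <- tab[order(tab$time, tab$tf), ]
  rownames(tab) <- NULL
  new("RegulonActivity", table = tab)
}

#' Deconvolve overlapping regulons at one treatment/time
#'
#' TFs with near-identical target sets inherit each other's apparent
#' activity. For every pair of significant TFs whose significant-effector
#' regulons overlap significantly (guarded Fisher, BH across pairs), the
#' relevant dysregulated genes are re-tested against (a) the regulon
#' intersection and (b, c) each TF's exclusive targets (BH across all such
#' tests). Within a significant-overlap pair, a TF whose exclusive set
#' remains significant is retained with its original FDR; a TF whose
#' exclusive set is not significant is removed (state
#' `removed_deconvolution`). A TF failing the exclusive-set criterion in
#' any of its significant pairs is removed. Pairs without significant
#' overlap are untouched.
#'
#' @param activity a [RegulonActivity-class] (one treatment).
#' @param network the [SignedNetwork-class] used for the activity calls.
#' @param degs DEG table from [callDegs()].
#' @param time time point to deconvolve.
#' @param universe background universe.
#' @param fdr significance threshold (default 0.05).
#' @return the updated [RegulonActivity-class].
#' @export
deconvolveRegulons <- function(activity, network, degs, time, universe,
                               fdr = 0.05) {
  tab <- activity@table
  treatment <- unique(tab$treatment)
  stopifnot(length(treatment) == 1)
  da <- c("activated", "inactivated")
  atT <- tab[tab$time == time, , drop = FALSE]
  sig <- atT$tf[atT$pos_state %in% da | atT$neg_state %in% da]
  if (length(sig) < 2) return(activity)
  regs <- regulons(network)
  ## significant-effector regulon and its relevant DEG set per TF
  up <- degSet(degs, treatment, time, "up")
  down <- degSet(degs, treatment, time, "down")
  sigReg <- list(); relGenes <- list()
  for (tf in sig) {
    row <- atT[atT$tf == tf, ]
    r <- character(); g <- character()
    if (row$pos_state %in% da) {
      r <- c(r, regs[[tf]]$pos)
      g <- c(g, if (row$pos_state == "activated") up else down)
    }
    if (row$neg_state %in% da) {
      r <- c(r, regs[[tf]]$neg)
      g <- c(g, if (row$neg_state == "activated") down else up)
    }
    sigReg[[tf]] <- unique(r); relGenes[[tf]] <- unique(g)
  }
  pairs <- utils::combn(sig, 2, simplify = FALSE)
  pOv <- vapply(pairs, function(pr)
    guardedFisher(sigReg[[pr[1]]], sigReg[[pr[2]]], universe)$p, numeric(1))
  qOv <- stats::p.adjust(pOv, "BH")
  sigPairs <- pairs[qOv < fdr]
  if (!length(sigPairs)) return(activity)
  ## exclusive/intersection enrichment tests, one BH family
  tests <- list()
  for (i in seq_along(sigPairs)) {
    a <- sigPairs[[i]][1]; b <- sigPairs[[i]][2]
    inter <- intersect(sigReg[[a]], sigReg[[b]])
    rel <- union(relGenes[[a]], relGenes[[b]])
    tests[[length(tests) + 1L]] <- list(pair = i, tf = NA, part = "inter",
      p = guardedFisher(inter, rel, universe)$p)
    tests[[length(tests) + 1L]] <- list(pair = i, tf = a, part = "exclusive",
      p = guardedFisher(setdiff(sigReg[[a]], inter), relGenes[[a]],
                        universe)$p)
    tests[[length(tests) + 1L]] <- list(pair = i, tf = b, part = "exclusive",
      p = guardedFisher(setdiff(sigReg[[b]], inter), relGenes[[b]],
                        universe)$p)
  }
  q <- stats::p.adjust(vapply(tests, `[[`, numeric(1), "p"), "BH")
  removed <- character()
  for (i in seq_along(sigPairs)) {
    excl <- which(vapply(tests, function(t)
      t$pair == i && identical(t$part, "exclusive"), logical(1)))
    for (j in excl) {
      if (q[j] >= fdr) removed <- union(removed, tests[[j]]$tf)
    }
  }
  sel <- tab$time == time & tab$tf %in% removed
  tab$pos_state[sel & tab$pos_state %in% da] <- "removed_deconvolution"
  tab$neg_state[sel & tab$neg_state %in% da] <- "removed_deconvolution"
  tab$concordance[sel] <- "none"
  new("RegulonActivity", table = tab)
}
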