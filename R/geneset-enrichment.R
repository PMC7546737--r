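#' Read a GMT gene-set library
#' @param path GMT file path.
#' @return named list of gene-id vectors.
#' @export
readGmt <- function(path) fgsea::gmtPathways(path)

#' Write a GMT gene-set library
#' @param sets named list of gene-id vectors.
#' @param path destination file.
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "synersig", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Direction-wise union of two monotherapies' DEG sets
#'
#' The "TUM" baseline: a gene is in the union up-set when upregulated in
#' either monotherapy (likewise down). A gene moving in opposite
#' directions appears in both union directions. Gene sets enriched in this
#' union but not specifically in the combination reflect additive rather
#' than synergistic expression.
#'
#' @param degsA,degsB DEG tables ([callDegs()]) restricted to the two
#'   monotherapies.
#' @param treatmentA,treatmentB treatment labels.
#' @param time time point.
#' @return list with `up` and `down` gene vectors.
#' @export
buildTum <- function(degsA, degsB, treatmentA, treatmentB, time) {
  list(up = union(degSet(degsA, treatmentA, time, "up"),
                  degSet(degsB, treatmentB, time, "up")),
       down = union(degSet(degsA, treatmentA, time, "down"),
                    degSet(degsB, treatmentB, time, "down")))
}

#' Guarded Fisher enrichment of gene sets in DEG sets over conditions
#'
#' @param geneSets named list of gene sets (e.g. from [readGmt()]).
#' @param degLists named list: condition label -> list(time -> list(up,
#'   down)) of DEG vectors.
#' @param universe background universe.
#' @return `EnrichmentTable` data.frame: `gene_set`, `condition`, `time`,
#'   `direction`, `overlap`, `p`, `guarded`, `fdr` (BH across all rows of
#'   this run).
#' @export
enrichmentTable <- function(geneSets, degLists, universe) {
  rows <- list()
  for (cond in names(degLists)) for (tm in names(degLists[[cond]])) {
    dl <- degLists[[cond]][[tm]]
    for (dir in c("up", "down")) for (gs in names(geneSets)) {
      f <- guardedFisher(geneSets[[gs]], dl[[dir]], universe)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_set = gs, condition = cond, time = tm, direction = dir,
        overlap = f$overlap, p = f$p, guarded = f$guarded)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$fdr <- stats::p.adjust(out$p, "BH")
  out
}

## synergistic/additive rule on one FDR-by-time vector pair
.setClassRule <- function(fdrCombo, fdrTum, strong, weak) {
  comboStrong <- min(fdrCombo) < strong && max(fdrCombo) < weak
  tumStrong <- min(fdrTum) < strong && max(fdrTum) < weak
  if (tumStrong) "additive"
  else if (comboStrong) "synergistic"
  else "neither"
}

#' Classify gene sets as synergistic or additive
#'
#' A gene set is synergistic when its combination enrichment is strong and
#' sustained (FDR < `strong` at >= 1 time point and < `weak` at all time
#' points in the combination) while the monotherapy-union (TUM) enrichment
#' is not; it is additive when the TUM enrichment itself is strong and
#' sustained. Directions are tested separately and the set is classified
#' on its best direction; the per-direction labels are also returned.
#'
#' @param enrich `EnrichmentTable` ([enrichmentTable()]) containing both
#'   the combination condition and the TUM condition at the same time
#'   points.
#' @param comboCondition,tumCondition condition labels inside `enrich`.
#' @param strong,weak thresholds (defaults 1e-5, 0.01).
#' @return data.frame: `gene_set`, `direction`, `label`, plus a collapsed
#'   per-set `best` table in attribute `"best"`.
#' @export
classifyGeneSets <- function(enrich, comboCondition, tumCondition,
                             strong = 1e-5, weak = 0.01) {
  sets <- unique(enrich$gene_set)
  rows <- list()
  for (gs in sets) for (dir in c("up", "down")) {
    fc <- enrich$fdr[enrich$gene_set == gs & enrich$direction == dir &
                       enrich$condition == comboCondition]
    ft <- enrich$fdr[enrich$gene_set == gs & enrich$direction == dir &
                       enrich$condition == tumCondition]
    if (!length(fc) || !length(ft))
      stop("missing combo/TUM rows for gene set ", gs)
    rows[[paste(gs, dir)]] <- data.frame(
      gene_set = gs, direction = dir,
      label = .setClassRule(fc, ft, strong, weak))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rank <- c(synergistic = 1, additive = 2, neither = 3)
  best <- do.call(rbind, lapply(split(out, out$gene_set), function(s) {
    data.frame(gene_set = s$gene_set[1],
               label = s$label[which.min(rank[s$label])])
  }))
  rownames(best) <- NULL
  attr(out, "best") <- best
  out
}
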