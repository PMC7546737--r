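#' Activity-pattern sets at one time point
#'
#' Classifies TFs by the binary triple of their activity across
#' (monotherapy A, monotherapy B, combination): e.g. `(101)` holds TFs
#' active in A and the combination but not B, `(111)` TFs active in all
#' three, and `(001)` the synergistic TFs, active only in the combination.
#' A TF is "active" in a treatment when at least one effector function is
#' differentially active after deconvolution.
#'
#' @param activityA,activityB,activityCombo [RegulonActivity-class]
#'   objects for the two monotherapies and the combination.
#' @param treatmentA,treatmentB,treatmentCombo treatment labels inside
#'   those objects.
#' @param time time point.
#' @return named list of the seven pattern sets (`"100"`, `"010"`,
#'   `"001"`, `"110"`, `"101"`, `"011"`, `"111"`), pairwise disjoint.
#' @export
classifyTfSets <- function(activityA, activityB, activityCombo,
                           treatmentA, treatmentB, treatmentCombo, time) {
  a <- activeTfs(activityA, treatmentA, time)
  b <- activeTfs(activityB, treatmentB, time)
  co <- activeTfs(activityCombo, treatmentCombo, time)
  all3 <- unique(c(a, b, co))
  pat <- paste0(as.integer(all3 %in% a), as.integer(all3 %in% b),
                as.integer(all3 %in% co))
  pats <- c("100", "010", "001", "110", "101", "011", "111")
  stats::setNames(lapply(pats, function(p) all3[pat == p]), pats)
}

## joint DD/AND/MIXED classification of a parent set against one time
## point's pattern sets; NA when none of the three conditions holds
.jointMechanism <- function(parents, s) {
  inDD <- any(parents %in% s[["111"]])
  inA <- any(parents %in% s[["101"]])
  inB <- any(parents %in% s[["011"]])
  if (inDD && inA && inB) "MIXED"
  else if (inA && inB) "AND"
  else if (inDD) "DD"
  else NA_character_
}

#' Explain synergistic TFs by the transcriptional cascade
#'
#' Labels every combination-only ((001)) TF at each time point by the
#' first matching mechanism, in precedence order:
#' \describe{
#'   \item{DD (double-down)}{a network parent is active in both
#'     monotherapies and the combination ((111)) and the AND condition
#'     does not also hold.}
#'   \item{AND}{one parent active only with monotherapy A ((101)) and one
#'     only with monotherapy B ((011)), none in (111).}
#'   \item{MIXED}{parents in (111) and in both (101) and (011).}
#'   \item{PROP_SAME}{a parent is an already-explained synergistic TF at
#'     the same time point; applied iteratively to a fixed point, with the
#'     round recorded in `depth`.}
#'   \item{DD_PREV / AND_PREV}{the DD/AND/MIXED conditions hold against
#'     the previous time point's sets (a MIXED-at-previous case is
#'     reported as DD_PREV).}
#'   \item{PROP_PREV}{a parent is an explained synergistic TF at the
#'     previous time point.}
#'   \item{UNEXPLAINED}{none of the above, or the TF is absent from the
#'     network (flagged in `in_network`).}
#' }
#'
#' @param setsByTime named list (time point -> pattern-set list from
#'   [classifyTfSets()]), in increasing time order.
#' @param network a [SignedNetwork-class].
#' @return a [CascadeExplanation-class] with the TF labels filled in.
#' @export
explainSynergisticTfs <- function(setsByTime, network) {
  times <- names(setsByTime)
  rows <- list()
  explainedAt <- stats::setNames(vector("list", length(times)), times)
  for (ti in seq_along(times)) {
    sets <- setsByTime[[ti]]
    prevSets <- if (ti > 1) setsByTime[[ti - 1]] else NULL
    explainedPrev <- if (ti > 1) explainedAt[[ti - 1]] else character()
    s001 <- sets[["001"]]
    lab <- stats::setNames(rep(NA_character_, length(s001)), s001)
    depth <- stats::setNames(rep(NA_integer_, length(s001)), s001)
    parUsed <- stats::setNames(rep("", length(s001)), s001)
    inNet <- stats::setNames(
      s001 %in% unique(c(network@edges$tf, network@edges$target)), s001)
    parentSets <- lapply(stats::setNames(s001, s001), function(tf)
      if (inNet[tf]) parentsOf(network, tf) else character())
    anchors <- function(s) unlist(s[c("111", "101", "011")],
                                  use.names = FALSE)
    ## phase 1: direct same-time mechanisms
    for (tf in s001) {
      if (!inNet[tf]) next
      m <- .jointMechanism(parentSets[[tf]], sets)
      if (!is.na(m)) {
        lab[tf] <- m
        parUsed[tf] <- paste(intersect(parentSets[[tf]], anchors(sets)),
                             collapse = ";")
      }
    }
    ## phase 2: same-time propagation, iterated to a fixed point
    round <- 0L
    repeat {
      round <- round + 1L
      explainedSame <- names(lab)[!is.na(lab)]
      changed <- FALSE
      for (tf in s001) {
        if (!is.na(lab[tf]) || !inNet[tf]) next
        hit <- intersect(parentSets[[tf]], explainedSame)
        if (length(hit)) {
          lab[tf] <- "PROP_SAME"; depth[tf] <- round
          parUsed[tf] <- paste(hit, collapse = ";")
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    ## phases 3-4: previous-time mechanisms, then previous-time propagation
    for (tf in s001) {
      if (!is.na(lab[tf]) || !inNet[tf]) next
      if (!is.null(prevSets)) {
        m <- .jointMechanism(parentSets[[tf]], prevSets)
        if (!is.na(m)) {
          lab[tf] <- switch(m, DD = "DD_PREV", AND = "AND_PREV",
                            MIXED = "DD_PREV")
          parUsed[tf] <- paste(intersect(parentSets[[tf]],
                                         anchors(prevSets)),
                               collapse = ";")
          next
        }
      }
      hit <- intersect(parentSets[[tf]], explainedPrev)
      if (length(hit)) {
        lab[tf] <- "PROP_PREV"
        parUsed[tf] <- paste(hit, collapse = ";")
      }
    }
    lab[is.na(lab)] <- "UNEXPLAINED"
    explainedAt[[ti]] <- names(lab)[lab != "UNEXPLAINED"]
    if (length(s001))
      rows[[times[ti]]] <- data.frame(
        time = times[ti], tf = s001, mechanism = unname(lab[s001]),
        depth = unname(depth[s001]), parents_used = unname(parUsed[s001]),
        in_network = inNet, row.names = NULL)
  }
  tfTab <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else data.frame(time = character(), tf = character(),
                  mechanism = character(), depth = integer(),
                  parents_used = character(), in_network = logical())
  new("CascadeExplanation", tfLabels = tfTab,
      segLabels = data.frame(time = character(), gene = character(),
                             mechanism = character(),
                             parents_used = character()),
      sets = setsByTime)
}

#' Explain SEGs by the transcriptional cascade
#'
#' Labels each synergistically expressed gene at time t by precedence:
#' `DD` (a network parent in (111)(t)); `AND` (parents in (101)(t) and
#' (011)(t)); `TARGET_SAME` (target of an explained synergistic TF at t);
#' `TARGET_PREV` (target of an explained synergistic TF or of a
#' (111)/(101)/(011) member at t-1); else `UNEXPLAINED`.
#'
#' @param segsByTime named list (time point -> character vector of SEGs);
#'   names must match `explanation`'s time points.
#' @param explanation a [CascadeExplanation-class] from
#'   [explainSynergisticTfs()].
#' @param network a [SignedNetwork-class].
#' @return the explanation with SEG labels filled in.
#' @export
explainSegs <- function(segsByTime, explanation, network) {
  setsByTime <- explanation@sets
  tfTab <- explanation@tfLabels
  times <- names(setsByTime)
  rows <- list()
  for (ti in seq_along(times)) {
    tm <- times[ti]
    segs <- segsByTime[[tm]]
    if (is.null(segs) || !length(segs)) next
    sets <- setsByTime[[ti]]
    prevSets <- if (ti > 1) setsByTime[[ti - 1]] else NULL
    explSame <- tfTab$tf[tfTab$time == tm &
                           tfTab$mechanism != "UNEXPLAINED"]
    explPrev <- if (ti > 1)
      tfTab$tf[tfTab$time == times[ti - 1] &
                 tfTab$mechanism != "UNEXPLAINED"] else character()
    prevActors <- unique(c(explPrev,
      if (!is.null(prevSets)) unlist(prevSets[c("111", "101", "011")])))
    lab <- character(length(segs)); par <- character(length(segs))
    netNodes <- unique(c(network@edges$tf, network@edges$target))
    for (i in seq_along(segs)) {
      g <- segs[i]
      if (!(g %in% netNodes)) { lab[i] <- "UNEXPLAINED"; next }
      parents <- parentsOf(network, g)
      if (any(parents %in% sets[["111"]])) {
        lab[i] <- "DD"
        par[i] <- paste(intersect(parents, sets[["111"]]), collapse = ";")
      } else if (any(parents %in% sets[["101"]]) &&
                 any(parents %in% sets[["011"]])) {
        lab[i] <- "AND"
        par[i] <- paste(intersect(parents, c(sets[["101"]], sets[["011"]])),
                        collapse = ";")
      } else if (any(parents %in% explSame)) {
        lab[i] <- "TARGET_SAME"
        par[i] <- paste(intersect(parents, explSame), collapse = ";")
      } else if (any(parents %in% prevActors)) {
        lab[i] <- "TARGET_PREV"
        par[i] <- paste(intersect(parents, prevActors), collapse = ";")
      } else lab[i] <- "UNEXPLAINED"
    }
    rows[[tm]] <- data.frame(time = tm, gene = segs, mechanism = lab,
                             parents_used = par, row.names = NULL)
  }
  segTab <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else explanation@segLabels
  methods::initialize(explanation, segLabels = segTab)
}

#' Summarize a cascade explanation
#'
#' @param explanation a [CascadeExplanation-class].
#' @return list with `tf` (per-time mechanism counts and explained
#'   fraction), `seg` (likewise for SEGs) and `edges` (explanatory
#'   parent-child pairs for graph export).
#' @export
cascadeReport <- function(explanation) {
  count <- function(tab, unit) {
    if (!nrow(tab)) return(data.frame())
    do.call(rbind, lapply(split(tab, tab$time), function(s) {
      m <- table(s$mechanism)
      data.frame(time = s$time[1], mechanism = names(m),
                 n = as.integer(m),
                 explained_fraction =
                   1 - sum(s$mechanism == "UNEXPLAINED") / nrow(s),
                 row.names = NULL)
    }))
  }
  edge <- function(tab, idcol) {
    sel <- tab$parents_used != "" & !is.na(tab$parents_used)
    if (!any(sel)) return(data.frame(parent = character(),
                                     child = character(),
                                     time = character()))
    do.call(rbind, lapply(which(sel), function(i) {
      data.frame(parent = strsplit(tab$parents_used[i], ";")[[1]],
                 child = tab[[idcol]][i], time = tab$time[i],
                 row.names = NULL)
    }))
  }
  list(tf = count(explanation@tfLabels, "tf"),
       seg = count(explanation@segLabels, "gene"),
       edges = rbind(edge(explanation@tfLabels, "tf"),
                     edge(explanation@segLabels, "gene")))
}
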