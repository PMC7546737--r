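#' @import methods
NULL

#' Signed transcription-factor regulatory network
#'
#' Directed TF-to-target edges carrying a regulation sign (+1 activation,
#' -1 repression), typically obtained by correlating TF and target
#' expression across samples ([signNetwork()]) or emitted by a synthetic
#' generator. Each TF's positively and negatively regulated target sets (its
#' positive and negative regulon) are derived from the edge signs.
#'
#' @slot edges data.frame with columns `tf`, `target`, `sign` (+1/-1) and
#'   optionally `rho` (association statistic) and `fdr`.
#' @slot dropped integer, edges discarded during construction (nodes not
#'   measured, or association not significant).
#' @export
setClass("SignedNetwork",
         representation(edges = "data.frame", dropped = "integer"),
         prototype(edges = data.frame(tf = character(), target = character(),
                                      sign = integer()),
                   dropped = 0L))

setValidity("SignedNetwork", function(object) {
  e <- object@edges
  if (!all(c("tf", "target", "sign") %in% names(e)))
    return("edges must have columns tf, target, sign")
  if (nrow(e) && !all(e$sign %in% c(-1L, 1L)))
    return("edge signs must be +1 or -1")
  if (anyDuplicated(paste(e$tf, e$target)))
    return("duplicate (tf, target) edges")
  TRUE
})

#' Construct a SignedNetwork from an edge table
#' @param edges data.frame with columns `tf`, `target`, `sign`.
#' @param dropped number of edges discarded upstream.
#' @return a [SignedNetwork-class] object.
#' @export
SignedNetwork <- function(edges, dropped = 0L) {
  edges$sign <- as.integer(edges$sign)
  new("SignedNetwork", edges = as.data.frame(edges),
      dropped = as.integer(dropped))
}

#' @describeIn SignedNetwork-class edge table accessor.
#' @param x,object a `SignedNetwork`.
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname SignedNetwork-class
#' @export
setMethod("networkEdges", "SignedNetwork", function(x) x@edges)

#' Regulons of a transcription factor
#'
#' @param x a [SignedNetwork-class].
#' @param tf TF identifier, or NULL for all TFs.
#' @return for one TF a list with `pos` and `neg` target vectors; for all
#'   TFs a named list of such lists.
#' @export
setGeneric("regulons", function(x, tf = NULL) standardGeneric("regulons"))

#' @rdname regulons
#' @export
setMethod("regulons", "SignedNetwork", function(x, tf = NULL) {
  e <- x@edges
  one <- function(t) {
    sub <- e[e$tf == t, , drop = FALSE]
    list(pos = sub$target[sub$sign > 0], neg = sub$target[sub$sign < 0])
  }
  if (!is.null(tf)) return(one(tf))
  tfs <- unique(e$tf)
  stats::setNames(lapply(tfs, one), tfs)
})

#' Parents (regulators) of a node
#' @param x a [SignedNetwork-class].
#' @param node target identifier.
#' @return character vector of TFs with an edge into `node`.
#' @export
setGeneric("parentsOf", function(x, node) standardGeneric("parentsOf"))

#' @rdname parentsOf
#' @export
setMethod("parentsOf", "SignedNetwork", function(x, node) {
  unique(x@edges$tf[x@edges$target %in% node])
})

setMethod("show", "SignedNetwork", function(object) {
  e <- object@edges
  cat("SignedNetwork:", length(unique(e$tf)), "TFs,",
      length(unique(e$target)), "targets,", nrow(e), "edges (",
      sum(e$sign > 0), "+ /", sum(e$sign < 0), "- );",
      object@dropped, "edge(s) dropped\n")
})

#' Per-TF differential activity calls
#'
#' Holds, for each (TF, treatment, time point), the activity state of the
#' TF's positive and negative effector function (assessed on its positive
#' and negative regulon respectively), the concordance label, and the
#' underlying Fisher p-values/FDRs.
#'
#' @slot table data.frame with columns `tf`, `treatment`, `time`,
#'   `pos_state`, `neg_state` (each one of `activated`, `inactivated`,
#'   `not_DA`, `removed_nonsensical`, `removed_deconvolution`),
#'   `concordance` (`concordant`, `discordant`, `unique`, `none`), and the
#'   raw p / FDR columns for the four regulon-direction comparisons.
#' @export
setClass("RegulonActivity", representation(table = "data.frame"))

setValidity("RegulonActivity", function(object) {
  t <- object@table
  need <- c("tf", "treatment", "time", "pos_state", "neg_state",
            "concordance")
  if (!all(need %in% names(t)))
    return(paste("activity table must have columns:",
                 paste(need, collapse = ", ")))
  states <- c("activated", "inactivated", "not_DA", "removed_nonsensical",
              "removed_deconvolution")
  if (nrow(t) && (!all(t$pos_state %in% states) ||
                  !all(t$neg_state %in% states)))
    return("invalid activity state")
  TRUE
})

#' @describeIn RegulonActivity-class full activity table accessor.
#' @param x,object a `RegulonActivity`.
#' @export
setGeneric("activityTable", function(x) standardGeneric("activityTable"))

#' @rdname RegulonActivity-class
#' @export
setMethod("activityTable", "RegulonActivity", function(x) x@table)

#' TFs active at a treatment/time
#'
#' A TF counts as active when at least one effector function is
#' differentially active (activated or inactivated) after any removals.
#'
#' @param x a [RegulonActivity-class].
#' @param treatment,time condition selectors.
#' @return character vector of active TFs.
#' @export
setGeneric("activeTfs", function(x, treatment, time)
  standardGeneric("activeTfs"))

#' @rdname activeTfs
#' @export
setMethod("activeTfs", "RegulonActivity", function(x, treatment, time) {
  t <- x@table
  da <- c("activated", "inactivated")
  sel <- t$treatment == treatment & t$time == time &
    (t$pos_state %in% da | t$neg_state %in% da)
  unique(t$tf[sel])
})

setMethod("show", "RegulonActivity", function(object) {
  t <- object@table
  da <- c("activated", "inactivated")
  cat("RegulonActivity:", length(unique(t$tf)), "TFs x",
      length(unique(paste(t$treatment, t$time))), "condition/time points;",
      sum(t$pos_state %in% da | t$neg_state %in% da),
      "differentially active entries\n")
})

#' Transcriptional-cascade explanation of synergistic regulators
#'
#' Result of classifying combination-only (synergistic) TFs and
#' synergistically expressed genes by the network mechanism that can account
#' for them (double-down, AND, mixed, same-time or previous-time
#' propagation).
#'
#' @slot tfLabels data.frame: `time`, `tf`, `mechanism`, `depth` (same-time
#'   propagation round at which the TF became explained; NA otherwise),
#'   `parents_used` (semicolon-joined).
#' @slot segLabels data.frame: `time`, `gene`, `mechanism`, `parents_used`.
#' @slot sets per-time list of the seven activity-pattern sets.
#' @export
setClass("CascadeExplanation",
         representation(tfLabels = "data.frame", segLabels = "data.frame",
                        sets = "list"))

#' @describeIn CascadeExplanation-class TF mechanism labels.
#' @param x,object a `CascadeExplanation`.
#' @export
setGeneric("tfLabels", function(x) standardGeneric("tfLabels"))

#' @rdname CascadeExplanation-class
#' @export
setMethod("tfLabels", "CascadeExplanation", function(x) x@tfLabels)

#' @describeIn CascadeExplanation-class SEG mechanism labels.
#' @export
setGeneric("segLabels", function(x) standardGeneric("segLabels"))

#' @rdname CascadeExplanation-class
#' @export
setMethod("segLabels", "CascadeExplanation", function(x) x@segLabels)

setMethod("show", "CascadeExplanation", function(object) {
  tl <- object@tfLabels
  expl <- sum(tl$mechanism != "UNEXPLAINED")
  cat("CascadeExplanation:", nrow(tl), "synergistic TF(s),", expl,
      "explained", sprintf("(%.0f%%);", if (nrow(tl)) 100 * expl / nrow(tl)
                           else 0),
      nrow(object@segLabels), "SEG(s) traced\n")
})
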