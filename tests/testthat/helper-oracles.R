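# Independent oracles used to cross-check the package implementations.
# Each is written from first principles (enumeration / direct definitions)
# and deliberately shares no code with the functions under test.

# Benjamini-Hochberg by direct step-up enumeration
oracleBH <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, n * p[ord[i]] / i)
    adj[ord[i]] <- prev
  }
  adj
}

# hypergeometric upper tail P(X >= k) by term-wise summation
oracleHyperTail <- function(k, setA, setB, N) {
  kk <- k:min(setA, setB)
  sum(choose(setA, kk) * choose(N - setA, setB - kk)) / choose(N, setB)
}

# Simes combination evaluated index by index on the sorted vector
oracleSimes <- function(p) {
  ps <- sort(p)
  best <- Inf
  for (i in seq_along(ps)) best <- min(best, length(ps) * ps[i] / i)
  best
}

# AUROC by explicit positive-negative pair counting
oracleAuroc <- function(score, label) {
  pos <- score[as.logical(label)]
  neg <- score[!as.logical(label)]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# cascade mechanism labels by direct rule-by-rule evaluation; an
# independent, unoptimized implementation of the precedence semantics
oracleCascade <- function(setsByTime, edges) {
  parentsOfNode <- function(node) unique(edges$tf[edges$target == node])
  nodes <- unique(c(edges$tf, edges$target))
  times <- names(setsByTime)
  labels <- list()
  explained <- list()
  for (ti in seq_along(times)) {
    s <- setsByTime[[ti]]
    sp <- if (ti > 1) setsByTime[[ti - 1]] else NULL
    ep <- if (ti > 1) explained[[ti - 1]] else character()
    lab <- stats::setNames(rep(NA_character_, length(s[["001"]])),
                           s[["001"]])
    joint <- function(par, ss) {
      dd <- length(intersect(par, ss[["111"]])) > 0
      a <- length(intersect(par, ss[["101"]])) > 0
      b <- length(intersect(par, ss[["011"]])) > 0
      if (dd && a && b) return("MIXED")
      if (a && b) return("AND")
      if (dd) return("DD")
      NA_character_
    }
    for (tf in s[["001"]]) {
      if (!(tf %in% nodes)) next
      m <- joint(parentsOfNode(tf), s)
      if (!is.na(m)) lab[tf] <- m
    }
    repeat {
      done <- names(lab)[!is.na(lab)]
      newly <- FALSE
      for (tf in s[["001"]]) {
        if (!is.na(lab[tf]) || !(tf %in% nodes)) next
        if (length(intersect(parentsOfNode(tf), done))) {
          lab[tf] <- "PROP_SAME"; newly <- TRUE
        }
      }
      if (!newly) break
    }
    for (tf in s[["001"]]) {
      if (!is.na(lab[tf]) || !(tf %in% nodes)) next
      if (!is.null(sp)) {
        m <- joint(parentsOfNode(tf), sp)
        if (!is.na(m)) {
          lab[tf] <- c(DD = "DD_PREV", AND = "AND_PREV",
                       MIXED = "DD_PREV")[[m]]
          next
        }
      }
      if (length(intersect(parentsOfNode(tf), ep))) lab[tf] <- "PROP_PREV"
    }
    lab[is.na(lab)] <- "UNEXPLAINED"
    labels[[times[ti]]] <- lab
    explained[[ti]] <- names(lab)[lab != "UNEXPLAINED"]
  }
  labels
}

# random seven-set activity pattern over a TF universe, pairwise disjoint
randomPatternSets <- function(tfs, pActive = 0.5) {
  pats <- c("100", "010", "001", "110", "101", "011", "111")
  assign <- sample(c(pats, "000"), length(tfs), replace = TRUE,
                   prob = c(rep(pActive / 7, 7), 1 - pActive))
  stats::setNames(lapply(pats, function(p) tfs[assign == p]), pats)
}
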