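emptySets <- function() {
  stats::setNames(lapply(1:7, function(i) character()),
                  c("100", "010", "001", "110", "101", "011", "111"))
}

test_that("pattern sets partition active TFs by their activity triple", {
  mkAct <- function(treatment, tfs) {
    new("RegulonActivity", table = data.frame(
      tf = tfs, treatment = treatment, time = 6,
      pos_state = "activated", neg_state = "not_DA",
      concordance = "unique"))
  }
  a <- mkAct("T", c("x", "z", "w"))
  b <- mkAct("M", c("y", "z", "w"))
  co <- mkAct("TM", c("x", "y", "z", "s"))
  sets <- classifyTfSets(a, b, co, "T", "M", "TM", 6)
  expect_identical(sets[["101"]], "x")
  expect_identical(sets[["011"]], "y")
  expect_identical(sets[["111"]], "z")
  expect_identical(sets[["110"]], "w")
  expect_identical(sets[["001"]], "s")
  ## pairwise disjoint
  all <- unlist(sets)
  expect_identical(anyDuplicated(all), 0L)
})

test_that("scenario fixtures are labeled exactly as planted", {
  cs <- simulateCascadeScenario(c(DD = 3, AND = 2), seed = 1)
  checkGroundTruth(cs)
  expl <- explainSynergisticTfs(cs$setsByTime, cs$network)
  tl <- tfLabels(expl)
  expect_identical(sum(tl$mechanism == "DD"), 3L)
  expect_identical(sum(tl$mechanism == "AND"), 2L)
  rep <- cascadeReport(expl)
  expect_equal(sum(rep$tf$n), 5)
  ## all-NONE scenario: explained fraction 0
  cs0 <- simulateCascadeScenario(c(DD = 0, NONE = 4), seed = 2)
  expl0 <- explainSynergisticTfs(cs0$setsByTime, cs0$network)
  expect_true(all(tfLabels(expl0)$mechanism == "UNEXPLAINED"))
  expect_equal(cascadeReport(expl0)$tf$explained_fraction[1], 0)
  ## MIXED TFs have parents in all three anchor sets by construction
  csM <- simulateCascadeScenario(c(MIXED = 1), seed = 3)
  e <- networkEdges(csM$network)
  par <- e$tf[e$target == "MIX01"]
  s2 <- csM$setsByTime[[2]]
  expect_true(all(c(any(par %in% s2[["111"]]), any(par %in% s2[["101"]]),
                    any(par %in% s2[["011"]]))))
  ## full scenario incl. propagation
  csF <- simulateCascadeScenario(
    c(DD = 2, AND = 1, MIXED = 1, PROP_SAME = 2, PROP_PREV = 1, NONE = 1),
    seed = 4)
  checkGroundTruth(csF)
  explF <- explainSynergisticTfs(csF$setsByTime, csF$network)
  tlF <- tfLabels(explF)
  got <- stats::setNames(tlF$mechanism, tlF$tf)
  truth <- csF$truth$cascade_mechanism
  expect_identical(got[names(truth)], truth)
})

test_that("infeasible scenario requests are rejected", {
  expect_error(simulateCascadeScenario(c(PROP_PREV = 1, DD = 1),
                                       times = c(0, 3)), "time point")
  expect_error(simulateCascadeScenario(c(PROP_SAME = 1)), "DD")
  expect_error(simulateCascadeScenario(c(DD = -1)), ">= 0")
})

test_that("a DD-fed chain propagates across time points", {
  ## A (111, t1) -> B (001, t1) -> C (001, t2): B is DD at t1, C is
  ## PROP_PREV at t2
  net <- SignedNetwork(data.frame(tf = c("A", "B"), target = c("B", "C"),
                                  sign = 1L))
  s1 <- emptySets(); s1[["111"]] <- "A"; s1[["001"]] <- "B"
  s2 <- emptySets(); s2[["001"]] <- "C"
  expl <- explainSynergisticTfs(list(`3` = s1, `6` = s2), net)
  tl <- tfLabels(expl)
  expect_identical(tl$mechanism[tl$tf == "B"], "DD")
  expect_identical(tl$mechanism[tl$tf == "C"], "PROP_PREV")
  ## same-time propagation depth is recorded
  net2 <- SignedNetwork(data.frame(tf = c("A", "B", "C"),
                                   target = c("B", "C", "D"), sign = 1L))
  s <- emptySets(); s[["111"]] <- "A"; s[["001"]] <- c("B", "C", "D")
  expl2 <- explainSynergisticTfs(list(`3` = s), net2)
  tl2 <- tfLabels(expl2)
  expect_identical(tl2$mechanism[tl2$tf == "B"], "DD")
  expect_identical(tl2$mechanism[tl2$tf == "C"], "PROP_SAME")
  expect_identical(tl2$depth[tl2$tf == "C"], 1L)
  expect_identical(tl2$depth[tl2$tf == "D"], 2L)
})

test_that("TFs absent from the network are unexplained regardless of sets", {
  net <- SignedNetwork(data.frame(tf = "A", target = "B", sign = 1L))
  s <- emptySets(); s[["111"]] <- "A"; s[["001"]] <- c("B", "ghost")
  tl <- tfLabels(explainSynergisticTfs(list(`3` = s), net))
  expect_identical(tl$mechanism[tl$tf == "ghost"], "UNEXPLAINED")
  expect_false(tl$in_network[tl$tf == "ghost"])
})

test_that("labels agree with the brute-force enumerator on random networks", {
  set.seed(11)
  for (rep in 1:25) {
    nTf <- sample(6:15, 1)
    tfs <- sprintf("T%02d", seq_len(nTf))
    nE <- sample(5:25, 1)
    edges <- unique(data.frame(tf = sample(tfs, nE, replace = TRUE),
                               target = sample(tfs, nE, replace = TRUE)))
    edges <- edges[edges$tf != edges$target, , drop = FALSE]
    if (!nrow(edges)) next
    edges$sign <- sample(c(-1L, 1L), nrow(edges), replace = TRUE)
    net <- SignedNetwork(edges)
    setsByTime <- list(`3` = randomPatternSets(tfs),
                       `6` = randomPatternSets(tfs))
    got <- tfLabels(explainSynergisticTfs(setsByTime, net))
    want <- oracleCascade(setsByTime, edges)
    for (tm in names(want)) {
      w <- want[[tm]]
      for (tf in names(w)) {
        expect_identical(
          got$mechanism[got$time == tm & got$tf == tf], unname(w[tf]),
          label = sprintf("rep %d, time %s, tf %s", rep, tm, tf))
      }
    }
    ## every synergistic TF receives exactly one label
    s001 <- unlist(lapply(setsByTime, `[[`, "001"))
    expect_identical(nrow(got), length(s001))
  }
})

test_that("SEGs are traced to the cascade with the documented precedence", {
  net <- SignedNetwork(data.frame(
    tf = c("P111", "P101", "P011", "B", "B", "Q101"),
    target = c("seg_dd", "seg_and", "seg_and", "seg_tgt", "seg_prev",
               "seg_and"),
    sign = 1L))
  s1 <- emptySets()
  s1[["111"]] <- "P111"; s1[["101"]] <- c("P101", "Q101")
  s1[["011"]] <- "P011"; s1[["001"]] <- "B"
  ## B is unexplained at t1 (no parents) -> seg_tgt cannot be TARGET_SAME
  s2 <- emptySets()
  netB <- SignedNetwork(rbind(networkEdges(net),
                              data.frame(tf = "P111", target = "B",
                                         sign = 1L)))
  expl <- explainSynergisticTfs(list(`3` = s1, `6` = s2), netB)
  segs <- list(`3` = c("seg_dd", "seg_and", "seg_tgt", "ghost"),
               `6` = c("seg_prev"))
  expl <- explainSegs(segs, expl, netB)
  sl <- segLabels(expl)
  lab <- stats::setNames(sl$mechanism, paste(sl$gene, sl$time))
  expect_identical(unname(lab["seg_dd 3"]), "DD")
  expect_identical(unname(lab["seg_and 3"]), "AND")
  expect_identical(unname(lab["seg_tgt 3"]), "TARGET_SAME")  # B is DD
  expect_identical(unname(lab["ghost 3"]), "UNEXPLAINED")
  expect_identical(unname(lab["seg_prev 6"]), "TARGET_PREV")
  rep <- cascadeReport(expl)
  expect_equal(rep$seg$explained_fraction[rep$seg$time == "3"][1], 0.75)
  expect_true(all(c("parent", "child") %in% names(rep$edges)))
})

test_that("explained fraction matches a planted 80% target construction", {
  ## 10 SEGs, 8 of them targets of an explained synergistic TF
  edges <- rbind(data.frame(tf = "P111", target = "B", sign = 1L),
                 data.frame(tf = "B", target = sprintf("s%d", 1:8),
                            sign = 1L))
  net <- SignedNetwork(edges)
  s <- emptySets(); s[["111"]] <- "P111"; s[["001"]] <- "B"
  expl <- explainSynergisticTfs(list(`3` = s), net)
  expl <- explainSegs(list(`3` = sprintf("s%d", 1:10)), expl, net)
  rep <- cascadeReport(expl)
  expect_equal(rep$seg$explained_fraction[1], 0.8)
})
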