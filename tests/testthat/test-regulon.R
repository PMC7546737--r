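test_that("network signing recovers monotone relations and drops noise edges", {
  set.seed(1)
  n <- 38
  x <- rnorm(n)
  Y <- rbind(tf1 = x, up = 2 * x + rnorm(n, 0, 0.1),
             down = -x + rnorm(n, 0, 0.1), noise = rnorm(n))
  colnames(Y) <- sprintf("s%d", 1:n)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(logCPM = Y))
  edges <- data.frame(tf = "tf1", target = c("up", "down", "noise",
                                             "absent"))
  expect_warning(net <- signNetwork(edges, se), regexp = NA)
  e <- networkEdges(net)
  expect_identical(e$sign[e$target == "up"], 1L)
  expect_identical(e$sign[e$target == "down"], -1L)
  expect_false("noise" %in% e$target)
  expect_gte(net@dropped, 1L)  # the unmeasured node
  expect_error(signNetwork(edges, se[, 1:3]), "4 samples")
})

test_that("guarded Fisher equals hypergeometric tail enumeration", {
  universe <- sprintf("g%d", 1:20)
  f <- guardedFisher(universe[1:5], universe[c(1:3, 10)], universe)
  expect_equal(f$p, 155 / 4845, tolerance = 1e-12)
  expect_false(f$guarded)
  ## guards
  expect_equal(guardedFisher(universe[1:2], universe[1:5], universe)$p, 1)
  expect_equal(guardedFisher(universe[1:5], universe[c(1, 10, 11)],
                             universe)$p, 1)
  ## oracle equivalence on random tables, N <= 30
  set.seed(2)
  for (i in 1:40) {
    N <- sample(8:30, 1)
    uni <- sprintf("u%d", 1:N)
    A <- sample(uni, sample(3:N, 1))
    B <- sample(uni, sample(3:N, 1))
    f <- guardedFisher(A, B, uni)
    if (!f$guarded)
      expect_equal(f$p, oracleHyperTail(length(intersect(A, B)),
                                        length(A), length(B), N),
                   tolerance = 1e-12)
  }
})

test_that("the four regulon comparisons map to effector states correctly", {
  universe <- sprintf("g%d", 1:200)
  regulon <- list(pos = universe[1:20], neg = universe[21:40])
  up <- universe[1:25]     # strongly hits the positive regulon
  down <- universe[150:170]
  rf <- regulonFisher(regulon, up, down, universe)
  expect_identical(nrow(rf), 4L)
  expect_lt(rf$p[rf$effector == "pos" & rf$direction == "up"], 1e-10)
  expect_equal(rf$p[rf$effector == "neg" & rf$direction == "down"], 1)
  ## empty up-set: all up comparisons guarded to 1
  rf0 <- regulonFisher(regulon, character(), down, universe)
  expect_true(all(rf0$p[rf0$direction == "up"] == 1))
})

makeActivityFixture <- function() {
  ## one TF whose positive regulon is enriched in up genes only
  universe <- sprintf("g%d", 1:200)
  edges <- data.frame(tf = "tfA", target = universe[1:20], sign = 1L)
  net <- SignedNetwork(edges)
  degs <- data.frame(gene = universe[1:25], treatment = "TM", time = 6,
                     direction = "up", logFC = 2, fdr = 1e-6)
  list(net = net, degs = degs, universe = universe)
}

test_that("differential activity uses the direction mapping and labels", {
  fx <- makeActivityFixture()
  act <- callDifferentialActivity(fx$net, fx$degs, "TM", times = 6,
                                  universe = fx$universe)
  tab <- activityTable(act)
  expect_identical(tab$pos_state, "activated")
  expect_identical(tab$neg_state, "not_DA")
  expect_identical(tab$concordance, "unique")
  ## add a negative regulon enriched in down genes: negative effector
  ## activated as well -> concordant
  edges2 <- rbind(networkEdges(fx$net),
                  data.frame(tf = "tfA", target = fx$universe[30:49],
                             sign = -1L))
  degs2 <- rbind(fx$degs,
                 data.frame(gene = fx$universe[30:52], treatment = "TM",
                            time = 6, direction = "down", logFC = -2,
                            fdr = 1e-6))
  act2 <- callDifferentialActivity(SignedNetwork(edges2), degs2, "TM",
                                   times = 6, universe = fx$universe)
  tab2 <- activityTable(act2)
  expect_identical(tab2$pos_state, "activated")
  expect_identical(tab2$neg_state, "activated")
  expect_identical(tab2$concordance, "concordant")
})

test_that("a regulon enriched in both directions is removed as nonsensical", {
  universe <- sprintf("g%d", 1:200)
  edges <- data.frame(tf = "tfA", target = universe[1:40], sign = 1L)
  degs <- rbind(
    data.frame(gene = universe[1:20], treatment = "TM", time = 6,
               direction = "up", logFC = 2, fdr = 1e-6),
    data.frame(gene = universe[21:40], treatment = "TM", time = 6,
               direction = "down", logFC = -2, fdr = 1e-6))
  act <- callDifferentialActivity(SignedNetwork(edges), degs, "TM",
                                  times = 6, universe = universe)
  expect_identical(activityTable(act)$pos_state, "removed_nonsensical")
})

test_that("planted TF activity is recovered with correct directions", {
  sens <- dir <- numeric(0)
  for (sd in 1:5) {
    na <- simulateNetworkActivity(nTfs = 25, nTargets = 250,
                                  statesPerCondition = 5,
                                  targetEffectSize = 1.5, minDegree = 10,
                                  seed = sd)
    de <- deAllConditions(na$se)
    degs <- callDegs(de, 0.05)
    act <- callDifferentialActivity(na$network, degs, "TM", times = 6,
                                    universe = rownames(na$se))
    act <- deconvolveRegulons(act, na$network, degs, 6, rownames(na$se))
    truth <- na$truth$tf_states$TM
    found <- activeTfs(act, "TM", 6)
    sens <- c(sens, mean(names(truth) %in% found))
    tab <- activityTable(act)
    ok <- vapply(names(truth), function(tf) {
      row <- tab[tab$tf == tf, ]
      want <- if (truth[[tf]] > 0) "activated" else "inactivated"
      isTRUE(row$pos_state == want) || isTRUE(row$neg_state == want)
    }, logical(1))
    dir <- c(dir, mean(ok[names(truth) %in% found]))
  }
  expect_gte(mean(sens), 0.9)
  expect_gte(mean(dir, na.rm = TRUE), 0.95)
})

test_that("null networks produce no differential activity", {
  na <- simulateNetworkActivity(statesPerCondition = 0, seed = 9)
  de <- deAllConditions(na$se)
  degs <- callDegs(de, 0.05)
  act <- callDifferentialActivity(na$network, degs, "TM", times = 6,
                                  universe = rownames(na$se))
  expect_length(activeTfs(act, "TM", 6), 0)
})

test_that("regulon deconvolution keeps independent TFs and removes shadows", {
  universe <- sprintf("g%d", 1:300)
  shared <- universe[1:30]
  exclA <- universe[31:60]   # carries its own signal
  exclB <- universe[61:90]   # no exclusive signal
  edges <- rbind(
    data.frame(tf = "tfA", target = c(shared, exclA), sign = 1L),
    data.frame(tf = "tfB", target = c(shared, exclB), sign = 1L))
  net <- SignedNetwork(edges)
  up <- c(shared, exclA)  # dysregulation hits the shared block and A only
  degs <- data.frame(gene = up, treatment = "TM", time = 6,
                     direction = "up", logFC = 2, fdr = 1e-8)
  act <- callDifferentialActivity(net, degs, "TM", times = 6,
                                  universe = universe)
  expect_setequal(activeTfs(act, "TM", 6), c("tfA", "tfB"))
  act2 <- deconvolveRegulons(act, net, degs, 6, universe)
  expect_identical(activeTfs(act2, "TM", 6), "tfA")
  tab <- activityTable(act2)
  expect_identical(tab$pos_state[tab$tf == "tfB"],
                   "removed_deconvolution")
  ## disjoint regulons: overlap test not significant, both retained
  edges3 <- rbind(
    data.frame(tf = "tfC", target = universe[101:130], sign = 1L),
    data.frame(tf = "tfD", target = universe[131:160], sign = 1L))
  net3 <- SignedNetwork(edges3)
  degs3 <- data.frame(gene = universe[101:160], treatment = "TM", time = 6,
                      direction = "up", logFC = 2, fdr = 1e-8)
  act3 <- callDifferentialActivity(net3, degs3, "TM", times = 6,
                                   universe = universe)
  act3 <- deconvolveRegulons(act3, net3, degs3, 6, universe)
  expect_setequal(activeTfs(act3, "TM", 6), c("tfC", "tfD"))
  ## identical regulons: exclusive sets empty, both removed
  edges4 <- rbind(
    data.frame(tf = "tfE", target = universe[201:230], sign = 1L),
    data.frame(tf = "tfF", target = universe[201:230], sign = 1L))
  net4 <- SignedNetwork(edges4)
  degs4 <- data.frame(gene = universe[201:230], treatment = "TM", time = 6,
                      direction = "up", logFC = 2, fdr = 1e-8)
  act4 <- callDifferentialActivity(net4, degs4, "TM", times = 6,
                                   universe = universe)
  act4 <- deconvolveRegulons(act4, net4, degs4, 6, universe)
  expect_length(activeTfs(act4, "TM", 6), 0)
})

test_that("SignedNetwork validity rejects malformed edge tables", {
  expect_error(SignedNetwork(data.frame(tf = "a", target = "b",
                                        sign = 2L)), "sign")
  expect_error(SignedNetwork(data.frame(tf = c("a", "a"),
                                        target = c("b", "b"),
                                        sign = c(1L, -1L))), "duplicate")
  net <- SignedNetwork(data.frame(tf = c("a", "a"), target = c("b", "c"),
                                  sign = c(1L, -1L)))
  expect_identical(regulons(net, "a"), list(pos = "b", neg = "c"))
  expect_identical(parentsOf(net, "b"), "a")
})
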