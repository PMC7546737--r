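makeToySe <- function(nGenes = 50, effect = 0, sd = 0.3, seed = 1,
                      nReps = 3) {
  set.seed(seed)
  samples <- data.frame(
    sample_id = c(paste0("DMSO_r", 1:nReps), paste0("T_r", 1:nReps)),
    treatment = rep(c("DMSO", "T"), each = nReps),
    time_h = 6, replicate = rep(1:nReps, 2),
    plate = "P1")
  base <- matrix(rnorm(nGenes * 2 * nReps, 8, sd), nGenes,
                 dimnames = list(sprintf("g%03d", 1:nGenes),
                                 samples$sample_id))
  base[, samples$treatment == "T"] <- base[, samples$treatment == "T"] +
    effect
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(logCPM = base),
    colData = S4Vectors::DataFrame(samples,
                                   row.names = samples$sample_id))
  se
}

test_that("low-count filter keeps genes with >= 3 expressed vehicle samples at one time", {
  samples <- data.frame(
    sample_id = sprintf("DMSO_t%d_r%d", rep(c(3, 6), each = 3), rep(1:3, 2)),
    treatment = "DMSO", time_h = rep(c(3, 6), each = 3),
    replicate = rep(1:3, 2), plate = "P1")
  counts <- rbind(
    allzero = rep(0L, 6),
    three_at_3h = c(1L, 1L, 1L, 0L, 0L, 0L),
    two_per_time = c(1L, 1L, 0L, 1L, 1L, 0L))
  colnames(counts) <- samples$sample_id
  kept <- filterLowCounts(counts, samples)
  expect_identical(rownames(kept), "three_at_3h")
  expect_error(filterLowCounts(counts, transform(samples, treatment = "T")),
               "vehicle")
})

test_that("TMM factors are 1 for identical and depth-scaled samples", {
  set.seed(4)
  counts <- matrix(rnbinom(200 * 4, mu = 100, size = 10), 200,
                   dimnames = list(sprintf("g%d", 1:200), NULL))
  counts <- cbind(counts, counts[, 1], counts[, 1] * 2L)
  colnames(counts) <- paste0("s", 1:6)
  samples <- data.frame(sample_id = paste0("s", 1:6), treatment = "DMSO",
                        time_h = 0, replicate = 1:6, plate = "P1")
  se <- tmmNormalize(counts, samples)
  f <- S4Vectors::metadata(se)$normFactors
  ## identical sample and exact 2x depth scaling: factors equal (depth is
  ## absorbed by the library size, not the factor)
  expect_equal(f[5], f[1], tolerance = 0.01)
  expect_equal(f[6], f[1], tolerance = 0.01)
  ## a single strongly inflated gene (100x, ~5% of the library) is trimmed
  ## away and barely moves the factor
  set.seed(6)
  big <- matrix(rnbinom(2000 * 4, mu = 100, size = 10), 2000)
  colnames(big) <- paste0("s", 1:4)
  rownames(big) <- sprintf("g%d", 1:2000)
  samples4 <- data.frame(sample_id = paste0("s", 1:4), treatment = "DMSO",
                         time_h = 0, replicate = 1:4, plate = "P1")
  fBig <- S4Vectors::metadata(tmmNormalize(big, samples4))$normFactors
  big2 <- big
  big2[1, 2] <- 10000L
  fBig2 <- S4Vectors::metadata(tmmNormalize(big2, samples4))$normFactors
  expect_lt(abs(fBig2[2] / fBig[2] - 1), 0.05)
})

test_that("null contrasts yield no rejections; planted effects are recovered", {
  seNull <- makeToySe(nGenes = 500, effect = 0, seed = 11)
  deNull <- differentialExpression(seNull, "T", 6)
  se3 <- sqrt(0.05 * 0.95 / 500)
  expect_lte(mean(deNull$fdr < 0.05), 0.05 + 3 * se3)
  seEff <- makeToySe(nGenes = 500, effect = 2, sd = 0.3, seed = 12)
  deEff <- differentialExpression(seEff, "T", 6)
  expect_gte(mean(deEff$fdr < 0.05), 0.95)
  expect_equal(mean(deEff$logFC), 2, tolerance = 0.1)
})

test_that("identical treatment and vehicle values give logFC 0 and p 1", {
  se <- makeToySe(nGenes = 20, effect = 0, sd = 0.3, seed = 13)
  SummarizedExperiment::assay(se, "logCPM")[, 4:6] <-
    SummarizedExperiment::assay(se, "logCPM")[, 1:3]
  de <- differentialExpression(se, "T", 6)
  expect_lt(max(abs(de$logFC)), 1e-12)
  expect_true(all(de$p > 0.999))
  expect_true(all(de$fdr > 0.999))
})

test_that("unmoderated statistics agree with limma's ordinary t", {
  skip_if_not_installed("limma")
  se <- makeToySe(nGenes = 100, effect = 1, sd = 0.4, seed = 14)
  de <- differentialExpression(se, "T", 6, shrink = 0)
  Y <- SummarizedExperiment::assay(se, "logCPM")
  design <- cbind(1, as.integer(grepl("^T_", colnames(Y))))
  fit <- limma::lmFit(Y, design)
  tOrd <- (fit$coefficients / fit$stdev.unscaled / fit$sigma)[, 2]
  expect_equal(unname(de$t), unname(tOrd[de$gene]), tolerance = 1e-8)
  expect_equal(unname(de$logFC), unname(fit$coefficients[de$gene, 2]),
               tolerance = 1e-10)
})

test_that("BH adjustment agrees with step-up enumeration", {
  set.seed(21)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))^sample(1:3, 1)
    expect_equal(stats::p.adjust(p, "BH"), oracleBH(p), tolerance = 1e-12)
  }
})

test_that("cutoff selection follows the whitelist and zero-time0 rules", {
  t0 <- data.frame(gene = c("EGR1", "FOS", "geneX"),
                   treatment = "T", time = 0, logFC = 1,
                   p = c(1e-26, 1e-21, 1e-11),
                   fdr = c(1e-25, 1e-20, 1e-10))
  expect_equal(as.numeric(
    selectFdrCutoff(t0, "whitelist", whitelist = c("EGR1", "FOS"))), 1e-10)
  ## enlarging the whitelist never lowers the cutoff
  expect_gte(as.numeric(selectFdrCutoff(
    t0, "whitelist", whitelist = c("EGR1", "FOS", "geneX"))), 1e-10)
  t0b <- transform(t0, fdr = c(0.002, 0.3, 0.9))
  expect_equal(as.numeric(selectFdrCutoff(t0b, "zero_time0")), 1e-3)
  expect_error(selectFdrCutoff(t0, "whitelist", whitelist = character()),
               "whitelist")
  expect_error(selectFdrCutoff(t0, "whitelist", whitelist = "EGR1",
                               grid = numeric()), "grid")
})

test_that("count-matched cutoff selection picks the most stringent feasible cutoff", {
  de <- data.frame(gene = rep(sprintf("g%d", 1:100), 2),
                   treatment = rep(c("T", "M"), each = 100),
                   time = 24, logFC = 1,
                   p = rep(10^-(seq(0.5, 50, length.out = 100)), 2))
  de$fdr <- de$p
  cut <- selectFdrCutoff(de, "count_matched",
                         referenceCounts = c(T = 50, M = 50))
  expect_true(sum(de$fdr < cut & de$treatment == "T") >= 50)
  expect_true(sum(de$fdr < cut / 10 & de$treatment == "T") < 50)
  expect_error(selectFdrCutoff(de, "count_matched",
                               referenceCounts = c(T = 1000)),
               "exceed")
})

test_that("DEG calling is monotone in the cutoff and splits by sign", {
  de <- data.frame(gene = sprintf("g%d", 1:20), treatment = "T", time = 6,
                   logFC = rep(c(2, -2), 10), p = seq(1e-6, 0.5,
                                                      length.out = 20))
  de$fdr <- stats::p.adjust(de$p, "BH")
  d1 <- callDegs(de, 1e-3); d2 <- callDegs(de, 0.05)
  expect_true(all(d1$gene %in% d2$gene))
  expect_setequal(unique(d2$direction[d2$logFC > 0]), "up")
  expect_identical(nrow(callDegs(de[0, ], 0.05)), 0L)
})

test_that("SEG identification is exact set arithmetic with Venn counts", {
  s <- identifySegs(c("a", "b", "c"), "a", character())
  expect_setequal(s$segs, c("b", "c"))
  expect_identical(unname(s$venn[["001"]]), 2L)
  expect_length(identifySegs(c("a", "b"), c("a", "x"), c("b"))$segs, 0)
  ## brute force over the Venn partition reproduces every region count
  set.seed(5)
  for (i in 1:10) {
    pool <- sprintf("g%d", 1:30)
    A <- sample(pool, 12); B <- sample(pool, 12); C <- sample(pool, 12)
    s <- identifySegs(C, A, B)
    for (pat in names(s$venn)) {
      inA <- substr(pat, 1, 1) == "1"; inB <- substr(pat, 2, 2) == "1"
      inC <- substr(pat, 3, 3) == "1"
      n <- sum(vapply(union(union(A, B), C), function(g)
        (g %in% A) == inA && (g %in% B) == inB && (g %in% C) == inC,
        logical(1)))
      expect_identical(unname(s$venn[[pat]]), n)
    }
  }
})

test_that("monotherapy correlation handles self, negation and collinearity", {
  de <- data.frame(gene = c("a", "b", "c"), logFC = c(1, 2, 3),
                   fdr = c(0.01, 0.01, 0.01))
  expect_equal(as.numeric(monotherapyCorrelation(de, de)), 1)
  neg <- transform(de, logFC = -logFC)
  expect_equal(as.numeric(monotherapyCorrelation(de, neg)), -1)
  dbl <- transform(de, logFC = 2 * logFC)
  expect_equal(as.numeric(monotherapyCorrelation(de, dbl)), 1)
  small <- transform(de, fdr = c(0.01, 0.5, 0.5))
  expect_error(monotherapyCorrelation(small, small), "fewer than 3")
})

test_that("planted monotherapy-effect correlation is recovered from the generator", {
  tc <- simulateTimecourseCounts(nGenes = 600, rho = 1,
                                 segFraction = 0, seed = 31)
  expect_equal(unname(stats::cor(tc$truth$effect_monoA,
                                 tc$truth$effect_monoB)), 1)
  rs <- vapply(1:3, function(sd) {
    tc <- simulateTimecourseCounts(nGenes = 600, rho = 0.9, seed = sd)
    cts <- filterLowCounts(tc$counts, tc$samples)
    se <- tmmNormalize(cts, tc$samples)
    deA <- differentialExpression(se, "T", 24)
    deB <- differentialExpression(se, "M", 24)
    as.numeric(monotherapyCorrelation(deA, deB))
  }, numeric(1))
  expect_true(all(rs >= 0.8 & rs <= 1))
})

test_that("SEG counts track phenotypic synergy in correlation", {
  a <- segEobAssociation(c(1, 4, 9, 16, 30), c(2, 8, 18, 30, 55))
  expect_equal(a$r[a$method == "spearman"], 1)
  expect_gt(a$r[a$method == "pearson"], 0.99)
  flat <- segEobAssociation(rep(5, 5), c(1, 2, 3, 4, 5))
  expect_true(all(flat$degenerate))
  expect_error(segEobAssociation(1:3, 1:3), "at least 4")
})
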