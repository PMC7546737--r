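## Seeded generators for every input the pipeline consumes, each returning
## a `truth` record so parameter recovery can be tested. All generators are
## deterministic given `seed`; per-generator offsets keep their streams
## independent when a single base seed is reused.

.SEED_OFFSETS <- c(viability = 101L, timecourse = 202L, network = 303L,
                   cascade = 404L, exons = 505L, pairs = 606L)

.setSeed <- function(seed, generator) {
  set.seed((as.integer(seed) + .SEED_OFFSETS[[generator]]) %% .Machine$integer.max)
}

.hillInhibition <- function(dose, ec50, h) {
  ifelse(dose <= 0, 0, dose^h / (dose^h + ec50^h))
}

#' Simulate a replicate viability surface for a drug pair
#'
#' Monotherapy inhibition follows a Hill curve per drug; the combination
#' inhibition is the Bliss expectation plus a constant synergy offset
#' (clipped to \[0, 1\]), so the noiseless Excess Over Bliss equals
#' `100 * synergyOffset` wherever clipping does not bind. Replicate
#' viabilities add Gaussian noise.
#'
#' @param hillA,hillB lists with `ec50` and `h` for the two drugs.
#' @param synergyOffset inhibition-fraction excess planted in the
#'   combination (0 = exactly Bliss-additive).
#' @param nDoses dose levels per drug (plus dose 0); log-spaced around the
#'   EC50.
#' @param nReps replicates (>= 1).
#' @param noiseSd replicate viability noise SD.
#' @param seed RNG seed.
#' @return list with `cube` (doses x doses x reps viability array, see
#'   [eobMatrix()]) and `truth` (`planted_eob` percent, per-pair
#'   `eob_postclip`, the dose grids and noiseless inhibition margins).
#' @export
simulateViabilitySurface <- function(hillA = list(ec50 = 10, h = 2),
                                     hillB = list(ec50 = 5, h = 2),
                                     synergyOffset = 0, nDoses = 5,
                                     nReps = 3, noiseSd = 0.02, seed = 1) {
  if (nReps < 1) stop("nReps must be >= 1")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  .setSeed(seed, "viability")
  dosesA <- c(0, hillA$ec50 * 2^seq(-2, 2, length.out = nDoses))
  dosesB <- c(0, hillB$ec50 * 2^seq(-2, 2, length.out = nDoses))
  if (any(dosesA[-1] <= 0) || any(dosesB[-1] <= 0))
    stop("dose grids must be positive")
  Ia <- .hillInhibition(dosesA, hillA$ec50, hillA$h)
  Ib <- .hillInhibition(dosesB, hillB$ec50, hillB$h)
  bliss <- outer(Ia, Ib, function(x, y) x + y - x * y)
  Ixy <- bliss
  interior <- outer(dosesA > 0, dosesB > 0, FUN = "&")
  Ixy[interior] <- pmin(pmax(bliss[interior] + synergyOffset, 0), 1)
  V <- 1 - Ixy
  cube <- array(rep(V, nReps), dim = c(length(dosesA), length(dosesB), nReps),
                dimnames = list(dose_a = dosesA, dose_b = dosesB,
                                replicate = seq_len(nReps)))
  cube <- cube + stats::rnorm(length(cube), 0, noiseSd)
  truth <- list(planted_eob = 100 * synergyOffset,
                eob_postclip = 100 * (Ixy - bliss),
                doses_a = dosesA, doses_b = dosesB,
                inhibition_a = Ia, inhibition_b = Ib)
  structure(list(cube = cube, truth = truth, seed = seed),
            class = c("synViability", "synData"))
}

.timeFactor <- function(t, h) t / (t + h)

#' Simulate a time-course RNA-seq count matrix with planted SEGs
#'
#' Negative-binomial counts with per-gene baselines. A fraction of genes
#' carry monotherapy log2 effects drawn from a bivariate normal with
#' correlation `rho`; the combination effect is their sum. A disjoint
#' fraction of genes are planted SEGs: no monotherapy effect, a
#' combination-only effect of `effectSizeLog2` (random sign). All effects
#' scale with the saturating time factor t/(t + `timeHalfSaturation`), so
#' the signal is zero at t = 0 and near-plateau by ~9 h. Each replicate is
#' processed on its own plate with per-(gene, plate) offsets.
#'
#' @param nGenes number of genes.
#' @param monoA,monoB,combo treatment labels (vehicle `"DMSO"` is always
#'   included).
#' @param times time points in hours, must include 0.
#' @param nReps replicates per condition/time.
#' @param rho correlation of the two monotherapy effect vectors, in
#'   \[-1, 1\].
#' @param deFraction fraction of genes with monotherapy effects.
#' @param segFraction fraction of genes planted as SEGs, in \[0, 1\].
#' @param effectSizeLog2 effect scale (log2 units); 0 plants nothing.
#' @param timeHalfSaturation half-saturation time (hours, default 4.5 so
#'   the response is near-plateau by 9 h).
#' @param dispersion negative-binomial dispersion.
#' @param plateEffectSd SD of per-(gene, plate) log2 offsets.
#' @param meanLog2Baseline,sdLog2Baseline baseline abundance distribution.
#' @param seed RNG seed.
#' @return list with `counts`, `samples` (sample sheet), and `truth`
#'   (`effect_monoA`/`effect_monoB`/`effect_combo` per gene, `seg_flags`,
#'   `de_status` gene x condition logical for t > 0, `rho`).
#' @export
simulateTimecourseCounts <- function(nGenes = 2000, monoA = "T", monoB = "M",
                                     combo = "TM",
                                     times = c(0, 3, 6, 9, 12, 24),
                                     nReps = 3, rho = 0.9,
                                     deFraction = 0.2, segFraction = 0.05,
                                     effectSizeLog2 = 2,
                                     timeHalfSaturation = 4.5,
                                     dispersion = 0.05, plateEffectSd = 0.1,
                                     meanLog2Baseline = 7,
                                     sdLog2Baseline = 1, seed = 1) {
  if (abs(rho) > 1) stop("rho must be in [-1, 1]")
  if (segFraction < 0 || segFraction > 1)
    stop("segFraction must be in [0, 1]")
  if (!0 %in% times) stop("times must include 0")
  .setSeed(seed, "timecourse")
  genes <- sprintf("G%04d", seq_len(nGenes))
  base <- pmax(stats::rnorm(nGenes, meanLog2Baseline, sdLog2Baseline), 1)
  nDE <- round(deFraction * nGenes)
  nSEG <- round(segFraction * nGenes)
  if (nDE + nSEG > nGenes) stop("deFraction + segFraction exceed 1")
  idx <- sample.int(nGenes, nDE + nSEG)
  deIdx <- idx[seq_len(nDE)]
  segIdx <- idx[nDE + seq_len(nSEG)]
  effA <- effB <- effSeg <- numeric(nGenes)
  if (nDE > 0 && effectSizeLog2 > 0) {
    Sigma <- matrix(c(1, rho, rho, 1), 2)
    ab <- MASS::mvrnorm(nDE, mu = c(0, 0), Sigma = Sigma)
    if (nDE == 1) ab <- matrix(ab, nrow = 1)
    ## magnitudes bounded away from 0 so every planted effect is a real
    ## effect; the monotone transform preserves the correlation structure
    ## (identical vectors at rho = 1)
    bound <- function(z) effectSizeLog2 * sign(z) * (1 + abs(z)) / 1.8
    effA[deIdx] <- bound(ab[, 1]); effB[deIdx] <- bound(ab[, 2])
  }
  if (nSEG > 0 && effectSizeLog2 > 0)
    effSeg[segIdx] <- sample(c(-1, 1), nSEG, replace = TRUE) * effectSizeLog2
  conditions <- c("DMSO", monoA, monoB, combo)
  condEffect <- function(cond) {
    switch(cond, DMSO = numeric(nGenes),
           `if`(cond == monoA, effA,
                `if`(cond == monoB, effB, effA + effB + effSeg)))
  }
  plateOffsets <- matrix(stats::rnorm(nGenes * nReps, 0, plateEffectSd),
                         nGenes, nReps)
  samples <- expand.grid(replicate = seq_len(nReps), time_h = times,
                         treatment = conditions, stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)
  samples$plate <- paste0("P", samples$replicate)
  samples$sample_id <- sprintf("%s_t%g_r%d", samples$treatment,
                               samples$time_h, samples$replicate)
  samples$drugs <- samples$treatment
  samples <- samples[, c("sample_id", "treatment", "drugs", "time_h",
                         "replicate", "plate")]
  counts <- matrix(0L, nGenes, nrow(samples),
                   dimnames = list(genes, samples$sample_id))
  for (i in seq_len(nrow(samples))) {
    s <- samples[i, ]
    eff <- condEffect(s$treatment) * .timeFactor(s$time_h, timeHalfSaturation)
    logmu <- base + eff + plateOffsets[, s$replicate]
    counts[, i] <- stats::rnbinom(nGenes, mu = 2^logmu,
                                  size = 1 / dispersion)
  }
  de <- matrix(FALSE, nGenes, 3,
               dimnames = list(genes, c(monoA, monoB, combo)))
  de[, monoA] <- effA != 0
  de[, monoB] <- effB != 0
  de[, combo] <- (effA + effB + effSeg) != 0
  truth <- list(effect_monoA = stats::setNames(effA, genes),
                effect_monoB = stats::setNames(effB, genes),
                effect_combo = stats::setNames(effA + effB + effSeg, genes),
                seg_flags = stats::setNames(effSeg != 0, genes),
                de_status = de, rho = rho,
                time_half_saturation = timeHalfSaturation)
  structure(list(counts = counts, samples = samples, truth = truth,
                 monoA = monoA, monoB = monoB, combo = combo, seed = seed),
            class = c("synTimecourse", "synData"))
}

#' Simulate a signed TF network with planted activity states
#'
#' Builds a scale-free-ish network (truncated power-law out-degrees,
#' exponent `outDegreeExponent`) with a fraction of repressive edges,
#' plants per-condition TF activity states, and emits a log2-CPM
#' expression matrix in which the targets of an activated TF shift by
#' `+sign * targetEffectSize` (inverted for inactivated TFs).
#'
#' @param nTfs,nTargets node counts.
#' @param outDegreeExponent power-law exponent (default 2).
#' @param negativeEdgeFraction fraction of repressive edges, in \[0, 1\].
#' @param conditions treatment labels receiving planted states.
#' @param statesPerCondition planted active TFs per condition.
#' @param targetEffectSize log2 shift of a regulated target.
#' @param minDegree,maxDegree out-degree truncation bounds.
#' @param nReps replicates per condition (plus vehicle).
#' @param noiseSd replicate noise SD (log2 units).
#' @param time nominal time point for the sample sheet.
#' @param seed RNG seed.
#' @return list with `network` ([SignedNetwork-class]), `se`
#'   (`SummarizedExperiment` of log2-CPM for vehicle + conditions) and
#'   `truth` (`tf_states`: condition -> named +1/-1 vector).
#' @export
simulateNetworkActivity <- function(nTfs = 30, nTargets = 300,
                                    outDegreeExponent = 2,
                                    negativeEdgeFraction = 0.3,
                                    conditions = "TM",
                                    statesPerCondition = 5,
                                    targetEffectSize = 2,
                                    minDegree = 10, maxDegree = 50,
                                    nReps = 3, noiseSd = 0.3, time = 6,
                                    seed = 1) {
  if (negativeEdgeFraction < 0 || negativeEdgeFraction > 1)
    stop("negativeEdgeFraction must be in [0, 1]")
  .setSeed(seed, "network")
  tfs <- sprintf("TF%02d", seq_len(nTfs))
  targets <- sprintf("G%04d", seq_len(nTargets))
  degPool <- minDegree:min(maxDegree, nTargets)
  degProb <- degPool^(-outDegreeExponent)
  edges <- do.call(rbind, lapply(tfs, function(tf) {
    d <- sample(degPool, 1, prob = degProb)
    data.frame(tf = tf, target = sample(targets, d),
               sign = sample(c(-1L, 1L), d, replace = TRUE,
                             prob = c(negativeEdgeFraction,
                                      1 - negativeEdgeFraction)))
  }))
  zeroDeg <- setdiff(tfs, unique(edges$tf))
  if (length(zeroDeg)) warning("TF(s) with zero targets: ",
                               paste(zeroDeg, collapse = ", "))
  network <- SignedNetwork(edges)
  states <- lapply(stats::setNames(conditions, conditions), function(cond) {
    act <- sample(tfs, min(statesPerCondition, nTfs))
    stats::setNames(sample(c(-1L, 1L), length(act), replace = TRUE), act)
  })
  genes <- c(tfs, targets)
  base <- stats::setNames(stats::rnorm(length(genes), 6, 1), genes)
  shiftFor <- function(cond) {
    shift <- stats::setNames(numeric(length(genes)), genes)
    st <- states[[cond]]
    for (tf in names(st)) {
      sub <- edges[edges$tf == tf, ]
      shift[sub$target] <- shift[sub$target] +
        st[[tf]] * sub$sign * targetEffectSize
      ## the TF itself moves with its activity state, so expression-based
      ## edge signing can recover the planted regulation signs
      shift[tf] <- shift[tf] + st[[tf]] * targetEffectSize
    }
    shift
  }
  allConds <- c("DMSO", conditions)
  samples <- expand.grid(replicate = seq_len(nReps), treatment = allConds,
                         stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  samples$time_h <- time
  samples$plate <- paste0("P", samples$replicate)
  samples$sample_id <- sprintf("%s_r%d", samples$treatment,
                               samples$replicate)
  samples$drugs <- samples$treatment
  samples <- samples[, c("sample_id", "treatment", "drugs", "time_h",
                         "replicate", "plate")]
  Y <- matrix(NA_real_, length(genes), nrow(samples),
              dimnames = list(genes, samples$sample_id))
  for (i in seq_len(nrow(samples))) {
    cond <- samples$treatment[i]
    shift <- if (cond == "DMSO") 0 else shiftFor(cond)
    Y[, i] <- base + shift + stats::rnorm(length(genes), 0, noiseSd)
  }
  se <- SummarizedExperiment(
    assays = list(logCPM = Y),
    colData = DataFrame(samples, row.names = samples$sample_id))
  structure(list(network = network, se = se,
                 truth = list(tf_states = states,
                              target_effect_size = targetEffectSize),
                 seed = seed),
            class = c("synNetworkActivity", "synData"))
}

#' Construct a cascade scenario with known mechanism labels
#'
#' Builds a network and per-time activity-pattern sets in which each
#' requested synergistic TF's mechanism is guaranteed by its parent set:
#' a DD TF has a single parent in (111); an AND TF one parent in (101)
#' and one in (011); a MIXED TF parents in all three; a PROP_SAME TF a
#' single explained synergistic parent at the same time; a PROP_PREV TF a
#' single parent that is an explained synergistic TF at the previous time
#' point; a NONE TF has no parents. Direct mechanisms and PROP_SAME are
#' planted at the second time point, PROP_PREV at the third.
#'
#' @param mechanismCounts named integer vector over
#'   `c("DD", "AND", "MIXED", "PROP_SAME", "PROP_PREV", "NONE")`
#'   (missing names = 0).
#' @param times time point labels (>= 2; >= 3 when PROP_PREV > 0).
#' @param seed RNG seed (edge signs only).
#' @return list with `network`, `setsByTime` (input for
#'   [explainSynergisticTfs()]) and `truth` (`cascade_mechanism`: named
#'   labels, `mechanism_counts`).
#' @export
simulateCascadeScenario <- function(mechanismCounts,
                                    times = c(0, 3, 6), seed = 1) {
  cnt <- stats::setNames(rep(0L, 6),
                         c("DD", "AND", "MIXED", "PROP_SAME", "PROP_PREV",
                           "NONE"))
  cnt[names(mechanismCounts)] <- as.integer(mechanismCounts)
  if (any(cnt < 0)) stop("mechanism counts must be >= 0")
  if (length(times) < 2) stop("need at least 2 time points")
  if (cnt["PROP_PREV"] > 0 && length(times) < 3)
    stop("PROP_PREV requires a time point after the planted one")
  if (cnt["PROP_SAME"] > 0 && cnt["DD"] == 0)
    stop("PROP_SAME TFs chain off a DD TF; request DD >= 1")
  if (cnt["PROP_PREV"] > 0 && cnt["DD"] == 0)
    stop("PROP_PREV TFs chain off a DD TF; request DD >= 1")
  .setSeed(seed, "cascade")
  t2 <- as.character(times[2])
  t3 <- if (length(times) >= 3) as.character(times[3]) else NULL
  anchors <- c(P111 = "A111", P101 = "A101", P011 = "A011")
  mkTfs <- function(mech, n) if (n > 0) sprintf("%s%02d", mech, seq_len(n))
    else character()
  tfsDD <- mkTfs("DD", cnt["DD"]); tfsAND <- mkTfs("AND", cnt["AND"])
  tfsMIX <- mkTfs("MIX", cnt["MIXED"])
  tfsPS <- mkTfs("PS", cnt["PROP_SAME"])
  tfsPP <- mkTfs("PP", cnt["PROP_PREV"])
  tfsNONE <- mkTfs("NONE", cnt["NONE"])
  edges <- rbind(
    if (length(tfsDD)) data.frame(tf = "A111", target = tfsDD),
    if (length(tfsAND)) rbind(data.frame(tf = "A101", target = tfsAND),
                              data.frame(tf = "A011", target = tfsAND)),
    if (length(tfsMIX)) rbind(data.frame(tf = "A111", target = tfsMIX),
                              data.frame(tf = "A101", target = tfsMIX),
                              data.frame(tf = "A011", target = tfsMIX)),
    if (length(tfsPS)) data.frame(tf = tfsDD[1], target = tfsPS),
    if (length(tfsPP)) data.frame(tf = tfsDD[1], target = tfsPP))
  if (is.null(edges))
    edges <- data.frame(tf = character(), target = character())
  edges$sign <- if (nrow(edges))
    sample(c(-1L, 1L), nrow(edges), replace = TRUE) else integer()
  network <- SignedNetwork(edges)
  emptySets <- stats::setNames(
    lapply(1:7, function(i) character()),
    c("100", "010", "001", "110", "101", "011", "111"))
  setsByTime <- stats::setNames(
    lapply(times, function(t) emptySets), as.character(times))
  setsByTime[[t2]][["111"]] <- "A111"
  setsByTime[[t2]][["101"]] <- "A101"
  setsByTime[[t2]][["011"]] <- "A011"
  setsByTime[[t2]][["001"]] <- c(tfsDD, tfsAND, tfsMIX, tfsPS, tfsNONE)
  if (!is.null(t3) && length(tfsPP))
    setsByTime[[t3]][["001"]] <- tfsPP
  mech <- c(stats::setNames(rep("DD", length(tfsDD)), tfsDD),
            stats::setNames(rep("AND", length(tfsAND)), tfsAND),
            stats::setNames(rep("MIXED", length(tfsMIX)), tfsMIX),
            stats::setNames(rep("PROP_SAME", length(tfsPS)), tfsPS),
            stats::setNames(rep("PROP_PREV", length(tfsPP)), tfsPP),
            stats::setNames(rep("UNEXPLAINED", length(tfsNONE)), tfsNONE))
  structure(list(network = network, setsByTime = setsByTime,
                 truth = list(cascade_mechanism = mech,
                              mechanism_counts = cnt),
                 seed = seed),
            class = c("synCascade", "synData"))
}

#' Simulate exon counts with planted combination-only exon skipping
#'
#' Gene-level effects are log-additive across the monotherapies and the
#' combination (so the synergistic exon contrast is null), except for
#' planted skipped exons, whose usage drops by `skipEffectLog2` in the
#' combination only.
#'
#' @param exonsPerGene named integer vector, gene -> number of exons
#'   (>= 1 each).
#' @param skippedExonPlan data.frame (`gene_id`, `exon_index`) of planted
#'   combination-only skipping; genes in the plan must have >= 2 exons.
#' @param monoA,monoB,combo treatment labels.
#' @param time time point.
#' @param nReps replicates per condition.
#' @param skipEffectLog2 log2 usage reduction of a skipped exon.
#' @param geneEffectSd SD of gene-level monotherapy effects.
#' @param dispersion negative-binomial dispersion.
#' @param seed RNG seed.
#' @return list with `counts`, `exonMap`, `samples` and `truth`
#'   (`skipped_exons` data.frame).
#' @export
simulateExonCounts <- function(exonsPerGene, skippedExonPlan = NULL,
                               monoA = "T", monoB = "M", combo = "TM",
                               time = 6, nReps = 3, skipEffectLog2 = 2,
                               geneEffectSd = 1, dispersion = 0.02,
                               seed = 1) {
  if (any(exonsPerGene < 1)) stop("each gene needs >= 1 exon")
  if (!is.null(skippedExonPlan) && nrow(skippedExonPlan)) {
    bad <- exonsPerGene[skippedExonPlan$gene_id] < 2
    if (any(is.na(bad)) || any(bad))
      stop("skipped-exon plan includes unknown or single-exon gene(s)")
  }
  .setSeed(seed, "exons")
  genes <- names(exonsPerGene)
  exonMap <- do.call(rbind, lapply(genes, function(g)
    data.frame(exon_id = sprintf("%s.e%d", g, seq_len(exonsPerGene[[g]])),
               gene_id = g, exon_index = seq_len(exonsPerGene[[g]]))))
  nExon <- nrow(exonMap)
  base <- stats::runif(nExon, 7, 10)
  effA <- stats::setNames(stats::rnorm(length(genes), 0, geneEffectSd),
                          genes)
  effB <- stats::setNames(stats::rnorm(length(genes), 0, geneEffectSd),
                          genes)
  skip <- numeric(nExon)
  if (!is.null(skippedExonPlan) && nrow(skippedExonPlan)) {
    key <- paste(exonMap$gene_id, exonMap$exon_index)
    hit <- match(paste(skippedExonPlan$gene_id,
                       skippedExonPlan$exon_index), key)
    if (any(is.na(hit))) stop("plan refers to exon(s) outside the gene map")
    skip[hit] <- -skipEffectLog2
  }
  conds <- c("DMSO", monoA, monoB, combo)
  samples <- expand.grid(replicate = seq_len(nReps), treatment = conds,
                         stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  samples$time_h <- time
  samples$plate <- paste0("P", samples$replicate)
  samples$sample_id <- sprintf("%s_r%d", samples$treatment,
                               samples$replicate)
  samples$drugs <- samples$treatment
  samples <- samples[, c("sample_id", "treatment", "drugs", "time_h",
                         "replicate", "plate")]
  condShift <- function(cond) {
    gEff <- switch(cond, DMSO = 0,
                   `if`(cond == monoA, effA[exonMap$gene_id],
                        `if`(cond == monoB, effB[exonMap$gene_id],
                             effA[exonMap$gene_id] + effB[exonMap$gene_id])))
    gEff + if (cond == combo) skip else 0
  }
  counts <- matrix(0L, nExon, nrow(samples),
                   dimnames = list(exonMap$exon_id, samples$sample_id))
  for (i in seq_len(nrow(samples))) {
    logmu <- base + condShift(samples$treatment[i])
    counts[, i] <- stats::rnbinom(nExon, mu = 2^logmu, size = 1 / dispersion)
  }
  truth <- list(skipped_exons = if (is.null(skippedExonPlan))
    data.frame(gene_id = character(), exon_index = integer())
    else skippedExonPlan,
    skip_effect_log2 = skipEffectLog2)
  structure(list(counts = counts, exonMap = exonMap, samples = samples,
                 truth = truth, monoA = monoA, monoB = monoB, combo = combo,
                 time = time, seed = seed),
            class = c("synExons", "synData"))
}

#' Simulate a drug-pair panel linking profile correlation to synergy
#'
#' Each pair receives a planted monotherapy-profile correlation; its
#' planted Excess Over Bliss is `corrToEobSlope * correlation` plus noise,
#' so correlation is predictive of synergy exactly to the extent the slope
#' says. Designated confounder pairs additionally share a block of
#' identical strong responses in both profiles (emulating a shared
#' toxicity signature): their realized correlation is high but their
#' planted EOB stays low - correlation is then necessary but not
#' sufficient for synergy.
#'
#' @param nPairs number of drug pairs (>= 10).
#' @param corrToEobSlope EOB percent per unit correlation.
#' @param noiseSd EOB noise SD (percent).
#' @param nGenes genes per monotherapy profile.
#' @param confounderPairs how many pairs get the confounder block.
#' @param confounderSetSize genes in the shared block.
#' @param eobThreshold label threshold: synergy when planted EOB exceeds
#'   it (default 10).
#' @param seed RNG seed.
#' @return list with `panel` (`pair_id`, `drug_a`, `drug_b`, `eob`,
#'   `label`, `confounded`), `profiles` (drug -> data.frame `gene`,
#'   `logFC`, `fdr`) and `truth` (planted correlations, EOBs, labels,
#'   confounder genes).
#' @export
simulateDrugPairPanel <- function(nPairs = 40, corrToEobSlope = 50,
                                  noiseSd = 2, nGenes = 500,
                                  confounderPairs = 0,
                                  confounderSetSize = 50,
                                  eobThreshold = 10, seed = 1) {
  if (nPairs < 10) stop("nPairs must be >= 10")
  if (confounderPairs > nPairs) stop("more confounder pairs than pairs")
  .setSeed(seed, "pairs")
  genes <- sprintf("G%04d", seq_len(nGenes))
  confGenes <- genes[seq_len(min(confounderSetSize, nGenes))]
  confIdx <- seq_along(confGenes)
  isConf <- c(rep(TRUE, confounderPairs),
              rep(FALSE, nPairs - confounderPairs))
  plantedCorr <- ifelse(isConf, stats::runif(nPairs, 0, 0.2),
                        stats::runif(nPairs, 0, 0.9))
  profiles <- list(); rows <- list()
  confSignal <- stats::rnorm(length(confGenes), 0, 3)
  for (p in seq_len(nPairs)) {
    dA <- sprintf("D%03da", p); dB <- sprintf("D%03db", p)
    z <- stats::rnorm(nGenes)
    c0 <- plantedCorr[p]
    a <- sqrt(c0) * z + sqrt(1 - c0) * stats::rnorm(nGenes)
    b <- sqrt(c0) * z + sqrt(1 - c0) * stats::rnorm(nGenes)
    a <- a * 1.5; b <- b * 1.5
    if (isConf[p]) { a[confIdx] <- confSignal; b[confIdx] <- confSignal }
    mkProfile <- function(v) {
      pval <- 2 * stats::pnorm(-abs(v) / 0.5)
      data.frame(gene = genes, logFC = v,
                 fdr = stats::p.adjust(pval, "BH"))
    }
    profiles[[dA]] <- mkProfile(a); profiles[[dB]] <- mkProfile(b)
    ## planted EOB follows the *realized* profile correlation over the
    ## union-of-DEGs gene set (the quantity the predictor measures), so a
    ## noiseless panel carries an exactly monotone correlation-EOB link.
    ## For confounded pairs the driving correlation excludes the shared
    ## confounder block: those pairs look correlated but gain no synergy.
    pa <- profiles[[dA]]; pb <- profiles[[dB]]
    sel <- pa$fdr < 0.1 | pb$fdr < 0.1
    if (isConf[p]) sel <- sel & !(genes %in% confGenes)
    realized <- stats::cor(pa$logFC[sel], pb$logFC[sel])
    eob <- corrToEobSlope * realized + stats::rnorm(1, 0, noiseSd)
    if (isConf[p]) eob <- min(eob, 0.8 * eobThreshold)
    plantedCorr[p] <- realized
    rows[[p]] <- data.frame(pair_id = sprintf("pair%03d", p),
                            drug_a = dA, drug_b = dB, eob = eob,
                            label = eob > eobThreshold,
                            confounded = isConf[p])
  }
  panel <- do.call(rbind, rows)
  structure(list(panel = panel, profiles = profiles,
                 truth = list(planted_correlation = plantedCorr,
                              planted_eob = panel$eob,
                              labels = panel$label,
                              confounder_genes = if (confounderPairs > 0)
                                confGenes else character()),
                 seed = seed),
            class = c("synPairPanel", "synData"))
}

#' Machine-check the ground-truth invariants of a synthetic fixture
#'
#' Verifies, by direct inspection, the structural guarantees each
#' generator promises: SEG flags imply combination-only effects,
#' planted cascade mechanisms are consistent with the emitted parent
#' sets, skipped exons belong to multi-exon genes, confounded pairs carry
#' low planted EOB.
#'
#' @param x an object returned by a `simulate*` generator.
#' @return `TRUE` (invisibly); stops with a message on violation.
#' @export
checkGroundTruth <- function(x) {
  stopifnot(inherits(x, "synData"))
  if (inherits(x, "synTimecourse")) {
    tr <- x$truth
    seg <- names(tr$seg_flags)[tr$seg_flags]
    if (length(seg)) {
      ok <- tr$de_status[seg, x$combo] &
        !tr$de_status[seg, x$monoA] & !tr$de_status[seg, x$monoB]
      if (!all(ok)) stop("SEG flag without combination-only DE status")
    }
  } else if (inherits(x, "synCascade")) {
    e <- networkEdges(x$network)
    m <- x$truth$cascade_mechanism
    sets2 <- x$setsByTime[[2]]
    for (tf in names(m)) {
      par <- e$tf[e$target == tf]
      ok <- switch(m[[tf]],
        DD = any(par %in% sets2[["111"]]) && !(any(par %in% sets2[["101"]]) &&
                                                 any(par %in% sets2[["011"]])),
        AND = any(par %in% sets2[["101"]]) && any(par %in% sets2[["011"]]) &&
          !any(par %in% sets2[["111"]]),
        MIXED = any(par %in% sets2[["111"]]) &&
          any(par %in% sets2[["101"]]) && any(par %in% sets2[["011"]]),
        PROP_SAME = all(par %in% sets2[["001"]]) && length(par) > 0,
        PROP_PREV = all(par %in% sets2[["001"]]) && length(par) > 0,
        UNEXPLAINED = length(par) == 0)
      if (!isTRUE(ok))
        stop("cascade truth inconsistent with parent set for ", tf)
    }
  } else if (inherits(x, "synExons")) {
    plan <- x$truth$skipped_exons
    if (nrow(plan)) {
      nex <- table(x$exonMap$gene_id)
      if (any(nex[plan$gene_id] < 2))
        stop("skipped exon planted in a single-exon gene")
    }
  } else if (inherits(x, "synPairPanel")) {
    conf <- x$panel[x$panel$confounded, , drop = FALSE]
    if (nrow(conf) && any(conf$label))
      stop("confounded pair labelled synergistic")
  }
  invisible(TRUE)
}
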