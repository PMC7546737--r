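## TSV + JSON are the canonical interchange formats: every stage reads and
## writes plain tables so runs are auditable and diffable.

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.readTsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

.writeCounts <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE)
  .writeTsv(df, path)
}

.readCounts <- function(path) {
  df <- .readTsv(path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$feature_id
  mat
}

#' Generate a self-contained synthetic demo dataset
#'
#' Emits, under `dir/inputs/`, every input the pipeline consumes - a
#' replicate viability matrix, a time-course count matrix with sample
#' sheet, exon counts with exon map, a TF-target edge list with an
#' expression matrix for signing and activity calling, a gene-set library,
#' and a drug-pair panel with monotherapy profiles - plus `config.yaml`
#' describing a full run. All parts derive from `seed`; identical seeds
#' reproduce the dataset byte for byte.
#'
#' @param dir destination directory (created).
#' @param seed base RNG seed.
#' @param nGenes,nTfs,nTargets,nPairs dataset sizes (defaults: 2000 genes,
#'   30 TFs with 300 targets, 40 drug pairs).
#' @param clusterRestarts k-means restarts recorded in the config.
#' @return the config file path (invisibly).
#' @export
makeDemo <- function(dir, seed = 1, nGenes = 2000, nTfs = 30,
                     nTargets = 300, nPairs = 40, clusterRestarts = 30) {
  inp <- file.path(dir, "inputs")
  dir.create(inp, recursive = TRUE, showWarnings = FALSE)
  viab <- simulateViabilitySurface(synergyOffset = 0.25, nDoses = 4,
                                   nReps = 3, noiseSd = 0.02, seed = seed)
  cube <- viab$cube
  long <- expand.grid(dose_a = as.numeric(dimnames(cube)[[1]]),
                      dose_b = as.numeric(dimnames(cube)[[2]]),
                      replicate = seq_len(dim(cube)[3]),
                      KEEP.OUT.ATTRS = FALSE)
  long$viability <- as.vector(cube)
  .writeTsv(long, file.path(inp, "viability.tsv"))

  tc <- simulateTimecourseCounts(nGenes = nGenes, seed = seed)
  .writeCounts(tc$counts, file.path(inp, "counts.tsv"))
  .writeTsv(tc$samples, file.path(inp, "samples.tsv"))

  exons <- simulateExonCounts(
    exonsPerGene = stats::setNames(rep(4L, 100), sprintf("SG%03d", 1:100)),
    skippedExonPlan = data.frame(gene_id = sprintf("SG%03d", 1:10),
                                 exon_index = 2L),
    seed = seed)
  .writeCounts(exons$counts, file.path(inp, "exon_counts.tsv"))
  .writeTsv(exons$exonMap, file.path(inp, "exon_map.tsv"))
  .writeTsv(exons$samples, file.path(inp, "exon_samples.tsv"))

  na <- simulateNetworkActivity(nTfs = nTfs, nTargets = nTargets,
                                conditions = c("T", "M", "TM"),
                                statesPerCondition = 5, seed = seed)
  .writeTsv(networkEdges(na$network)[, c("tf", "target")],
            file.path(inp, "network_edges.tsv"))
  .writeCounts(assay(na$se, "logCPM"), file.path(inp, "network_expr.tsv"))
  .writeTsv(as.data.frame(colData(na$se)),
            file.path(inp, "network_samples.tsv"))

  ## gene sets: one seeded with planted SEGs (should classify synergistic),
  ## one with monotherapy-DE genes, plus random sets
  set.seed(seed + 7)
  genes <- rownames(tc$counts)
  segGenes <- names(tc$truth$seg_flags)[tc$truth$seg_flags]
  segDir <- sign(tc$truth$effect_combo[segGenes])
  monoGenes <- names(tc$truth$effect_monoA)[tc$truth$effect_monoA > 0]
  sets <- list(seg_up_block = segGenes[segDir > 0],
               seg_down_block = segGenes[segDir < 0],
               mono_up_block = utils::head(monoGenes, 50))
  for (i in 1:5) sets[[paste0("random", i)]] <- sample(genes, 40)
  writeGmt(sets, file.path(inp, "gene_sets.gmt"))

  pp <- simulateDrugPairPanel(nPairs = nPairs, confounderPairs = 5,
                              seed = seed)
  .writeTsv(pp$panel, file.path(inp, "pair_panel.tsv"))
  profLong <- do.call(rbind, lapply(names(pp$profiles), function(d)
    data.frame(drug = d, pp$profiles[[d]])))
  .writeTsv(profLong, file.path(inp, "pair_profiles.tsv"))

  config <- list(
    seed = seed,
    inputs = list(viability = "inputs/viability.tsv",
                  counts = "inputs/counts.tsv",
                  samples = "inputs/samples.tsv",
                  exon_counts = "inputs/exon_counts.tsv",
                  exon_map = "inputs/exon_map.tsv",
                  exon_samples = "inputs/exon_samples.tsv",
                  network_edges = "inputs/network_edges.tsv",
                  network_expr = "inputs/network_expr.tsv",
                  network_samples = "inputs/network_samples.tsv",
                  gene_sets = "inputs/gene_sets.gmt",
                  pair_panel = "inputs/pair_panel.tsv",
                  pair_profiles = "inputs/pair_profiles.tsv"),
    treatments = list(monoA = "T", monoB = "M", combo = "TM"),
    de = list(cutoff_strategy = "zero_time0", shrink = 10),
    clustering = list(k = 4, restarts = clusterRestarts),
    splicing = list(fdr = 0.05),
    tf_activity = list(fdr = 0.05, time = 6),
    enrichment = list(strong = 1e-5, weak = 0.01, times = c(9, 12, 24)),
    prediction = list(union_fdr = 0.1, n_boot = 200)
  )
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  invisible(file.path(dir, "config.yaml"))
}

.validateConfig <- function(config) {
  checkFrac <- function(x, field) {
    if (!is.null(x) && (!is.numeric(x) || x <= 0 || x >= 1))
      stop("config validation error: field '", field,
           "' must be in (0, 1)", call. = FALSE)
  }
  checkFrac(config$splicing$fdr, "splicing.fdr")
  checkFrac(config$tf_activity$fdr, "tf_activity.fdr")
  checkFrac(config$enrichment$strong, "enrichment.strong")
  checkFrac(config$enrichment$weak, "enrichment.weak")
  checkFrac(config$prediction$union_fdr, "prediction.union_fdr")
  if (is.null(config$seed)) stop("config validation error: field 'seed' missing",
                                 call. = FALSE)
  invisible(config)
}

#' Run the full synergy pipeline from a config file
#'
#' Executes the stages in dependency order - phenotypic synergy scoring,
#' differential expression with cutoff selection and SEG calling, temporal
#' clustering, splicing synergy, TF activity with cascade explanation,
#' gene-set classification, and the correlation-based synergy predictor -
#' reading every input and writing every output through plain TSV/JSON
#' files. A `manifest.json` records the config, the seed and the MD5 of
#' every input and output, so a rerun with the same config reproduces the
#' outputs byte-identically.
#'
#' @param configPath path to a YAML config ([makeDemo()] writes one);
#'   input paths are resolved relative to its directory.
#' @param outDir output directory (default `<config dir>/output`).
#' @return the manifest (invisibly, as a list).
#' @export
runPipeline <- function(configPath, outDir = NULL) {
  config <- .validateConfig(yaml::read_yaml(configPath))
  root <- dirname(normalizePath(configPath))
  if (is.null(outDir)) outDir <- file.path(root, "output")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  inPath <- function(key) file.path(root, config$inputs[[key]])
  out <- function(name) file.path(outDir, name)
  monoA <- config$treatments$monoA
  monoB <- config$treatments$monoB
  combo <- config$treatments$combo
  outputs <- character()

  ## stage: phenotype
  long <- .readTsv(inPath("viability"))
  eob <- eobMatrix(viabilityCube(long))
  outputs <- c(outputs, .writeTsv(eob$table, out("eob.tsv")))

  ## stage: differential expression + SEGs
  counts <- .readCounts(inPath("counts"))
  samples <- .readTsv(inPath("samples"))
  counts <- filterLowCounts(counts, samples)
  se <- tmmNormalize(counts, samples)
  de <- deAllConditions(se, shrink = if (is.null(config$de$shrink)) 10 else config$de$shrink)
  cutoff <- selectFdrCutoff(de, strategy = config$de$cutoff_strategy,
                            whitelist = immediateEarlyGenes())
  degs <- callDegs(de, cutoff)
  outputs <- c(outputs, .writeTsv(de, out("de.tsv")),
               .writeTsv(degs, out("degs.tsv")))
  times <- sort(unique(de$time))
  segRows <- lapply(times, function(tm) {
    s <- identifySegs(degSet(degs, combo, tm),
                      degSet(degs, monoA, tm), degSet(degs, monoB, tm))
    if (length(s$segs)) data.frame(time = tm, gene = s$segs) else NULL
  })
  segTab <- do.call(rbind, segRows)
  if (is.null(segTab)) segTab <- data.frame(time = numeric(),
                                            gene = character())
  outputs <- c(outputs, .writeTsv(segTab, out("segs.tsv")))

  ## stage: temporal clustering (genes DE at >= 1 time in >= 1 condition)
  clusterGenes <- sort(unique(degs$gene[degs$treatment %in%
                                          c(monoA, monoB, combo)]))
  if (length(clusterGenes) > config$clustering$k) {
    fv <- buildFeatureVectors(se, c(monoA, monoB, combo), times,
                              genes = clusterGenes)
    cm <- kmeansRestarts(fv, k = config$clustering$k,
                         nRestarts = config$clustering$restarts,
                         seed = config$seed)
    outputs <- c(outputs, .writeTsv(
      data.frame(gene = names(cm$cluster), cluster = unname(cm$cluster)),
      out("clusters.tsv")))
  }

  ## stage: splicing synergy
  exonCounts <- .readCounts(inPath("exon_counts"))
  exonMap <- .readTsv(inPath("exon_map"))
  exonSamples <- .readTsv(inPath("exon_samples"))
  exonSE <- filterNormalizeExons(exonCounts, exonMap, exonSamples)
  see <- synergyContrast(exonSE, combo, monoA, monoB,
                         time = unique(exonSamples$time_h)[1])
  exonTest <- exonDeviationTest(see, fdrCutoff = config$splicing$fdr)
  spliced <- simesGeneTest(exonTest, cutoff = config$splicing$fdr)
  outputs <- c(outputs, .writeTsv(exonTest, out("exons.tsv")),
               .writeTsv(spliced, out("spliced_genes.tsv")))

  ## stage: TF activity + cascade
  netEdges <- .readTsv(inPath("network_edges"))
  netExpr <- .readCounts(inPath("network_expr"))
  netSamples <- .readTsv(inPath("network_samples"))
  netSE <- SummarizedExperiment(
    assays = list(logCPM = netExpr),
    colData = DataFrame(netSamples, row.names = netSamples$sample_id))
  network <- signNetwork(netEdges, netSE, fdr = config$tf_activity$fdr)
  universe <- rownames(netExpr)
  tfTime <- config$tf_activity$time
  netDe <- deAllConditions(netSE)  # expression already on the log2 scale
  netDegs <- callDegs(netDe, 0.05)
  act <- lapply(stats::setNames(c(monoA, monoB, combo),
                                c(monoA, monoB, combo)), function(tr) {
    a <- callDifferentialActivity(network, netDegs, tr, times = tfTime,
                                  universe = universe,
                                  fdr = config$tf_activity$fdr)
    deconvolveRegulons(a, network, netDegs, tfTime, universe,
                       fdr = config$tf_activity$fdr)
  })
  actTab <- do.call(rbind, lapply(act, activityTable))
  rownames(actTab) <- NULL
  outputs <- c(outputs, .writeTsv(actTab, out("tf_activity.tsv")))
  sets <- classifyTfSets(act[[monoA]], act[[monoB]], act[[combo]],
                         monoA, monoB, combo, tfTime)
  setsByTime <- stats::setNames(list(sets), as.character(tfTime))
  expl <- explainSynergisticTfs(setsByTime, network)
  segsByTime <- stats::setNames(
    list(segTab$gene[segTab$time == tfTime]), as.character(tfTime))
  expl <- explainSegs(segsByTime, expl, network)
  rep <- cascadeReport(expl)
  outputs <- c(outputs, .writeTsv(tfLabels(expl), out("cascade_tfs.tsv")))
  if (nrow(rep$tf))
    outputs <- c(outputs, .writeTsv(rep$tf, out("cascade_summary.tsv")))

  ## stage: gene-set enrichment + synergy classification
  geneSets <- readGmt(inPath("gene_sets"))
  degLists <- list()
  ## time 0 precedes any transcriptional response by design (only
  ## immediate early genes can move), so the sustained-enrichment clause
  ## is evaluated over post-induction time points; the config may narrow
  ## the window further (e.g. to the saturated phase of the response)
  times <- setdiff(times, 0)
  if (!is.null(config$enrichment$times))
    times <- intersect(times, config$enrichment$times)
  for (tm in times) {
    degLists[[combo]][[as.character(tm)]] <-
      list(up = degSet(degs, combo, tm, "up"),
           down = degSet(degs, combo, tm, "down"))
    degLists[["TUM"]][[as.character(tm)]] <-
      buildTum(degs, degs, monoA, monoB, tm)
  }
  enr <- enrichmentTable(geneSets, degLists, universe = rownames(counts))
  cls <- classifyGeneSets(enr, combo, "TUM",
                          strong = config$enrichment$strong,
                          weak = config$enrichment$weak)
  outputs <- c(outputs, .writeTsv(enr, out("enrichment.tsv")),
               .writeTsv(cls, out("gene_set_classes.tsv")))

  ## stage: synergy prediction
  panel <- .readTsv(inPath("pair_panel"))
  profLong <- .readTsv(inPath("pair_profiles"))
  profiles <- lapply(split(profLong, profLong$drug), function(d)
    d[, c("gene", "logFC", "fdr")])
  ranked <- rankPairs(panel, profiles,
                      unionFdr = config$prediction$union_fdr)
  perf <- data.frame(auroc = auroc(ranked$correlation, ranked$label),
                     aupr = aupr(ranked$correlation, ranked$label))
  outputs <- c(outputs, .writeTsv(ranked, out("pair_ranking.tsv")),
               .writeTsv(perf, out("prediction_performance.tsv")))

  manifest <- list(
    config = config,
    seed = config$seed,
    inputs = as.list(tools::md5sum(vapply(names(config$inputs), inPath,
                                          character(1)))),
    outputs = as.list(tools::md5sum(sort(outputs))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
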