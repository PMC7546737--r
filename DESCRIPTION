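Package: synersig
Title: Transcriptomic Characterization and Prediction of Drug-Combination Synergy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing and predicting drug-combination synergy
    from matched monotherapy/combination experiments. Implements phenotypic
    synergy scoring (Excess Over Bliss with propagated error, Loewe
    combination index via median-effect fits, sham self-combinations),
    differential expression against time-matched vehicle with
    immediate-early-gene anchored FDR cutoff selection, synergistically
    expressed gene (SEG) calling, temporal k-means clustering of
    condition-joined expression trajectories, synergistic exon usage with
    Simes gene-level aggregation, signed-regulon transcription factor
    activity inference with regulon deconvolution, transcriptional-cascade
    explanation of synergistic regulators (double-down, AND and propagation
    mechanisms), guarded Fisher gene-set synergy classification, and a
    monotherapy-correlation synergy predictor scored by AUROC/AUPR and
    bootstrap Bayes factors. Includes seeded synthetic-data generators with
    ground-truth records for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    edgeR,
    fgsea,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
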