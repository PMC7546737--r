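---
title: "Characterizing and predicting drug-combination synergy from matched transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing and predicting drug-combination synergy from matched transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synersig)
```

## The problem

When two drugs are combined, the phenotypic effect (loss of viability) can
exceed what either drug predicts — synergy — and the transcriptome offers a
molecular window on how that excess arises. `synersig` implements a
pipeline for matched monotherapy/combination experiments: triplicate
time-course RNA-seq of vehicle (DMSO), each monotherapy, and the
combination, alongside replicate dose-matrix viability measurements. Its
statistics answer three questions: *how synergistic is the combination
phenotypically*, *which genes, exons and transcription factors respond
only to the combination*, and *can synergy be predicted from the
monotherapies alone*.

## Phenotypic synergy

**Excess Over Bliss.** Under Bliss independence two non-interacting drugs
leave the surviving fraction $V_XV_Y = (1-I_X)(1-I_Y)$, where $I$ is the
inhibition fraction. The score

$$EOB = 100\,\big(I_{XY} - (I_X + I_Y - I_X I_Y)\big)$$

is positive under synergy and negative under antagonism, bounded by
$\pm 100$ for clamped inputs. Negative raw inhibitions (growth promotion)
are set to 0 before scoring; inhibitions above 1 (an artifact of
background-subtracted viability) are capped at 1 with a logged warning —
the score therefore never leaves its stated bounds. The propagated error

$$Error_{EOB} = 100\sqrt{SEM_X^2(1+I_Y^2-2I_Y) + SEM_Y^2(1+I_X^2-2I_X) + SEM_{XY}^2}$$

is reported on the same percent scale; the quadratic terms are
algebraically $(1-I)^2$, an identity the test suite verifies to $10^{-12}$.
`eobMatrix()` applies this per dose pair of a replicate viability cube and
reports the maximum over the matrix, the summary used to screen
combinations.

**Combination index.** Because a drug combined with itself can score a
positive EOB (a pure dose effect), the Loewe combination index is computed
as a complement: monotherapy curves are fitted to the median-effect
equation $f_a/(1-f_a) = (D/D_m)^m$ by least squares on the log-odds scale
($f_a$ values at 0 or 1 are clipped to $10^{-4}$, where the transform is
undefined), and $CI = d_1/D_1 + d_2/D_2$ with $D_k$ the monotherapy doses
matching the combination's effect. Any sham self-combination on exact
median-effect data yields $CI = 1$ regardless of the dose split — the
package's acceptance target — while `shamCombinationEOB()` quantifies how
much Bliss excess a mere dose increase produces.

## Differential expression and SEGs

Counts are filtered (a gene needs a count in at least three vehicle
samples at one time point), TMM-normalized via edgeR, and tested per
(treatment, time) against time-matched vehicle with a per-gene linear
model on log2-CPM including a plate covariate. With three replicates per
arm and plates blocked on replicates, only two residual degrees of freedom
remain per gene, so by default the residual variances are shrunk toward
the cross-gene mean with $d_0 = 10$ pseudo-degrees-of-freedom — the same
reason moderated-t pipelines exist. `shrink = 0` recovers plain OLS, which
the tests cross-check against limma's ordinary t-statistic. This engine is
deliberately simpler than a full mean–variance-weighted pipeline;
consequently published FDR values from such pipelines are not expected to
be reproduced numerically.

The FDR cutoff is selected from a powers-of-ten grid by one of three
strategies anchored on time 0, collected roughly 30 minutes
post-treatment, when only immediate early genes (FOS, EGR1, JUN, ...) can
plausibly respond: *whitelist* (largest cutoff at which every time-0 DEG
is a known immediate early gene), *zero_time0* (largest cutoff with no
time-0 DEGs at all), and *count_matched* (smallest cutoff giving at least
a reference number of DEGs per condition, to align separately-run
experiments). For count matching we follow the "lowest cutoff" reading:
the monotone alternative ("least stringent") is degenerate, since any
looser cutoff also satisfies the count condition.

A **synergistically expressed gene (SEG)** is a DEG of the combination
that is a DEG of neither monotherapy at the same time point — pure set
arithmetic over the Venn partition, reported with all seven region
counts. SEG counts correlate with EOB across conditions
(`segEobAssociation()` reports Pearson and Spearman coefficients).

## Temporal clustering

For each gene the pipeline concatenates vehicle-normalized mean
expression at each time in each of the three conditions (18 values for a
3-condition, 6-time design) with the consecutive-time deltas per condition
(15 values) — 33 values per gene, deltas deliberately unstandardized so
level and slope share a scale. Clustering is best-of-`nRestarts` k-means
(default 10,000 restarts, configurable down; Lloyd with k-means++ seeding
by default, Hartigan–Wong as an option — with that many restarts the
local-search flavor is immaterial on separated data). The elbow for $k$
is suggested by maximum curvature of the log-WCSS profile: past the true
cluster count the *relative* per-cluster gain collapses, which is a
curvature spike on the log scale regardless of absolute separations (the
raw-scale chord heuristic systematically under-shoots when separations
differ in magnitude). The full WCSS curve is always returned.

## Synergistic splicing

Exon-level log2-CPM enters the four-term contrast
$See = \overline{combo} + \overline{DMSO} - \overline{monoA} -
\overline{monoB}$, which is zero when the combination effect is
log-additive. Within each multi-exon gene, each exon's $See$ is compared
with the unweighted mean of the gene's other exons; the deviation is
tested with an unmoderated t (pooled within-group variance, Satterthwaite
degrees of freedom) and BH-adjusted across all exons genome-wide. Gene
level calls combine exon p-values with the Simes statistic
$p_{gene} = \min_i n\,p_{(i)}/i$, BH-adjusted across genes (thresholding
the raw Simes p instead is a switch, since "Simes-adjusted" is readable
both ways). Single-exon genes carry no within-gene contrast and are
excluded but recorded.

## TF activity and the transcriptional cascade

A directed TF→target network is signed by the Spearman correlation of TF
and target expression across all samples (BH across edges, FDR < 0.05 to
retain, sign of the correlation as the regulation sign). Each TF then has
a positive and a negative regulon, interrogated by four guarded one-sided
Fisher tests per treatment and time — positive/negative regulon ×
up/down DEGs — where tests with either set under 3 genes or overlap
under 2 return p = 1 rather than noise. P-values are pooled into one BH
family per treatment (all TFs × times × both effector functions). The
direction map is: positive regulon enriched in up-genes ⇒ positive
effector activated; positive×down ⇒ inactivated; negative×up ⇒
inactivated; negative×down ⇒ activated. An effector both activated and
inactivated is removed as nonsensical; concordance labels summarize the
two effector functions. Overlapping regulons are deconvolved: for
significantly-overlapping pairs of significant TFs, each TF survives only
if its *exclusive* target set remains enriched — so a shadow TF riding on
a shared block is removed while two independently supported TFs both
stay. We apply the overlap test to the significant effector's regulon
(the spec-level ambiguity) and remove a TF that fails the exclusive test
in any of its pairs.

The **cascade** classifies TFs at each time by their activity triple over
(monoA, monoB, combo): (101), (011), (111), and the synergistic (001)
set. Each synergistic TF is explained by the first matching rule:
**double-down** (a parent active in both monotherapies and the
combination), **AND** (one parent from each monotherapy-specific set,
none from (111)), **mixed** (both), same-time **propagation** from
already-explained synergistic TFs (iterated to a fixed point, depth
recorded), the same three conditions against the previous time point, or
previous-time propagation — else unexplained. Membership is
direction-agnostic ("active" = any differentially active effector), and
previous-time rules are evaluated only after the same-time fixed point,
matching the rule ordering; a mixed configuration at the previous time is
reported as DD_PREV since the label set has no mixed-previous class. SEGs
are traced analogously (direct (111)/AND parents, then targets of
explained TFs at the same or previous time). An independent brute-force
enumerator reproduces every label on random networks in the tests.

## Gene-set synergy classification

Guarded Fisher enrichment (same guards as above) is computed for each
gene set against up- and down-DEGs of the combination and of **TUM**, the
direction-wise union of the two monotherapies' DEGs — the additive
baseline. A set is *synergistic* when its combination enrichment is
strong at some time (FDR < $10^{-5}$) and sustained at all times
(FDR < 0.01) while TUM's is not; *additive* when TUM's enrichment itself
passes both. Directions are classified separately and the set takes its
best direction. The pipeline evaluates the sustained clause over
post-induction time points: at time 0 the DEG sets are empty by design,
which would guard every FDR to 1 and make the rule vacuous.

## Synergy prediction

For each drug pair the predictor computes the Pearson correlation of the
monotherapy log fold-change profiles over the union of genes with
FDR < 0.1 in either profile, optionally after removing an exclusion list
(e.g. a shared lysosomal-toxicity signature that inflates similarity
without synergy), and ranks pairs by descending correlation. Performance
against binary synergy labels is AUROC (Mann–Whitney with tie
correction) and AUPR (average precision). Two rankers are compared with a
bootstrap Bayes factor: pairs are resampled with replacement (stratified
within positives and negatives so every resample is scorable), and
$BF = (w_1 + t/2)/(w_2 + t/2)$ over wins and ties; identical rankers give
exactly 1, a ranker that wins every resample is reported capped at the
number of resamples. Stratification and tie-splitting are documented
choices where the underlying protocol is not fully specified.

## The synthetic-data generators

Every input has a seeded generator with a machine-checkable ground-truth
record (`checkGroundTruth()`); identical seeds reproduce outputs byte for
byte, and each generator draws from its own offset of a shared seed
namespace so fixtures are independent.

- **Viability surfaces**: Hill-curve monotherapies; combination
  inhibition = Bliss expectation + a constant offset, clipped to [0, 1];
  truth records the planted EOB ($100\times$ offset) and its post-clip
  value per dose pair. Replicates add Gaussian noise.
- **Time-course counts**: negative-binomial with per-gene baselines
  ($\log_2$ means $\sim N(7,1)$, dispersion 0.05 — a biological
  coefficient of variation of ~0.22, at the noisier end of what cell-line
  triplicates show). A `deFraction` of genes receive monotherapy effects
  whose signs and ordering come from a bivariate normal with correlation
  $\rho$ and whose magnitudes are bounded away from zero
  ($\text{effect}\cdot\text{sign}(z)(1+|z|)/1.8$): a raw bivariate draw
  would plant arbitrarily small "effects" whose truth labels no test
  could meaningfully recover. Combination effect = sum of monotherapy
  effects; a disjoint `segFraction` of genes are SEGs with a
  combination-only effect. All effects scale with $t/(t+4.5\,h)$ — zero
  at $t=0$, near-plateau by 9 h. Replicates sit on their own plates with
  per-(gene, plate) offsets, so the plate covariate in the DE model is
  load-bearing.
- **Signed networks with activity**: truncated power-law out-degrees
  (exponent 2, hub-like), 30% repressive edges; planted TF states shift
  each target by state × sign × effect and the TF's own expression
  likewise, so expression-based signing can recover the edge signs.
- **Cascade scenarios**: networks constructed so each requested
  mechanism label is guaranteed by direct parent-set inspection; the
  truth checker re-verifies this on every fixture.
- **Exon counts**: gene-level effects exactly log-additive across arms
  (null for the contrast), planted skipped exons reduced by 2 log2 units
  in the combination only; dispersion 0.02 (BCV ~0.14, typical of
  exon-level cell-line replicates), baselines well-expressed.
- **Drug-pair panels**: planted EOB = slope × the *realized*
  union-DEG profile correlation + noise, so a noiseless panel has an
  exactly monotone correlation→EOB link (the quantity the predictor
  measures is the one that drives synergy). Confounded pairs share an
  identical strong block in both profiles but their EOB is driven by the
  correlation excluding that block and capped below the label threshold:
  high correlation, no synergy — correlation as a necessary but not
  sufficient condition.

**What the generators do not emulate:** real library-size composition
effects, gene–gene correlation beyond the planted network, hormesis,
isoform structure, batch structure beyond plates, or any property of a
specific deposited dataset. Passing recovery tests therefore demonstrates
the estimators' correctness and calibration under the stated model, not
performance on any particular real dataset.

## Problem sizes and defaults used in validation

The shipped validation suite runs the demo pipeline at 600–2000 genes, 6
time points × 3 replicates, 15–30 TFs with 150–300 targets, 100 genes × 4
exons, and 15–40 drug pairs, with 10–30 k-means restarts; recovery runs
use 800 genes / 200 five-exon genes / 25 TFs over 3–10 seeds, and the
planted-EOB bias check averages 100 seeds. These sizes are chosen so each
statistic is estimated with comfortable power while a full validation run
remains a desk-scale computation; all of them scale up by argument.
SEG recovery is scored at the 24 h plateau with a fixed FDR 0.05 cutoff —
at saturating signal the combination/monotherapy distinction is sharpest,
which is what the truth labels describe.

## Known limitations

- The DE engine is a simplified moderated-OLS stand-in; exact agreement
  with voom/limma numerics is out of scope by design.
- The EOB bound $[-100, 100]$ is enforced via clamping; datasets scored
  without the negative-inhibition rule can exceed it and are not
  reproduced.
- Deconvolution removes a TF failing its exclusive-set test in *any*
  significant pair (conservative); a literal "remove all the rest"
  reading would also discard independently supported regulators.
- The cutoff-selection strategies assume time 0 carries no real response
  beyond immediate early genes; designs without an anchoring time point
  must supply a cutoff directly.

## A worked demo

```{r demo, eval = FALSE}
dir <- tempfile("synersig-demo")
makeDemo(dir, seed = 1)
manifest <- runPipeline(file.path(dir, "config.yaml"))
read.delim(file.path(dir, "output", "prediction_performance.tsv"))
```

`makeDemo()` writes every input as TSV/GMT plus a YAML config;
`runPipeline()` executes all stages and writes a manifest with the MD5 of
every input and output — rerunning the same config reproduces every
output byte-identically.
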