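---
title: "Scoring cis enhancer-gene regulatory links: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring cis enhancer-gene regulatory links: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enlink)
library(dplyr)
```

## The problem

Enhancers upregulate target-gene transcription in a cell type-specific way,
often over large genomic distances, and the target genes of most enhancers
are unknown. `enlink` casts enhancer-to-gene assignment as an imbalanced
binary classification problem over *cis pairs*: every (enhancer, gene)
combination whose enhancer intersects the window 1 Mb up- or downstream of
the gene's transcription start site (TSS). A trained classifier emits a raw
score in [0, 1] per pair and per cell type; higher scores indicate a higher
chance of an active regulatory relationship. Because the two classes are not
sampled in proportion to their (unknown) genome-wide frequencies, the raw
score is *not* a probability; it is comparable only within one cell type,
which is why per-cell-type Z-scores and percentile F(scores) are attached to
every pair.

## Dataset construction

**Positives** are literature-curated enhancer-gene links (or significant
CRISPR/CRISPRi screen hits). Curated intervals are mapped onto the enhancer
catalog when at least 33% of either region overlaps — the same either-region
fractional rule used everywhere in the package, implemented in
`meets_overlap_threshold()` and configurable to reciprocal semantics.

**Negatives** exploit chromatin accessibility: an enhancer that never
overlaps any DNase/FAIRE peak, or a gene whose body padded by 2 kb never
does, is treated as inaccessible, and every cis pair containing an
inaccessible member enters the negative universe. Because that universe is
enormous relative to the positives, `sample_matched_negatives()` draws up to
30 negatives per positive-set gene, uniformly without replacement, visiting
genes in sorted order under a single seed so the draw is reproducible and
independent of row order. Gene matching keeps the negatives in the same
genomic neighborhoods as the positives, so the classifier cannot separate
the classes on locus context alone. When a gene has fewer than 30 available
negatives the package takes all of them and warns; erroring or resampling
with replacement would either lose the gene or duplicate rows, and neither
seemed defensible.

## Features

Each pair receives up to nine main features:

| feature | type | meaning |
|---|---|---|
| `h3k27ac_enh` | binary | high H3K27ac over the enhancer |
| `h3k4me1_enh` | continuous | best H3K4me1 peak score over the enhancer |
| `h3k4me3_prom` | binary | high H3K4me3 over the promoter |
| `p300_enh` | continuous | best P300 peak score (structurally missing in some cell types) |
| `eqtl_z` | continuous | combined Z of eQTL p-values in the enhancer targeting the gene |
| `nearest_gene` | binary | is this gene the enhancer's nearest? |
| `intronic` | binary | is the enhancer inside an intron of this gene? |
| `eqtl_avg_abs_coef` | continuous | mean absolute eQTL slope |
| `h3k27ac_prom` | continuous | best H3K27ac peak score over the promoter |

plus eight interaction terms: the six enhancer-mark x promoter-mark products
(the promoter H3K27ac factor is the continuous score, the promoter H3K4me3
factor the binary call), the significance-by-effect product
`eqtl_z * eqtl_avg_abs_coef`, and the double enhancer mark
`h3k27ac_enh * h3k4me1_enh`. Interactions are exact products of the raw
factors, computed *before* standardization; continuous columns are then
rescaled to mean 0, sd 1 on the training rows only, and the training moments
are replayed onto any data the model later scores.

Choices worth calling out:

* **eQTL combination.** The combined significance feature uses Stouffer's
  method on one-sided z-values, `Z = sum(qnorm(1 - p)) / sqrt(k)`; a Fisher
  variant is available (`feature_config(eqtl_method = "fisher")`). Stouffer
  is the standard p-to-Z combination and degrades gracefully to 0 when no
  eQTL evidence exists. Note Z can be negative for large p; no clamping is
  applied since practically relevant eQTL tables carry small p-values.
* **Peak assignment.** A ChIP peak counts for an element when 50% of either
  region overlaps. With several qualifying peaks the maximum score is taken
  — the conservative single-peak reading; sum or mean would conflate peak
  fragmentation with signal strength.
* **Promoter extent.** TSS ± 1 kb, strand-aware and configurable; with
  symmetric extents the window is identical on both strands.
* **Missing vs absent evidence.** No peak or eQTL means a feature value of
  0 (absence of signal). P300 is the exception: some cell types simply have
  no P300 ChIP-seq data, so the column is `NA`-flagged and model routing
  (below) switches to the alternate feature space rather than imputing.
* **Distance anchor.** The nearest-gene flag measures enhancer midpoint to
  TSS, with equidistant ties broken by lexicographic gene id, so results do
  not depend on input order.

## Models, evaluation and selection

`train_model()` exposes a registry (`model_algorithms()`): the in-package
k-nearest-neighbors scorer (`k = 5` by default — a small odd default that
avoids vote ties), ridge logistic regression (`glmnet`), LDA, random forest,
and SVMs with Gaussian, Laplace and ANOVA radial-basis kernels (`kernlab`).
Default hyperparameters are used throughout; tuning is deliberately out of
scope. The k-NN score is the fraction of the k nearest standardized training
rows labeled positive, with distance ties resolved by training-row index.
SVM decision values pass through a logistic link (orientation checked at
training time and recorded), since margin scores are treated as scores, not
probabilities.

Performance is judged by the area under the precision-recall curve (AUPRC),
the right metric under heavy class imbalance, with ROC AUC as a companion.
`auprc()` uses average-precision step summation with tied scores grouped
into one threshold; trapezoidal PR interpolation is known to be biased and
is not used. The analytic baseline is the prevalence: a random classifier's
AUPRC equals the positive fraction of the dataset
(`random_baseline_auprc()`).

Model selection is cross-cell-type: `cross_cell_evaluate()` scores every
model on every dataset that shares no (enhancer, gene, cell type)
observation with its training data — the strictest reading of train/test
disjointness. `select_final_model()` keeps, per training set, the model
maximizing `min(AUPRC) + mean(AUPRC)` across its validation sets,
disqualifying any model whose minimum AUPRC falls below 0.10, and picks the
final winner across training sets by mean AUC; all ties break on model id.
`ablate_features()` then drops features one at a time, retraining and
re-measuring mean AUPRC, and repeats greedily while some drop improves it.

A single-feature reference model built on the signed midpoint distance
`gene_mid - enhancer_mid` (or its absolute value) is available via
`make_distance_dataset()`; any registry algorithm can be trained on it.

## Scoring and normalization

`score_cis_pairs()` scores each cell type's full cis-pair table with the
final model when the P300 feature is available, and with the alternate
(P300-free) model otherwise; a cell type missing anything beyond P300 is
reported as unscorable rather than silently imputed. Raw scores are then
normalized per cell type:

* **Z-score** — `(s - mean(s)) / sd(s)` with the sample sd (immaterial at
  genome scale; documented because the package is routinely run on small
  fixtures).
* **F(score)** — the weak percentile `#{scores <= s} / N`, so the maximum
  score always has F = 1 and tied scores share a percentile. Normalization
  always runs over *all* scored pairs of the cell type, never a subset.

`compare_link_sets()` partitions a score table into pairs that match a
reference link set (33% enhancer mapping + gene id) and the rest, and
contrasts the two score distributions with a two-sample Kolmogorov-Smirnov
test (asymptotic p-values; exact small-sample p is out of scope).
`regulatory_summary()` reports, over pairs with F(score) >= 0.95 by default,
the share of enhancers linked to more than one gene, the share of genes
linked to more than one enhancer, and the top-degree gene(s)/enhancer(s)
with all ties listed.

## The synthetic regulatory genome

Real training data for this problem requires curated literature links and
consortium-scale ChIP-seq/accessibility/eQTL releases, none of which belong
in a package. `simulate_regulatory_genome()` therefore builds a
self-contained toy genome: by default two 5 Mb chromosomes, 60 genes with
exon structure, 400 enhancers, and two emulated cell types that share
coordinates but redraw their own active links and peaks — which is exactly
what makes cross-cell-type transfer testable at toy scale.

Each cell type plants `n_active_links = 40` active pairs among accessible
elements. An active pair receives each supporting mark and 1-3 eQTLs
(p log-uniform in [1e-8, 1e-3], slopes Normal(0, 0.5)) independently with
probability `signal_strength = 0.9`; any element picks up a spurious mark or
a weak eQTL (p uniform in [0.05, 1]) with probability
`background_rate = 0.05`. Half of the enhancers (and a quarter of the genes)
are designated inaccessible and receive no accessibility peaks, seeding the
negative universe. Curated-link coordinates are jittered by up to 30% of the
enhancer length so the 33% mapping step is genuinely exercised. The bundle
is byte-deterministic given its config.

```{r planted, message = FALSE, warning = FALSE}
bundle <- simulate_regulatory_genome(synthetic_config(seed = 7))
train <- build_cell_dataset(bundle, "cell_1", seed = 11)
test  <- build_cell_dataset(bundle, "cell_2", seed = 12)
model <- train_model(train, "knn", seed = 3)
scores <- predict_scores(model, test)
c(auprc = auprc(scores, test$pairs$label),
  auc = roc_auc(scores, test$pairs$label),
  baseline = test$prevalence)
```

What passing on this fixture does and does not show: the generator produces
monotone feature-label relationships with independent noise, no chromatin-
domain structure, no correlated marks, no linkage between eQTLs, and no
systematic biases between "cell types". Recovery of planted signal
demonstrates that the pipeline wiring — mapping, negative sampling,
standardization, training, transfer, normalization — is correct, not that
any particular AUPRC is attainable on real epigenomes. The headline numbers
reported for real cell lines in the source literature require the original
ENCODE/GTEx-scale inputs and are out of reach of a desk-scale fixture; the
package's acceptance checks therefore verify analytic identities (baseline =
prevalence), oracle agreement for the metrics, contracts (sampling,
normalization, interactions), and planted-signal recovery instead.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open throughout (BED convention); readers
  convert on ingest, and half-open adjacency counts as disjoint.
* Zero-length intervals are rejected; constant feature columns are flagged
  and passed through unscaled; Z-scores on constant score vectors are an
  error rather than NaN.
* Genes without exon annotation treat the whole body as non-exonic for the
  intronic flag, with a data-quality warning.
* All stochastic steps (negative sampling, simulation, stochastic learners)
  take explicit integer seeds, and sampling iterates in sorted key order so
  results never depend on row order.
* Problem sizes used by the test-suite and acceptance runs (2 x 5 Mb
  genome, 60 genes, 400 enhancers, ~40 positives / ~1200 negatives per cell
  type) were chosen as the smallest fixture on which class imbalance,
  cross-cell transfer and the 30-per-gene sampling depth all behave as they
  would at scale.

## Known limitations

* The binary "high-signal" calls for H3K27ac (enhancer) and H3K4me3
  (promoter) accept a precomputed registry-style element list; when absent
  they fall back to the 50% peak rule, which is a simplification of how
  external registries define "high".
* Whether the 33% mapping rule should be either-region or reciprocal is
  genuinely ambiguous in the field; either-region is the default and both
  are supported.
* KS p-values are asymptotic; with heavily tied score distributions the D
  statistic is still exact but the p-value is approximate.
* Scores are relative within a cell type; no calibration to probabilities
  is attempted, by design.
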