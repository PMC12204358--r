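---
title: "Methods: detecting malignant transformation in NF1 nerve sheath tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting malignant transformation in NF1 nerve sheath tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Patients with neurofibromatosis type 1 (NF1) carry benign plexiform
neurofibromas (PN) that can progress through an atypical stage (AN) to
malignant peripheral nerve sheath tumor (MPNST), an aggressive sarcoma.
Tissue biopsy of these large, heterogeneous tumors under-samples malignant
foci, so two computational questions matter: (1) from single-cell RNA-seq
of a tumor, which cells are malignant and how confident is that call; and
(2) can the single-cell picture of the tumor microenvironment nominate
circulating proteins that detect malignancy from a blood draw.

`mpnstdetect` implements that chain end to end: single-cell quality
control, normalization and variable-gene selection; cluster composition
and a Pearson-residual enrichment score against the PN baseline;
reference-based cell-type label transfer with a per-cell confidence;
expression-based copy-number (CNV) inference with discrete state calling
and a per-cell aneuploidy score; a per-cell malignant score; and a plasma
proteomics workflow ending in a cross-validated SVM "MPNST probability
score". A synthetic-data module generates cell atlases and plasma cohorts
with planted ground truth, so every stage is testable at desk scale.

# Single-cell preprocessing

**QC.** Cells are removed when the number of detected genes falls below
300 or above 7,500, total counts fall below 500 or above 50,000, or the
mitochondrial count fraction exceeds 70%. All violations are strict
inequalities: a cell sitting exactly on a threshold (e.g. mitochondrial
fraction exactly 0.70) is retained. The 70% mitochondrial cutoff is
unusually permissive by general single-cell standards but is kept as the
protocol's stated value. `qc_filter()` is idempotent and logs
per-criterion removal counts.

**Normalization.** Library-size scaling to 10,000 counts followed by
log1p — `value = log(1 + count/colsum * 10^4)` — the convention of the
standard single-cell toolchain. It preserves the zero pattern and is
invariant to per-cell depth.

**Variable genes.** Genes are ranked by the z-score of their dispersion
(variance/mean of normalized expression) within 20 equal-occupancy
mean-expression bins; mitochondrial ("MT-") and ribosomal ("RPS"/"RPL")
genes are excluded before ranking. Zero-variance genes get a z of
negative infinity so a constant gene can never outrank a varying one, and
remaining ties break by gene name, making the ranking independent of the
input gene order. The default of 5,000 genes applies to genome-scale
data; the examples and tests use a few hundred, matched to the synthetic
gene counts.

**Clustering.** Downstream stages only need per-cell labels, so
clustering is a deterministic stand-in: PCA on the scaled variable genes
(30 components, capped at the data's dimensionality) followed by seeded
k-means with 10 restarts. Graph-based community detection would be a
drop-in replacement; on synthetic data the generator's truth labels can
bypass clustering entirely.

# Composition and enrichment

Cluster frequencies are computed within each pathology, and each
cluster's enrichment in AN or MPNST relative to PN is the Pearson
residual

$$s = \frac{f_{obs} - f_{exp}}{\sqrt{f_{exp}}},$$

where `f_exp` is the cluster's frequency in PN. PN scores are fixed at 0.
Two representation choices were genuinely open:

* **Residual vs relative change.** The defining formula could also be
  read as a relative change `(obs - exp)/exp`; the Pearson residual is
  used as the primary score (it matches the score's name) and the
  relative change is exposed alongside in the same table.
* **Scale.** Scores are kept on the fractional scale, with a
  `score_pct = 100 * score` column matching the percent display
  convention: the display clamp at +/- 50% and the panel-selection rule
  "enrichment score > 25" both live on the percent scale.

A cluster absent from PN (e.g. malignant cells) makes the residual
undefined; such clusters receive the clamp ceiling (+0.5, i.e. +50%) and
an `absent_in_baseline` flag, mirroring the visual treatment of
out-of-range scores.

**Markers.** One-vs-rest Wilcoxon rank-sum per gene (normal approximation
with tie and continuity correction, cross-checked against
`stats::wilcox.test` in the tests), with `avg_log2FC = log2(mean expm1
in + 1) - log2(mean expm1 out + 1)` and Bonferroni adjustment over the
genes tested. Genes detected in at least 25% of either the in-cluster or
out-cluster cells are eligible for testing (the toolchain's `min.pct`
semantics); the reported top-50 profile additionally requires in-cluster
detection of at least 25%, so every retained marker is expressed where it
is claimed. Ordering is avg_log2FC (descending), then adjusted p, then
gene name.

**Module activity** is the plain mean of normalized expression over a
gene set (the "average expression of the top 50 markers" definition). A
control-bin adjustment (subtracting the mean of expression-matched
control genes) is available behind the `control_bins` argument but is off
by default because the plain mean is the definition being reproduced.

# Label transfer

The reference model is a principal-component basis over the reference's
variable genes (per-gene centering and scaling stored with the basis;
component signs fixed by the largest-loading convention so fits are
reproducible). Query cells are projected with the *reference's* centering
and scaling; model genes missing from a query are imputed at the
reference mean, i.e. zero after centering. Class scores are a
distance-weighted k-nearest-neighbor vote in the embedding, weight
`1/(d + 1e-9)` with k = 30, normalized to sum to 1 per cell. The
predicted label is the argmax (ties break lexicographically) and
`prediction_score_max` — the confidence that feeds the malignant score —
is the maximum class score, bounded in [1/n_classes, 1].

This is a re-implementation of reference-based label transfer rather
than a wrapper around the anchor-based procedure of the original
toolchain: the downstream malignant score needs only a label and a
bounded confidence, and the kNN vote provides exactly that contract with
fully specified, testable behavior. Queries with under 50% of the model
genes are rejected rather than silently imputed.

# CNV inference and the malignant score

`infer_cnv_profile()` follows the standard expression-based CNV recipe:
drop genes with mean expression below 0.1 across all cells; subtract the
per-gene mean of the reference (presumed-diploid) cells — by default the
predicted pericyte, immune and endothelial cells; cap residuals at +/- 3;
order genes by genomic position (0-based half-open BED convention) and
smooth with a 101-gene centered moving average within each chromosome
(windows shrink at chromosome ends rather than padding); subtract each
cell's median to remove global shifts; and finally zero residuals within
+/- 1.5 global SDs of the smoothed reference residuals (denoising). The
window of 101 genes is the conventional default; chromosomes with fewer
than 3 surviving genes are excluded with a warning.

**State calling.** Smoothed residuals are thresholded into the six-state
convention with neutral = 3: gains 4/5/6 above 0.15/0.4/0.7, losses 2/1
below -0.15/-0.4. A hidden Markov model along the genome would add
positional persistence; fixed thresholds were chosen because they
reproduce the six-state output contract with fully testable behavior,
and an HMM upgrade is noted as future work.

**cnv score.** Per cell, `sum((state - 3)^2) / 2`. The defining formula
admits two readings (squared vs absolute deviation from neutral); the
squared form is primary and `method = "absolute"` gives
`sum(|state - 3|) / 2`. Both are non-negative, zero only for an
all-neutral cell, gene-order invariant and monotone in every
|state - 3|.

**Malignant score.** For each cell,

$$\text{malignant score} = \mathbb{1}[\text{predicted label is malignant}]
  \times \text{prediction.score.max} \times \text{cnv score},$$

with the malignant label set {"Malignant cell 1", "Malignant cell 2",
"Bridging malignant cell"}. The score is exactly 0 for any cell typed
non-malignant, regardless of its CNV profile. No confidence threshold is
imposed on transferred labels, matching the procedure being reproduced.

**Bridging-cell grouping.** Cells of the bridging malignant cluster are
grouped by Ward-linkage (ward.D2) hierarchical clustering of their
smoothed CNV profiles, cut at 8 groups by default.

# Plasma proteomics

**Preprocessing.** Values below a protein's limit of detection are
replaced by LOD/sqrt(2), then each protein is rescaled to mean 0 and SD 1.
The population (divide-by-n) SD is used; the choice is recorded and the
contract tested is the scaling itself, not the divisor. Zero-variance
proteins cannot be scaled and are dropped with a warning.

**Differential abundance.** Per protein, one-way ANOVA across the four
diagnosis groups and Tukey HSD for every group pair, computed in
vectorized form from the studentised-range distribution on the pooled
mean-square error (verified against `aov()`/`TukeyHSD()` in the tests).
Three p-values are reported for the MPNST-vs-PN contrast: the unadjusted
pooled-MSE t-test p (`p_mpnst_pn_raw`, the quantity that is uniform under
the null and therefore the one used for calibration checks), the Tukey
HSD p (family-adjusted within protein), and a Benjamini-Hochberg
adjustment of the Tukey p across proteins (`p_adj`). Whether a published
"adjusted p" means the Tukey or the across-protein adjustment is
ambiguous in general, which is why all three are emitted.

**Panel selection.** A protein enters the scRNA-seq-informed panel when
(1) it is elevated in MPNST plasma relative to PN (`p_adj < 0.05` and
delta NPX > 0); (2) its encoded gene (via a user-supplied exact-match
protein-to-gene table; no identifier services) is a cluster marker; and
(3) that cluster's MPNST-vs-PN enrichment exceeds 25 on the percent
scale. Each selected protein records its source cluster (the most
enriched cluster marking its gene). Recursive feature elimination is
named in the source protocol's heading but never specified, so it is
deliberately not implemented.

**Per-protein OVA metrics.** For each protein, the ROC of its NPX value
against MPNST-vs-everything (healthy included in the negative class):
trapezoid AUC and the Youden-optimal threshold (max sensitivity +
specificity - 1) with its operating point, plus panel-level
median/IQR summaries.

**Kernel selection.** Leave-one-out cross-validation over the panel for
each of the four kernels (linear, radial, polynomial, sigmoid), choosing
the highest LOOCV accuracy among kernels with AUC > 0.8; remaining ties
break by AUC, then fixed kernel order.

**MPNST probability score.** One-vs-all SVM (e1071, cost C = 1 to limit
overfitting at cohort sizes of ~10^2, Platt-calibrated probabilities)
under 10 repeats of stratified 5-fold cross-validation; each sample's
score is the median of its held-out probabilities over repeats. Fold
assignment is keyed to sorted sample ids and repeat seeds are
`base_seed + repeat`, so scores are invariant to input row order and
reproducible. `evaluate_model()` reports the ROC/AUC plus operating
points both at the fixed 0.5 threshold and at the Youden optimum.

# The synthetic-data generators

**Cell atlases** are gamma-Poisson (negative binomial, size 10): per-gene
log-normal base means, per-gene x per-cluster log-normal effects (SD =
`cluster_means_dispersion`), plus planted marker blocks (25 genes per
cluster at 4-fold by default) so marker recovery has a ground truth.
Malignant clusters — present only in MPNST by default, at 30% of MPNST
cells — have their expected counts multiplied by the configured CNV
segment fold-changes, matching the expression-dosage assumption that
underlies expression-based CNV inference. Mitochondrial and ribosomal
name blocks let the QC and gene-exclusion rules operate on realistic
names; low-quality cells are drawn as a 250-count multinomial with 80%
mitochondrial mass, so they violate the minimum-count threshold
deterministically. Cluster names come from a tumor-microenvironment pool
(fibroblast, Schwann cell, immune, endothelial, pericyte, ...) and
malignant clusters take the three malignant type names, so the default
reference-cell rule and malignant label set work unchanged on synthetic
data.

**Plasma cohorts** are simulated directly on the normalized (log2-like)
NPX scale — NPX is already logarithmic in concentration — as per-protein
baselines plus a mean shift in MPNST samples for the signal proteins plus
Gaussian noise, with per-protein LOD censoring at a configurable
quantile. The default cohort shape (healthy 10 / PN 29 / AN 25 / MPNST
54; 1,436 proteins) mirrors the study design this package models.

**What the generators do not emulate:** ambient RNA, doublets, batch
effects, UMI duplication, isoform structure, protein-protein correlation
structure, plate effects. Passing tests therefore demonstrate the
correctness and calibration of the computational chain under its own
assumptions, not performance on real tumors; no distributional
description of the real cohorts exists to calibrate against.

# Problem sizes and numerical choices

Tests and the acceptance script run at desk scale, chosen as the smallest
sizes at which the statistical properties under test are stable: atlases
of 1,000-1,500 genes and 1,200-5,000 cells (8-cluster/5,000-cell for
transfer accuracy; 1,500-gene with 350-gene planted gain and loss
segments for CNV detection), plasma cohorts of 118 samples with 200-1,436
proteins, 25-100 seeded null runs for calibration. Determinism contracts
are asserted bitwise. Degenerate inputs are handled explicitly: empty QC
results warn rather than error, constant proteins are dropped, constant
scores yield a flagged degenerate ROC with AUC 0.5, clusters below 3
cells are skipped in marker testing, and chromosomes with fewer than 3
usable genes are excluded from CNV smoothing.

# Known limitations

* Threshold-based CNV state calling has no positional persistence; an
  HMM would smooth single-gene state flips.
* The kNN label transfer assumes query and reference share a measurement
  platform; no cross-platform (cell vs nucleus) correction is applied.
* The enrichment score's residual-vs-relative-change ambiguity is
  resolved by exposing both; consumers should state which they use.
* Panel selection depends on exact gene-symbol matches between the
  protein assay and the single-cell reference.
* The integrated SVM's probability calibration is Platt scaling on
  training folds; probabilities near 0.5 should not be over-interpreted
  at these cohort sizes.
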