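---
title: "Nuclear morphometry and bag-of-visual-words slide classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear morphometry and bag-of-visual-words slide classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Some renal tumor subtypes that look alike to the eye differ in subtle,
population-level properties of their cell nuclei. The motivating contrast is
TFE3 Xp11.2 translocation renal cell carcinoma (TFE3-RCC) versus clear cell
RCC (ccRCC): on H&E-stained slides, TFE3-RCC tends to show more heterogeneous
nucleus sizes (more very small *and* very large nuclei), fewer perfectly
round nuclei, different staining intensity, and more tightly clumped cells.
None of these cues is decisive in a single field of view, but across the
tens of thousands of nuclei on a whole slide they become measurable.

`morphobow` implements the full quantification chain: segment every nucleus,
measure ten features per nucleus, compress each slide's nucleus population
into 150 image-level features with a bag-of-visual-words (BoVW) model,
screen the features statistically, and classify slides. Because real
whole-slide cohorts are large, access-restricted, and have no pixel-level
ground truth, the package is driven end-to-end by a synthetic H&E-like slide
generator whose every nucleus is known exactly. All package guarantees are
therefore statements about this generative model, and only qualitatively
about real tissue (see *Limitations*).

# The synthetic slide generator

A `class_generator` defines one tumor class as a set of sampling
distributions:

* **area** — a mixture of lognormals (pixels). The ccRCC-like preset uses a
  single component (`meanlog = log 300, sdlog = 0.25`); the TFE3-like preset
  a bimodal mixture (`log 150` and `log 600`, equal weights, `sdlog = 0.2`),
  encoding the "two extremes" size heterogeneity.
* **axis ratio** — `1 + Gamma(shape = 2, scale)`; scale 0.08 (round,
  ccRCC-like) or 0.20 (elongated, TFE3-like).
* **nuclear color** — per-channel Gaussian around a bluish-purple mean,
  constrained darker than the eosin-pink background (230, 200, 215). The
  TFE3-like preset is brighter in red (135, 95, 155) than the ccRCC-like
  (110, 85, 150), giving the red/green staining contrast a direction.
* **clumping** — a cluster process: parent points are scattered uniformly
  and each nucleus is placed inside a disk of `cluster_radius` around its
  parent (40 px / 8 per cluster for the TFE3-like preset, 150 px / 4 for
  the ccRCC-like one).

No quantitative effect sizes exist for these contrasts in the literature at
the level of generative parameters; the preset magnitudes were chosen once
as plausible for high-grade renal tumors and so that each contrast is
detectable by the screening stage on mid-sized cohorts, and they are not
tuned further.

Placement draws nuclei **largest first** and accepts a candidate position
only if the candidate ellipse, dilated by a 2-px guard ring, touches no
already-placed nucleus (a pixel-exact test, so elongated nuclei can pack
realistically tightly). If a cluster saturates, the nucleus is re-assigned
to another parent with a placement radius that grows geometrically, so
generation always terminates; after exhausting a retry budget it fails
loudly, reporting how many nuclei fit. Non-overlap is a deliberate
simplification: it keeps the segmentation ground truth unambiguous, while
clumping remains expressible through centroid distances. Additive Gaussian
pixel noise (default sigma 5 gray levels) is applied after rendering.
Determinism: a slide is a pure function of (generator, size, count, seed),
and cohort slides use `master seed + slide index`.

What the generator does **not** emulate: texture inside nuclei, chromatin
patterns, stromal and vascular structures, out-of-focus blur, overlapping
nuclei, and staining gradients. Passing tests therefore demonstrate the
correctness of the pipeline's computations, not state-of-the-art robustness
on real tissue.

# Stain normalization

Slides from different institutions differ in color. The normalizer works in
optical density, `OD = -log((I + 1)/256)`: background pixels (all-channel
OD below 0.15) are excluded, the two dominant stain directions are obtained
from an SVD plane fit to the tissue OD cloud followed by robust
extreme-angle selection (1st/99th percentile of angles within the plane),
negative components are clipped and vectors renormalized, and the vector
with the larger red-channel OD is labeled hematoxylin. Per-stain "maximum"
concentrations are 99th percentiles. Normalization rescales each pixel's
concentrations by the ratio of reference to source maxima and re-renders
with the reference vectors.

Two deliberate choices: (i) the estimator is a deterministic SVD/percentile
construction — the same interface as sparse-NMF-based structure-preserving
normalizers, with no iterative factorization; (ii) the OD component
orthogonal to the source stain plane is carried over unchanged rather than
discarded. The carried residual is what makes normalizing an image to its
own basis the identity up to quantization, keeps white background white,
and preserves image structure exactly (only colors move, never geometry).
Rank-deficient inputs (effectively one stain) fall back to a fixed standard
H&E basis for the missing vector.

By default the pipeline normalizes only the `external` split to the first
training slide's basis, matching the typical design where the discovery
cohort is internally consistent and only outside material needs mapping;
`normalize_splits = NULL` normalizes everything.

# Segmentation

Large images are subdivided into 2000 x 2000 tiles (stride
`tile - 2*overlap`, overlap 200 px). Each tile owns a *core* region — the
tile minus its overlap margins, extended at image borders — and the cores
partition the image exactly. Per tile:

1. The RGB tile is reduced to a nuclear-stain channel: hematoxylin
   concentration when a stain basis is supplied, otherwise the grayscale
   complement, scaled to 0–255 and lightly smoothed (Gaussian sigma 1).
2. Tiles with almost no stain contrast (robust spread < 30 gray levels) or
   almost no tissue (< 5% of pixels above OD 0.15) yield empty masks.
3. Multilevel Otsu with three classes (exhaustive two-threshold search
   maximizing between-class variance) marks the most stain-dense class as
   candidate nuclei.
4. Hierarchical refinement: any candidate component larger than 3x the
   median candidate area is re-thresholded with 2-class Otsu *inside the
   component*, splitting clumps that the global thresholds merged.
5. Holes are filled, objects below 40 px dropped, and touching nuclei are
   separated by watershed on the distance transform (EBImage), with a peak
   tolerance of 2 px chosen so that single elongated nuclei are not split
   while adjacent round nuclei are.

Stitching keeps a nucleus if and only if its centroid lies in its tile's
core, then relabels consecutively — every nucleus in an overlap band is
counted exactly once. On synthetic cohorts with default noise this pipeline
is held to a quality gate of recall and precision at least 0.95 at IoU 0.5,
which the test suite enforces.

All features are in raw pixel units; the package deliberately does not
assume a physical pixel size.

# Nucleus-level features

Ten features per nucleus: `area` (pixel count); `major`, `minor`, `ratio`
from the ellipse with the same normalized second central moments as the
component (regionprops convention, including the 1/12 pixel-variance
correction; axes floored at 1 px so single-pixel components keep a finite
ratio); `rMean`, `gMean`, `bMean` (channel means over the nucleus mask, on
the normalized image when normalization is active); and `distMean`,
`distMax`, `distMin` — the mean, maximum and minimum of the Euclidean
distances from the nucleus centroid to its k = 5 nearest neighbor centroids.
Neighbors are computed per slide, not per tile, so density features reflect
slide-level architecture; k caps at n−1, and slides with fewer than two
nuclei produce no records (the density features are undefined there).

# Image-level features

For each feature type, a codebook of 10 "words" is learned by 1-D K-means
(`stats::kmeans`, Hartigan–Wong with 10 restarts under a fixed seed, up to
10,000 nuclei sampled per slide) on nuclei pooled across **training slides
only**. Centroids are sorted ascending, so `area_bin1` … `area_bin10` always
read small → large. Each slide's values are assigned to their nearest word
(ties to the lower bin) and the counts L1-normalized — slides with different
nucleus counts become comparable, and duplicating every nucleus leaves the
histogram unchanged. Five distribution statistics complete each type: mean,
population (biased) standard deviation, population skewness, Pearson
(non-excess) kurtosis of the raw values, and Shannon entropy in bits of the
normalized histogram (0 for a one-hot histogram, log2(10) ≈ 3.32 for a
uniform one). 10 types x (10 bins + 5 stats) = 150 named features per
slide.

Moment conventions (population, Pearson) and entropy base 2 are fixed and
documented so that every number is reproducible; empty slides yield all-zero
rows with a warning and are meant to be excluded from modeling.

# Feature screening

Each of the 150 features is compared between classes with a two-sided
Mann–Whitney U test: exact null distribution when both groups have at most
8 tie-free observations, tie-corrected normal approximation with continuity
correction otherwise. P-values are adjusted by Benjamini–Hochberg, with
significance at adjusted p < 0.05. The fold change is the ratio of class
medians, comparison class over positive class; a significant feature is
*overrepresented* when its positive-class (TFE3-like) median is higher
(fold change < 1), *underrepresented* when lower. A zero positive-class
median is reported as an infinite fold change with a flag rather than an
error. Empirical FDR control is verified in the test suite on 200 simulated
null cohorts (identical generators for both arms).

# Classification

Features are reduced to 30 by greedy mRMR (MID difference variant):
relevance and redundancy are mutual information in bits after
equal-frequency discretization into 3 bins (features with at most 3
distinct values are used as-is; constant features get zero relevance). The
reported importance score is the mRMR objective value at the step each
feature was selected. Four models are supported — ridge-penalized logistic
regression (glmnet, lambda 0.01), linear and Gaussian-kernel SVM (e1071,
cost 1, gamma 1/(d·Var(X)) on the standardized matrix), and random forest
(500 trees, seeded) — all on features z-scored with training-fold
statistics. Classifier scores for the positive class feed ROC analysis:
AUC (equal to the normalized Mann–Whitney U, ties counted 1/2) with DeLong
95% confidence intervals via pROC, and operating points at the
Youden-optimal threshold (Youden index = sensitivity + specificity − 1).

Cross-validation is stratified; standardization and mRMR are refit inside
every fold, and when per-slide nucleus tables are supplied the codebook is
relearned per fold too, so no validation information leaks into the
representation. External evaluation freezes the entire training pipeline
(codebook, selected features, scaling, model) before scoring the held-out
cohort; permuting external labels provably cannot change the fitted
artifacts, which the tests assert.

# Problem sizes and numerical choices

The reference experiment in the test suite and the acceptance script uses
50 + 50 discovery slides and 12 + 12 external slides of 512 x 512 px with
120 nuclei each — large enough for every feature family to be screened and
for five-fold CV to be stable, small enough to run comfortably on one CPU.
The empirical-FDR simulation uses 200 null cohorts of 5 + 5 slides
(256 x 256 px, 40 nuclei), built from ground-truth nucleus tables so the
simulation measures the statistics, not the segmenter. Other fixed choices:
histogram ties go to the lower bin; K-means uses 10 restarts rather than a
k-means++ initialization (not available in `stats::kmeans`; restarts serve
the same robustness goal); mRMR ties resolve by column order, making
selection fully deterministic.

# Limitations

* Guarantees are relative to the generative model; real H&E tissue has
  overlapping nuclei, texture, and artifacts this package's segmenter is
  not hardened against.
* The stain normalizer is a deterministic deconvolution construction, not a
  sparse-NMF factorization; extremely stain-unbalanced images rely on its
  fixed fallback basis.
* Density features use a dense distance matrix per slide, which is the
  right tool up to a few thousand nuclei per slide but would need a spatial
  index at true whole-slide scale.
* The classifiers use fixed, conventional hyperparameters; no tuning is
  performed, by design, to keep results reproducible.
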