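# morphobow

Quantitative nuclear morphometry and bag-of-visual-words classification
for H&E histology slides.

## What problem this solves

Some renal cell carcinoma subtypes are hard to tell apart by eye.
TFE3 Xp11.2 translocation RCC (TFE3-RCC) closely mimics clear cell RCC
(ccRCC) on routine H&E slides, yet the two differ in population-level
properties of their cell nuclei: TFE3-RCC tends to have more heterogeneous
nucleus sizes (excesses of both very small and very large nuclei), fewer
perfectly round nuclei, different staining intensity, and more tightly
clumped cells. `morphobow` is for image-analysis and computational
pathology researchers who want a tested, fully reproducible implementation
of the classical feature-engineering pipeline for this kind of two-class
slide comparison — from pixels to ROC curves — plus a synthetic slide
generator that provides exact ground truth for benchmarking every stage.

## The method

1. **Segmentation.** Slides are tiled (2000 × 2000, 200 px overlap) and
   nuclei segmented by hierarchical multilevel thresholding: 3-class Otsu
   on a nuclear-stain channel selects the stain-dense class, oversized
   components are re-thresholded internally to split clumps, and touching
   nuclei are separated by watershed on the distance transform. Tile masks
   are stitched with centroid-in-core de-duplication.
2. **Nucleus-level features.** For each nucleus *i*: area `a_i`, ellipse
   axes `major_i >= minor_i` from the second-moment ellipse fit,
   `ratio_i = major_i / minor_i`, channel means `rMean, gMean, bMean`, and
   the mean/max/min distance from its centroid to its k = 5 nearest
   neighbors (`distMean, distMax, distMin`).
3. **Image-level features (bag of visual words).** Per feature type, 10
   "words" `w_1 < … < w_10` are learned by K-means on training-set nuclei;
   a slide's nuclei are assigned to their nearest word and counts are
   L1-normalized, giving bins `f_bin1 … f_bin10`. Five distribution
   statistics (mean, population SD, skewness, Pearson kurtosis, and
   entropy −Σ pᵢ log₂ pᵢ of the normalized histogram) complete each type:
   10 × (10 + 5) = **150 features per slide**.
4. **Screening.** Two-sided Mann–Whitney U per feature with
   Benjamini–Hochberg FDR at 5%; fold change = median(ccRCC)/median(TFE3);
   significant features are called over-/under-represented with respect to
   the TFE3-like class.
5. **Classification.** mRMR (MID variant, mutual information on
   equal-frequency bins) selects 30 features; ridge logistic regression,
   linear/Gaussian SVM and random forest are trained on z-scored features
   and evaluated by stratified 5-fold CV and/or frozen-model external
   validation with AUC, DeLong 95% CI, and the Youden-optimal operating
   point (Youden index = sensitivity + specificity − 1).

Color differences between slide sources are handled by a stain
deconvolution normalizer (SVD plane fit in optical density, robust
extreme-angle stain vectors, concentration rescaling to a reference
image).

## Worked example

```r
library(morphobow)

# a 10-vs-10 synthetic cohort with the built-in class contrasts
coh <- generate_cohort(tfe3_like_generator(), ccrcc_like_generator(),
                       n_per_class = 10, size_hw = c(512, 512),
                       n_nuclei = 120, seed = 42)
labels <- vapply(coh, function(s) s$class_label, "")

res <- run_pipeline(coh, labels,
                    config = pipeline_config(normalize = FALSE, n_folds = 5,
                      models = list(svm_gaussian = model_spec("svm_gaussian"))))

dim(res$features)
#> [1]  20 150

sig <- subset(res$comparisons, significant)
nrow(sig)
#> [1] 116
head(sig[order(sig$p_adjusted),
         c("feature", "p_adjusted", "fold_change", "representation")], 5)
#>     feature   p_adjusted fold_change   representation
#> 1 area_bin1 0.0003653436  0.04347826  overrepresented
#> 2 area_bin2 0.0003653436  3.29411765 underrepresented
#> 3 area_bin3 0.0003653436         Inf underrepresented
#> 4 area_bin4 0.0003653436         Inf underrepresented
#> 5 area_bin5 0.0003653436  3.20000000 underrepresented

res$cv$svm_gaussian$auc_mean
#> [1] 1
```

Reading the output: each slide is summarized by 150 features; 116 of them
differ significantly between the two synthetic classes after FDR
correction. `area_bin1` (the proportion of the very smallest nuclei) is
*overrepresented* in the TFE3-like class — its fold change
(ccRCC-median / TFE3-median) is far below 1 — while the mid-size bins
`area_bin2…bin5` are *underrepresented* there, exactly the
"sizes pushed to both extremes" signature the generator encodes. An `Inf`
fold change simply means the TFE3-like median for that bin is zero (no
mid-sized nuclei at all on most such slides); it is flagged, not an error.
With contrasts this strong the cross-validated AUC of the Gaussian-kernel
SVM is 1.

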