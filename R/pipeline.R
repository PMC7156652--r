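#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis: color normalization,
#' tiling/segmentation, neighbor count for density features, codebook
#' learning, the significance level for feature screening, and the model
#' specifications to cross-validate.
#'
#' @param normalize whether to color-normalize slides to a reference slide
#'   before feature extraction (default TRUE). By default only slides whose
#'   manifest split is `"external"` are normalized, mirroring the common
#'   situation where the validation cohort comes from other institutions;
#'   set `normalize_splits = NULL` to normalize everything.
#' @param normalize_splits character vector of splits to normalize, or NULL
#'   for all.
#' @param reference_slide index (into the slide list) of the reference
#'   slide whose stain basis defines the target appearance; default the
#'   first training slide.
#' @param seg segmentation parameters, a [seg_params()] list.
#' @param tile_size,overlap tiling geometry, see [plan_tiles()].
#' @param k_neighbors neighbor count for density features.
#' @param n_words,sample_per_slide codebook parameters, see
#'   [learn_codebook()].
#' @param alpha FDR significance level for feature screening.
#' @param models named list of [model_spec()]s.
#' @param n_folds cross-validation folds.
#' @param seed master seed for codebook learning and fold assignment.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(normalize = TRUE, normalize_splits = "external",
                            reference_slide = NULL, seg = seg_params(),
                            tile_size = 2000, overlap = 200, k_neighbors = 5,
                            n_words = 10, sample_per_slide = 10000,
                            alpha = 0.05,
                            models = list(
                              logistic_regression = model_spec("logistic_regression"),
                              svm_linear = model_spec("svm_linear"),
                              svm_gaussian = model_spec("svm_gaussian"),
                              random_forest = model_spec("random_forest")),
                            n_folds = 5, seed = 1) {
  structure(list(normalize = normalize, normalize_splits = normalize_splits,
                 reference_slide = reference_slide, seg = seg,
                 tile_size = tile_size, overlap = overlap,
                 k_neighbors = k_neighbors, n_words = n_words,
                 sample_per_slide = sample_per_slide, alpha = alpha,
                 models = models, n_folds = n_folds, seed = seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a cohort of slides
#'
#' Stages, in order: optional stain normalization to a reference slide;
#' nucleus segmentation of every slide; nucleus-level feature extraction;
#' bag-of-visual-words codebook learning on the training split only;
#' image-level feature assembly for all slides; Mann-Whitney/FDR feature
#' screening on the training split; stratified cross-validation of every
#' configured model on the training split; and, if any slide is marked
#' `split == "external"`, external validation of models trained on the full
#' training split. The codebook and feature selection never see non-train
#' slides.
#'
#' @param slides list of slides; each element needs `$image` (H x W x 3,
#'   0-255) and optionally `$slide_id` ([generate_cohort()] and
#'   [read_cohort()] outputs qualify).
#' @param labels class label per slide.
#' @param split per-slide split: `"train"` or `"external"` (default all
#'   train).
#' @param config a [pipeline_config()].
#' @param positive_class positive label (default "TFE3").
#' @return list of class `pipeline_result` with `features` (slides x 150
#'   data frame), `labels`, `split`, `codebook`, `nucleus_tables`,
#'   `comparisons`, `cv` (per model), and `external` (per model, when an
#'   external split exists).
#' @export
run_pipeline <- function(slides, labels, split = NULL,
                         config = pipeline_config(),
                         positive_class = "TFE3") {
  stopifnot(length(slides) == length(labels))
  if (is.null(split)) split <- rep("train", length(slides))
  stopifnot(length(split) == length(slides))
  ids <- vapply(seq_along(slides), function(i) {
    s <- slides[[i]]
    if (!is.null(s$slide_id)) as.character(s$slide_id) else sprintf("slide_%03d", i)
  }, character(1))
  ids <- make.unique(ids, sep = "_")

  images <- lapply(slides, function(s) s$image)
  if (config$normalize) {
    ref_i <- config$reference_slide
    if (is.null(ref_i)) ref_i <- which(split == "train")[1]
    ref_basis <- estimate_stain_basis(images[[ref_i]])
    todo <- if (is.null(config$normalize_splits)) seq_along(images)
            else which(split %in% config$normalize_splits)
    for (i in setdiff(todo, ref_i)) {
      src <- estimate_stain_basis(images[[i]])
      images[[i]] <- normalize_image(images[[i]], src, ref_basis)
    }
  }

  nucleus_tables <- lapply(seq_along(images), function(i) {
    seg <- tryCatch(
      segment_slide(images[[i]], config$seg, config$tile_size, config$overlap),
      error = function(e) stop(sprintf("segmentation failed for slide '%s': %s",
                                       ids[i], conditionMessage(e)), call. = FALSE))
    extract_nucleus_features(images[[i]], seg, config$k_neighbors)
  })
  names(nucleus_tables) <- ids

  train <- split == "train"
  codebook <- learn_codebook(nucleus_tables[train], n_words = config$n_words,
                             sample_per_slide = config$sample_per_slide,
                             seed = config$seed)
  features <- assemble_feature_matrix(nucleus_tables, codebook)
  rownames(features) <- ids

  comparisons <- compare_features(features[train, , drop = FALSE],
                                  labels[train], positive_class, config$alpha)

  cv <- lapply(config$models, function(spec)
    cross_validate(spec, features[train, , drop = FALSE], labels[train],
                   n_folds = config$n_folds, seed = config$seed,
                   positive_class = positive_class))

  external <- NULL
  if (any(split == "external")) {
    ext <- split == "external"
    external <- lapply(config$models, function(spec)
      evaluate_external(spec, features[train, , drop = FALSE], labels[train],
                        features[ext, , drop = FALSE], labels[ext],
                        positive_class))
  }

  structure(list(features = features, labels = labels, split = split,
                 codebook = codebook, nucleus_tables = nucleus_tables,
                 comparisons = comparisons, cv = cv, external = external,
                 config = config),
            class = "pipeline_result")
}
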