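#' Minimum-redundancy maximum-relevance (mRMR) feature selection
#'
#' Greedy forward selection: the first feature maximizes mutual information
#' (MI) with the class label; each subsequent feature maximizes its
#' relevance minus its mean redundancy (MI with the already-selected
#' features) -- the "MID" difference variant. MI is estimated in bits after
#' discretizing each feature into equal-frequency bins, which makes the
#' procedure deterministic and invariant to monotone feature rescaling.
#'
#' @param feature_matrix data frame or matrix, samples x features, no NAs.
#' @param labels class label per sample (2 or more classes).
#' @param n_select number of features to return (default 30).
#' @param n_bins equal-frequency bins for MI estimation (default 3).
#' @return data frame with `feature` (in selection order) and `score` (the
#'   mRMR objective value at the step the feature was selected, in bits).
#' @export
mrmr_select <- function(feature_matrix, labels, n_select = 30, n_bins = 3) {
  feature_matrix <- as.data.frame(feature_matrix)
  stopifnot(n_select <= ncol(feature_matrix),
            nrow(feature_matrix) == length(labels))
  if (anyNA(feature_matrix)) stop("feature matrix contains NAs")
  disc <- lapply(feature_matrix, discretize_ef, n_bins = n_bins)
  y <- as.factor(labels)
  feats <- names(disc)
  relevance <- vapply(disc, mutual_information, numeric(1), y = y)
  selected <- character(0)
  scores <- numeric(0)
  red_sum <- stats::setNames(numeric(length(feats)), feats)
  for (step in seq_len(n_select)) {
    cand <- setdiff(feats, selected)
    obj <- relevance[cand] -
      if (length(selected)) red_sum[cand] / length(selected) else 0
    pick <- cand[which.max(obj)]   # ties resolved by column order
    selected <- c(selected, pick)
    scores <- c(scores, obj[[pick]])
    rest <- setdiff(feats, selected)
    if (length(rest))
      red_sum[rest] <- red_sum[rest] +
        vapply(rest, function(f) mutual_information(disc[[f]], disc[[pick]]),
               numeric(1))
  }
  data.frame(feature = selected, score = scores)
}

# Equal-frequency discretization into at most n_bins levels. Features with
# n_bins or fewer distinct values are used as-is (quantile breaks would
# collapse them); constant features end up with a single level and zero MI.
discretize_ef <- function(x, n_bins = 3) {
  if (length(unique(x)) <= n_bins) return(factor(x))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2) return(factor(rep(1L, length(x))))
  cut(x, breaks = br, include.lowest = TRUE)
}

# MI in bits between two factors, from the plug-in joint distribution.
mutual_information <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}

#' Specify one of the four classification models
#'
#' @param kind one of `"logistic_regression"` (ridge-penalized),
#'   `"svm_linear"`, `"svm_gaussian"`, `"random_forest"`.
#' @param n_selected_features how many mRMR features the model uses
#'   (default 30).
#' @param seed RNG seed for stochastic fitters (random forest).
#' @param cost SVM cost parameter.
#' @param gamma Gaussian-kernel width; `NULL` means `1 / (d * var(X))`
#'   computed on the (standardized) training matrix.
#' @param lambda ridge penalty for logistic regression.
#' @param n_trees random-forest size.
#' @return a list of class `model_spec`.
#' @export
model_spec <- function(kind = c("svm_gaussian", "logistic_regression",
                                "svm_linear", "random_forest"),
                       n_selected_features = 30, seed = 1, cost = 1,
                       gamma = NULL, lambda = 0.01, n_trees = 500) {
  kind <- match.arg(kind)
  structure(list(kind = kind, n_selected_features = n_selected_features,
                 seed = seed, cost = cost, gamma = gamma, lambda = lambda,
                 n_trees = n_trees),
            class = "model_spec")
}

#' Train one classifier on a standardized training matrix
#'
#' Features are z-scored with training-set statistics (stored in the fit and
#' re-applied at prediction time). The fitted object exposes a continuous
#' score for the positive class via [predict_scores()].
#'
#' @param spec a [model_spec()].
#' @param x_train samples x features matrix/data frame.
#' @param y_train labels; must contain both classes.
#' @param positive_class label scored as positive (default "TFE3").
#' @return a list of class `morphobow_fit`.
#' @export
train_classifier <- function(spec, x_train, y_train,
                             positive_class = "TFE3") {
  x_train <- as.matrix(x_train)
  y <- factor(y_train)
  if (nlevels(y) < 2) stop("training set contains a single class")
  stopifnot(positive_class %in% levels(y))
  y <- stats::relevel(y, ref = setdiff(levels(y), positive_class)[1])
  center <- colMeans(x_train)
  scale <- apply(x_train, 2, stats::sd)
  scale[scale < 1e-12] <- 1
  xs <- scale(x_train, center = center, scale = scale)
  fit <- with_seed(spec$seed, switch(
    spec$kind,
    logistic_regression = glmnet::glmnet(xs, y, family = "binomial",
                                         alpha = 0, lambda = spec$lambda),
    svm_linear = e1071::svm(xs, y, kernel = "linear", cost = spec$cost,
                            scale = FALSE),
    svm_gaussian = {
      g <- if (is.null(spec$gamma)) 1 / (ncol(xs) * max(stats::var(as.numeric(xs)), 1e-12))
           else spec$gamma
      e1071::svm(xs, y, kernel = "radial", cost = spec$cost, gamma = g,
                 scale = FALSE)
    },
    random_forest = randomForest::randomForest(xs, y, ntree = spec$n_trees)))
  structure(list(spec = spec, model = fit, center = center, scale = scale,
                 positive_class = positive_class,
                 feature_names = colnames(x_train)),
            class = "morphobow_fit")
}

#' Continuous positive-class scores from a fitted classifier
#'
#' @param fit a [train_classifier()] result.
#' @param x_new samples x features matrix with the training columns.
#' @return numeric vector; larger means more positive-class-like.
#' @export
predict_scores <- function(fit, x_new) {
  x_new <- as.matrix(x_new)
  missing <- setdiff(fit$feature_names, colnames(x_new))
  if (length(missing))
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  xs <- scale(x_new[, fit$feature_names, drop = FALSE],
              center = fit$center, scale = fit$scale)
  switch(fit$spec$kind,
    logistic_regression =
      as.numeric(stats::predict(fit$model, xs, type = "response")),
    svm_linear = ,
    svm_gaussian = {
      dv <- attr(stats::predict(fit$model, xs, decision.values = TRUE),
                 "decision.values")
      sgn <- if (grepl(paste0("/", fit$positive_class, "$"), colnames(dv)[1]))
        -1 else 1
      sgn * as.numeric(dv)
    },
    random_forest =
      as.numeric(stats::predict(fit$model, xs,
                                type = "prob")[, fit$positive_class]))
}

#' AUC with DeLong 95% confidence interval
#'
#' The AUC equals the probability that a random positive scores above a
#' random negative (ties counted 1/2) -- the normalized Mann-Whitney U
#' statistic. The confidence interval uses DeLong's nonparametric variance,
#' clipped to \[0, 1\].
#'
#' @param scores numeric classifier scores.
#' @param labels class labels (both classes present).
#' @param positive_class label treated as positive (default "TFE3").
#' @return list with `auc`, `ci_low`, `ci_high`, and the `pROC::roc` object
#'   in `roc`.
#' @export
roc_auc_ci <- function(scores, labels, positive_class = "TFE3") {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  neg <- setdiff(unique(labels), positive_class)
  ro <- pROC::roc(response = labels, predictor = scores,
                  levels = c(neg, positive_class), direction = "<",
                  quiet = TRUE)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(ro, method = "delong")))
  list(auc = as.numeric(pROC::auc(ro)),
       ci_low = clamp(ci[1], 0, 1), ci_high = clamp(ci[3], 0, 1), roc = ro)
}

#' Youden index of an ROC operating point
#'
#' @param sensitivity,specificity the operating point, each in \[0, 1\].
#' @return `sensitivity + specificity - 1`.
#' @export
youden_index <- function(sensitivity, specificity) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  sensitivity + specificity - 1
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin into folds.
stratified_folds <- function(labels, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

#' Stratified k-fold cross-validation of one model
#'
#' In each fold, feature standardization and mRMR selection are refit on the
#' training portion only; when per-slide nucleus tables are supplied, the
#' bag-of-visual-words codebook is also relearned per fold so no validation
#' information leaks into the representation.
#'
#' @param spec a [model_spec()].
#' @param feature_matrix slides x features (used directly when
#'   `nucleus_tables` is NULL).
#' @param labels class labels per slide.
#' @param n_folds folds (default 5).
#' @param seed controls the fold assignment.
#' @param nucleus_tables optional named list of per-slide nucleus tables;
#'   when given, a codebook is learned on each training fold and feature
#'   matrices are assembled per fold.
#' @param positive_class positive label (default "TFE3").
#' @param codebook_args extra arguments passed to [learn_codebook()].
#' @return list of class `cv_result`: `fold_aucs`, `auc_mean`, `auc_sd`,
#'   `fold` assignment, and per-fold selected features.
#' @export
cross_validate <- function(spec, feature_matrix, labels, n_folds = 5,
                           seed = 1, nucleus_tables = NULL,
                           positive_class = "TFE3",
                           codebook_args = list()) {
  labels <- as.character(labels)
  n <- length(labels)
  stopifnot(is.null(feature_matrix) || nrow(feature_matrix) == n,
            min(table(labels)) >= n_folds)
  fold <- stratified_folds(labels, n_folds, seed)
  per_fold <- lapply(seq_len(n_folds), function(k) {
    tr <- fold != k
    if (!is.null(nucleus_tables)) {
      cb <- do.call(learn_codebook,
                    c(list(training_records = nucleus_tables[tr]),
                      codebook_args))
      fm <- assemble_feature_matrix(nucleus_tables, cb)
    } else fm <- as.data.frame(feature_matrix)
    sel <- mrmr_select(fm[tr, , drop = FALSE], labels[tr],
                       n_select = min(spec$n_selected_features, ncol(fm)))
    fit <- train_classifier(spec, fm[tr, sel$feature, drop = FALSE],
                            labels[tr], positive_class)
    scores <- predict_scores(fit, fm[!tr, sel$feature, drop = FALSE])
    list(auc = roc_auc_ci(scores, labels[!tr], positive_class)$auc,
         selected = sel$feature)
  })
  aucs <- vapply(per_fold, `[[`, numeric(1), "auc")
  structure(list(fold_aucs = aucs, auc_mean = mean(aucs),
                 auc_sd = stats::sd(aucs), fold = fold,
                 selected = lapply(per_fold, `[[`, "selected")),
            class = "cv_result")
}

#' Train on one cohort and evaluate on an external validation cohort
#'
#' Standardization, mRMR selection and the classifier are fit on the
#' training cohort only; the external cohort is scored with the frozen
#' model. Reports the ROC with AUC and DeLong 95% CI, plus sensitivity,
#' specificity and Youden index at the Youden-optimal threshold.
#'
#' @param spec a [model_spec()].
#' @param train_matrix,train_labels training cohort.
#' @param test_matrix,test_labels external validation cohort (columns must
#'   include the training features).
#' @param positive_class positive label (default "TFE3").
#' @return list of class `eval_result`: `auc`, `auc_ci_95`, `roc_points`,
#'   `sensitivity`, `specificity`, `youden`, `threshold`,
#'   `selected_features`, `scores`.
#' @export
evaluate_external <- function(spec, train_matrix, train_labels,
                              test_matrix, test_labels,
                              positive_class = "TFE3") {
  sel <- mrmr_select(train_matrix, train_labels,
                     n_select = min(spec$n_selected_features,
                                    ncol(train_matrix)))
  absent <- setdiff(sel$feature, colnames(test_matrix))
  if (length(absent))
    stop("missing feature(s) in the external matrix: ",
         paste(absent, collapse = ", "))
  fit <- train_classifier(spec,
                          as.data.frame(train_matrix)[, sel$feature, drop = FALSE],
                          train_labels, positive_class)
  scores <- predict_scores(fit,
                           as.data.frame(test_matrix)[, sel$feature, drop = FALSE])
  rc <- roc_auc_ci(scores, test_labels, positive_class)
  best <- pROC::coords(rc$roc, x = "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  best <- best[1, , drop = FALSE]
  structure(list(auc = rc$auc, auc_ci_95 = c(rc$ci_low, rc$ci_high),
                 roc_points = data.frame(fpr = 1 - rc$roc$specificities,
                                         tpr = rc$roc$sensitivities),
                 sensitivity = best$sensitivity,
                 specificity = best$specificity,
                 youden = youden_index(best$sensitivity, best$specificity),
                 threshold = best$threshold,
                 selected_features = sel, scores = scores, fit = fit),
            class = "eval_result")
}
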