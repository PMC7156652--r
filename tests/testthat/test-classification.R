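make_toy <- function(n = 40, d = 6, sep = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c("TFE3", "ccRCC"), each = n / 2)
  x <- matrix(rnorm(n * d), n, d)
  x[y == "TFE3", 1] <- x[y == "TFE3", 1] + sep
  colnames(x) <- paste0("f", 1:d)
  list(x = as.data.frame(x), y = y)
}

test_that("mRMR picks a perfect predictor first and penalizes duplicates", {
  set.seed(2)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  fm <- data.frame(F1 = y,                               # exact copy of label
                   F2 = rnorm(n), F3 = rnorm(n))
  sel <- mrmr_select(fm, y, n_select = 2)
  expect_equal(sel$feature[1], "F1")   # maximal relevance wins step 1

  # duplicate penalty: G2 is a copy of the first pick G1; an independent
  # informative feature G3 must be selected before the duplicate
  g1 <- y + rnorm(n, 0, 0.4)
  fm2 <- data.frame(G1 = g1, G2 = g1, G3 = y + rnorm(n, 0, 0.5),
                    G4 = rnorm(n))
  sel2 <- mrmr_select(fm2, y, n_select = 4)
  expect_equal(sel2$feature[1], "G1")
  expect_lt(match("G3", sel2$feature), match("G2", sel2$feature))
  # verify the step-2 objective against brute-force MI arithmetic
  disc <- function(v) {
    if (length(unique(v)) <= 3) return(factor(v))
    br <- unique(quantile(v, seq(0, 1, length.out = 4)))
    cut(v, br, include.lowest = TRUE)
  }
  mi <- function(a, b) {
    tab <- table(a, b); p <- tab / sum(tab)
    px <- rowSums(p); py <- colSums(p); nz <- p > 0
    sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
  }
  expected_step2 <- sapply(c("G2", "G3", "G4"), function(f)
    mi(disc(fm2[[f]]), factor(y)) - mi(disc(fm2[[f]]), disc(fm2$G1)))
  expect_equal(sel2$score[2], unname(max(expected_step2)), tolerance = 1e-10)
  expect_lte(expected_step2[["G2"]], expected_step2[["G3"]])
  expect_error(mrmr_select(fm2, y, n_select = 10))
})

test_that("mRMR returns the configured number of features from a 150-column matrix", {
  set.seed(3)
  fm <- as.data.frame(matrix(rnorm(100 * 150), 100, 150))
  names(fm) <- paste0("v", 1:150)
  y <- rep(c("a", "b"), 50)
  sel <- mrmr_select(fm, y, n_select = 30)
  expect_equal(nrow(sel), 30)
  expect_equal(anyDuplicated(sel$feature), 0)
  # determinism
  expect_identical(sel, mrmr_select(fm, y, n_select = 30))
})

test_that("all four models separate a separable toy problem and are seeded", {
  toy <- make_toy(sep = 4)
  for (kind in c("logistic_regression", "svm_linear", "svm_gaussian",
                 "random_forest")) {
    fit <- train_classifier(model_spec(kind, seed = 5), toy$x, toy$y)
    sc <- predict_scores(fit, toy$x)
    expect_equal(roc_auc_ci(sc, toy$y)$auc, 1,
                 info = kind, tolerance = 1e-9)
  }
  f1 <- train_classifier(model_spec("random_forest", seed = 7), toy$x, toy$y)
  f2 <- train_classifier(model_spec("random_forest", seed = 7), toy$x, toy$y)
  expect_identical(predict_scores(f1, toy$x), predict_scores(f2, toy$x))
  expect_error(train_classifier(model_spec(), toy$x, rep("TFE3", 40)),
               "single class")
})

test_that("AUC equals the brute-force pair count and the normalized U statistic", {
  set.seed(11)
  scores <- round(rnorm(200), 1)   # rounding forces ties
  labs <- sample(rep(c("TFE3", "ccRCC"), 100))
  r <- roc_auc_ci(scores, labs)
  expect_equal(r$auc, auc_oracle(scores, labs))
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  # cross-module consistency with the rank-sum U
  u <- mann_whitney_u(scores[labs == "TFE3"], scores[labs == "ccRCC"])$u
  expect_equal(r$auc, u / (100 * 100))
  # randomized small instances
  for (trial in 1:1000) {
    n <- sample(6:14, 1)
    sc <- sample(5, n, replace = TRUE)
    lb <- c("TFE3", "ccRCC", sample(c("TFE3", "ccRCC"), n - 2, replace = TRUE))
    expect_equal(roc_auc_ci(sc, lb)$auc, auc_oracle(sc, lb))
  }
  expect_equal(roc_auc_ci(c(0.9, 0.8, 0.1, 0.2),
                          c("TFE3", "TFE3", "ccRCC", "ccRCC"))$auc, 1)
  expect_equal(roc_auc_ci(rep(1, 10), rep(c("TFE3", "ccRCC"), 5))$auc, 0.5)
  expect_error(roc_auc_ci(1:3, rep("TFE3", 3)), "both classes")
})

test_that("Youden index reproduces published sensitivity/specificity arithmetic", {
  expect_equal(youden_index(0.85, 0.57), 0.42)
  expect_equal(youden_index(0.70, 0.95), 0.65)
  expect_equal(youden_index(1, 1), 1)
  expect_error(youden_index(1.2, 0.5))
})

test_that("cross-validation partitions slides exactly once and scores sanely", {
  toy <- make_toy(n = 40, sep = 4, seed = 9)
  cv <- cross_validate(model_spec("svm_linear", n_selected_features = 3),
                       toy$x, toy$y, n_folds = 5, seed = 2)
  expect_length(cv$fold_aucs, 5)
  expect_equal(sort(unique(cv$fold)), 1:5)
  expect_equal(as.vector(table(cv$fold)), rep(8, 5))
  # stratified: both classes in every fold
  for (k in 1:5)
    expect_equal(length(unique(toy$y[cv$fold == k])), 2)
  expect_gte(cv$auc_mean, 0.9)
  # chance level on shuffled labels
  set.seed(4)
  cvnull <- cross_validate(model_spec("svm_gaussian", n_selected_features = 3),
                           toy$x, sample(toy$y), n_folds = 5, seed = 2)
  expect_lt(abs(cvnull$auc_mean - 0.5), 0.3)
})

test_that("external evaluation freezes the training pipeline (leakage guard)", {
  toy <- make_toy(n = 40, sep = 4, seed = 12)
  test <- make_toy(n = 20, sep = 4, seed = 13)
  ev <- evaluate_external(model_spec("svm_gaussian", n_selected_features = 3),
                          toy$x, toy$y, test$x, test$y)
  expect_gte(ev$auc, 0.9)
  expect_true(ev$auc_ci_95[1] <= ev$auc && ev$auc <= ev$auc_ci_95[2])
  expect_equal(ev$youden, ev$sensitivity + ev$specificity - 1)
  # permuting the external labels must not change model or scores
  ev2 <- evaluate_external(model_spec("svm_gaussian", n_selected_features = 3),
                          toy$x, toy$y, test$x, rev(test$y))
  expect_identical(ev$scores, ev2$scores)
  expect_identical(ev$selected_features, ev2$selected_features)
  # perfect model on a copy of the training set
  ev3 <- evaluate_external(model_spec("svm_linear", n_selected_features = 3),
                           toy$x, toy$y, toy$x, toy$y)
  expect_equal(ev3$auc, 1)
  expect_equal(ev3$auc_ci_95[2], 1)
  expect_error(evaluate_external(model_spec(), toy$x, toy$y,
                                 toy$x[, 1:2], toy$y), "missing feature")
})
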