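fake_table <- function(values) {
  tab <- as.data.frame(setNames(rep(list(values), 10),
                                c("area", "major", "minor", "ratio", "rMean",
                                  "gMean", "bMean", "distMean", "distMax",
                                  "distMin")))
  tab
}

test_that("codebook learning: exact small case, separated clouds, determinism", {
  tab <- fake_table(1:10)
  cb <- learn_codebook(list(tab), n_words = 10, seed = 1)
  expect_s3_class(cb, "bow_codebook")
  expect_equal(cb$area, as.numeric(1:10))
  expect_true(all(vapply(cb, function(w) !is.unsorted(w), TRUE)))

  # two well-separated clouds, k = 2: centroids near the cloud means
  set.seed(42)
  v <- c(rnorm(200, 0, 0.1), rnorm(200, 100, 0.1))
  cb2 <- learn_codebook(list(fake_table(v)), n_words = 2, seed = 7)
  expect_equal(cb2$ratio, c(0, 100), tolerance = 0.01)

  v3 <- rnorm(500)
  cb3a <- learn_codebook(list(fake_table(v3)), n_words = 10, seed = 3)
  cb3b <- learn_codebook(list(fake_table(v3)), n_words = 10, seed = 3)
  expect_identical(cb3a, cb3b)

  expect_error(learn_codebook(list(fake_table(rep(1:3, 10))), n_words = 10),
               "distinct")
})

test_that("histogram assignment is nearest-word with L1 normalization", {
  words <- as.numeric(1:10)
  h <- histogram_features(rep(3, 17), words)
  expect_equal(h, c(0, 0, 1, rep(0, 7)))
  expect_equal(histogram_features(c(1, 1, 9), words),
               c(2 / 3, 0, 0, 0, 0, 0, 0, 0, 1 / 3, 0))
  expect_warning(h0 <- histogram_features(numeric(0), words), "no values")
  expect_equal(h0, rep(0, 10))
})

test_that("histogram matches the brute-force nearest-centroid oracle", {
  set.seed(9)
  for (trial in 1:5) {
    words <- sort(runif(10, 0, 100))
    values <- runif(10000, -10, 110)
    h <- histogram_features(values, words)
    # oracle: explicit nearest-word loop, ties to the lower bin
    dmat <- abs(outer(values, words, "-"))
    bins <- apply(dmat, 1, which.min)   # which.min takes the first (lower) tie
    expect_equal(h, as.numeric(tabulate(bins, 10) / length(values)))
    expect_equal(sum(h), 1)
  }
})

test_that("distribution statistics match closed forms", {
  uni <- rep(0.1, 10)
  s <- distribution_stats(rnorm(50), uni)
  expect_equal(unname(s["entropy"]), log2(10))
  onehot <- c(1, rep(0, 9))
  expect_equal(unname(distribution_stats(rep(5, 4), onehot)["entropy"]), 0)
  st <- distribution_stats(c(1, 2, 3, 4), histogram_features(c(1, 2, 3, 4), 1:10))
  expect_equal(unname(st["mean"]), 2.5)
  expect_equal(unname(st["std"]), sqrt(1.25))     # population moment
  expect_equal(unname(st["skewness"]), 0)
  expect_warning(s1 <- distribution_stats(7, c(1, rep(0, 9))), "single value")
  expect_equal(unname(s1[c("std", "skewness", "kurtosis")]), c(0, 0, 0))
})

test_that("feature vectors have 150 named entries with unit-sum histograms", {
  s <- generate_slide(small_gen(), c(256, 256), 30, seed = 4)
  tab <- nucleus_table_from_truth(s)
  cb <- learn_codebook(list(tab), seed = 1)
  v <- assemble_feature_vector(tab, cb)
  expect_length(v, 150)
  types <- c("area", "major", "minor", "ratio", "rMean", "gMean", "bMean",
             "distMean", "distMax", "distMin")
  expect_setequal(names(v), unlist(lapply(types, function(t)
    c(paste0(t, "_bin", 1:10),
      paste0(t, "_", c("mean", "std", "skewness", "kurtosis", "entropy"))))))
  for (t in types) {
    expect_equal(sum(v[paste0(t, "_bin", 1:10)]), 1, tolerance = 1e-9)
    expect_gte(v[paste0(t, "_entropy")], 0)
    expect_lte(v[paste0(t, "_entropy")], log2(10))
    expect_gte(v[paste0(t, "_std")], 0)
  }
  # identical nuclei: zero spread and zero entropy everywhere
  tab1 <- fake_table(rep(2, 20))
  cbx <- learn_codebook(list(fake_table(1:40)), seed = 1)
  vx <- assemble_feature_vector(tab1, cbx)
  expect_true(all(vx[grepl("_std$", names(vx))] == 0))
  expect_true(all(vx[grepl("_entropy$", names(vx))] == 0))
  # missing column errors by name
  expect_error(assemble_feature_vector(tab[, setdiff(names(tab), "major")], cb),
               "major")
})

test_that("codebooks round-trip through JSON without losing precision", {
  s <- generate_slide(small_gen(), c(256, 256), 30, seed = 14)
  tab <- nucleus_table_from_truth(s)
  cb <- learn_codebook(list(tab), seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_codebook(cb, path)
  cb2 <- read_codebook(path)
  expect_equal(cb2, cb)
  expect_equal(assemble_feature_vector(tab, cb2),
               assemble_feature_vector(tab, cb))
})

test_that("histogram features are invariant to duplicating every nucleus", {
  s <- generate_slide(small_gen(), c(256, 256), 25, seed = 5)
  tab <- nucleus_table_from_truth(s)
  cb <- learn_codebook(list(tab), seed = 2)
  v1 <- assemble_feature_vector(tab, cb)
  v2 <- assemble_feature_vector(rbind(tab, tab), cb)
  bins <- grepl("_bin", names(v1))
  expect_equal(v1[bins], v2[bins])
  # permutation invariance of the whole vector
  v3 <- assemble_feature_vector(tab[sample(nrow(tab)), ], cb)
  expect_equal(v1, v3)
})
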