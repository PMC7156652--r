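disk_mask <- function(n, ctr, radius) {
  m <- matrix(0L, n, n)
  for (r in 1:n) for (cc in 1:n)
    if ((r - ctr[1])^2 + (cc - ctr[2])^2 <= radius^2) m[r, cc] <- 1L
  m
}

test_that("shape features recover disks, drawn ellipses and degenerate pixels", {
  f <- shape_features(disk_mask(40, c(20, 20), 10))
  expect_equal(unname(f["ratio"]), 1, tolerance = 0.05)
  expect_equal(unname(f["major"]), 20, tolerance = 0.06)
  expect_equal(unname(f["minor"]), 20, tolerance = 0.06)

  # ellipse drawn from known generator axes: moment fit within 5%
  s <- generate_slide(small_gen(noise_sd = 0), c(200, 200), 1, seed = 2)
  s$label_mask[] <- 0L
  th <- 0.4
  for (r in 1:200) for (cc in 1:200) {
    u <- (r - 100) * cos(th) + (cc - 100) * sin(th)
    v <- -(r - 100) * sin(th) + (cc - 100) * cos(th)
    if ((u / 15)^2 + (v / 10)^2 <= 1) s$label_mask[r, cc] <- 1L
  }
  f2 <- shape_features(s$label_mask)
  expect_equal(unname(f2["major"]), 30, tolerance = 0.05)
  expect_equal(unname(f2["minor"]), 20, tolerance = 0.05)
  expect_equal(unname(f2["ratio"]), 1.5, tolerance = 0.05)

  m1 <- matrix(0L, 5, 5); m1[3, 3] <- 1L
  f3 <- shape_features(m1)
  expect_equal(unname(f3["area"]), 1)
  expect_gte(unname(f3["minor"]), 1)
  expect_true(is.finite(f3["ratio"]))
  expect_error(shape_features(matrix(0L, 3, 3)), "empty")
})

test_that("color features are exact channel means over the mask", {
  img <- array(255, dim = c(10, 10, 3))
  m <- matrix(0L, 10, 10); m[2:4, 2:4] <- 1L
  img[2:4, 2:4, 1] <- 99; img[2:4, 2:4, 2] <- 55; img[2:4, 2:4, 3] <- 102
  expect_equal(color_features(img, m),
               c(rMean = 99, gMean = 55, bMean = 102))
  m2 <- matrix(0L, 10, 10); m2[8:9, 8:9] <- 1L
  expect_equal(color_features(img, m2),
               c(rMean = 255, gMean = 255, bMean = 255))
  img[2, 2, 1] <- 0; img[2, 3, 1] <- 255
  m3 <- matrix(0L, 10, 10); m3[2, 2:3] <- 1L
  expect_equal(unname(color_features(img, m3)["rMean"]), 127.5)
  expect_error(color_features(img, matrix(0L, 10, 10)), "empty")
})

test_that("density features match brute-force neighbor distances", {
  pts <- cbind(0, c(0, 3, 10))   # collinear at x = 0, 3, 10
  d <- density_features(pts, k_neighbors = 2)
  expect_equal(unlist(d[1, ]), c(distMean = 6.5, distMax = 10, distMin = 3))
  expect_equal(unlist(d[2, ]), c(distMean = 5, distMax = 7, distMin = 3))

  two <- density_features(cbind(c(0, 3), c(0, 4)), k_neighbors = 5)
  expect_equal(unlist(two[1, ]), c(distMean = 5, distMax = 5, distMin = 5))
  expect_equal(unlist(two[2, ]), c(distMean = 5, distMax = 5, distMin = 5))

  tri <- density_features(7 * cbind(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2)), 2)
  for (i in 1:3) expect_equal(unname(unlist(tri[i, ])), c(7, 7, 7))

  expect_warning(d1 <- density_features(cbind(1, 1), 3), "fewer than 2")
  expect_equal(nrow(d1), 0)
})

test_that("extracted features agree with the ground-truth oracle", {
  g <- small_gen(noise_sd = 0)
  s <- generate_slide(g, c(384, 384), 50, seed = 6)
  nf <- extract_nucleus_features(s$image, s$label_mask, k_neighbors = 5)
  gt <- ground_truth_features(s)
  expect_equal(nrow(nf), 50)
  # ground-truth mask as segmentation: areas exact, axes within 5%
  expect_equal(nf$area, gt$area)
  expect_equal(nf$major, gt$major, tolerance = 0.05)
  expect_equal(nf$minor, gt$minor, tolerance = 0.05)
  expect_equal(nf$rMean, gt$rMean)
  # with default noise, RGB means stay within a few gray levels
  sn <- generate_slide(g, c(384, 384), 50, seed = 6)
  sn$image <- pmin(pmax(sn$image + round(array(rnorm(length(sn$image), 0, 5),
                                               dim(sn$image))), 0), 255)
  nfn <- extract_nucleus_features(sn$image, sn$label_mask, 5)
  expect_lt(max(abs(nfn$rMean - gt$rMean)), 5)
})

test_that("record-level invariants hold across generated slides", {
  for (sd in 1:3) {
    s <- generate_slide(small_gen(), c(256, 256), 35, seed = sd)
    nf <- extract_nucleus_features(s$image, s$label_mask, 5)
    expect_equal(nrow(nf), 35)
    expect_true(all(nf$ratio >= 1))
    expect_true(all(nf$major >= nf$minor))
    expect_true(all(nf$distMin <= nf$distMean & nf$distMean <= nf$distMax))
    expect_true(all(nf$area > 0))
    expect_true(all(nf[c("rMean", "gMean", "bMean")] >= 0 &
                    nf[c("rMean", "gMean", "bMean")] <= 255))
  }
  # empty and singleton slides
  s0 <- generate_slide(small_gen(), c(64, 64), 0, seed = 1)
  expect_equal(nrow(extract_nucleus_features(s0$image, s0$label_mask, 5)), 0)
  s1 <- generate_slide(small_gen(), c(128, 128), 1, seed = 1)
  expect_message(nf1 <- extract_nucleus_features(s1$image, s1$label_mask, 5),
                 "fewer than 2")
  expect_equal(nrow(nf1), 0)
})

test_that("per-slide feature medians track the generator parameters", {
  # vary one generator knob at a time; the matching measured median must
  # rank the slides the same way (Spearman rho >= 0.9)
  area_logs <- seq(log(100), log(500), length.out = 8)
  med_area <- sapply(seq_along(area_logs), function(i) {
    s <- generate_slide(small_gen(area_meanlog = area_logs[i]),
                        c(320, 320), 40, seed = 100 + i)
    median(nucleus_table_from_truth(s)$area)
  })
  expect_gte(cor(area_logs, med_area, method = "spearman"), 0.9)

  red_means <- seq(90, 170, length.out = 8)
  med_red <- sapply(seq_along(red_means), function(i) {
    s <- generate_slide(small_gen(stain_mean = c(red_means[i], 85, 150)),
                        c(320, 320), 40, seed = 200 + i)
    median(nucleus_table_from_truth(s)$rMean)
  })
  expect_gte(cor(red_means, med_red, method = "spearman"), 0.9)
})
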