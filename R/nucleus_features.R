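#' Shape features of one segmented nucleus
#'
#' Area is the pixel count; major and minor axis lengths are those of the
#' ellipse having the same normalized second central moments as the
#' component (the standard regionprops convention, including the 1/12
#' per-pixel variance correction), and the ratio is major/minor. Degenerate
#' components (single pixels, 1-pixel lines) have their axes floored at one
#' pixel so the ratio stays finite.
#'
#' @param mask_component logical or 0/1 matrix marking one connected
#'   component.
#' @return named numeric vector `(area, major, minor, ratio)` in pixels
#'   (ratio dimensionless).
#' @export
shape_features <- function(mask_component) {
  px <- which(mask_component > 0)
  if (length(px) == 0) stop("empty component")
  r <- (px - 1L) %% nrow(mask_component)
  c <- (px - 1L) %/% nrow(mask_component)
  n <- length(px)
  mr <- mean(r); mc <- mean(c)
  # 1/12 is the variance of a unit pixel, so single pixels have finite axes
  urr <- sum((r - mr)^2) / n + 1 / 12
  ucc <- sum((c - mc)^2) / n + 1 / 12
  urc <- sum((r - mr) * (c - mc)) / n
  common <- sqrt((urr - ucc)^2 + 4 * urc^2)
  l1 <- (urr + ucc + common) / 2
  l2 <- (urr + ucc - common) / 2
  major <- max(4 * sqrt(l1), 1)
  minor <- max(4 * sqrt(max(l2, 0)), 1)
  c(area = n, major = major, minor = minor, ratio = major / minor)
}

#' Mean staining intensity of one nucleus per RGB channel
#'
#' @param image_rgb RGB array (0-255); when color normalization is enabled
#'   this should be the normalized image, so intensities are comparable
#'   across slides.
#' @param mask_component logical or 0/1 matrix marking the nucleus.
#' @return named numeric vector `(rMean, gMean, bMean)`.
#' @export
color_features <- function(image_rgb, mask_component) {
  stopifnot_rgb(image_rgb)
  px <- which(mask_component > 0)
  if (length(px) == 0) stop("empty mask")
  npx <- prod(dim(image_rgb)[1:2])
  c(rMean = mean(image_rgb[px]),
    gMean = mean(image_rgb[px + npx]),
    bMean = mean(image_rgb[px + 2L * npx]))
}

#' Neighbor-distance (density) features for a set of nucleus centroids
#'
#' For each nucleus the Euclidean distances to its `k_neighbors` nearest
#' other nuclei are collected (k is capped at n - 1); `distMean`, `distMax`
#' and `distMin` are the mean, maximum and minimum of that set. Distances
#' are computed per slide, so the features reflect slide-level cell density
#' and clumping.
#'
#' @param centroids two-column matrix (row, col) of nucleus centers, pixels.
#' @param k_neighbors number of nearest neighbors (default 5).
#' @return data frame with columns `distMean`, `distMax`, `distMin`, one
#'   row per centroid; with fewer than two centroids an empty data frame is
#'   returned with a warning (the features are undefined).
#' @export
density_features <- function(centroids, k_neighbors = 5) {
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  if (n < 2) {
    warning("fewer than 2 centroids: neighbor-distance features undefined")
    return(data.frame(distMean = numeric(0), distMax = numeric(0),
                      distMin = numeric(0)))
  }
  k <- min(k_neighbors, n - 1L)
  d <- as.matrix(stats::dist(centroids))
  diag(d) <- Inf
  res <- t(apply(d, 1, function(row) {
    nn <- sort(row, partial = seq_len(k))[seq_len(k)]
    c(mean(nn), max(nn), min(nn))
  }))
  data.frame(distMean = res[, 1], distMax = res[, 2], distMin = res[, 3])
}

#' Extract the 10 nucleus-level features for every nucleus in a slide
#'
#' Combines [shape_features()], [color_features()] and [density_features()]
#' into one record per segmented nucleus: area, major, minor, ratio, rMean,
#' gMean, bMean, distMean, distMax, distMin, plus the nucleus id and its
#' centroid. Slides with fewer than two nuclei yield no records (the
#' density features are undefined there).
#'
#' @param slide_image RGB array aligned with the segmentation.
#' @param segmentation a `segmentation_result` from [segment_slide()], or a
#'   plain integer label matrix.
#' @param k_neighbors passed to [density_features()].
#' @return data frame with one row per nucleus and columns `nucleus_id`,
#'   `x` (column), `y` (row), and the 10 features in canonical order.
#' @export
extract_nucleus_features <- function(slide_image, segmentation,
                                     k_neighbors = 5) {
  stopifnot_rgb(slide_image)
  mask <- if (inherits(segmentation, "segmentation_result"))
    segmentation$label_mask else segmentation
  stopifnot(all(dim(mask) == dim(slide_image)[1:2]))
  ids <- sort(unique(mask[mask > 0]))
  empty <- data.frame(nucleus_id = integer(0), x = numeric(0), y = numeric(0),
                      area = numeric(0), major = numeric(0), minor = numeric(0),
                      ratio = numeric(0), rMean = numeric(0), gMean = numeric(0),
                      bMean = numeric(0), distMean = numeric(0),
                      distMax = numeric(0), distMin = numeric(0))
  if (length(ids) == 0) return(empty)
  px <- which(mask > 0)
  lab <- mask[px]
  rows <- (px - 1L) %% nrow(mask)
  cols <- (px - 1L) %/% nrow(mask)
  npx <- prod(dim(mask))
  f <- factor(lab, levels = ids)
  n_i <- as.integer(table(f))
  mr <- tapply(rows, f, mean); mc <- tapply(cols, f, mean)
  shp <- t(vapply(seq_along(ids), function(i) {
    sel <- lab == ids[i]
    r <- rows[sel]; c <- cols[sel]; n <- n_i[i]
    urr <- sum((r - mr[i])^2) / n + 1 / 12
    ucc <- sum((c - mc[i])^2) / n + 1 / 12
    urc <- sum((r - mr[i]) * (c - mc[i])) / n
    common <- sqrt((urr - ucc)^2 + 4 * urc^2)
    major <- max(4 * sqrt((urr + ucc + common) / 2), 1)
    minor <- max(4 * sqrt(max((urr + ucc - common) / 2, 0)), 1)
    c(n, major, minor, major / minor)
  }, numeric(4)))
  rM <- tapply(slide_image[px], f, mean)
  gM <- tapply(slide_image[px + npx], f, mean)
  bM <- tapply(slide_image[px + 2L * npx], f, mean)
  if (length(ids) < 2) {
    message("slide has fewer than 2 nuclei; records dropped ",
            "(neighbor-distance features undefined)")
    return(empty)
  }
  dens <- density_features(cbind(mr, mc), k_neighbors)
  data.frame(nucleus_id = ids, x = as.numeric(mc), y = as.numeric(mr),
             area = shp[, 1], major = shp[, 2], minor = shp[, 3],
             ratio = shp[, 4],
             rMean = as.numeric(rM), gMean = as.numeric(gM),
             bMean = as.numeric(bM),
             distMean = dens$distMean, distMax = dens$distMax,
             distMin = dens$distMin)
}
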