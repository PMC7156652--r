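#' Define a class-conditional generator of synthetic H&E-like slides
#'
#' A `class_generator` bundles the sampling distributions that control how
#' nuclei of one tumor-class look and how they are arranged: a (possibly
#' multimodal) lognormal mixture for nucleus area, a shifted-gamma
#' distribution for the major/minor axis ratio, Gaussian per-channel nuclear
#' stain color, and a cluster process (parents plus offspring within a disk)
#' that controls spatial clumping. Two built-in presets,
#' [tfe3_like_generator()] and [ccrcc_like_generator()], encode the
#' morphological contrasts reported for TFE3-translocation versus clear-cell
#' renal cell carcinoma: bimodal nucleus size, elongated nuclei, redder
#' staining and tighter clumping for the TFE3-like class.
#'
#' @param area_meanlog,area_sdlog,area_weights parameters of the lognormal
#'   mixture over nucleus area (pixels). Vectors of equal length, one entry
#'   per mixture component; `area_weights` need not be normalized.
#' @param ratio_shape,ratio_scale shape/scale of the gamma distribution added
#'   to 1 to give the major/minor axis ratio (so sampled ratios are >= 1).
#' @param stain_mean,stain_sd mean and standard deviation of the nuclear fill
#'   color per RGB channel, on the 0-255 scale. The mean must be channel-wise
#'   darker than `background_rgb`.
#' @param cluster_radius radius (pixels) of the disk around a cluster parent
#'   within which member nuclei are placed. Smaller radius means tighter
#'   clumps.
#' @param nuclei_per_cluster expected number of nuclei per cluster parent.
#' @param background_rgb background color, default eosin-pink.
#' @param noise_sd standard deviation of additive Gaussian pixel noise (gray
#'   levels) applied to the rendered image; 0 disables noise.
#' @return an object of class `class_generator`.
#' @export
class_generator <- function(area_meanlog = log(300), area_sdlog = 0.25,
                            area_weights = 1,
                            ratio_shape = 2, ratio_scale = 0.08,
                            stain_mean = c(110, 85, 150), stain_sd = 8,
                            cluster_radius = 150, nuclei_per_cluster = 4,
                            background_rgb = c(230, 200, 215),
                            noise_sd = 5) {
  k <- length(area_meanlog)
  stopifnot(length(area_sdlog) == k, length(area_weights) == k,
            all(is.finite(c(area_meanlog, area_sdlog, area_weights,
                            ratio_shape, ratio_scale, stain_mean, stain_sd,
                            cluster_radius, nuclei_per_cluster,
                            background_rgb, noise_sd))),
            all(area_sdlog > 0), all(area_weights > 0),
            ratio_shape > 0, ratio_scale >= 0,
            cluster_radius > 0, nuclei_per_cluster >= 1,
            length(stain_mean) == 3, length(background_rgb) == 3,
            all(background_rgb >= 0 & background_rgb <= 255),
            all(stain_mean >= 0 & stain_mean <= 255), noise_sd >= 0)
  if (!all(stain_mean < background_rgb))
    stop("nuclear stain_mean must be darker than background_rgb in every channel")
  structure(list(area_meanlog = area_meanlog, area_sdlog = area_sdlog,
                 area_weights = area_weights / sum(area_weights),
                 ratio_shape = ratio_shape, ratio_scale = ratio_scale,
                 stain_mean = stain_mean, stain_sd = stain_sd,
                 cluster_radius = cluster_radius,
                 nuclei_per_cluster = nuclei_per_cluster,
                 background_rgb = background_rgb, noise_sd = noise_sd),
            class = "class_generator")
}

#' @rdname class_generator
#' @details The TFE3-like preset has a bimodal ("two extremes") area
#'   distribution, more elongated nuclei, brighter red-channel staining and
#'   a small cluster radius (clumped cells). The ccRCC-like preset has a
#'   unimodal area distribution, rounder nuclei and dispersed placement.
#' @export
tfe3_like_generator <- function() {
  class_generator(area_meanlog = c(log(150), log(600)),
                  area_sdlog = c(0.20, 0.20), area_weights = c(0.5, 0.5),
                  ratio_shape = 2, ratio_scale = 0.20,
                  stain_mean = c(135, 95, 155), stain_sd = 8,
                  cluster_radius = 40, nuclei_per_cluster = 8)
}

#' @rdname class_generator
#' @export
ccrcc_like_generator <- function() {
  class_generator(area_meanlog = log(300), area_sdlog = 0.25,
                  area_weights = 1,
                  ratio_shape = 2, ratio_scale = 0.08,
                  stain_mean = c(110, 85, 150), stain_sd = 8,
                  cluster_radius = 150, nuclei_per_cluster = 4)
}

sample_nucleus_params <- function(gen, n) {
  comp <- sample.int(length(gen$area_weights), n, replace = TRUE,
                     prob = gen$area_weights)
  area <- stats::rlnorm(n, gen$area_meanlog[comp], gen$area_sdlog[comp])
  ratio <- 1 + stats::rgamma(n, shape = gen$ratio_shape, scale = gen$ratio_scale)
  major <- 2 * sqrt(area * ratio / pi)
  minor <- major / ratio
  theta <- stats::runif(n, 0, pi)
  rgb <- sapply(1:3, function(ch)
    clamp(round(stats::rnorm(n, gen$stain_mean[ch], gen$stain_sd)),
          0, pmax(0, gen$background_rgb[ch] - 10)))
  if (n == 1L) rgb <- matrix(rgb, nrow = 1)
  list(major = major, minor = minor, ratio = ratio, theta = theta, rgb = rgb)
}

#' Generate one synthetic H&E-like slide with ground truth
#'
#' Renders `n_nuclei` non-overlapping filled ellipses ("nuclei") on a pink
#' background, using a cluster process for placement: cluster parent points
#' are scattered uniformly and each nucleus is placed within
#' `gen$cluster_radius` pixels of its parent, so spatial clumping is
#' controlled by the cluster radius. Every nucleus is recorded in an integer
#' label mask (0 = background, k = nucleus id) together with its generative
#' parameters, giving exact ground truth for segmentation and feature
#' benchmarks. Optional additive Gaussian noise is applied after rendering.
#' The output is deterministic given `(gen, size_hw, n_nuclei, seed)`.
#'
#' @param gen a [class_generator()].
#' @param size_hw integer pair `c(height, width)` in pixels.
#' @param n_nuclei number of nuclei to place (>= 0).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @param max_retries total placement attempts allowed before giving up.
#' @return an object of class `synthetic_slide`: a list with `image`
#'   (H x W x 3 array, 0-255), `label_mask` (H x W integer matrix), `nuclei`
#'   (data frame of per-nucleus generative parameters: center row/col in
#'   0-based pixel coordinates, major/minor axis lengths, orientation,
#'   fill RGB), `class_label`, and `seed`.
#' @export
generate_slide <- function(gen, size_hw = c(512, 512), n_nuclei = 150,
                           seed = 1, max_retries = 200 * max(n_nuclei, 1)) {
  stopifnot(inherits(gen, "class_generator"), n_nuclei >= 0,
            length(size_hw) == 2, all(size_hw >= 8))
  H <- as.integer(size_hw[1]); W <- as.integer(size_hw[2])
  with_seed(seed, {
    image <- array(rep(gen$background_rgb, each = H * W), dim = c(H, W, 3))
    mask <- matrix(0L, H, W)
    nuc <- data.frame(nucleus_id = integer(0), center_row = numeric(0),
                      center_col = numeric(0), major = numeric(0),
                      minor = numeric(0), ratio = numeric(0),
                      orientation = numeric(0), fill_r = integer(0),
                      fill_g = integer(0), fill_b = integer(0))
    if (n_nuclei > 0) {
      p <- sample_nucleus_params(gen, n_nuclei)
      # place large nuclei first: packing is much more reliable when the
      # big ellipses claim space before the field fragments
      ord <- order(p$major, decreasing = TRUE)
      p <- list(major = p$major[ord], minor = p$minor[ord],
                ratio = p$ratio[ord], theta = p$theta[ord],
                rgb = p$rgb[ord, , drop = FALSE])
      n_clusters <- max(1L, round(n_nuclei / gen$nuclei_per_cluster))
      margin <- max(p$major) / 2 + 2
      if (2 * margin >= min(H, W))
        stop("slide too small for the requested nucleus sizes")
      parents <- cbind(stats::runif(n_clusters, margin, H - 1 - margin),
                       stats::runif(n_clusters, margin, W - 1 - margin))
      assign_cluster <- sample.int(n_clusters, n_nuclei, replace = TRUE)
      centers <- matrix(NA_real_, n_nuclei, 2)
      gap <- 2   # pixels kept free around every nucleus
      occupied <- matrix(FALSE, H, W)   # mask dilated by `gap`
      placed <- 0L
      tries <- 0L
      i <- 1L
      fails_i <- 0L
      while (i <= n_nuclei) {
        if (tries >= max_retries)
          stop(sprintf("placed only %d of %d nuclei after %d attempts",
                       placed, n_nuclei, tries))
        tries <- tries + 1L
        # when a cluster saturates, re-parent the nucleus and widen its
        # placement radius so placement always terminates while clumping
        # is preserved for the nuclei that do fit
        if (fails_i > 0L && fails_i %% 20L == 0L)
          assign_cluster[i] <- sample.int(n_clusters, 1)
        radius_i <- min(gen$cluster_radius * 1.5^(fails_i %/% 20L),
                        sqrt(H^2 + W^2))
        par <- parents[assign_cluster[i], ]
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- radius_i * sqrt(stats::runif(1))
        cand <- par + rad * c(cos(ang), sin(ang))
        smaj <- p$major[i] / 2 + gap
        if (cand[1] < smaj + 1 || cand[1] > H - 2 - smaj ||
            cand[2] < smaj + 1 || cand[2] > W - 2 - smaj) {
          fails_i <- fails_i + 1L
          next
        }
        # pixel-exact non-overlap test: the candidate ellipse, grown by
        # `gap`, must not touch any already-placed nucleus
        px_pad <- ellipse_pixels(cand[1], cand[2],
                                 p$major[i] / 2 + gap, p$minor[i] / 2 + gap,
                                 p$theta[i], H, W)
        if (any(occupied[px_pad])) { fails_i <- fails_i + 1L; next }
        px <- ellipse_pixels(cand[1], cand[2], p$major[i] / 2, p$minor[i] / 2,
                             p$theta[i], H, W)
        occupied[px_pad] <- TRUE
        mask[px] <- i
        for (ch in 1:3) {
          plane <- image[, , ch]
          plane[px] <- p$rgb[i, ch]
          image[, , ch] <- plane
        }
        placed <- placed + 1L
        centers[i, ] <- cand
        fails_i <- 0L
        i <- i + 1L
      }
      nuc <- data.frame(nucleus_id = seq_len(n_nuclei),
                        center_row = centers[, 1], center_col = centers[, 2],
                        major = p$major, minor = p$minor, ratio = p$ratio,
                        orientation = p$theta,
                        fill_r = p$rgb[, 1], fill_g = p$rgb[, 2],
                        fill_b = p$rgb[, 3])
    }
    if (gen$noise_sd > 0)
      image <- clamp(round(image + stats::rnorm(length(image), 0, gen$noise_sd)),
                     0, 255)
    structure(list(image = image, label_mask = mask, nuclei = nuc,
                   class_label = NA_character_, seed = seed),
              class = "synthetic_slide")
  })
}

# Linear indices (into an H x W matrix) of the pixels inside an ellipse
# centered at 0-based (cr, cc) with semi-axes (a, b) and orientation theta.
ellipse_pixels <- function(cr, cc, a, b, theta, H, W) {
  r0 <- max(0L, floor(cr - a)); r1 <- min(H - 1L, ceiling(cr + a))
  c0 <- max(0L, floor(cc - a)); c1 <- min(W - 1L, ceiling(cc + a))
  rows <- r0:r1; cols <- c0:c1
  dr <- outer(rows - cr, rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - cc)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx_r <- rep(rows, times = length(cols))[as.vector(inside)]
  idx_c <- rep(cols, each = length(rows))[as.vector(inside)]
  (idx_c) * H + idx_r + 1L   # column-major linear index, 0-based coords
}

#' Generate a balanced two-class cohort of synthetic slides
#'
#' Produces `n_per_class` slides from each of two class generators with
#' per-slide seeds derived as `seed + slide index`, so cohorts are
#' reproducible and slides can be regenerated independently.
#'
#' @param gen_a,gen_b [class_generator()]s for the two classes.
#' @param n_per_class slides per class (>= 1).
#' @param size_hw slide size in pixels.
#' @param n_nuclei nuclei per slide.
#' @param seed master seed.
#' @param label_a,label_b class labels attached to the slides.
#' @return a list of `synthetic_slide`s of length `2 * n_per_class`
#'   (class-A slides first), each with `class_label` and a `slide_id` field.
#' @export
generate_cohort <- function(gen_a, gen_b, n_per_class, size_hw = c(512, 512),
                            n_nuclei = 150, seed = 1,
                            label_a = "TFE3", label_b = "ccRCC") {
  stopifnot(n_per_class >= 1)
  gens <- c(rep(list(gen_a), n_per_class), rep(list(gen_b), n_per_class))
  labels <- rep(c(label_a, label_b), each = n_per_class)
  lapply(seq_along(gens), function(i) {
    s <- generate_slide(gens[[i]], size_hw, n_nuclei, seed = seed + i)
    s$class_label <- labels[i]
    s$slide_id <- sprintf("%s_%02d", labels[i], ((i - 1L) %% n_per_class) + 1L)
    s
  })
}

#' Ground-truth nucleus feature table for a synthetic slide
#'
#' The oracle against which measured nucleus features are checked: the true
#' area is obtained by counting label-mask pixels per nucleus id, axis
#' lengths and ratio come from the generative parameters, and RGB means are
#' averaged over each nucleus's mask pixels in the rendered image.
#'
#' @param slide a `synthetic_slide`.
#' @return a data frame with one row per nucleus: `nucleus_id`, true center
#'   (`center_row`, `center_col`), `area`, `major`, `minor`, `ratio`,
#'   `rMean`, `gMean`, `bMean`. Empty slide gives an empty data frame.
#' @export
ground_truth_features <- function(slide) {
  stopifnot(inherits(slide, "synthetic_slide"))
  ids <- slide$nuclei$nucleus_id
  if (length(ids) == 0)
    return(data.frame(nucleus_id = integer(0), center_row = numeric(0),
                      center_col = numeric(0), area = numeric(0),
                      major = numeric(0), minor = numeric(0),
                      ratio = numeric(0), rMean = numeric(0),
                      gMean = numeric(0), bMean = numeric(0)))
  m <- slide$label_mask
  area <- tabulate(m[m > 0], nbins = max(ids))[ids]
  ch_mean <- sapply(1:3, function(ch) {
    plane <- slide$image[, , ch]
    as.numeric(tapply(plane[m > 0], m[m > 0], mean))[match(ids, sort(unique(m[m > 0])))]
  })
  if (length(ids) == 1L) ch_mean <- matrix(ch_mean, nrow = 1)
  data.frame(nucleus_id = ids,
             center_row = slide$nuclei$center_row,
             center_col = slide$nuclei$center_col,
             area = area,
             major = slide$nuclei$major, minor = slide$nuclei$minor,
             ratio = slide$nuclei$ratio,
             rMean = ch_mean[, 1], gMean = ch_mean[, 2], bMean = ch_mean[, 3])
}

#' Nucleus feature table from a slide's ground truth
#'
#' Builds the same 10-feature-per-nucleus table as
#' [extract_nucleus_features()] but from the generative ground truth
#' (label-mask pixel counts, generator axis parameters, mask-pixel color
#' means and true centroid distances) instead of a segmentation. Useful for
#' testing downstream stages in isolation from segmentation quality, and
#' for large simulation studies where segmenting every slide would
#' dominate the runtime.
#'
#' @param slide a `synthetic_slide` with at least 2 nuclei.
#' @param k_neighbors neighbor count for the density features (default 5).
#' @return data frame with the same columns as
#'   [extract_nucleus_features()].
#' @export
nucleus_table_from_truth <- function(slide, k_neighbors = 5) {
  gt <- ground_truth_features(slide)
  if (nrow(gt) < 2)
    stop("slide needs at least 2 nuclei for density features")
  dens <- density_features(cbind(gt$center_row, gt$center_col), k_neighbors)
  data.frame(nucleus_id = gt$nucleus_id, x = gt$center_col, y = gt$center_row,
             area = gt$area, major = gt$major, minor = gt$minor,
             ratio = gt$ratio, rMean = gt$rMean, gMean = gt$gMean,
             bMean = gt$bMean, distMean = dens$distMean,
             distMax = dens$distMax, distMin = dens$distMin)
}

#' Write a synthetic cohort to disk
#'
#' Writes each slide as an 8-bit RGB PNG, its label mask as a 16-bit
#' single-channel TIFF, and a cohort manifest CSV with columns
#' `slide_id, path, mask_path, label, seed`.
#'
#' @param cohort a list of `synthetic_slide`s from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest data frame (also written to
#'   `manifest.csv` in `dir`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(s) {
    id <- if (!is.null(s$slide_id)) s$slide_id else sprintf("slide_%d", s$seed)
    img_path <- file.path(dir, paste0(id, ".png"))
    mask_path <- file.path(dir, paste0(id, "_mask.tif"))
    png::writePNG(aperm(array(s$image / 255, dim(s$image)), c(1, 2, 3)), img_path)
    tiff::writeTIFF(s$label_mask / 65535, mask_path, bits.per.sample = 16)
    data.frame(slide_id = id, path = img_path, mask_path = mask_path,
               label = s$class_label, seed = s$seed)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param manifest_path path to the manifest CSV.
#' @return a list of `synthetic_slide`-like objects (image, label mask,
#'   class label, slide id). Errors name the offending slide id if an image
#'   is missing or unreadable.
#' @export
read_cohort <- function(manifest_path) {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    img <- tryCatch(png::readPNG(row$path),
                    error = function(e) stop(sprintf(
                      "slide '%s': cannot read image at %s", row$slide_id, row$path),
                      call. = FALSE))
    mask <- NULL
    if (!is.na(row$mask_path) && nzchar(row$mask_path) && file.exists(row$mask_path))
      mask <- matrix(as.integer(round(tiff::readTIFF(row$mask_path) * 65535)),
                     nrow = dim(img)[1])
    structure(list(image = round(img[, , 1:3] * 255), label_mask = mask,
                   nuclei = NULL, class_label = row$label,
                   seed = row$seed, slide_id = row$slide_id),
              class = "synthetic_slide")
  })
}
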