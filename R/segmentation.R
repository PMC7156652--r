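#' Multilevel Otsu thresholds
#'
#' Exhaustive search for the `n_classes - 1` thresholds that maximize the
#' between-class variance of a 256-bin intensity histogram (the multilevel
#' generalization of Otsu's method). Only `n_classes` of 2 or 3 are needed
#' by the segmentation pipeline and supported here.
#'
#' @param values numeric vector of intensities in \[0, 255\].
#' @param n_classes number of intensity classes (2 or 3).
#' @return increasing numeric vector of `n_classes - 1` thresholds; a value
#'   `v` belongs to class `k` if it lies in `(t_{k-1}, t_k]`.
#' @export
multilevel_otsu <- function(values, n_classes = 3) {
  stopifnot(n_classes %in% c(2, 3), length(values) > 0)
  h <- tabulate(pmin(pmax(floor(values), 0), 255) + 1L, nbins = 256L)
  p <- h / sum(h)
  lev <- 0:255
  cw <- cumsum(p)                 # class weight up to level
  cm <- cumsum(p * lev)           # class first moment up to level
  w <- function(a, b) if (a > b) 0 else cw[b + 1L] - if (a == 0) 0 else cw[a]
  m <- function(a, b) if (a > b) 0 else cm[b + 1L] - if (a == 0) 0 else cm[a]
  crit <- function(cuts) {
    bounds <- c(0L, cuts + 1L, 256L)   # class k = [bounds[k], bounds[k+1]-1]
    s <- 0
    for (k in seq_len(length(bounds) - 1L)) {
      wk <- w(bounds[k], bounds[k + 1L] - 1L)
      if (wk > 0) s <- s + m(bounds[k], bounds[k + 1L] - 1L)^2 / wk
    }
    s
  }
  if (n_classes == 2) {
    vals <- vapply(0:254, function(t) crit(t), numeric(1))
    best <- which.max(vals) - 1L
    return(as.numeric(best))
  }
  best <- c(0L, 1L); best_val <- -Inf
  nz <- range(which(h > 0)) - 1L
  lo <- max(0L, nz[1]); hi <- min(254L, nz[2])
  for (t1 in lo:(hi - 1L)) {
    for (t2 in (t1 + 1L):hi) {
      v <- crit(c(t1, t2))
      if (v > best_val) { best_val <- v; best <- c(t1, t2) }
    }
  }
  as.numeric(best)
}

#' Segmentation parameters
#'
#' @param n_classes intensity classes for the first multilevel thresholding
#'   pass; the darkest-stained (highest hematoxylin) class seeds the nuclei.
#' @param min_area minimum object area kept, in pixels.
#' @param size_cap_factor components larger than `size_cap_factor` times the
#'   median candidate area are re-thresholded (2-class Otsu) to split clumps.
#' @param watershed_tolerance minimum height of an object's distance-map peak
#'   for it to be kept separate during watershed splitting of touching nuclei.
#' @param smooth_sigma Gaussian blur applied to the stain channel before
#'   thresholding (pixels; 0 disables).
#' @param stain_basis optional [estimate_stain_basis()] result; when present
#'   the nuclear channel is the hematoxylin concentration, otherwise the
#'   grayscale complement is used.
#' @param tissue_min_fraction tiles with a smaller fraction of tissue pixels
#'   (OD above `od_threshold`) are skipped entirely.
#' @param od_threshold OD threshold defining tissue for the gating test.
#' @param min_contrast minimum robust spread (0.1st to 99.9th percentile) of
#'   the stain channel, in gray levels, for a tile to be considered to
#'   contain stained objects at all; below it the tile yields an empty mask.
#' @return a list of class `seg_params`.
#' @export
seg_params <- function(n_classes = 3, min_area = 40, size_cap_factor = 3,
                       watershed_tolerance = 2, smooth_sigma = 1,
                       stain_basis = NULL, tissue_min_fraction = 0.05,
                       od_threshold = 0.15, min_contrast = 30) {
  structure(list(n_classes = n_classes, min_area = min_area,
                 size_cap_factor = size_cap_factor,
                 watershed_tolerance = watershed_tolerance,
                 smooth_sigma = smooth_sigma, stain_basis = stain_basis,
                 tissue_min_fraction = tissue_min_fraction,
                 od_threshold = od_threshold, min_contrast = min_contrast),
            class = "seg_params")
}

# Nuclear stain intensity channel, scaled to [0, 255] (high = nucleus).
nuclear_channel <- function(image, params) {
  if (!is.null(params$stain_basis)) {
    od <- matrix(rgb_to_od(as.numeric(image)), ncol = 3)
    conc <- stain_concentrations(od, params$stain_basis$stain_vectors)
    ch <- matrix(conc[, 1], nrow = dim(image)[1])
    255 * ch / max(ch, 1e-6)
  } else {
    255 - (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  }
}

#' Segment the nuclei in one image tile
#'
#' Hierarchical multilevel thresholding: (1) the RGB tile is reduced to a
#' nuclear-stain intensity channel; (2) multilevel Otsu with `n_classes`
#' classes marks the most stain-dense class as candidate nuclei; (3) any
#' candidate component larger than a size cap is re-thresholded with 2-class
#' Otsu inside the component, splitting clumps that the global thresholds
#' merged; (4) holes are filled, objects below `min_area` are dropped, and
#' touching nuclei are separated by watershed on the distance transform.
#'
#' @param tile_rgb RGB array, 0-255.
#' @param params a [seg_params()] list.
#' @return integer label matrix (0 = background, ids consecutive from 1).
#' @export
segment_tile <- function(tile_rgb, params = seg_params()) {
  stopifnot_rgb(tile_rgb)
  ch <- nuclear_channel(tile_rgb, params)
  if (params$smooth_sigma > 0)
    ch <- EBImage::gblur(ch, sigma = params$smooth_sigma) |> as.matrix()
  # a tile of pure background (even noisy) has no stain contrast to segment
  spread <- diff(stats::quantile(ch, c(0.001, 0.999)))
  if (spread < params$min_contrast)
    return(matrix(0L, nrow(ch), ncol(ch)))
  th <- multilevel_otsu(as.numeric(ch), params$n_classes)
  cand <- ch > th[length(th)]
  if (!any(cand)) return(matrix(0L, nrow(ch), ncol(ch)))
  lab <- EBImage::bwlabel(cand)
  areas <- tabulate(lab[lab > 0])
  cap <- params$size_cap_factor * stats::median(areas)
  big <- which(areas > cap)
  for (id in big) {
    px <- which(lab == id)
    t2 <- multilevel_otsu(ch[px], 2)
    cand[px[ch[px] <= t2]] <- FALSE
  }
  cand <- EBImage::fillHull(EBImage::bwlabel(cand)) > 0
  # drop specks before watershed so noise does not seed spurious basins
  lab <- EBImage::bwlabel(cand)
  areas <- tabulate(lab[lab > 0])
  cand[lab > 0 & areas[pmax(lab, 1)] < params$min_area] <- FALSE
  if (!any(cand)) return(matrix(0L, nrow(ch), ncol(ch)))
  dm <- EBImage::distmap(cand)
  ws <- EBImage::watershed(dm, tolerance = params$watershed_tolerance)
  lab <- matrix(as.integer(ws), nrow(ch), ncol(ch))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= params$min_area)
  relabel <- integer(max(lab))
  relabel[keep] <- seq_along(keep)
  lab[lab > 0] <- relabel[lab[lab > 0]]
  lab
}

#' Plan a tile grid covering a large image
#'
#' Tiles of `tile_size` pixels are laid out with stride
#' `tile_size - 2 * overlap`, so each interior tile has an `overlap`-wide
#' margin shared with its neighbors. Each tile owns a core region (the tile
#' minus its margins, extended to the image boundary for edge tiles); the
#' cores partition the image exactly, which is what makes centroid-in-core
#' de-duplication at stitch time unambiguous.
#'
#' @param image_hw integer pair (height, width).
#' @param tile_size tile edge in pixels (default 2000).
#' @param overlap overlap margin in pixels; must satisfy
#'   `tile_size > 2 * overlap`.
#' @return an object of class `tile_grid`: a data frame with one row per
#'   tile (`row_off`, `col_off`, `height`, `width`, and core bounds
#'   `core_r0/r1/c0/c1`, all 0-based, core end-exclusive) plus the grid
#'   attributes.
#' @export
plan_tiles <- function(image_hw, tile_size = 2000, overlap = 200) {
  stopifnot(length(image_hw) == 2, tile_size > 2 * overlap, overlap >= 0)
  offsets_1d <- function(extent) {
    stride <- tile_size - 2 * overlap
    offs <- 0L
    while (utils::tail(offs, 1) + tile_size < extent)
      offs <- c(offs, utils::tail(offs, 1) + stride)
    offs
  }
  core_1d <- function(offs, extent) {
    n <- length(offs)
    size <- pmin(tile_size, extent - offs)
    start <- ifelse(seq_len(n) == 1L, 0L, offs + overlap)
    end <- ifelse(seq_len(n) == n, extent, offs + size - overlap)
    list(size = size, start = start, end = end)
  }
  H <- image_hw[1]; W <- image_hw[2]
  ro <- offsets_1d(H); co <- offsets_1d(W)
  rr <- core_1d(ro, H); cc <- core_1d(co, W)
  g <- expand.grid(ri = seq_along(ro), ci = seq_along(co))
  tiles <- data.frame(row_off = ro[g$ri], col_off = co[g$ci],
                      height = rr$size[g$ri], width = cc$size[g$ci],
                      core_r0 = rr$start[g$ri], core_r1 = rr$end[g$ri],
                      core_c0 = cc$start[g$ci], core_c1 = cc$end[g$ci])
  structure(tiles, class = c("tile_grid", "data.frame"),
            image_hw = image_hw, tile_size = tile_size, overlap = overlap)
}

#' Stitch per-tile label masks into one slide-level segmentation
#'
#' A nucleus is kept if and only if its centroid falls inside the core
#' region of the tile it was segmented in; since cores partition the image,
#' every nucleus in an overlap band is counted exactly once. Kept nuclei are
#' relabeled consecutively.
#'
#' @param tile_masks list of integer label matrices, one per grid row.
#' @param grid the [plan_tiles()] grid the masks were computed on.
#' @return a list of class `segmentation_result`: `label_mask` (full-size
#'   integer matrix), `nucleus_ids`, and `provenance` (source tile index per
#'   nucleus).
#' @export
stitch_tiles <- function(tile_masks, grid) {
  stopifnot(inherits(grid, "tile_grid"), length(tile_masks) == nrow(grid))
  hw <- attr(grid, "image_hw")
  out <- matrix(0L, hw[1], hw[2])
  prov <- integer(0)
  next_id <- 1L
  for (i in seq_len(nrow(grid))) {
    m <- tile_masks[[i]]
    exp_h <- min(attr(grid, "tile_size"), hw[1] - grid$row_off[i])
    exp_w <- min(attr(grid, "tile_size"), hw[2] - grid$col_off[i])
    if (!all(dim(m) == c(exp_h, exp_w)))
      stop(sprintf("tile %d mask has dimensions %dx%d, expected %dx%d",
                   i, nrow(m), ncol(m), exp_h, exp_w))
    if (!any(m > 0)) next
    ids <- sort(unique(m[m > 0]))
    cr <- tapply(row(m)[m > 0] - 1 + grid$row_off[i], m[m > 0], mean)
    cc <- tapply(col(m)[m > 0] - 1 + grid$col_off[i], m[m > 0], mean)
    keep <- ids[cr >= grid$core_r0[i] & cr < grid$core_r1[i] &
                cc >= grid$core_c0[i] & cc < grid$core_c1[i]]
    for (id in keep) {
      sel <- which(m == id)
      rows <- (sel - 1L) %% nrow(m) + grid$row_off[i]
      cols <- (sel - 1L) %/% nrow(m) + grid$col_off[i]
      out[cols * hw[1] + rows + 1L] <- next_id
      prov <- c(prov, i)
      next_id <- next_id + 1L
    }
  }
  structure(list(label_mask = out, nucleus_ids = seq_len(next_id - 1L),
                 provenance = prov),
            class = "segmentation_result")
}

#' Segment a whole slide image
#'
#' Plans a tile grid, segments each tile with [segment_tile()] (skipping
#' tiles whose tissue fraction is below `params$tissue_min_fraction`), and
#' stitches the per-tile masks with centroid-in-core de-duplication.
#'
#' @inheritParams segment_tile
#' @param image RGB array, 0-255.
#' @param tile_size,overlap tiling geometry, see [plan_tiles()].
#' @return a `segmentation_result`, see [stitch_tiles()].
#' @export
segment_slide <- function(image, params = seg_params(), tile_size = 2000,
                          overlap = 200) {
  stopifnot_rgb(image)
  grid <- plan_tiles(dim(image)[1:2], tile_size, overlap)
  masks <- lapply(seq_len(nrow(grid)), function(i) {
    rows <- grid$row_off[i] + seq_len(min(tile_size, dim(image)[1] - grid$row_off[i]))
    cols <- grid$col_off[i] + seq_len(min(tile_size, dim(image)[2] - grid$col_off[i]))
    tile <- image[rows, cols, , drop = FALSE]
    od <- rgb_to_od(tile)
    od_max <- pmax(od[, , 1], od[, , 2], od[, , 3])
    if (mean(od_max >= params$od_threshold) < params$tissue_min_fraction)
      return(matrix(0L, length(rows), length(cols)))
    segment_tile(tile, params)
  })
  stitch_tiles(masks, grid)
}

#' Detection accuracy of a segmentation against ground truth
#'
#' Matches predicted and true nuclei greedily by decreasing intersection
#' over union (IoU), each object used at most once; a match counts when its
#' IoU reaches `iou_threshold`.
#'
#' @param pred_mask,true_mask integer label matrices of equal size.
#' @param iou_threshold minimum IoU for a valid match (default 0.5).
#' @return list with `recall`, `precision`, `n_matched`, `mean_iou` (over
#'   matched pairs), `n_pred`, `n_true`.
#' @export
segmentation_accuracy <- function(pred_mask, true_mask, iou_threshold = 0.5) {
  stopifnot(all(dim(pred_mask) == dim(true_mask)))
  n_pred <- length(unique(pred_mask[pred_mask > 0]))
  n_true <- length(unique(true_mask[true_mask > 0]))
  if (n_pred == 0 || n_true == 0)
    return(list(recall = 0, precision = 0, n_matched = 0L, mean_iou = NA_real_,
                n_pred = n_pred, n_true = n_true))
  a_pred <- tabulate(pred_mask[pred_mask > 0], nbins = max(pred_mask))
  a_true <- tabulate(true_mask[true_mask > 0], nbins = max(true_mask))
  both <- pred_mask > 0 & true_mask > 0
  ov <- as.data.frame(table(p = pred_mask[both], t = true_mask[both]),
                      stringsAsFactors = FALSE)
  ov <- ov[ov$Freq > 0, ]
  ov$p <- as.integer(ov$p); ov$t <- as.integer(ov$t)
  ov$iou <- ov$Freq / (a_pred[ov$p] + a_true[ov$t] - ov$Freq)
  ov <- ov[order(-ov$iou), ]
  used_p <- logical(max(pred_mask)); used_t <- logical(max(true_mask))
  matched <- 0L; ious <- numeric(0)
  for (i in seq_len(nrow(ov))) {
    if (ov$iou[i] < iou_threshold) break
    if (used_p[ov$p[i]] || used_t[ov$t[i]]) next
    used_p[ov$p[i]] <- TRUE; used_t[ov$t[i]] <- TRUE
    matched <- matched + 1L
    ious <- c(ious, ov$iou[i])
  }
  list(recall = matched / n_true, precision = matched / n_pred,
       n_matched = matched, mean_iou = if (matched) mean(ious) else NA_real_,
       n_pred = n_pred, n_true = n_true)
}
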