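#' Stain basis estimation and color normalization for H&E images
#'
#' Slides scanned at different institutions differ in color appearance, and
#' intensity-based features are only comparable after mapping images to a
#' common stain appearance. These functions implement a deterministic
#' stain-deconvolution normalizer: pixel colors are converted to optical
#' density (OD), the two dominant stain directions (hematoxylin and eosin)
#' are estimated from the tissue pixels by a plane fit (SVD) with robust
#' extreme-angle selection, and per-pixel stain concentrations are rescaled
#' to a reference basis and re-rendered with the reference stain colors.
#' Geometry is untouched: only pixel colors change.
#'
#' @name stain_norm
NULL

# OD transform: 8-bit intensity -> optical density per channel.
rgb_to_od <- function(x) -log((x + 1) / 256)
od_to_rgb <- function(od) clamp(round(256 * exp(-od) - 1), 0, 255)

# Fixed fallback basis (unit-norm hematoxylin / eosin OD directions) used
# when the tissue is effectively single-stain.
fallback_basis <- function() {
  v <- rbind(c(0.650, 0.704, 0.286), c(0.072, 0.990, 0.105))
  v / sqrt(rowSums(v^2))
}

#' Estimate the stain basis of an H&E image
#'
#' @param image RGB array (H x W x 3, values 0-255).
#' @param od_background_threshold pixels whose OD is below this value in
#'   every channel are treated as background and excluded (default 0.15).
#' @param conc_percentile percentile used for the robust per-stain maximum
#'   concentration (default 99).
#' @param angle_percentile robust percentile for the extreme-angle selection
#'   on the OD plane (default 1, i.e. the 1st/99th percentile directions).
#' @return an object of class `stain_basis`: `stain_vectors` (2 x 3 matrix
#'   of unit OD vectors, row 1 = hematoxylin, row 2 = eosin) and
#'   `max_concentrations` (length-2 positive vector).
#' @export
estimate_stain_basis <- function(image, od_background_threshold = 0.15,
                                 conc_percentile = 99, angle_percentile = 1) {
  stopifnot_rgb(image)
  od <- matrix(rgb_to_od(as.numeric(image)), ncol = 3)
  tissue <- od[apply(od, 1, max) >= od_background_threshold, , drop = FALSE]
  if (nrow(tissue) < 0.01 * nrow(od) || nrow(tissue) < 2)
    stop("no tissue: too few pixels above the OD background threshold")
  sv <- svd(tissue, nu = 0, nv = 3)
  basis <- if (sv$d[2] < 1e-3 * sv$d[1]) {
    # rank-1 color content: direction forced, second vector from fallback
    v1 <- sv$v[, 1] * sign(sum(sv$v[, 1]))
    fb <- fallback_basis()
    ang <- abs(fb %*% v1)
    rbind(v1, fb[which.min(ang), ])
  } else {
    e <- sv$v[, 1:2]
    e[, 1] <- e[, 1] * sign(sum(e[, 1]))   # point into the positive octant
    proj <- tissue %*% e
    phi <- atan2(proj[, 2], proj[, 1])
    q <- stats::quantile(phi, c(angle_percentile, 100 - angle_percentile) / 100)
    v1 <- e %*% c(cos(q[1]), sin(q[1]))
    v2 <- e %*% c(cos(q[2]), sin(q[2]))
    rbind(as.numeric(v1), as.numeric(v2))
  }
  basis[basis < 0] <- 0
  basis <- basis / sqrt(rowSums(basis^2))
  # hematoxylin (blue-purple) absorbs more red light than eosin
  if (basis[1, 1] < basis[2, 1]) basis <- basis[2:1, , drop = FALSE]
  rownames(basis) <- c("hematoxylin", "eosin")
  conc <- stain_concentrations(od, basis)
  cmax <- apply(conc, 2, stats::quantile, probs = conc_percentile / 100)
  cmax <- pmax(cmax, 1e-6)
  structure(list(stain_vectors = basis, max_concentrations = as.numeric(cmax)),
            class = "stain_basis")
}

# Least-squares per-pixel stain concentrations (N x 2), clipped at 0.
stain_concentrations <- function(od, basis) {
  if (abs(det(basis %*% t(basis))) < 1e-8)
    stop("singular stain basis: stain vectors are not linearly independent")
  conc <- od %*% t(basis) %*% solve(basis %*% t(basis))
  conc[conc < 0] <- 0
  conc
}

#' Normalize an image's stain appearance to a reference basis
#'
#' @param image RGB array (0-255).
#' @param source a `stain_basis` estimated from `image` (or its dataset).
#' @param reference a `stain_basis` estimated from the reference image.
#' @details The OD component not explained by the two source stain vectors
#'   (noise and off-plane color) is carried over unchanged rather than
#'   discarded, so normalizing an image to its own basis is the identity up
#'   to quantization.
#' @return an RGB array of the same size, 0-255, re-rendered with the
#'   reference stain vectors and concentration scale.
#' @export
normalize_image <- function(image, source, reference) {
  stopifnot_rgb(image)
  stopifnot(inherits(source, "stain_basis"), inherits(reference, "stain_basis"))
  dm <- dim(image)
  od <- matrix(rgb_to_od(as.numeric(image)), ncol = 3)
  conc <- stain_concentrations(od, source$stain_vectors)
  residual <- od - conc %*% source$stain_vectors
  conc <- sweep(conc, 2, reference$max_concentrations / source$max_concentrations, `*`)
  od_new <- conc %*% reference$stain_vectors + residual
  array(od_to_rgb(od_new), dim = dm)
}
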