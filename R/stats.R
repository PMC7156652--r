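#' Two-sided Mann-Whitney U test
#'
#' Rank-sum test for a location difference between two independent samples.
#' The returned U statistic counts the pairs `(x_i, y_j)` with `x_i > y_j`
#' (ties counted 1/2). The exact null distribution is used for small
#' tie-free samples (both groups of size at most `exact_max`); otherwise the
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param exact_max largest group size for which the exact distribution is
#'   used (default 8; ties always force the normal approximation).
#' @return list with `u` and `p` (two-sided).
#' @export
mann_whitney_u <- function(x, y, exact_max = 8) {
  if (length(x) == 0 || length(y) == 0)
    stop("both groups must be non-empty")
  if (length(unique(c(x, y))) == 1L)   # all values tied: no evidence either way
    return(list(u = length(x) * length(y) / 2, p = 1))
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && min(length(x), length(y)) <= exact_max
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = TRUE))
  list(u = as.numeric(wt$statistic), p = min(wt$p.value, 1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; the output is in the same order
#' as the input.
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Compare every image-level feature between the two classes
#'
#' Each feature is tested with a two-sided Mann-Whitney U test between the
#' positive (TFE3-like) and comparison (ccRCC-like) groups; p-values are
#' adjusted by Benjamini-Hochberg FDR. The fold change is the ratio of the
#' class medians, comparison class over positive class; a significant
#' feature is "overrepresented" when its median in the positive class
#' exceeds the comparison-class median (equivalently fold change < 1) and
#' "underrepresented" in the opposite case.
#'
#' @param feature_matrix data frame or matrix, slides x features.
#' @param labels factor/character vector of class labels per slide.
#' @param positive_class label of the positive group (default "TFE3").
#' @param alpha significance level on the adjusted p-values (default 0.05).
#' @return data frame of class `feature_comparison` with columns `feature`,
#'   `u_statistic`, `p_raw`, `p_adjusted`, `median_positive`,
#'   `median_comparison`, `fold_change` (`Inf`, flagged in
#'   `fold_change_degenerate`, when the positive-class median is 0),
#'   `significant`, `representation` (one of "overrepresented",
#'   "underrepresented", "ns").
#' @export
compare_features <- function(feature_matrix, labels, positive_class = "TFE3",
                             alpha = 0.05) {
  labels <- as.character(labels)
  stopifnot(nrow(feature_matrix) == length(labels),
            positive_class %in% labels, length(unique(labels)) == 2)
  pos <- labels == positive_class
  if (sum(pos) < 2 || sum(!pos) < 2)
    stop("need at least 2 slides per class")
  feats <- colnames(feature_matrix)
  res <- lapply(feats, function(f) {
    xp <- feature_matrix[[f]][pos]
    xc <- feature_matrix[[f]][!pos]
    mw <- mann_whitney_u(xp, xc)
    mp <- stats::median(xp); mc <- stats::median(xc)
    fc <- if (mp == 0) Inf else mc / mp
    data.frame(feature = f, u_statistic = mw$u, p_raw = mw$p,
               median_positive = mp, median_comparison = mc,
               fold_change = fc, fold_change_degenerate = mp == 0)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- bh_fdr(out$p_raw)
  out$significant <- out$p_adjusted < alpha
  out$representation <- ifelse(!out$significant, "ns",
                        ifelse(out$median_positive > out$median_comparison,
                               "overrepresented",
                        ifelse(out$median_positive < out$median_comparison,
                               "underrepresented", "ns")))
  class(out) <- c("feature_comparison", "data.frame")
  out
}
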