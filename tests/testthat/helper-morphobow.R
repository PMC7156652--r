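# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; no binary fixtures.

# Small, fast generator presets for unit tests (fewer/smaller nuclei than
# the cohort presets so individual tests run in milliseconds).
small_gen <- function(area_meanlog = log(150), area_sdlog = 0.2,
                      cluster_radius = 60, nuclei_per_cluster = 4, ...) {
  class_generator(area_meanlog = area_meanlog, area_sdlog = area_sdlog,
                  cluster_radius = cluster_radius,
                  nuclei_per_cluster = nuclei_per_cluster, ...)
}

# Mean nearest-neighbor distance of true nucleus centers, computed directly
# from the generative parameters (brute force; oracle for clumping checks).
mean_nn_distance <- function(slide) {
  xy <- as.matrix(slide$nuclei[, c("center_row", "center_col")])
  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# choose(nx+ny, nx) group assignments (oracle; tie-free inputs only).
mw_exact_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  u_obs <- sum(outer(x, y, ">"))
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, function(idx)
    sum(outer(pooled[idx], pooled[-idx], ">")))
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Step-up BH adjustment applied by hand (oracle).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# AUC by brute-force pairwise comparison, ties counted 1/2 (oracle).
auc_oracle <- function(scores, labels, positive = "TFE3") {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
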