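# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopifnot_rgb <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("expected an RGB array of dimension H x W x 3", call. = FALSE)
  invisible(image)
}

# Feature types measured per nucleus, in canonical order.
NUCLEUS_FEATURE_TYPES <- c("area", "major", "minor", "ratio",
                           "rMean", "gMean", "bMean",
                           "distMean", "distMax", "distMin")
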