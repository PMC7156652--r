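#' Learn the bag-of-visual-words codebook from training nuclei
#'
#' For each of the 10 nucleus-level feature types, nucleus values are pooled
#' across the training slides (uniformly subsampled per slide to bound
#' memory) and clustered by 1-D K-means into `n_words` representative
#' "words". The sorted centroids become the histogram bin centers, so bin 1
#' always corresponds to the smallest values of a feature (e.g. `area_bin1`
#' counts the smallest nuclei) and bins read from small to large.
#'
#' The codebook must be learned from training slides only; assembling
#' feature vectors for validation slides never updates it.
#'
#' @param training_records list of per-slide nucleus feature tables from
#'   [extract_nucleus_features()] (training split only).
#' @param n_words words (bins) per feature type, default 10.
#' @param sample_per_slide cap on nuclei sampled per slide (default 10000).
#' @param seed RNG seed controlling subsampling and K-means restarts.
#' @param n_restarts K-means restarts (`nstart`), default 10.
#' @return object of class `bow_codebook`: named list mapping each feature
#'   type to its sorted centroid vector, with attributes recording the
#'   sample size and seed.
#' @export
learn_codebook <- function(training_records, n_words = 10,
                           sample_per_slide = 10000, seed = 1,
                           n_restarts = 10) {
  stopifnot(length(training_records) >= 1)
  with_seed(seed, {
    pooled <- lapply(NUCLEUS_FEATURE_TYPES, function(type) {
      unlist(lapply(training_records, function(tab) {
        v <- tab[[type]]
        if (length(v) > sample_per_slide)
          v <- v[sample.int(length(v), sample_per_slide)]
        v
      }))
    })
    names(pooled) <- NUCLEUS_FEATURE_TYPES
    words <- lapply(NUCLEUS_FEATURE_TYPES, function(type) {
      v <- pooled[[type]]
      nd <- length(unique(v))
      if (nd < n_words)
        stop(sprintf("feature '%s' has only %d distinct values; %d words requested",
                     type, nd, n_words))
      if (nd == n_words) return(sort(unique(v)))
      # Hartigan-Wong emits spurious Quick-TRANSFER warnings on heavily
      # tied 1-D data; restarts make the fit robust regardless
      km <- suppressWarnings(stats::kmeans(v, centers = n_words,
                                           nstart = n_restarts,
                                           iter.max = 100))
      sort(as.numeric(km$centers))
    })
    names(words) <- NUCLEUS_FEATURE_TYPES
    structure(words, class = "bow_codebook",
              n_nuclei = length(pooled[[1]]), seed = seed)
  })
}

#' L1-normalized word histogram of one slide's values for one feature type
#'
#' Each value is assigned to the nearest word (absolute difference; a value
#' equidistant between two words goes to the lower bin), and the counts are
#' divided by the number of values so slides with different nucleus counts
#' are comparable.
#'
#' @param values numeric vector (one slide, one feature type).
#' @param words sorted centroid vector from the codebook.
#' @return numeric vector of `length(words)` proportions summing to 1; for
#'   an empty slide, all zeros with a warning.
#' @export
histogram_features <- function(values, words) {
  stopifnot(!is.unsorted(words))
  if (length(values) == 0) {
    warning("no values: returning an all-zero histogram")
    return(rep(0, length(words)))
  }
  mids <- (words[-1] + words[-length(words)]) / 2
  bins <- findInterval(values, mids, left.open = TRUE) + 1L
  tabulate(bins, nbins = length(words)) / length(values)
}

#' Distribution statistics of one slide's values for one feature type
#'
#' Mean, standard deviation, skewness and kurtosis are population (biased)
#' moment statistics of the raw values; kurtosis is the non-excess (Pearson)
#' form, so a normal sample has kurtosis near 3. Entropy is Shannon entropy
#' in bits of the L1-normalized word histogram, so it ranges from 0 (all
#' nuclei in one bin) to log2 of the number of bins.
#'
#' @param values numeric vector of raw nucleus values.
#' @param normalized_histogram the matching [histogram_features()] output.
#' @return named numeric vector `(mean, std, skewness, kurtosis, entropy)`.
#'   With a single value, std/skewness/kurtosis are set to 0 with a warning;
#'   with zero spread, skewness and kurtosis are 0.
#' @export
distribution_stats <- function(values, normalized_histogram) {
  p <- normalized_histogram[normalized_histogram > 0]
  entropy <- if (length(p)) -sum(p * log2(p)) else 0
  if (length(values) < 2) {
    if (length(values) == 1)
      warning("single value: std, skewness and kurtosis set to 0")
    m <- if (length(values)) values else NA_real_
    return(c(mean = m, std = 0, skewness = 0, kurtosis = 0, entropy = entropy))
  }
  m <- mean(values)
  s2 <- mean((values - m)^2)
  s <- sqrt(s2)
  if (s < .Machine$double.eps^0.5) {
    skew <- 0; kurt <- 0
  } else {
    skew <- mean((values - m)^3) / s^3
    kurt <- mean((values - m)^4) / s2^2
  }
  c(mean = m, std = s, skewness = skew, kurtosis = kurt, entropy = entropy)
}

#' Serialize a codebook to JSON / read it back
#'
#' @param codebook a [learn_codebook()] result.
#' @param path JSON file path.
#' @return `read_codebook` returns a `bow_codebook`; `write_codebook`
#'   returns `path` invisibly.
#' @export
write_codebook <- function(codebook, path) {
  stopifnot(inherits(codebook, "bow_codebook"))
  jsonlite::write_json(list(words = unclass(codebook),
                            n_nuclei = attr(codebook, "n_nuclei"),
                            seed = attr(codebook, "seed")),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(as.list(obj$words), class = "bow_codebook",
            n_nuclei = obj$n_nuclei, seed = obj$seed)
}

#' Assemble the 150 image-level features for one slide
#'
#' For each of the 10 nucleus-level feature types, the slide's nucleus
#' values are summarized as a 10-bin bag-of-visual-words histogram plus the
#' five distribution statistics, giving 15 image-level features per type
#' and 150 in total, named `<type>_bin1` ... `<type>_bin10`, `<type>_mean`,
#' `<type>_std`, `<type>_skewness`, `<type>_kurtosis`, `<type>_entropy`.
#'
#' @param nucleus_table a slide's [extract_nucleus_features()] table.
#' @param codebook a [learn_codebook()] result.
#' @return named numeric vector of length `15 * length(codebook)` (150 with
#'   the default 10 types).
#' @export
assemble_feature_vector <- function(nucleus_table, codebook) {
  stopifnot(inherits(codebook, "bow_codebook"))
  missing <- setdiff(names(codebook), names(nucleus_table))
  if (length(missing))
    stop("nucleus table is missing feature column(s): ",
         paste(missing, collapse = ", "))
  out <- lapply(names(codebook), function(type) {
    values <- nucleus_table[[type]]
    words <- codebook[[type]]
    h <- suppressWarnings(histogram_features(values, words))
    s <- suppressWarnings(distribution_stats(values, h))
    if (length(values) == 0) s[] <- 0
    v <- c(h, s)
    names(v) <- c(paste0(type, "_bin", seq_along(words)),
                  paste0(type, "_", c("mean", "std", "skewness",
                                      "kurtosis", "entropy")))
    v
  })
  unlist(out)
}

#' Assemble the image-level feature matrix for a set of slides
#'
#' @param nucleus_tables named list of per-slide nucleus tables.
#' @param codebook a [learn_codebook()] result (training slides only).
#' @return data frame with one row per slide (rownames = slide names) and
#'   150 feature columns. Slides with no nuclei get all-zero rows and are
#'   reported via a warning so they can be excluded from model fitting.
#' @export
assemble_feature_matrix <- function(nucleus_tables, codebook) {
  vecs <- lapply(nucleus_tables, assemble_feature_vector, codebook = codebook)
  m <- do.call(rbind, vecs)
  empty <- vapply(nucleus_tables, function(t) nrow(t) == 0, logical(1))
  if (any(empty))
    warning("slide(s) with no nuclei produced all-zero feature rows: ",
            paste(names(nucleus_tables)[empty], collapse = ", "))
  as.data.frame(m)
}
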