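#' Normalization specification
#'
#' One of six normalization variants used as a preprocessing
#' hyperparameter: `minmax`, `standard`, `robust`, each either global or
#' per batch. Per-batch z-scoring forces every batch to have feature mean
#' 0 and unit variance, which by itself removes location/scale batch
#' effects.
#'
#' @param method `"minmax"`, `"standard"` or `"robust"`.
#' @param per_batch compute statistics within each batch independently?
#' @return a `norm_spec` object.
#' @export
norm_spec <- function(method = c("standard", "minmax", "robust"),
                      per_batch = FALSE) {
  method <- match.arg(method)
  structure(list(method = method, per_batch = isTRUE(per_batch)),
            class = "norm_spec")
}

#' The six named normalization variants
#'
#' @return character vector of the six variant names accepted by
#'   [norm_spec_from_name()].
#' @export
norm_variants <- function() {
  c("minmax", "standard", "robust",
    "minmax_per_batch", "standard_per_batch", "robust_per_batch")
}

#' Build a norm_spec from its variant name
#'
#' @param name one of [norm_variants()].
#' @return a [norm_spec()].
#' @export
norm_spec_from_name <- function(name) {
  if (!name %in% norm_variants())
    stop("unknown normalization '", name, "'; valid: ",
         paste(norm_variants(), collapse = ", "))
  per_batch <- grepl("_per_batch$", name)
  norm_spec(sub("_per_batch$", "", name), per_batch)
}

# Column statistics for one scaling method on a sub-matrix.
scale_stats <- function(x, method) {
  switch(method,
    minmax = {
      lo <- apply(x, 2, min); hi <- apply(x, 2, max)
      list(center = lo, scale = hi - lo)
    },
    standard = {
      list(center = colMeans(x), scale = apply(x, 2, stats::sd))
    },
    robust = {
      med <- apply(x, 2, stats::median)
      q <- apply(x, 2, stats::quantile, probs = c(0.25, 0.75),
                 type = 7, names = FALSE)
      list(center = med, scale = q[2, ] - q[1, ])
    })
}

apply_scale <- function(x, st) {
  sc <- st$scale
  degenerate <- !is.finite(sc) | sc == 0
  if (any(degenerate)) {
    warning(sum(degenerate),
            " zero-variance feature(s) set to 0 during normalization")
    sc[degenerate] <- 1
  }
  out <- sweep(sweep(x, 2, st$center, "-"), 2, sc, "/")
  out[, degenerate] <- 0
  out
}

#' Normalize the features of an omics_matrix
#'
#' `minmax` maps each feature to \[0, 1\] by its min/max; `standard`
#' z-scores each feature; `robust` centers on the median and scales by the
#' interquartile range (25th/75th percentiles, linear interpolation). With
#' `per_batch = TRUE` the statistics are computed within each batch
#' independently. Zero-variance features are set to 0 with a warning
#' instead of dividing by zero.
#'
#' Statistics default to being fit on all samples (transductive, matching
#' a whole-dataset unsupervised warmup); pass `fit_on` to fit on a subset
#' (e.g. training samples only) for a leakage-free protocol.
#'
#' @param m an `omics_matrix`.
#' @param spec a [norm_spec()] or a variant name from [norm_variants()].
#' @param fit_on optional logical/integer sample mask on which statistics
#'   are computed; all samples are transformed either way.
#' @return the normalized `omics_matrix` (values may be negative after
#'   centering; downstream code treats them as z-scores, not intensities).
#' @export
normalize_omics <- function(m, spec, fit_on = NULL) {
  stopifnot(inherits(m, "omics_matrix"))
  if (is.character(spec)) spec <- norm_spec_from_name(spec)
  stopifnot(inherits(spec, "norm_spec"))
  x <- m$values
  fit_idx <- if (is.null(fit_on)) seq_len(nrow(x)) else which(
    if (is.logical(fit_on)) fit_on else seq_len(nrow(x)) %in% fit_on)
  if (!length(fit_idx)) stop("fit_on selects no samples")
  if (spec$per_batch) {
    for (b in unique(m$batch_labels)) {
      rows <- which(m$batch_labels == b)
      fit_rows <- intersect(rows, fit_idx)
      if (!length(fit_rows)) fit_rows <- rows
      if (length(fit_rows) < 2 && spec$method %in% c("standard", "robust"))
        stop("batch '", b, "' has fewer than 2 samples to fit ",
             spec$method, " statistics")
      st <- scale_stats(x[fit_rows, , drop = FALSE], spec$method)
      x[rows, ] <- apply_scale(x[rows, , drop = FALSE], st)
    }
  } else {
    st <- scale_stats(x[fit_idx, , drop = FALSE], spec$method)
    x <- apply_scale(x, st)
  }
  out <- m
  out$values <- x
  out
}

#' Full preprocessing pipeline: log1p then normalization
#'
#' @inheritParams normalize_omics
#' @return the preprocessed `omics_matrix`.
#' @export
preprocess <- function(m, spec = norm_spec("standard"), fit_on = NULL) {
  normalize_omics(log1p_transform(m), spec, fit_on)
}
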