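#' KNN batch-membership probabilities
#'
#' Fits a k-nearest-neighbour batch classifier (Euclidean distance) on the
#' embeddings and returns, for every sample, the relative frequency of each
#' batch among its k nearest neighbours. By default the neighbourhood
#' includes the query sample itself, mirroring the behaviour of fitting and
#' predicting a standard KNN classifier on the same data; set
#' `include_self = FALSE` for leave-self-out neighbourhoods.
#'
#' @param embeddings numeric matrix, samples x dimensions.
#' @param batch_labels per-sample batch labels.
#' @param k number of neighbours (default 20).
#' @param include_self count the query point as its own neighbour?
#' @return a `batch_probabilities` object: list with `probs`
#'   (samples x K matrix, rows summing to 1) and `batch_order` (the K
#'   batch labels, sorted).
#' @export
knn_batch_probabilities <- function(embeddings, batch_labels, k = 20,
                                    include_self = TRUE) {
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  batch_labels <- as.character(batch_labels)
  stopifnot(length(batch_labels) == n, ncol(embeddings) >= 1)
  if (k < 1) stop("k must be >= 1")
  needed <- if (include_self) k else k + 1
  if (n < needed)
    stop(sprintf("k = %d requires at least %d samples, got %d", k, needed, n))
  batches <- sort(unique(batch_labels))
  K <- length(batches)
  bidx <- match(batch_labels, batches)
  d2 <- squared_dist(embeddings)
  probs <- matrix(0, n, K, dimnames = list(rownames(embeddings), batches))
  for (i in seq_len(n)) {
    di <- d2[i, ]
    if (!include_self) di[i] <- Inf
    # stable order: ties broken by sample index
    nb <- order(di)[seq_len(k)]
    tab <- tabulate(bidx[nb], nbins = K)
    probs[i, ] <- tab / k
  }
  structure(list(probs = probs, batch_order = batches),
            class = "batch_probabilities")
}

squared_dist <- function(x) {
  s <- rowSums(x^2)
  d2 <- outer(s, s, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  d2
}

#' Shannon entropy of a batch-membership probability vector
#'
#' `H(p) = sum_i p_i * log(1/p_i)` in nats, with `0 * log(1/0) := 0`.
#' Maximal (`log K`) for the uniform vector over K batches, 0 for a
#' one-hot vector.
#'
#' @param p probability vector summing to 1.
#' @return entropy in nats.
#' @export
batch_entropy <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) stop("probabilities must sum to 1")
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

#' Normalized batch entropy (nBE)
#'
#' Per sample, `nBE_i = (log K - BE_i) / log K` where `BE_i` is the
#' Shannon entropy of the KNN batch-membership probabilities of sample i
#' and K the number of batches; the dataset-level value is the mean over
#' samples. 0 means perfect batch mixing (every neighbourhood batch
#' distribution uniform), 1 means perfect batch separation (one-hot).
#'
#' @param bp a `batch_probabilities` object from
#'   [knn_batch_probabilities()], or a bare probability matrix.
#' @return scalar in \[0, 1\].
#' @export
normalized_batch_entropy <- function(bp) {
  probs <- if (inherits(bp, "batch_probabilities")) bp$probs else as.matrix(bp)
  K <- ncol(probs)
  if (K < 2) stop("nBE requires K >= 2 batches")
  be <- apply(probs, 1, batch_entropy)
  mean((log(K) - be) / log(K))
}

contingency <- function(pred, true) {
  pred <- as.character(pred); true <- as.character(true)
  if (length(pred) != length(true))
    stop("pred and true must have equal length")
  table(pred, true)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-adjusted agreement computed from the contingency table of the
#' two labelings: 1 for identical partitions (up to label renaming),
#' about 0 for independent ones. Used here to compare KNN batch
#' predictions with true batch labels, where values near 0 indicate good
#' batch mixing.
#'
#' @param pred,true label vectors of equal length (>= 2).
#' @return scalar <= 1.
#' @export
adjusted_rand_index <- function(pred, true) {
  tab <- contingency(pred, true)
  if (sum(tab) < 2) stop("need at least 2 samples")
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  a <- rowSums(tab); b <- colSums(tab)
  sum_a <- sum(choose(a, 2)); sum_b <- sum(choose(b, 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)  # both partitions trivial
  unname((sum_ij - expected) / (maximum - expected))
}

entropy_counts <- function(cnt) {
  p <- cnt[cnt > 0] / sum(cnt)
  -sum(p * log(p))
}

# Expected mutual information under the permutation (hypergeometric) model.
expected_mi <- function(a, b, n) {
  emi <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      lo <- max(1, a[i] + b[j] - n)
      hi <- min(a[i], b[j])
      if (hi < lo) next
      for (nij in lo:hi) {
        term <- nij / n * log(n * nij / (a[i] * b[j]))
        lp <- lgamma(a[i] + 1) + lgamma(b[j] + 1) +
          lgamma(n - a[i] + 1) + lgamma(n - b[j] + 1) -
          lgamma(n + 1) - lgamma(nij + 1) - lgamma(a[i] - nij + 1) -
          lgamma(b[j] - nij + 1) - lgamma(n - a[i] - b[j] + nij + 1)
        emi <- emi + term * exp(lp)
      }
    }
  }
  emi
}

#' Adjusted mutual information between two partitions
#'
#' `AMI = (MI - E[MI]) / (mean(H(U), H(V)) - E[MI])`, where the expected
#' mutual information is taken under the hypergeometric model of random
#' partitions with fixed marginals. 1 for identical partitions, about 0
#' for independent ones. The normalizer is the arithmetic mean of the two
#' partition entropies.
#'
#' @param pred,true label vectors of equal length (>= 2).
#' @return scalar <= 1.
#' @export
adjusted_mutual_information <- function(pred, true) {
  tab <- contingency(pred, true)
  n <- sum(tab)
  if (n < 2) stop("need at least 2 samples")
  a <- rowSums(tab); b <- colSums(tab)
  hu <- entropy_counts(a); hv <- entropy_counts(b)
  if (hu == 0 && hv == 0) return(1)  # both single-cluster: identical
  p <- tab / n
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    if (tab[i, j] > 0)
      mi <- mi + p[i, j] * log(p[i, j] / (a[i] / n * b[j] / n))
  }
  emi <- expected_mi(a, b, n)
  normalizer <- (hu + hv) / 2
  denom <- normalizer - emi
  if (abs(denom) < 1e-15) return(0)
  unname((mi - emi) / denom)
}

#' Matthews correlation coefficient
#'
#' Binary MCC from the confusion matrix; for more than two classes the
#' generalized (Gorodkin) multi-category form is used, equal to the
#' Pearson correlation of the indicator matrices. Returns 0 (with a
#' message) when the denominator is degenerate, e.g. when every prediction
#' is the same class.
#'
#' @param pred,true label vectors of equal length.
#' @return scalar in \[-1, 1\].
#' @export
mcc <- function(pred, true) {
  pred <- as.character(pred); true <- as.character(true)
  if (length(pred) != length(true)) stop("pred and true lengths differ")
  classes <- sort(unique(c(pred, true)))
  tab <- table(factor(pred, classes), factor(true, classes))
  n <- sum(tab)
  correct <- sum(diag(tab))
  pk <- rowSums(tab)   # predicted counts
  tk <- colSums(tab)   # true counts
  num <- correct * n - sum(pk * tk)
  den <- sqrt(n^2 - sum(pk^2)) * sqrt(n^2 - sum(tk^2))
  if (den == 0) {
    message("MCC denominator degenerate; returning 0")
    return(0)
  }
  num / den
}

#' Accuracy
#' @param pred,true label vectors of equal length.
#' @return fraction of matching labels.
#' @export
accuracy <- function(pred, true) {
  if (length(pred) != length(true)) stop("pred and true lengths differ")
  mean(as.character(pred) == as.character(true))
}

#' Average Pearson correlation among pooled-QC samples (aPCC)
#'
#' Pooled-QC injections are replicates of one sample, so after perfect
#' batch correction every pair should correlate perfectly across features.
#' Returns the mean Pearson correlation over all unordered QC pairs
#' (constant-profile pairs are excluded with a warning), or `NA` when the
#' matrix holds fewer than two QC samples.
#'
#' @param m an `omics_matrix` (any representation: intensities, z-scores
#'   or reconstructions, as long as features are columns).
#' @return scalar in \[-1, 1\] or `NA_real_`.
#' @export
qc_apcc <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  qc <- m$values[m$qc_flags, , drop = FALSE]
  if (nrow(qc) < 2) return(NA_real_)
  cors <- c()
  dropped <- 0L
  for (i in seq_len(nrow(qc) - 1)) {
    for (j in (i + 1):nrow(qc)) {
      if (stats::sd(qc[i, ]) == 0 || stats::sd(qc[j, ]) == 0) {
        dropped <- dropped + 1L
        next
      }
      cors <- c(cors, stats::cor(qc[i, ], qc[j, ]))
    }
  }
  if (dropped > 0)
    warning(dropped, " QC pair(s) with a constant profile excluded from aPCC")
  if (!length(cors)) return(NA_real_)
  mean(cors)
}

#' Normalized median Euclidean distance of pooled-QC samples (nMED)
#'
#' The median pairwise Euclidean distance among QC samples divided by the
#' median pairwise distance among non-QC samples. 0 means all QC
#' injections coincide; the denominator guards against transformations
#' that shrink all distances alike.
#'
#' @param m an `omics_matrix`.
#' @return non-negative scalar, or `NA` with < 2 QC or < 2 non-QC samples.
#' @export
qc_nmed <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  qc <- m$values[m$qc_flags, , drop = FALSE]
  non <- m$values[!m$qc_flags, , drop = FALSE]
  if (nrow(qc) < 2 || nrow(non) < 2) return(NA_real_)
  med_qc <- stats::median(stats::dist(qc))
  med_non <- stats::median(stats::dist(non))
  if (med_non == 0)
    stop("median non-QC distance is 0; degenerate dataset")
  med_qc / med_non
}

#' Assemble an evaluation report for one representation
#'
#' Batch-mixing metrics (nBE, ARI, AMI) are computed on the embeddings via
#' a KNN batch classifier; classification metrics (MCC, accuracy) compare
#' `label_pred` with the class labels of non-QC samples; QC metrics (aPCC,
#' nMED) are computed on `qc_matrix` (default: an `omics_matrix` wrapping
#' the embeddings) and are `NA` unless it holds at least two QC samples.
#'
#' @param embeddings samples x d matrix, row-aligned with `m`.
#' @param m the annotated `omics_matrix` the embeddings came from.
#' @param label_pred predicted class labels for the non-QC samples (or for
#'   all samples; QC rows are ignored), or `NULL` to skip
#'   classification metrics.
#' @param k neighbours for the KNN batch classifier.
#' @param qc_matrix `omics_matrix` on which QC metrics are computed;
#'   defaults to the embeddings with `m`'s annotations.
#' @return an `evaluation_report`: list with `mcc`, `accuracy`, `nbe`,
#'   `ari`, `ami`, `qc_apcc`, `qc_nmed`.
#' @export
evaluate_representation <- function(embeddings, m, label_pred = NULL,
                                    k = 20, qc_matrix = NULL) {
  stopifnot(inherits(m, "omics_matrix"))
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) != nrow(m$values))
    stop("embeddings not row-aligned with the omics_matrix")
  if (length(unique(m$batch_labels)) >= 2) {
    bp <- knn_batch_probabilities(embeddings, m$batch_labels, k = k)
    batch_pred <- bp$batch_order[max.col(bp$probs, ties.method = "first")]
    nbe <- normalized_batch_entropy(bp)
    ari <- adjusted_rand_index(batch_pred, m$batch_labels)
    ami <- adjusted_mutual_information(batch_pred, m$batch_labels)
  } else {
    warning("batch-mixing metrics undefined with a single batch")
    nbe <- ari <- ami <- NA_real_
  }
  mcc_v <- NA_real_; acc_v <- NA_real_
  if (!is.null(label_pred)) {
    keep <- !m$qc_flags
    lp <- if (length(label_pred) == nrow(m$values)) label_pred[keep]
          else label_pred
    mcc_v <- mcc(lp, m$class_labels[keep])
    acc_v <- accuracy(lp, m$class_labels[keep])
  }
  if (is.null(qc_matrix)) {
    qc_matrix <- m
    qc_matrix$values <- embeddings
    qc_matrix$feature_ids <- paste0("dim", seq_len(ncol(embeddings)))
  }
  structure(list(mcc = mcc_v, accuracy = acc_v, nbe = nbe, ari = ari,
                 ami = ami, qc_apcc = qc_apcc(qc_matrix),
                 qc_nmed = qc_nmed(qc_matrix)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
  cat("evaluation_report\n")
  cat("  classification: MCC =", fmt(x$mcc), " accuracy =", fmt(x$accuracy), "\n")
  cat("  batch mixing:   nBE =", fmt(x$nbe), " ARI =", fmt(x$ari),
      " AMI =", fmt(x$ami), "\n")
  cat("  QC:             aPCC =", fmt(x$qc_apcc), " nMED =", fmt(x$qc_nmed), "\n")
  invisible(x)
}
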