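# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately re-derive every quantity from first
# principles (explicit loops, factorials) rather than calling package code.

# Adjusted Rand index evaluated term by term from the contingency table.
ari_oracle <- function(pred, true) {
  pred <- as.character(pred); true <- as.character(true)
  pl <- unique(pred); tl <- unique(true)
  n <- length(pred)
  nij <- matrix(0, length(pl), length(tl))
  for (i in seq_along(pl)) for (j in seq_along(tl))
    nij[i, j] <- sum(pred == pl[i] & true == tl[j])
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- 0
  for (i in seq_along(pl)) for (j in seq_along(tl))
    sum_ij <- sum_ij + ch2(nij[i, j])
  sum_a <- sum(ch2(rowSums(nij)))
  sum_b <- sum(ch2(colSums(nij)))
  expected <- sum_a * sum_b / ch2(n)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}

# Adjusted mutual information with the hypergeometric E[MI] computed with
# explicit factorials (valid for the small n used in tests).
ami_oracle <- function(pred, true) {
  pred <- as.character(pred); true <- as.character(true)
  pl <- unique(pred); tl <- unique(true)
  n <- length(pred)
  nij <- matrix(0, length(pl), length(tl))
  for (i in seq_along(pl)) for (j in seq_along(tl))
    nij[i, j] <- sum(pred == pl[i] & true == tl[j])
  a <- rowSums(nij); b <- colSums(nij)
  ent <- function(cnt) {
    p <- cnt[cnt > 0] / sum(cnt)
    -sum(p * log(p))
  }
  hu <- ent(a); hv <- ent(b)
  if (hu == 0 && hv == 0) return(1)
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    if (nij[i, j] > 0)
      mi <- mi + nij[i, j] / n * log(n * nij[i, j] / (a[i] * b[j]))
  }
  emi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    lo <- max(a[i] + b[j] - n, 0)
    for (m in lo:min(a[i], b[j])) {
      if (m == 0) next
      pr <- factorial(a[i]) * factorial(b[j]) * factorial(n - a[i]) *
        factorial(n - b[j]) /
        (factorial(n) * factorial(m) * factorial(a[i] - m) *
         factorial(b[j] - m) * factorial(n - a[i] - b[j] + m))
      emi <- emi + m / n * log(n * m / (a[i] * b[j])) * pr
    }
  }
  denom <- (hu + hv) / 2 - emi
  if (abs(denom) < 1e-15) return(0)
  (mi - emi) / denom
}

# All partitions of n items into at most kmax blocks, as restricted
# growth strings (canonical label vectors).
rgs_partitions <- function(n, kmax) {
  out <- list()
  rec <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (lab in seq_len(min(maxlab + 1, kmax)))
      rec(c(prefix, lab), max(maxlab, lab))
  }
  rec(integer(0), 0L)
  out
}

# Exact text fingerprint of a list of numeric parameter arrays.
num_hash <- function(params) {
  vapply(params, function(p)
    paste(sprintf("%a", as.numeric(p)), collapse = ","), character(1))
}

# A small annotated matrix with two batches and two classes.
tiny_omics <- function(n_per_batch = 4, n_features = 3, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_batch
  vals <- matrix(stats::runif(n * n_features, 1, 10), n)
  omics_matrix(vals,
               sample_ids = paste0("s", seq_len(n)),
               feature_ids = paste0("f", seq_len(n_features)),
               batch_labels = rep(c("b1", "b2"), each = n_per_batch),
               class_labels = rep(c("A", "B"), n_per_batch),
               qc_flags = rep(FALSE, n))
}

# Write a matrix + annotation fixture pair to temp files.
write_fixture_files <- function(mat_lines, ann_lines) {
  mp <- tempfile(fileext = ".tsv"); ap <- tempfile(fileext = ".tsv")
  writeLines(mat_lines, mp)
  writeLines(ann_lines, ap)
  list(matrix = mp, annotation = ap)
}

# Small preprocessed dataset + trained-model helper for training tests.
quick_sim <- function(seed = 1, batch_additive_sd = 1, n_batches = 4,
                      samples_per_batch = 12, n_features = 30, ...) {
  sim <- simulate_omics(simulation_spec(
    n_batches = n_batches, samples_per_batch = samples_per_batch,
    n_features = n_features, batch_additive_sd = batch_additive_sd,
    seed = seed, ...))
  sim$matrix
}
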