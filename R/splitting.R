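#' Batch-disjoint, class-stratified repeated holdout
#'
#' Assigns whole batches to train/validation/test sets: every sample of a
#' given batch lands in the same split, so validation and test always
#' consist of batches never seen during supervised training. Each repeat
#' resamples the assignment; among a pool of random candidate assignments
#' the one whose per-class sample proportions in each split are closest to
#' the global proportions is kept (greedy stratification). With exactly 3
#' batches the repeats rotate the three batches through the three roles.
#'
#' @param m an `omics_matrix` with K >= 3 batches.
#' @param n_repeats number of holdout repetitions.
#' @param valid_frac,test_frac fractions of *batches* assigned to the
#'   validation and test sets (each rounded to at least one batch).
#' @param seed integer seed; same seed, same split list.
#' @param n_candidates candidate assignments scored per repeat.
#' @return list of `holdout_split` objects: each has `train_batches`,
#'   `valid_batches`, `test_batches`, `repeat_index`, `seed`.
#' @export
repeated_holdout <- function(m, n_repeats = 5, valid_frac = 0.2,
                             test_frac = 0.2, seed = 1L,
                             n_candidates = 50) {
  stopifnot(inherits(m, "omics_matrix"))
  batches <- sort(unique(m$batch_labels))
  K <- length(batches)
  if (K < 3)
    stop("batch-disjoint holdout requires at least 3 batches, got ", K)
  if (valid_frac <= 0 || test_frac <= 0 || valid_frac + test_frac >= 1)
    stop("fractions must be in (0,1) and sum to < 1")
  n_valid <- max(1L, round(valid_frac * K))
  n_test <- max(1L, round(test_frac * K))
  if (n_valid + n_test >= K)
    stop("too few batches for the requested fractions")
  # class composition per batch (QC class excluded from stratification)
  keep <- !m$qc_flags
  classes <- sort(unique(m$class_labels[keep]))
  comp <- t(vapply(batches, function(b) {
    sel <- keep & m$batch_labels == b
    vapply(classes, function(cl) sum(m$class_labels[sel] == cl), numeric(1))
  }, numeric(length(classes))))
  if (length(classes) == 1) comp <- matrix(comp, nrow = K)
  global_prop <- colSums(comp) / sum(comp)
  score <- function(sets) {
    sum(vapply(sets, function(s) {
      cnt <- colSums(comp[match(s, batches), , drop = FALSE])
      if (sum(cnt) == 0) return(10)  # empty split: heavily penalized
      sum(abs(cnt / sum(cnt) - global_prop))
    }, numeric(1)))
  }
  splits <- vector("list", n_repeats)
  with_seed(seed, {
    if (K == 3) {
      rot <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
      for (r in seq_len(n_repeats)) {
        o <- rot[[(r - 1) %% 3 + 1]]
        splits[[r]] <- new_holdout_split(batches[o[1]], batches[o[2]],
                                         batches[o[3]], r, seed)
      }
    } else {
      seen_tests <- list()
      for (r in seq_len(n_repeats)) {
        best <- NULL; best_score <- Inf
        for (cand in seq_len(n_candidates)) {
          o <- sample(batches)
          sets <- list(test = o[seq_len(n_test)],
                       valid = o[n_test + seq_len(n_valid)],
                       train = o[-seq_len(n_test + n_valid)])
          s <- score(sets)
          # prefer test sets not used by an earlier repeat
          key <- paste(sort(sets$test), collapse = "|")
          if (key %in% seen_tests) s <- s + 5
          if (s < best_score) { best <- sets; best_score <- s }
        }
        seen_tests <- c(seen_tests, paste(sort(best$test), collapse = "|"))
        splits[[r]] <- new_holdout_split(best$train, best$valid, best$test,
                                         r, seed)
      }
    }
  })
  splits
}

new_holdout_split <- function(train_b, valid_b, test_b, repeat_index, seed) {
  stopifnot(length(train_b) >= 1, length(valid_b) >= 1, length(test_b) >= 1)
  if (length(intersect(train_b, valid_b)) || length(intersect(train_b, test_b)) ||
      length(intersect(valid_b, test_b)))
    stop("split batch sets overlap")
  structure(list(train_batches = sort(train_b), valid_batches = sort(valid_b),
                 test_batches = sort(test_b),
                 repeat_index = as.integer(repeat_index),
                 seed = as.integer(seed)),
            class = "holdout_split")
}

#' @export
print.holdout_split <- function(x, ...) {
  cat(sprintf("holdout_split (repeat %d): train {%s} | valid {%s} | test {%s}\n",
              x$repeat_index, paste(x$train_batches, collapse = ","),
              paste(x$valid_batches, collapse = ","),
              paste(x$test_batches, collapse = ",")))
  invisible(x)
}

#' Materialize a holdout split into three omics_matrix views
#'
#' QC samples follow their batch. A class present in the full data but
#' absent from the training view triggers a warning (degenerate split).
#'
#' @param split a `holdout_split`.
#' @param m the full `omics_matrix`.
#' @return list with elements `train`, `valid`, `test`.
#' @export
materialize_split <- function(split, m) {
  stopifnot(inherits(split, "holdout_split"), inherits(m, "omics_matrix"))
  all_b <- unique(m$batch_labels)
  unknown <- setdiff(c(split$train_batches, split$valid_batches,
                       split$test_batches), all_b)
  if (length(unknown))
    stop("split references unknown batch(es): ",
         paste(unknown, collapse = ", "))
  pick <- function(bs) subset_samples(m, m$batch_labels %in% bs)
  out <- list(train = pick(split$train_batches),
              valid = pick(split$valid_batches),
              test = pick(split$test_batches))
  full_classes <- unique(m$class_labels[!m$qc_flags])
  train_classes <- unique(out$train$class_labels[!out$train$qc_flags])
  missing <- setdiff(full_classes, train_classes)
  if (length(missing))
    warning("class(es) absent from the training split: ",
            paste(missing, collapse = ", "))
  out
}
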