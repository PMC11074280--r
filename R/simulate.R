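#' Simulation specification for multi-batch LC-MS-like data
#'
#' States the generative world used by the test-bed: log-normal baseline
#' intensities, class effects on a subset of features, per-batch
#' location/scale shifts applied on the log scale (additive there is
#' multiplicative on the intensity scale, matching how LC-MS drift is
#' usually modeled), optional per-batch monotone nonlinear warp, pooled-QC
#' replicate injections and zero-coded missing values.
#'
#' @param n_batches number of batches (>= 2 for any batch-effect work).
#' @param samples_per_batch non-QC samples per batch.
#' @param n_features number of features.
#' @param n_classes number of class labels (balanced within each batch).
#' @param class_effect_size mean log-scale shift, in units of `noise_sd`,
#'   added to affected features of non-reference classes.
#' @param class_effect_frac fraction of features carrying a class effect.
#' @param batch_additive_sd sd of the per-batch, per-feature additive
#'   offset on the log scale.
#' @param batch_multiplicative_sd sd of the log of the per-batch
#'   per-feature multiplicative factor applied to centered log values.
#' @param nonlinear_warp apply a per-batch monotone cubic warp to the log
#'   intensities (a batch distortion linear methods cannot undo)?
#' @param missing_rate fraction of entries zero-coded as missing.
#' @param qc_per_batch pooled-QC injections per batch.
#' @param noise_sd within-class log-scale noise sd.
#' @param seed integer seed; same seed, bitwise-identical output.
#' @return a `simulation_spec`.
#' @export
simulation_spec <- function(n_batches = 6, samples_per_batch = 40,
                            n_features = 200, n_classes = 2,
                            class_effect_size = 1, class_effect_frac = 0.1,
                            batch_additive_sd = 1,
                            batch_multiplicative_sd = 0.1,
                            nonlinear_warp = FALSE, missing_rate = 0,
                            qc_per_batch = 0, noise_sd = 1, seed = 1L) {
  stopifnot(n_batches >= 1, samples_per_batch >= 1, n_features >= 1,
            n_classes >= 1, qc_per_batch >= 0)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (class_effect_frac < 0 || class_effect_frac > 1)
    stop("class_effect_frac must be in [0, 1]")
  if (batch_additive_sd < 0 || batch_multiplicative_sd < 0 || noise_sd < 0)
    stop("sd parameters must be >= 0")
  structure(as.list(environment()), class = "simulation_spec")
}

#' Generate a synthetic multi-batch omics_matrix with known ground truth
#'
#' On the log scale, sample i in class c, batch b, feature j is
#' `v = ((m_j + delta_cj + e_ij) - mbar_j) * s_bj + mbar_j + a_bj`, where
#' `m_j` is the log-normal baseline log-mean, `delta_cj` the class effect
#' (nonzero on a seeded random feature subset), `e_ij` Gaussian noise,
#' `a_bj ~ N(0, batch_additive_sd)` and `log s_bj ~ N(0,
#' batch_multiplicative_sd)` the per-batch effects. An optional monotone
#' cubic warp per batch follows. Intensities are `expm1` of the log
#' values, floored at 0, and missing entries are zero-coded at
#' `missing_rate`. QC samples are the global mean profile plus the batch
#' effect and noise, flagged `is_qc` with the reserved class `"QC"`.
#'
#' @param spec a [simulation_spec()].
#' @return list with `matrix` (the `omics_matrix`) and `truth` (list:
#'   affected feature indices, per-batch additive/multiplicative effects,
#'   the log-scale signal matrix before batch effects, and the spec).
#' @export
simulate_omics <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    B <- spec$n_batches; S <- spec$samples_per_batch
    Fm <- spec$n_features; C <- spec$n_classes
    n <- B * (S + spec$qc_per_batch)
    base_mean <- stats::rnorm(Fm, mean = 2, sd = 1)  # log-normal baseline
    n_aff <- round(spec$class_effect_frac * Fm)
    affected <- if (n_aff > 0) sample.int(Fm, n_aff) else integer(0)
    # class-by-feature effect matrix (reference class 1 has none)
    delta <- matrix(0, C, Fm)
    if (C > 1 && n_aff > 0) {
      for (cl in 2:C) {
        sgn <- sample(c(-1, 1), n_aff, replace = TRUE)
        delta[cl, affected] <- sgn * spec$class_effect_size * spec$noise_sd
      }
    }
    add_b <- matrix(stats::rnorm(B * Fm, 0, spec$batch_additive_sd), B)
    mult_b <- matrix(exp(stats::rnorm(B * Fm, 0, spec$batch_multiplicative_sd)), B)
    batch_labels <- class_labels <- character(n)
    qc_flags <- logical(n)
    signal <- logv <- matrix(0, n, Fm)
    row <- 0
    for (b in seq_len(B)) {
      cls_assign <- rep_len(seq_len(C), S)
      for (s in seq_len(S)) {
        row <- row + 1
        cl <- cls_assign[s]
        sig <- base_mean + delta[cl, ] + stats::rnorm(Fm, 0, spec$noise_sd)
        signal[row, ] <- sig
        v <- (sig - base_mean) * mult_b[b, ] + base_mean + add_b[b, ]
        logv[row, ] <- v
        batch_labels[row] <- sprintf("batch%02d", b)
        class_labels[row] <- sprintf("class%d", cl)
      }
      for (q in seq_len(spec$qc_per_batch)) {
        row <- row + 1
        sig <- base_mean + stats::rnorm(Fm, 0, spec$noise_sd)
        signal[row, ] <- sig
        v <- (sig - base_mean) * mult_b[b, ] + base_mean + add_b[b, ]
        logv[row, ] <- v
        batch_labels[row] <- sprintf("batch%02d", b)
        class_labels[row] <- "QC"
        qc_flags[row] <- TRUE
      }
    }
    if (spec$nonlinear_warp) {
      # drawn after the sample loop so that a warped and an unwarped run
      # with the same seed share the underlying signal and noise draws
      warp_coef <- cbind(stats::runif(B, 0.7, 1.3),
                         stats::runif(B, 0.005, 0.03))
      for (b in seq_len(B)) {
        rows <- which(batch_labels == sprintf("batch%02d", b))
        v <- logv[rows, , drop = FALSE]
        cen <- v - mean(v)
        # monotone cubic: slope > 0 everywhere since both coefs > 0
        logv[rows, ] <- mean(v) + warp_coef[b, 1] * cen +
          warp_coef[b, 2] * cen^3
      }
    }
    intens <- pmax(expm1(logv), 0)
    if (spec$missing_rate > 0) {
      miss <- matrix(stats::runif(n * Fm) < spec$missing_rate, n)
      intens[miss] <- 0
    }
    sample_ids <- sprintf("s%04d", seq_len(n))
    rownames(intens) <- sample_ids
    colnames(intens) <- sprintf("feat%04d", seq_len(Fm))
    m <- omics_matrix(intens, batch_labels = batch_labels,
                      class_labels = class_labels, qc_flags = qc_flags)
    list(matrix = m,
         truth = list(affected_features = sort(affected),
                      class_effects = delta,
                      batch_additive = add_b, batch_multiplicative = mult_b,
                      log_signal = signal, spec = spec))
  })
}
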