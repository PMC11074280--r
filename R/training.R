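#' Inverse-frequency sampling weights for class imbalance
#'
#' Each sample is weighted by the reciprocal of its class count, so that
#' drawing with replacement under these weights gives every class the same
#' expected frequency.
#'
#' @param labels per-sample class labels.
#' @return numeric vector of per-sample weights.
#' @export
class_weights <- function(labels) {
  labels <- as.character(labels)
  cnt <- table(labels)
  as.numeric(1 / cnt[labels])
}

new_train_state <- function(rng_seed) {
  structure(list(epoch = 0L, best_valid_mcc = -Inf, best_epoch = NA_integer_,
                 epochs_since_improvement = 0L,
                 loss_history = data.frame(),
                 rng_seed = as.integer(rng_seed)),
            class = "train_state")
}

record_epoch <- function(state, phase, losses, valid_mcc = NA_real_) {
  state$loss_history <- rbind(state$loss_history, data.frame(
    epoch = state$epoch, phase = phase,
    rec = losses$rec, classif = losses$classif, kld = losses$kld,
    be = losses$be,
    total = total_loss(ifelse(is.na(losses$rec), 0, losses$rec),
                       losses$classif, losses$kld, losses$be,
                       nu = losses$nu, beta = losses$beta,
                       gamma = losses$gamma),
    valid_mcc = valid_mcc))
  state
}

mean_losses <- function(acc, cfg) {
  out <- lapply(c(rec = "rec", classif = "classif", kld = "kld", be = "be"),
                function(nm) {
                  v <- vapply(acc, function(l) l[[nm]], numeric(1))
                  if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
                })
  out$nu <- cfg$nu; out$beta <- cfg$beta; out$gamma <- cfg$gamma
  out
}

# One pass over all samples with the unsupervised losses (reconstruction,
# KLD if variational, batch-effect loss if any). For the batch-mapping
# strategy the discriminator takes its own minimizing step on a detached
# bottleneck before each encoder/decoder step (alternating min-max).
unsupervised_epoch <- function(model, x, batch_idx, batch_size = 32) {
  n <- nrow(x)
  ord <- sample.int(n)
  starts <- seq(1, n, by = batch_size)
  acc <- vector("list", length(starts))
  for (s in seq_along(starts)) {
    idx <- ord[starts[s]:min(starts[s] + batch_size - 1, n)]
    xb <- x[idx, , drop = FALSE]
    bb <- batch_idx[idx]
    if (model$cfg$be_strategy == "batch_mapping_adversarial") {
      ds <- disc_step_grads(model, xb, bb)
      model <- adam_update(model, ds$grads)
    }
    cg <- compute_grads(model, xb, batch_idx = bb, phase = "unsupervised")
    model <- adam_update(model, cg$grads)
    acc[[s]] <- cg$losses
  }
  list(model = model, losses = mean_losses(acc, model$cfg))
}

# One pass over the training samples with the supervised loss. Samples are
# drawn with replacement under inverse-class-frequency weights. frozen
# restricts updates to the label-classifier head (scenario 1 / step 2a);
# otherwise gradients flow through the encoder (step 2b) and the full
# objective is used.
supervised_epoch <- function(model, x, class_idx, batch_idx, weights,
                             frozen, batch_size = 32) {
  n <- nrow(x)
  ord <- sample.int(n, n, replace = TRUE, prob = weights)
  starts <- seq(1, n, by = batch_size)
  acc <- vector("list", length(starts))
  phase <- if (frozen) "supervised_frozen" else "supervised_full"
  for (s in seq_along(starts)) {
    idx <- ord[starts[s]:min(starts[s] + batch_size - 1, n)]
    if (model$cfg$be_strategy == "batch_mapping_adversarial" && !frozen) {
      ds <- disc_step_grads(model, x[idx, , drop = FALSE], batch_idx[idx])
      model <- adam_update(model, ds$grads)
    }
    cg <- compute_grads(model, x[idx, , drop = FALSE],
                        batch_idx = batch_idx[idx],
                        class_idx = class_idx[idx], phase = phase)
    model <- adam_update(model, cg$grads)
    acc[[s]] <- cg$losses
  }
  list(model = model, losses = mean_losses(acc, model$cfg))
}

prepare_labels <- function(model, m) {
  if (is.null(model$batch_levels))
    model$batch_levels <- sort(unique(m$batch_labels))
  if (is.null(model$class_levels))
    model$class_levels <- sort(unique(m$class_labels[!m$qc_flags]))
  model
}

valid_mcc_of <- function(model, valid_m) {
  keep <- !valid_m$qc_flags
  z <- encode(model, valid_m$values[keep, , drop = FALSE])$z
  probs <- predict_class_probs(model, z)
  pred <- model$class_levels[max.col(probs, ties.method = "first")]
  mcc(pred, valid_m$class_labels[keep])
}

#' Unsupervised warmup on the full dataset
#'
#' Step 1 of the training protocol: the autoencoder (and, for adversarial
#' strategies, the batch discriminator) is trained on *all* samples —
#' train, validation and test alike — using only unsupervised losses.
#' The label classifier is untouched. Using the held-out samples here is
#' deliberate and transductive: no class label is consumed; set
#' `strict = TRUE` upstream by passing only training samples if a
#' leakage-free protocol is preferred.
#'
#' @param model a `bae_model` (freshly built).
#' @param full_m preprocessed `omics_matrix` with every sample.
#' @param epochs number of warmup epochs (default: `cfg$warmup_epochs`).
#' @param batch_size minibatch size.
#' @return list with the updated `model` and a `train_state` whose loss
#'   history holds one row per warmup epoch.
#' @export
warmup <- function(model, full_m, epochs = model$cfg$warmup_epochs,
                   batch_size = 32) {
  stopifnot(inherits(model, "bae_model"), inherits(full_m, "omics_matrix"))
  if (epochs < 0) stop("epochs must be >= 0")
  model <- prepare_labels(model, full_m)
  state <- new_train_state(model$cfg$seed)
  if (epochs == 0) return(list(model = model, state = state))
  set.seed(model$cfg$seed + 1L)
  x <- full_m$values
  bidx <- match(full_m$batch_labels, model$batch_levels)
  for (e in seq_len(epochs)) {
    state$epoch <- state$epoch + 1L
    ep <- unsupervised_epoch(model, x, bidx, batch_size)
    model <- ep$model
    state <- record_epoch(state, "warmup", ep$losses)
  }
  list(model = model, state = state)
}

run_supervised_training <- function(model, train_m, valid_m, full_m,
                                    scenario, max_epochs, patience,
                                    batch_size) {
  stopifnot(inherits(model, "bae_model"))
  model <- prepare_labels(model, train_m)
  keep <- !train_m$qc_flags
  if (!any(keep)) stop("training split has no non-QC samples")
  x_tr <- train_m$values[keep, , drop = FALSE]
  cls_tr <- match(train_m$class_labels[keep], model$class_levels)
  if (anyNA(cls_tr))
    stop("training split contains class labels unseen at warmup")
  bidx_tr <- match(train_m$batch_labels[keep], model$batch_levels)
  w <- class_weights(train_m$class_labels[keep])
  state <- new_train_state(model$cfg$seed)
  set.seed(model$cfg$seed + 2L)
  best_params <- model$params
  if (scenario == 2) {
    x_full <- full_m$values
    bidx_full <- match(full_m$batch_labels, model$batch_levels)
  }
  for (e in seq_len(max_epochs)) {
    state$epoch <- state$epoch + 1L
    if (scenario == 2) {
      # alternation: unsupervised pass on everything, then a supervised
      # pass on the training split with gradients through the encoder
      ep_u <- unsupervised_epoch(model, x_full, bidx_full, batch_size)
      model <- ep_u$model
      ep <- supervised_epoch(model, x_tr, cls_tr, bidx_tr, w,
                             frozen = FALSE, batch_size = batch_size)
    } else {
      ep <- supervised_epoch(model, x_tr, cls_tr, bidx_tr, w,
                             frozen = TRUE, batch_size = batch_size)
    }
    model <- ep$model
    vm <- valid_mcc_of(model, valid_m)
    phase <- if (scenario == 2) "alternating" else "classifier"
    state <- record_epoch(state, phase, ep$losses, valid_mcc = vm)
    if (vm > state$best_valid_mcc) {
      state$best_valid_mcc <- vm
      state$best_epoch <- state$epoch
      state$epochs_since_improvement <- 0L
      best_params <- model$params
    } else {
      state$epochs_since_improvement <- state$epochs_since_improvement + 1L
    }
    if (state$epochs_since_improvement >= patience) break
  }
  model$params <- best_params
  list(model = model, state = state)
}

#' Scenario 1: train only the label classifier on a frozen autoencoder
#'
#' After warmup the encoder and decoder are frozen; only the label
#' classifier head is trained on the training split (step 2a), with
#' inverse-class-frequency weighted sampling, label smoothing, and early
#' stopping on validation MCC.
#'
#' @param model a warmed-up `bae_model`.
#' @param train_m,valid_m preprocessed training and validation
#'   `omics_matrix` splits (QC samples are excluded from supervised
#'   passes and from the validation MCC).
#' @param max_epochs cap on supervised epochs (default 1000).
#' @param patience early-stopping patience in epochs (default 100):
#'   training stops when the validation MCC has not strictly improved for
#'   this many consecutive epochs. Parameters of the best epoch are
#'   restored.
#' @param batch_size minibatch size (default 32).
#' @return list with the trained `model` and the `train_state`.
#' @export
train_scenario1 <- function(model, train_m, valid_m, max_epochs = 1000,
                            patience = 100, batch_size = 32) {
  run_supervised_training(model, train_m, valid_m, full_m = NULL,
                          scenario = 1, max_epochs = max_epochs,
                          patience = patience, batch_size = batch_size)
}

#' Scenario 2: alternate unsupervised and supervised epochs
#'
#' After warmup each training epoch runs one unsupervised pass over the
#' full dataset (as in warmup) followed by one supervised pass over the
#' training split in which backpropagation flows through the encoder
#' (step 2b). Stopping rules are the same as scenario 1.
#'
#' @inheritParams train_scenario1
#' @param full_m preprocessed `omics_matrix` with every sample, for the
#'   unsupervised half of the alternation.
#' @return list with the trained `model` and the `train_state`.
#' @export
train_scenario2 <- function(model, train_m, valid_m, full_m,
                            max_epochs = 1000, patience = 100,
                            batch_size = 32) {
  stopifnot(inherits(full_m, "omics_matrix"))
  run_supervised_training(model, train_m, valid_m, full_m,
                          scenario = 2, max_epochs = max_epochs,
                          patience = patience, batch_size = batch_size)
}
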