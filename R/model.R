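#' Model configuration for the autoencoder zoo
#'
#' Describes one member of the ten-model family: a plain or variational
#' autoencoder with a single hidden layer, combined with one of five
#' batch-effect removal strategies.
#'
#' Strategies:
#' \describe{
#'   \item{`none`}{plain autoencoder, no batch-effect loss.}
#'   \item{`dann`}{a batch (domain) classifier head on the bottleneck,
#'     trained through a gradient reversal layer so that the encoder is
#'     pushed to make batches indistinguishable.}
#'   \item{`batch_mapping_adversarial`}{a learned per-batch vector added to
#'     the bottleneck before decoding (so the decoder, not the embedding,
#'     carries batch identity), plus an adversarial batch discriminator
#'     trained by alternating min--max updates without a reversal layer.}
#'   \item{`inv_triplet`}{triplet loss on batch labels with positive and
#'     negative roles swapped, pulling different batches together and
#'     pushing same-batch samples apart.}
#'   \item{`rev_triplet`}{the standard batch triplet loss behind a gradient
#'     reversal layer.}
#' }
#'
#' @param n_features number of input features.
#' @param n_classes number of class labels.
#' @param n_batches number of batches.
#' @param layer1 hidden width of encoder and decoder.
#' @param layer2 bottleneck width.
#' @param variational variational autoencoder (Gaussian bottleneck)?
#' @param be_strategy one of `"none"`, `"batch_mapping_adversarial"`,
#'   `"dann"`, `"inv_triplet"`, `"rev_triplet"`.
#' @param dropout dropout rate in \[0, 1).
#' @param label_smoothing label-smoothing rate in \[0, 0.5).
#' @param margin triplet margin alpha >= 0 (triplet strategies only).
#' @param nu weight of the label-classification loss.
#' @param beta weight of the KL divergence (variational models only).
#' @param gamma weight of the batch-effect loss.
#' @param learning_rate Adam learning rate.
#' @param weight_decay decoupled weight-decay rate.
#' @param warmup_epochs unsupervised warmup epochs on the full dataset.
#' @param normalization a [norm_spec()] or variant name.
#' @param seed integer seed for parameter initialization and training
#'   randomness.
#' @return a `model_config` object.
#' @export
model_config <- function(n_features, n_classes, n_batches,
                         layer1 = 64, layer2 = 16,
                         variational = FALSE,
                         be_strategy = c("none", "batch_mapping_adversarial",
                                         "dann", "inv_triplet", "rev_triplet"),
                         dropout = 0.1, label_smoothing = 0,
                         margin = 1, nu = 1, beta = 1, gamma = 1,
                         learning_rate = 1e-3, weight_decay = 1e-6,
                         warmup_epochs = 50,
                         normalization = norm_spec("standard"),
                         seed = 1L) {
  be_strategy <- match.arg(be_strategy)
  if (is.character(normalization))
    normalization <- norm_spec_from_name(normalization)
  stopifnot(n_features >= 1, n_classes >= 1, n_batches >= 1,
            layer1 >= 1, layer2 >= 1)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (label_smoothing < 0 || label_smoothing >= 0.5)
    stop("label_smoothing must be in [0, 0.5)")
  if (margin < 0 || nu < 0 || beta < 0 || gamma < 0)
    stop("margin and loss weights must be >= 0")
  if (warmup_epochs < 0) stop("warmup_epochs must be >= 0")
  structure(list(n_features = as.integer(n_features),
                 n_classes = as.integer(n_classes),
                 n_batches = as.integer(n_batches),
                 layer1 = as.integer(layer1), layer2 = as.integer(layer2),
                 variational = isTRUE(variational),
                 be_strategy = be_strategy,
                 dropout = dropout, label_smoothing = label_smoothing,
                 margin = margin, nu = nu, beta = beta, gamma = gamma,
                 learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 warmup_epochs = as.integer(warmup_epochs),
                 normalization = normalization,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' The ten model families
#'
#' Every combination of \{plain, variational\} autoencoder with the five
#' batch-effect strategies.
#'
#' @return data.frame with columns `family`, `variational`, `be_strategy`.
#' @export
model_zoo <- function() {
  strategies <- c(none = "plain", dann = "dann",
                  batch_mapping_adversarial = "batchmap",
                  inv_triplet = "invtriplet", rev_triplet = "revtriplet")
  grid <- expand.grid(variational = c(FALSE, TRUE),
                      be_strategy = names(strategies),
                      stringsAsFactors = FALSE)
  tag <- ifelse(grid$variational, "vae", "ae")
  suffix <- ifelse(grid$be_strategy == "none", "",
                   paste0("_", strategies[grid$be_strategy]))
  data.frame(family = paste0(tag, suffix),
             variational = grid$variational,
             be_strategy = grid$be_strategy,
             stringsAsFactors = FALSE)
}

#' Build a model_config for a named family
#'
#' @param family one of `model_zoo()$family`.
#' @param ... passed to [model_config()] (must include `n_features`,
#'   `n_classes`, `n_batches`).
#' @return a `model_config`.
#' @export
config_from_family <- function(family, ...) {
  zoo <- model_zoo()
  i <- match(family, zoo$family)
  if (is.na(i))
    stop("unknown model family '", family, "'; valid families: ",
         paste(zoo$family, collapse = ", "))
  model_config(..., variational = zoo$variational[i],
               be_strategy = zoo$be_strategy[i])
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Build (initialize) a model from its configuration
#'
#' The architecture is a single-hidden-layer autoencoder: input ->
#' `layer1` (ReLU, dropout) -> bottleneck `layer2` -> `layer1` (ReLU,
#' dropout) -> output (linear). Variational models replace the bottleneck
#' by parallel `mu` and `log sigma^2` heads. A linear label-classifier
#' head sits on the bottleneck; `dann` and `batch_mapping_adversarial`
#' add a linear batch-classifier head, and `batch_mapping_adversarial`
#' also a zero-initialized per-batch embedding table added to the
#' bottleneck before decoding. Initialization is Glorot-uniform, seeded
#' from `cfg$seed`, so two builds from the same config are identical.
#'
#' @param cfg a [model_config()].
#' @return a `bae_model`: list with `cfg`, `params` (named list of
#'   matrices/vectors) and `opt` (Adam state, initially empty).
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  F <- cfg$n_features; L1 <- cfg$layer1; L2 <- cfg$layer2
  params <- with_seed(cfg$seed, {
    p <- list(W1 = glorot(F, L1), b1 = numeric(L1))
    if (cfg$variational) {
      p$Wmu <- glorot(L1, L2); p$bmu <- numeric(L2)
      p$Wlv <- glorot(L1, L2); p$blv <- numeric(L2)
    } else {
      p$W2 <- glorot(L1, L2); p$b2 <- numeric(L2)
    }
    p$W3 <- glorot(L2, L1); p$b3 <- numeric(L1)
    p$W4 <- glorot(L1, F); p$b4 <- numeric(F)
    p$Wc <- glorot(L2, cfg$n_classes); p$bc <- numeric(cfg$n_classes)
    if (cfg$be_strategy %in% c("dann", "batch_mapping_adversarial")) {
      p$Wb <- glorot(L2, cfg$n_batches); p$bb <- numeric(cfg$n_batches)
    }
    if (cfg$be_strategy == "batch_mapping_adversarial") {
      p$Eb <- matrix(0, cfg$n_batches, L2)  # identity mapping at init
    }
    p
  })
  structure(list(cfg = cfg, params = params, opt = list(),
                 batch_levels = NULL, class_levels = NULL),
            class = "bae_model")
}

#' @export
print.bae_model <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf("bae_model: %s autoencoder, be_strategy = %s\n",
              if (cfg$variational) "variational" else "plain",
              cfg$be_strategy))
  cat(sprintf("  %d features -> %d -> bottleneck %d; %d classes, %d batches\n",
              cfg$n_features, cfg$layer1, cfg$layer2, cfg$n_classes,
              cfg$n_batches))
  invisible(x)
}

relu <- function(x) (x > 0) * x

affine <- function(x, W, b) sweep(x %*% W, 2, b, "+")

# Forward pass with caches for backprop. `training` turns on dropout;
# `sample_noise` draws epsilon for variational bottlenecks (else eps = 0).
forward_cache <- function(model, x, training = FALSE, sample_noise = FALSE,
                          batch_idx = NULL) {
  cfg <- model$cfg; p <- model$params
  if (ncol(x) != cfg$n_features)
    stop(sprintf("input has %d features, model expects %d", ncol(x),
                 cfg$n_features))
  n <- nrow(x)
  keep <- 1 - cfg$dropout
  cache <- list(x = x, training = training)
  h1pre <- affine(x, p$W1, p$b1)
  h1 <- relu(h1pre)
  if (training && cfg$dropout > 0) {
    cache$m1 <- matrix(stats::rbinom(length(h1), 1, keep), nrow(h1)) / keep
    h1 <- h1 * cache$m1
  }
  cache$h1pre <- h1pre; cache$h1 <- h1
  if (cfg$variational) {
    mu <- affine(h1, p$Wmu, p$bmu)
    logvar <- affine(h1, p$Wlv, p$blv)
    logvar <- pmin(pmax(logvar, -10), 10)
    sigma <- exp(0.5 * logvar)
    eps <- if (sample_noise) matrix(stats::rnorm(n * cfg$layer2), n)
           else matrix(0, n, cfg$layer2)
    z <- mu + sigma * eps
    cache$mu <- mu; cache$logvar <- logvar; cache$sigma <- sigma
    cache$eps <- eps
  } else {
    z <- affine(h1, p$W2, p$b2)
  }
  cache$z <- z
  zd <- z
  if (cfg$be_strategy == "batch_mapping_adversarial") {
    if (is.null(batch_idx))
      stop("batch labels required for a batch-mapping model")
    zd <- z + p$Eb[batch_idx, , drop = FALSE]
  }
  cache$zd <- zd; cache$batch_idx <- batch_idx
  h2pre <- affine(zd, p$W3, p$b3)
  h2 <- relu(h2pre)
  if (training && cfg$dropout > 0) {
    cache$m2 <- matrix(stats::rbinom(length(h2), 1, keep), nrow(h2)) / keep
    h2 <- h2 * cache$m2
  }
  cache$h2pre <- h2pre; cache$h2 <- h2
  cache$xhat <- affine(h2, p$W4, p$b4)
  cache
}

#' Encode samples into the bottleneck representation
#'
#' Dropout is off (inference mode). Variational models return
#' `z = mu + sigma * eps` with `eps ~ N(0, I)` when `sample_noise = TRUE`
#' and `eps = 0` (so `z = mu`) otherwise.
#'
#' @param model a `bae_model`.
#' @param x samples x features matrix (already preprocessed) or an
#'   `omics_matrix`.
#' @param sample_noise draw reparameterization noise (variational only)?
#' @return a `latent_representation`: list with `z` and, for variational
#'   models, `mu`, `sigma` and the drawn `eps`.
#' @export
encode <- function(model, x, sample_noise = FALSE) {
  stopifnot(inherits(model, "bae_model"))
  if (inherits(x, "omics_matrix")) x <- x$values
  x <- as.matrix(x)
  cfg <- model$cfg; p <- model$params
  if (ncol(x) != cfg$n_features)
    stop(sprintf("input has %d features, model expects %d", ncol(x),
                 cfg$n_features))
  h1 <- relu(affine(x, p$W1, p$b1))
  if (cfg$variational) {
    mu <- affine(h1, p$Wmu, p$bmu)
    logvar <- pmin(pmax(affine(h1, p$Wlv, p$blv), -10), 10)
    sigma <- exp(0.5 * logvar)
    eps <- if (sample_noise)
      matrix(stats::rnorm(length(mu)), nrow(mu)) else
      matrix(0, nrow(mu), ncol(mu))
    structure(list(z = mu + sigma * eps, mu = mu, sigma = sigma, eps = eps),
              class = "latent_representation")
  } else {
    structure(list(z = affine(h1, p$W2, p$b2), mu = NULL, sigma = NULL,
                   eps = NULL),
              class = "latent_representation")
  }
}

#' Decode a latent representation back to feature space
#'
#' For batch-mapping models the learned per-batch vector is added to `z`
#' before decoding, so `batch_labels` (or integer batch indices) are
#' required; labels unknown to the model raise an error.
#'
#' @param model a `bae_model`.
#' @param rep a `latent_representation` or a bare `z` matrix.
#' @param batch_labels per-sample batch labels (batch-mapping models only).
#' @return reconstruction matrix, samples x features.
#' @export
decode <- function(model, rep, batch_labels = NULL) {
  stopifnot(inherits(model, "bae_model"))
  z <- if (inherits(rep, "latent_representation")) rep$z else as.matrix(rep)
  cfg <- model$cfg; p <- model$params
  if (cfg$be_strategy == "batch_mapping_adversarial") {
    if (is.null(batch_labels))
      stop("batch labels required to decode a batch-mapping model")
    bi <- resolve_batch_idx(model, batch_labels)
    z <- z + p$Eb[bi, , drop = FALSE]
  }
  h2 <- relu(affine(z, p$W3, p$b3))
  affine(h2, p$W4, p$b4)
}

resolve_batch_idx <- function(model, batch_labels) {
  if (is.numeric(batch_labels)) {
    bi <- as.integer(batch_labels)
    if (any(bi < 1 | bi > model$cfg$n_batches))
      stop("batch index out of range")
    return(bi)
  }
  if (is.null(model$batch_levels))
    stop("model has no recorded batch levels; pass integer batch indices")
  bi <- match(as.character(batch_labels), model$batch_levels)
  if (anyNA(bi))
    stop("unknown batch label(s): ",
         paste(unique(batch_labels[is.na(bi)]), collapse = ", "))
  bi
}

#' Class probabilities from the label-classifier head
#'
#' @param model a `bae_model`.
#' @param z bottleneck matrix (or `latent_representation`).
#' @return samples x n_classes matrix of softmax probabilities.
#' @export
predict_class_probs <- function(model, z) {
  if (inherits(z, "latent_representation")) z <- z$z
  softmax(affine(z, model$params$Wc, model$params$bc))
}

#' Predicted class labels for (preprocessed) inputs
#'
#' @param model a trained `bae_model` with recorded class levels.
#' @param x matrix or `omics_matrix` of preprocessed inputs.
#' @return character vector of predicted labels (or integer indices if the
#'   model has no recorded levels).
#' @export
predict_labels <- function(model, x) {
  probs <- predict_class_probs(model, encode(model, x)$z)
  idx <- max.col(probs, ties.method = "first")
  if (!is.null(model$class_levels)) model$class_levels[idx] else idx
}

#' Cross-entropy of the batch-discriminator head (adversarial loss)
#'
#' The scalar value of the domain-adversarial batch loss: plain
#' cross-entropy of the batch classifier head applied to the bottleneck.
#' During training the encoder-bound gradient of `gamma *` this loss is
#' passed through the gradient reversal layer (multiplied by `-gamma`)
#' while the discriminator head itself receives the unreversed gradient.
#'
#' @param model a `bae_model` with a batch head (`dann` or
#'   `batch_mapping_adversarial`).
#' @param z bottleneck matrix.
#' @param batch_idx integer batch indices in `1..n_batches`.
#' @return scalar cross-entropy in nats.
#' @export
dann_batch_loss <- function(model, z, batch_idx) {
  if (is.null(model$params$Wb)) stop("model has no batch classifier head")
  if (length(unique(batch_idx)) < 2) stop("need at least 2 batches")
  probs <- softmax(affine(z, model$params$Wb, model$params$bb))
  cross_entropy_smoothed(probs, batch_idx, smoothing = 0)
}

#' Composite adversarial objective of the batch-mapping (min-max) strategy
#'
#' The alternating objective without a reversal layer: the discriminator
#' step minimizes the batch cross-entropy on a detached bottleneck, and
#' the encoder/decoder step minimizes
#' `rec + nu*classif + beta*kld - gamma*disc`, clamped at 0 from below (a
#' negative composite, reachable when the discriminator loss grows large,
#' is not allowed to drive updates).
#'
#' @param rec,classif,kld component losses (see [total_loss()]).
#' @param disc batch-discriminator cross-entropy.
#' @param nu,beta,gamma non-negative weights.
#' @return the clamped composite objective.
#' @export
normae_objective <- function(rec, classif = NULL, kld = NULL, disc = 0,
                             nu = 0, beta = 0, gamma = 0) {
  base <- total_loss(rec, classif, kld, be = NULL, nu = nu, beta = beta)
  max(base - gamma * disc, 0)
}
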