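#' Gradient reversal (forward pass)
#'
#' Identity in the forward direction. During backpropagation the
#' sensitivity flowing back through this operation is multiplied by
#' `-lambda` (see [grad_reverse_backward()]); the training code applies
#' that rule on the encoder-bound path of adversarial losses, which makes
#' a jointly *minimized* batch discriminator adversarial to the encoder.
#'
#' @param x numeric array.
#' @param lambda non-negative reversal strength.
#' @return `x`, unchanged.
#' @export
grad_reverse <- function(x, lambda = 1) {
  if (lambda < 0) stop("lambda must be >= 0")
  x
}

#' Gradient reversal (backward pass)
#'
#' @param grad gradient arriving from downstream.
#' @param lambda non-negative reversal strength.
#' @return `-lambda * grad`.
#' @export
grad_reverse_backward <- function(grad, lambda = 1) {
  if (lambda < 0) stop("lambda must be >= 0")
  -lambda * grad
}

#' Mean-squared-error reconstruction loss
#'
#' @param x input matrix.
#' @param x_hat reconstruction, same shape.
#' @return mean of squared entrywise differences.
#' @export
reconstruction_loss <- function(x, x_hat) {
  if (!identical(dim(as.matrix(x)), dim(as.matrix(x_hat))))
    stop("x and x_hat shapes differ")
  mean((x - x_hat)^2)
}

#' Inverse batch triplet loss
#'
#' `max(||f(A) - f(N)||_2 - ||f(A) - f(P)||_2 + alpha, 0)`, where the
#' positive P shares the anchor A's batch and the negative N comes from a
#' different batch. Relative to the standard triplet loss the roles are
#' swapped: samples from *different* batches are pulled together while
#' same-batch samples are pushed apart (which prevents the embedding from
#' collapsing to a point). Row-wise over matrices; returns the mean.
#'
#' @param fA,fP,fN embedding matrices (or vectors) of equal dimension.
#' @param alpha margin, >= 0.
#' @return non-negative scalar.
#' @export
inv_triplet_loss <- function(fA, fP, fN, alpha) {
  d <- triplet_dists(fA, fP, fN)
  mean(pmax(d$an - d$ap + alpha, 0))
}

#' Reversed batch triplet loss
#'
#' The *standard* triplet loss on batch labels,
#' `max(||f(A) - f(P)||_2 - ||f(A) - f(N)||_2 + alpha, 0)`, intended to be
#' trained behind a gradient reversal layer: the loss itself clusters
#' batches, and the reversed encoder gradient therefore mixes them.
#'
#' @inheritParams inv_triplet_loss
#' @return non-negative scalar.
#' @export
rev_triplet_loss <- function(fA, fP, fN, alpha) {
  d <- triplet_dists(fA, fP, fN)
  mean(pmax(d$ap - d$an + alpha, 0))
}

triplet_dists <- function(fA, fP, fN) {
  fA <- rbind(fA); fP <- rbind(fP); fN <- rbind(fN)
  if (!all(dim(fA) == dim(fP)) || !all(dim(fA) == dim(fN)))
    stop("embedding dimensions differ")
  list(ap = sqrt(rowSums((fA - fP)^2)), an = sqrt(rowSums((fA - fN)^2)))
}

#' Gaussian KL divergence to the standard-normal prior
#'
#' Per sample, `KLD = -1/2 * sum_j (1 + log sigma_j^2 - mu_j^2 -
#' sigma_j^2)`; returns the mean over samples. This is the closed form of
#' `D_KL(N(mu, sigma^2) || N(0, I))` used by the variational models.
#'
#' @param mu matrix (samples x d) of posterior means.
#' @param sigma matrix of posterior standard deviations, > 0.
#' @return non-negative scalar.
#' @export
kld_gaussian <- function(mu, sigma) {
  mu <- rbind(mu); sigma <- rbind(sigma)
  if (!all(dim(mu) == dim(sigma))) stop("mu and sigma shapes differ")
  if (any(sigma <= 0)) stop("sigma must be positive")
  per_sample <- -0.5 * rowSums(1 + 2 * log(sigma) - mu^2 - sigma^2)
  mean(per_sample)
}

#' Cross-entropy with label smoothing
#'
#' Computes the mean cross-entropy between predicted class probabilities
#' and smoothed one-hot targets: the true class receives mass
#' `1 - smoothing` and the remaining mass is spread evenly over the other
#' `C - 1` classes.
#'
#' @param probs samples x C matrix of predicted probabilities.
#' @param class_idx integer vector of true class indices in `1..C`.
#' @param smoothing label-smoothing rate in \[0, 0.5).
#' @return non-negative scalar.
#' @export
cross_entropy_smoothed <- function(probs, class_idx, smoothing = 0) {
  probs <- rbind(probs)
  C <- ncol(probs)
  if (smoothing < 0 || smoothing >= 0.5) stop("smoothing must be in [0, 0.5)")
  if (any(class_idx < 1 | class_idx > C)) stop("class index out of range")
  tgt <- smooth_targets(class_idx, C, smoothing)
  -mean(rowSums(tgt * log(pmax(probs, 1e-12))))
}

smooth_targets <- function(class_idx, C, smoothing) {
  n <- length(class_idx)
  tgt <- matrix(if (C > 1) smoothing / (C - 1) else 0, n, C)
  tgt[cbind(seq_len(n), class_idx)] <- 1 - smoothing
  tgt
}

softmax <- function(logits) {
  logits <- logits - apply(logits, 1, max)
  e <- exp(logits)
  e / rowSums(e)
}

#' Composite training objective
#'
#' `L_total = L_rec + nu * L_classif + beta * KLD + gamma * L_BE`. The KLD
#' term applies only to variational models and the batch-effect term only
#' to models with an adversarial or triplet strategy; absent terms
#' contribute 0.
#'
#' @param rec reconstruction loss.
#' @param classif label-classification loss (or `NULL`/`NA`).
#' @param kld Gaussian KL divergence (or `NULL`/`NA`).
#' @param be batch-effect loss (or `NULL`/`NA`).
#' @param nu,beta,gamma non-negative weights for `classif`, `kld`, `be`.
#' @return scalar total loss.
#' @export
total_loss <- function(rec, classif = NULL, kld = NULL, be = NULL,
                       nu = 0, beta = 0, gamma = 0) {
  if (nu < 0 || beta < 0 || gamma < 0) stop("loss weights must be >= 0")
  term <- function(v, w) if (is.null(v) || is.na(v)) 0 else w * v
  rec + term(classif, nu) + term(kld, beta) + term(be, gamma)
}
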