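# Internal training engine: analytic gradients for every loss term and a
# hand-rolled Adam optimizer. All gradients are derived for the exact
# forward pass in forward_cache(); the gradient reversal layer is realized
# on the encoder-bound path of the adversarial losses by multiplying the
# incoming sensitivity by -gamma (see grad_reverse_backward()).

# Sample one (positive, negative) partner per anchor within a minibatch.
# Positives share the anchor's batch, negatives do not; anchors without a
# same-batch partner or without any foreign batch are dropped.
mine_triplets <- function(batch_idx) {
  n <- length(batch_idx)
  ia <- ip <- im <- integer(0)
  for (a in seq_len(n)) {
    same <- which(batch_idx == batch_idx[a])
    same <- same[same != a]
    diff <- which(batch_idx != batch_idx[a])
    if (!length(same) || !length(diff)) next
    ia <- c(ia, a)
    ip <- c(ip, same[sample.int(length(same), 1)])
    im <- c(im, diff[sample.int(length(diff), 1)])
  }
  list(a = ia, p = ip, n = im)
}

# Triplet loss value and gradient w.r.t. the bottleneck rows.
# standard = TRUE gives max(d_ap - d_an + alpha, 0) (reversed strategy,
# to be put behind the GRL); standard = FALSE the inverse strategy
# max(d_an - d_ap + alpha, 0).
triplet_grads <- function(z, trip, alpha, standard) {
  dz <- matrix(0, nrow(z), ncol(z))
  m <- length(trip$a)
  if (m == 0) return(list(loss = 0, dz = dz))
  za <- z[trip$a, , drop = FALSE]
  zp <- z[trip$p, , drop = FALSE]
  zn <- z[trip$n, , drop = FALSE]
  dap <- sqrt(rowSums((za - zp)^2))
  dan <- sqrt(rowSums((za - zn)^2))
  hinge <- if (standard) dap - dan + alpha else dan - dap + alpha
  active <- hinge > 0
  loss <- mean(pmax(hinge, 0))
  sgn <- if (standard) 1 else -1
  for (t in which(active)) {
    gap <- if (dap[t] > 0) (za[t, ] - zp[t, ]) / dap[t] else 0
    gan <- if (dan[t] > 0) (za[t, ] - zn[t, ]) / dan[t] else 0
    dz[trip$a[t], ] <- dz[trip$a[t], ] + sgn * (gap - gan) / m
    dz[trip$p[t], ] <- dz[trip$p[t], ] - sgn * gap / m
    dz[trip$n[t], ] <- dz[trip$n[t], ] + sgn * gan / m
  }
  list(loss = loss, dz = dz)
}

# Full loss-and-gradient computation for one minibatch.
# phase: "unsupervised"       rec + beta*KLD + gamma*L_BE, no classifier
#        "supervised_frozen"  nu*classif only, gradients for Wc/bc only
#        "supervised_full"    rec + nu*classif + beta*KLD + gamma*L_BE
compute_grads <- function(model, x, batch_idx = NULL, class_idx = NULL,
                          phase = c("unsupervised", "supervised_frozen",
                                    "supervised_full")) {
  phase <- match.arg(phase)
  cfg <- model$cfg; p <- model$params
  n <- nrow(x)
  training <- TRUE
  frozen <- phase == "supervised_frozen"
  use_rec <- !frozen
  use_classif <- phase != "unsupervised"
  use_be <- !frozen && cfg$be_strategy != "none"
  is_normae <- cfg$be_strategy == "batch_mapping_adversarial"
  cache <- forward_cache(model, x, training = !frozen,
                         sample_noise = cfg$variational,
                         batch_idx = if (is_normae) batch_idx else NULL)
  z <- cache$z
  g <- list()
  dz <- matrix(0, n, cfg$layer2)
  losses <- list(rec = NA_real_, classif = NA_real_, kld = NA_real_,
                 be = NA_real_)

  if (use_rec) {
    losses$rec <- mean((x - cache$xhat)^2)
    dxhat <- 2 * (cache$xhat - x) / length(x)
    g$W4 <- crossprod(cache$h2, dxhat)
    g$b4 <- colSums(dxhat)
    dh2 <- tcrossprod(dxhat, p$W4)
    if (!is.null(cache$m2)) dh2 <- dh2 * cache$m2
    dh2pre <- dh2 * (cache$h2pre > 0)
    g$W3 <- crossprod(cache$zd, dh2pre)
    g$b3 <- colSums(dh2pre)
    dzd <- tcrossprod(dh2pre, p$W3)
    if (is_normae) {
      g$Eb <- matrix(0, cfg$n_batches, cfg$layer2)
      acc <- rowsum(dzd, group = batch_idx)
      g$Eb[as.integer(rownames(acc)), ] <- acc
    }
    dz <- dz + dzd
  }

  if (use_classif) {
    keep <- 1 - cfg$dropout
    mc <- if (!frozen && cfg$dropout > 0)
      matrix(stats::rbinom(n * cfg$layer2, 1, keep), n) / keep
    else matrix(1, n, cfg$layer2)
    zc <- z * mc
    probs <- softmax(affine(zc, p$Wc, p$bc))
    tgt <- smooth_targets(class_idx, cfg$n_classes, cfg$label_smoothing)
    losses$classif <- -mean(rowSums(tgt * log(pmax(probs, 1e-12))))
    # the head always minimizes its own (unweighted) cross-entropy; nu
    # only scales the encoder-bound path of Eq-style total objective
    dlogits <- (probs - tgt) / n
    g$Wc <- crossprod(zc, dlogits)
    g$bc <- colSums(dlogits)
    if (!frozen) dz <- dz + cfg$nu * tcrossprod(dlogits, p$Wc) * mc
  }

  if (frozen) return(list(losses = losses, grads = g, clamped = FALSE))

  dmu <- dlogvar <- NULL
  if (cfg$variational) {
    losses$kld <- kld_gaussian(cache$mu, cache$sigma)
    dmu <- cfg$beta * cache$mu / n
    dlogvar <- cfg$beta * (exp(cache$logvar) - 1) / (2 * n)
  }

  if (use_be) {
    if (cfg$be_strategy %in% c("dann", "batch_mapping_adversarial")) {
      # dropout on the head input keeps the discriminator imperfect, which
      # keeps the adversarial gradient alive once batches become separable
      keep <- 1 - cfg$dropout
      mb <- if (cfg$dropout > 0)
        matrix(stats::rbinom(n * cfg$layer2, 1, keep), n) / keep
      else matrix(1, n, cfg$layer2)
      zb <- z * mb
      pb <- softmax(affine(zb, p$Wb, p$bb))
      tb <- smooth_targets(batch_idx, cfg$n_batches, 0)
      losses$be <- -mean(rowSums(tb * log(pmax(pb, 1e-12))))
      dlb <- (pb - tb) / n
      if (cfg$be_strategy == "dann") {
        # the discriminator head minimizes its own plain CE; only the
        # encoder path carries the gamma-scaled reversed gradient
        g$Wb <- crossprod(zb, dlb)
        g$bb <- colSums(dlb)
      }
      # GRL: encoder-bound gradient of gamma * CE is multiplied by -1
      dz <- dz + grad_reverse_backward(tcrossprod(dlb, p$Wb) * mb, cfg$gamma)
    } else {
      trip <- mine_triplets(batch_idx)
      standard <- cfg$be_strategy == "rev_triplet"
      tg <- triplet_grads(z, trip, cfg$margin, standard)
      losses$be <- tg$loss
      if (standard) {
        dz <- dz + grad_reverse_backward(tg$dz, cfg$gamma)
      } else {
        dz <- dz + cfg$gamma * tg$dz
      }
    }
  }

  # min-max clamp of the batch-mapping composite: when gamma * disc
  # exceeds the minimized losses the composite is 0 and no update happens
  clamped <- FALSE
  if (is_normae && use_be) {
    composite <- normae_objective(losses$rec,
                                  if (use_classif) losses$classif else NULL,
                                  if (cfg$variational) losses$kld else NULL,
                                  disc = losses$be, nu = cfg$nu,
                                  beta = cfg$beta, gamma = cfg$gamma)
    if (composite <= 0) clamped <- TRUE
  }

  # encoder backward
  h1 <- cache$h1
  if (cfg$variational) {
    dmu <- dmu + dz
    dlogvar <- dlogvar + dz * cache$eps * 0.5 * cache$sigma
    inside <- cache$logvar > -10 & cache$logvar < 10
    dlogvar <- dlogvar * inside
    g$Wmu <- crossprod(h1, dmu); g$bmu <- colSums(dmu)
    g$Wlv <- crossprod(h1, dlogvar); g$blv <- colSums(dlogvar)
    dh1 <- tcrossprod(dmu, p$Wmu) + tcrossprod(dlogvar, p$Wlv)
  } else {
    g$W2 <- crossprod(h1, dz); g$b2 <- colSums(dz)
    dh1 <- tcrossprod(dz, p$W2)
  }
  if (!is.null(cache$m1)) dh1 <- dh1 * cache$m1
  dh1pre <- dh1 * (cache$h1pre > 0)
  g$W1 <- crossprod(x, dh1pre)
  g$b1 <- colSums(dh1pre)

  if (clamped) g <- lapply(g, function(gr) gr * 0)
  list(losses = losses, grads = g, clamped = clamped)
}

# Discriminator-only step of the batch-mapping (alternating min-max)
# strategy: plain batch cross-entropy on a detached bottleneck; only the
# discriminator head parameters receive gradients.
disc_step_grads <- function(model, x, batch_idx) {
  p <- model$params; cfg <- model$cfg
  z <- encode(model, x, sample_noise = cfg$variational)$z
  pb <- softmax(affine(z, p$Wb, p$bb))
  tb <- smooth_targets(batch_idx, cfg$n_batches, 0)
  dlb <- (pb - tb) / nrow(x)
  list(loss = -mean(rowSums(tb * log(pmax(pb, 1e-12)))),
       grads = list(Wb = crossprod(z, dlb), bb = colSums(dlb)))
}

# Adam with decoupled weight decay on weight matrices (biases and the
# per-batch embedding table are not decayed).
adam_update <- function(model, grads, lr = model$cfg$learning_rate,
                        weight_decay = model$cfg$weight_decay,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt <- model$opt
  if (is.null(opt$t)) opt <- list(t = 0, m = list(), v = list())
  opt$t <- opt$t + 1
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    if (is.null(opt$m[[nm]])) {
      opt$m[[nm]] <- gr * 0
      opt$v[[nm]] <- gr * 0
    }
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * gr
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * gr^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    step <- lr * mhat / (sqrt(vhat) + eps)
    if (grepl("^W", nm) && weight_decay > 0)
      step <- step + lr * weight_decay * model$params[[nm]]
    model$params[[nm]] <- model$params[[nm]] - step
  }
  model$opt <- opt
  model
}
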