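#' Hyperparameter search space
#'
#' Ranges for the tunable hyperparameters. Conditional parameters are
#' sampled only when the model family uses them: `margin` for triplet
#' strategies, `beta` for variational models, `gamma` for any batch-effect
#' strategy. The normalization variant is a 6-way categorical choice.
#'
#' @param learning_rate,weight_decay,beta,gamma length-2 numeric:
#'   log-uniform bounds.
#' @param dropout,label_smoothing,margin length-2 numeric: uniform bounds.
#' @param warmup_epochs,layer1,layer2 length-2 integer bounds (layer2 is
#'   truncated at the sampled layer1).
#' @param normalization character vector of variant names.
#' @return a `search_space` object.
#' @export
search_space <- function(learning_rate = c(1e-5, 1e-2),
                         weight_decay = c(1e-8, 1e-2),
                         dropout = c(0, 0.5),
                         warmup_epochs = c(10L, 250L),
                         layer1 = c(32L, 1024L),
                         layer2 = c(16L, 256L),
                         label_smoothing = c(0, 0.2),
                         margin = c(0, 10),
                         beta = c(1e-4, 10),
                         gamma = c(1e-4, 10),
                         normalization = norm_variants()) {
  structure(list(
    learning_rate = list(type = "loguniform", low = learning_rate[1],
                         high = learning_rate[2]),
    weight_decay = list(type = "loguniform", low = weight_decay[1],
                        high = weight_decay[2]),
    dropout = list(type = "uniform", low = dropout[1], high = dropout[2]),
    warmup_epochs = list(type = "int", low = warmup_epochs[1],
                         high = warmup_epochs[2]),
    layer1 = list(type = "int", low = layer1[1], high = layer1[2]),
    layer2 = list(type = "int", low = layer2[1], high = layer2[2]),
    label_smoothing = list(type = "uniform", low = label_smoothing[1],
                           high = label_smoothing[2]),
    margin = list(type = "uniform", low = margin[1], high = margin[2]),
    beta = list(type = "loguniform", low = beta[1], high = beta[2]),
    gamma = list(type = "loguniform", low = gamma[1], high = gamma[2]),
    normalization = list(type = "choice", choices = normalization)
  ), class = "search_space")
}

active_params <- function(space, variational, be_strategy) {
  nm <- names(space)
  if (!variational) nm <- setdiff(nm, "beta")
  if (!be_strategy %in% c("inv_triplet", "rev_triplet"))
    nm <- setdiff(nm, "margin")
  if (be_strategy == "none") nm <- setdiff(nm, "gamma")
  nm
}

sample_param <- function(def) {
  switch(def$type,
    loguniform = exp(stats::runif(1, log(def$low), log(def$high))),
    uniform = stats::runif(1, def$low, def$high),
    int = sample(seq(def$low, def$high), 1),
    choice = sample(def$choices, 1))
}

sample_trial <- function(space, active) {
  out <- lapply(space[active], sample_param)
  if (!is.null(out$layer2) && !is.null(out$layer1))
    out$layer2 <- min(out$layer2, out$layer1)
  out
}

# Tree-of-Parzen-estimators-flavoured proposal: candidates are drawn
# around the better trials and scored by the ratio of "good" to "bad"
# kernel densities; categorical choices are re-weighted by their
# frequency among the good trials. Falls back to pure random sampling
# for the startup trials (and whenever sampler = "random").
tpe_trial <- function(space, active, history, n_candidates = 24,
                      good_frac = 0.25) {
  ok <- history[is.finite(history$objective), , drop = FALSE]
  if (nrow(ok) < 4) return(sample_trial(space, active))
  cut <- stats::quantile(ok$objective, 1 - good_frac, type = 7)
  good <- ok[ok$objective >= cut, , drop = FALSE]
  bad <- ok[ok$objective < cut, , drop = FALSE]
  if (nrow(good) < 2 || nrow(bad) < 2) return(sample_trial(space, active))
  out <- list()
  for (nm in active) {
    def <- space[[nm]]
    if (def$type == "choice") {
      wt <- table(factor(good[[nm]], def$choices)) + 1  # +1 smoothing
      out[[nm]] <- sample(def$choices, 1, prob = as.numeric(wt))
      next
    }
    tolog <- def$type == "loguniform"
    gv <- good[[nm]]; bv <- bad[[nm]]
    if (tolog) { gv <- log(gv); bv <- log(bv) }
    lo <- if (tolog) log(def$low) else def$low
    hi <- if (tolog) log(def$high) else def$high
    bw <- max((hi - lo) / 5, 1e-8)
    cand <- stats::rnorm(n_candidates, mean = sample(gv, n_candidates,
                                                     replace = TRUE),
                         sd = bw)
    cand <- pmin(pmax(cand, lo), hi)
    dens <- function(x, pts) rowMeans(outer(x, pts, function(a, b)
      stats::dnorm(a, b, bw)))
    ratio <- dens(cand, gv) / (dens(cand, bv) + 1e-12)
    pick <- cand[which.max(ratio)]
    if (tolog) pick <- exp(pick)
    if (def$type == "int") pick <- as.integer(round(pick))
    out[[nm]] <- pick
  }
  if (!is.null(out$layer2) && !is.null(out$layer1))
    out$layer2 <- min(out$layer2, out$layer1)
  out
}

#' Sequential hyperparameter search for one model family
#'
#' Runs `n_trials` hyperparameter configurations. Each trial preprocesses
#' the data with the trial's normalization variant, then trains and
#' evaluates the model on every holdout split; the objective is the
#' unweighted mean of the best validation MCC across splits. Returns the
#' argmax configuration and the full trial log (failed trials are kept
#' with objective `-Inf` and their error message).
#'
#' @param m the raw (untransformed) `omics_matrix`.
#' @param family one of `model_zoo()$family`.
#' @param splits list of `holdout_split` objects.
#' @param n_trials number of configurations (default 20).
#' @param seed integer seed; the trial sequence is reproducible.
#' @param scenario training scenario (1 or 2).
#' @param sampler `"tpe"` (density-ratio guided, default) or `"random"`.
#' @param space a [search_space()].
#' @param max_epochs,patience,batch_size training-loop controls passed to
#'   the scenario trainer (reduce them for quick searches).
#' @param fixed named list of [model_config()] arguments overriding
#'   sampled values (e.g. `list(nu = 1)`).
#' @return list with `best_config`, `best_objective`, and `trials`
#'   (data.frame: one row per trial with the sampled values, objective
#'   and error message).
#' @export
hyperopt_search <- function(m, family, splits, n_trials = 20, seed = 1L,
                            scenario = 2, sampler = c("tpe", "random"),
                            space = search_space(), max_epochs = 1000,
                            patience = 100, batch_size = 32,
                            fixed = list()) {
  sampler <- match.arg(sampler)
  stopifnot(inherits(m, "omics_matrix"), n_trials >= 1)
  zoo <- model_zoo()
  fi <- match(family, zoo$family)
  if (is.na(fi))
    stop("unknown model family '", family, "'; valid families: ",
         paste(zoo$family, collapse = ", "))
  active <- active_params(space, zoo$variational[fi], zoo$be_strategy[fi])
  active <- setdiff(active, names(fixed))
  n_features <- ncol(m$values)
  n_classes <- length(unique(m$class_labels[!m$qc_flags]))
  n_batches <- length(unique(m$batch_labels))
  logged <- log1p_transform(m)
  history <- data.frame()
  configs <- vector("list", n_trials)
  first_error <- NULL
  with_seed(seed, {
    for (t in seq_len(n_trials)) {
      params <- if (sampler == "tpe")
        tpe_trial(space, active, history) else sample_trial(space, active)
      params <- utils::modifyList(params, fixed)
      args <- c(list(family = family, n_features = n_features,
                     n_classes = n_classes, n_batches = n_batches,
                     seed = seed + t), params)
      cfg <- do.call(config_from_family, args)
      configs[[t]] <- cfg
      res <- tryCatch({
        objs <- vapply(splits, function(sp) {
          full_n <- normalize_omics(logged, cfg$normalization)
          views <- materialize_split(sp, full_n)
          tr <- views$train
          va <- views$valid
          model <- build_model(cfg)
          wu <- warmup(model, full_n)
          fit <- if (scenario == 2)
            train_scenario2(wu$model, tr, va, full_n,
                            max_epochs = max_epochs, patience = patience,
                            batch_size = batch_size)
          else
            train_scenario1(wu$model, tr, va, max_epochs = max_epochs,
                            patience = patience, batch_size = batch_size)
          fit$state$best_valid_mcc
        }, numeric(1))
        list(objective = mean(objs), error = NA_character_)
      }, error = function(e) {
        list(objective = -Inf, error = conditionMessage(e))
      })
      if (is.infinite(res$objective) && is.null(first_error) &&
          !is.na(res$error))
        first_error <- res$error
      row <- data.frame(trial = t, objective = res$objective,
                        error = res$error)
      for (nm in active)
        row[[nm]] <- if (is.numeric(params[[nm]])) params[[nm]]
                     else as.character(params[[nm]])
      history <- rbind(history, row)
    }
  })
  if (all(is.infinite(history$objective)))
    stop("all hyperparameter trials failed; first error: ", first_error)
  best <- which.max(history$objective)
  list(best_config = configs[[best]],
       best_objective = history$objective[best],
       trials = history)
}
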