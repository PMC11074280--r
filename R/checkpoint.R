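# Model checkpoints as structured text. Parameter values are written as
# C99 hexadecimal floating-point literals, which R parses back exactly, so
# a save/load round trip restores bitwise-identical forward passes.

num_to_hex <- function(x) sprintf("%a", as.numeric(x))
hex_to_num <- function(s) as.numeric(s)

#' Save a model to a single-file text checkpoint
#'
#' The checkpoint is JSON holding the configuration, the recorded batch
#' and class levels, and every parameter array with exact (hex-float)
#' values. Optimizer state is not saved.
#'
#' @param model a `bae_model`.
#' @param path output path.
#' @param overwrite allow clobbering an existing file.
#' @return invisibly, `path`.
#' @export
save_model <- function(model, path, overwrite = FALSE) {
  stopifnot(inherits(model, "bae_model"))
  if (file.exists(path) && !overwrite)
    stop("refusing to overwrite existing checkpoint: ", path)
  cfg <- model$cfg
  cfg_out <- unclass(cfg)
  cfg_out$normalization <- unclass(cfg$normalization)
  params_out <- lapply(model$params, function(p) {
    list(dim = if (is.matrix(p)) dim(p) else length(p),
         values = num_to_hex(p))
  })
  obj <- list(format = "bae_checkpoint_v1", config = cfg_out,
              batch_levels = model$batch_levels,
              class_levels = model$class_levels,
              params = params_out)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Load a model from a text checkpoint
#'
#' @param path checkpoint written by [save_model()].
#' @return a `bae_model` whose forward passes match the saved model
#'   bitwise.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "bae_checkpoint_v1"))
    stop("not a model checkpoint: ", path)
  cf <- obj$config
  cfg <- model_config(n_features = cf$n_features, n_classes = cf$n_classes,
                      n_batches = cf$n_batches, layer1 = cf$layer1,
                      layer2 = cf$layer2, variational = cf$variational,
                      be_strategy = cf$be_strategy, dropout = cf$dropout,
                      label_smoothing = cf$label_smoothing,
                      margin = cf$margin, nu = cf$nu, beta = cf$beta,
                      gamma = cf$gamma, learning_rate = cf$learning_rate,
                      weight_decay = cf$weight_decay,
                      warmup_epochs = cf$warmup_epochs,
                      normalization = norm_spec(cf$normalization$method,
                                                cf$normalization$per_batch),
                      seed = cf$seed)
  model <- build_model(cfg)
  for (nm in names(obj$params)) {
    p <- obj$params[[nm]]
    vals <- hex_to_num(p$values)
    model$params[[nm]] <- if (length(p$dim) == 2)
      matrix(vals, p$dim[1], p$dim[2]) else vals
  }
  model$batch_levels <- obj$batch_levels
  model$class_levels <- obj$class_levels
  model
}
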