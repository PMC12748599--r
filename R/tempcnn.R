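# R surface of the temporal CNN: configuration objects, training with
# spatial cross-validation, prediction, and plain-text serialization.

#' TempCNN architecture configuration
#'
#' Stacked 1-D convolution blocks along the time axis (64 filters, kernel
#' 3, same-length padding, ReLU, dropout 0.4), a dense hidden layer of
#' width 64 with dropout, and a softmax output.
#'
#' @param n_classes number of output classes (default: all training classes)
#' @param kernel_size convolution kernel length (default 3)
#' @param hidden_dim filters per conv block and dense width (default 64)
#' @param dropout dropout rate applied after every block (default 0.4)
#' @param n_conv_blocks number of convolution blocks (default 3)
#' @param n_timesteps,n_bands input window shape (default 10 years x 6 bands)
#' @return a `model_config` list
#' @export
model_config <- function(n_classes = nrow(class_scheme()), kernel_size = 3,
                         hidden_dim = 64, dropout = 0.4, n_conv_blocks = 3,
                         n_timesteps = 10, n_bands = 6) {
  assert(n_timesteps >= kernel_size, "window shorter than the kernel")
  assert(dropout >= 0 && dropout < 1, "dropout in [0,1)")
  assert(n_classes >= 2, "need at least 2 classes")
  structure(list(n_classes = as.integer(n_classes),
                 kernel_size = as.integer(kernel_size),
                 hidden_dim = as.integer(hidden_dim), dropout = dropout,
                 n_conv_blocks = as.integer(n_conv_blocks),
                 n_timesteps = as.integer(n_timesteps),
                 n_bands = as.integer(n_bands)),
            class = "model_config")
}

#' TempCNN training configuration
#'
#' Defaults follow the production protocol: 50 epochs, batch size 64,
#' weight decay 1e-5, initial learning rate 0.001 decreasing every epoch
#' (multiplicative factor `lr_decay`).
#'
#' @param epochs,batch_size,weight_decay,initial_lr,lr_decay optimizer
#'   settings
#' @param seed integer; all training randomness derives from it
#' @return a `train_config` list
#' @export
train_config <- function(epochs = 50, batch_size = 64, weight_decay = 1e-5,
                         initial_lr = 0.001, lr_decay = 0.95, seed = 1L) {
  assert(epochs >= 1 && batch_size >= 1 && initial_lr > 0 && weight_decay >= 0,
         "training parameters must be positive")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, initial_lr = initial_lr,
                 lr_decay = lr_decay, seed = as.integer(seed)),
            class = "train_config")
}

#' Build an (untrained) TempCNN
#'
#' @param cfg a [model_config()]
#' @param classes character vector of class labels in output order (ties at
#'   prediction time break toward the lowest index)
#' @param seed integer seed for weight initialization
#' @return a `tempcnn_model`
#' @export
build_model <- function(cfg = model_config(), classes = NULL, seed = 1L) {
  assert(inherits(cfg, "model_config"), "cfg must be a model_config")
  if (is.null(classes)) classes <- class_scheme()$class[seq_len(cfg$n_classes)]
  assert(length(classes) == cfg$n_classes, "classes must match n_classes")
  w <- cnn_init(cfg$n_bands, cfg$n_timesteps, cfg$n_classes, cfg$hidden_dim,
                cfg$kernel_size, cfg$n_conv_blocks, as.double(seed))
  structure(list(weights = w, cfg = cfg, classes = classes,
                 norm = NULL, history = NULL),
            class = "tempcnn_model")
}

#' @export
print.tempcnn_model <- function(x, ...) {
  cat(sprintf("<tempcnn_model> %d conv blocks x %d filters, kernel %d, %d classes%s\n",
              x$cfg$n_conv_blocks, x$cfg$hidden_dim, x$cfg$kernel_size,
              x$cfg$n_classes, if (is.null(x$norm)) " (untrained)" else ""))
  invisible(x)
}

flatten_windows <- function(x, cfg) {
  if (is.matrix(x) && !is.array(x)) x <- array(x, c(1, dim(x)))
  if (length(dim(x)) == 2 && all(dim(x) == c(cfg$n_timesteps, cfg$n_bands)))
    x <- array(x, c(1, dim(x)))
  assert(length(dim(x)) == 3 && dim(x)[2] == cfg$n_timesteps &&
           dim(x)[3] == cfg$n_bands,
         sprintf("windows must be n x %d x %d", cfg$n_timesteps, cfg$n_bands))
  matrix(x, nrow = dim(x)[1])  # column index = (band-1)*T + t
}

apply_norm <- function(flat, norm, cfg) {
  tcol <- cfg$n_timesteps
  for (b in seq_len(cfg$n_bands)) {
    cols <- ((b - 1) * tcol + 1):(b * tcol)
    flat[, cols] <- (flat[, cols] - norm$mean[b]) / norm$sd[b]
  }
  flat
}

fit_once <- function(flat, yint, cfg, tcfg, seed_offset = 0) {
  w0 <- cnn_init(cfg$n_bands, cfg$n_timesteps, cfg$n_classes, cfg$hidden_dim,
                 cfg$kernel_size, cfg$n_conv_blocks,
                 as.double(tcfg$seed + seed_offset))
  cnn_train(flat, yint, w0, tcfg$epochs, tcfg$batch_size, tcfg$initial_lr,
            tcfg$lr_decay, tcfg$weight_decay, cfg$dropout,
            as.double(tcfg$seed + seed_offset))
}

#' Train the TempCNN
#'
#' Per-band standardization statistics are computed from the training set
#' and stored with the model. When `folds` (from [spatial_cv_split()]) is
#' supplied, a model is refit on each fold's training tiles and evaluated
#' on its test tiles (spatial cross-validation), the holdout tiles are
#' scored with the final model as an overfitting check, and the final model
#' is trained on all non-holdout points.
#'
#' @param x windows, array n x 10 x 6
#' @param label character/factor vector of training classes
#' @param cfg [model_config()] (n_classes may be left at default; it is
#'   reconciled with the observed classes)
#' @param tcfg [train_config()]
#' @param folds optional result of [spatial_cv_split()]
#' @return trained `tempcnn_model` with `history` (per-epoch loss),
#'   `fold_metrics` (data.frame fold/accuracy, if folds given),
#'   `holdout_accuracy`, and `train_accuracy`
#' @export
tempcnn_train <- function(x, label, cfg = NULL, tcfg = train_config(),
                          folds = NULL) {
  label <- as.character(label)
  sch <- class_scheme()$class
  classes <- c(intersect(sch, unique(label)), setdiff(sort(unique(label)), sch))
  assert(length(classes) >= 2, "need at least 2 classes present")
  if (is.null(cfg)) cfg <- model_config(n_classes = length(classes))
  if (cfg$n_classes != length(classes))
    cfg$n_classes <- length(classes)
  flat <- flatten_windows(x, cfg)
  yint <- match(label, classes) - 1L

  norm <- list(mean = numeric(cfg$n_bands), sd = numeric(cfg$n_bands))
  for (b in seq_len(cfg$n_bands)) {
    cols <- ((b - 1) * cfg$n_timesteps + 1):(b * cfg$n_timesteps)
    norm$mean[b] <- mean(flat[, cols])
    norm$sd[b] <- max(sd(flat[, cols]), 1e-8)
  }
  nf <- apply_norm(flat, norm, cfg)

  acc_of <- function(w, idx) {
    if (!length(idx)) return(NA_real_)
    p <- cnn_predict(nf[idx, , drop = FALSE], w)
    mean(max.col(p, ties.method = "first") == yint[idx] + 1L)
  }

  fold_metrics <- NULL
  train_idx <- seq_along(yint)
  if (!is.null(folds)) {
    train_idx <- setdiff(seq_along(yint), folds$holdout_idx)
    accs <- vapply(seq_along(folds$fold_idx), function(f) {
      tr <- folds$fold_idx[[f]]$train; te <- folds$fold_idx[[f]]$test
      missing_cl <- setdiff(classes, unique(label[tr]))
      if (length(missing_cl))
        warning("classes absent from fold ", f, " training tiles: ",
                paste(missing_cl, collapse = ", "), call. = FALSE)
      fit <- fit_once(nf[tr, , drop = FALSE], yint[tr], cfg, tcfg, seed_offset = f)
      keep <- te[label[te] %in% setdiff(classes, missing_cl)]
      acc_of(fit$weights, keep)
    }, 0)
    fold_metrics <- data.frame(fold = seq_along(accs), accuracy = accs)
  }

  fit <- fit_once(nf[train_idx, , drop = FALSE], yint[train_idx], cfg, tcfg)
  model <- structure(list(weights = fit$weights, cfg = cfg, classes = classes,
                          norm = norm, history = as.numeric(fit$epoch_loss),
                          fold_metrics = fold_metrics,
                          train_accuracy = acc_of(fit$weights, train_idx),
                          holdout_accuracy =
                            if (is.null(folds)) NA_real_
                            else acc_of(fit$weights, folds$holdout_idx)),
                     class = "tempcnn_model")
  model
}

#' Predict class probabilities for 10-year windows
#'
#' @param object trained `tempcnn_model`
#' @param x one window (10 x 6 matrix) or an array n x 10 x 6
#' @param type "prob" for the probability matrix, "class" for argmax labels
#'   (ties break toward the lowest class index)
#' @param ... unused
#' @return matrix n x n_classes (colnames = classes), or character vector
#' @export
predict.tempcnn_model <- function(object, x, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  assert(!is.null(object$norm), "model is untrained (no normalization stats)")
  flat <- flatten_windows(x, object$cfg)
  assert(all(is.finite(flat)), "windows must be fully observed (impute first)")
  p <- cnn_predict(apply_norm(flat, object$norm, object$cfg), object$weights)
  colnames(p) <- object$classes
  if (type == "class") object$classes[max.col(p, ties.method = "first")] else p
}

#' Serialize a trained model to a single versioned JSON file
#' @param model tempcnn_model
#' @param path output path
#' @return invisibly, the path
#' @export
tempcnn_save <- function(model, path) {
  w <- model$weights
  bn_out <- function(b) lapply(b, as.numeric)
  obj <- list(
    format = "borealdist-tempcnn", version = 2L,
    cfg = unclass(model$cfg), classes = model$classes, norm = model$norm,
    history = model$history,
    weights = list(convW = lapply(w$convW, as.matrix),
                   convBN = lapply(w$convBN, bn_out),
                   denseW = as.matrix(w$denseW), denseBN = bn_out(w$denseBN),
                   outW = as.matrix(w$outW), outB = as.numeric(w$outB),
                   kernel = w$kernel))
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' Load a model written by [tempcnn_save()]
#' @param path JSON path
#' @return tempcnn_model
#' @export
tempcnn_load <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  assert(identical(obj$format, "borealdist-tempcnn"), "not a tempcnn model file")
  w <- obj$weights
  # equal-shape per-block weights may come back simplified to one array
  as_mat_list <- function(x) {
    if (is.data.frame(x)) list(as.matrix(x))
    else if (is.list(x)) lapply(x, as.matrix)
    else if (length(dim(x)) == 3)
      lapply(seq_len(dim(x)[1]), function(i) as.matrix(x[i, , ]))
    else list(as.matrix(x))
  }
  as_bn <- function(b) lapply(b, as.numeric)
  bn_list <- function(x) {
    if (is.data.frame(x))  # n_blocks rows x 4 list-columns
      lapply(seq_len(nrow(x)), function(i) as_bn(lapply(x, `[[`, i)))
    else if (!is.null(x$gamma)) list(as_bn(x))
    else lapply(x, as_bn)
  }
  weights <- list(convW = as_mat_list(w$convW),
                  convBN = bn_list(w$convBN),
                  denseW = as.matrix(w$denseW), denseBN = as_bn(w$denseBN),
                  outW = as.matrix(w$outW), outB = as.numeric(w$outB),
                  kernel = as.integer(w$kernel))
  cfg <- do.call(model_config, obj$cfg)
  structure(list(weights = weights, cfg = cfg, classes = obj$classes,
                 norm = list(mean = as.numeric(obj$norm$mean),
                             sd = as.numeric(obj$norm$sd)),
                 history = as.numeric(obj$history)),
            class = "tempcnn_model")
}
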