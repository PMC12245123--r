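#' Model configuration for the concentration-regression networks
#'
#' Describes one of the three network families:
#' \itemize{
#'   \item DBCNet (`dual_branch = TRUE`, `input_mode = "rpm_2d"`): shared
#'     residual 2D backbone on RPM images, then one branch per metabolite,
#'     each `dense -> relu -> batch correlation -> dense(1)`.
#'   \item 2D residual baseline (`dual_branch = FALSE`,
#'     `input_mode = "rpm_2d"`): same backbone, single fully connected head
#'     with 2 outputs, no batch correlation.
#'   \item 1D residual baseline (`input_mode = "raw_1d"`): residual 1D
#'     convolutions on the preprocessed spectra themselves.
#' }
#'
#' Two backbone scales exist. `"reduced"` is the desk-scale default: an
#' input average-pool (`pool_input`) shrinks the RPM image, followed by two
#' strided convolutions and one residual block. `"resnet18"` is the full
#' 18-layer residual topology (7x7 stem, max-pool, four stages of two basic
#' blocks, global average pooling, 512-d features) with the RPM matrix
#' replicated to the 3 input channels the stem expects; it is provided for
#' completeness and scales far beyond what a single CPU needs for the
#' synthetic calibration problem.
#'
#' @param input_length Number of points M in the preprocessed spectra.
#' @param input_mode `"rpm_2d"` (RPM image input) or `"raw_1d"`.
#' @param backbone `"reduced"` or `"resnet18"`.
#' @param pool_input Average-pool factor applied to the RPM image before the
#'   reduced backbone (must divide `input_length`).
#' @param widths Channel widths of the reduced backbone's stride-2 conv
#'   stages (one stage per entry); the last entry is the shared feature
#'   dimension.
#' @param branch_hidden Width of the per-branch hidden dense layer
#'   (0 = none).
#' @param dual_branch Use the two-branch architecture with batch
#'   correlation.
#' @param bc_method Batch-correlation weight normalization, `"softmax"` or
#'   `"sumpos"` (see [batch_correlation()]).
#' @param bc_temperature Softmax temperature.
#' @param init_seed Seed for weight initialization at build time.
#' @return A `sers_model_config`.
#' @export
model_config <- function(input_length,
                         input_mode = c("rpm_2d", "raw_1d"),
                         backbone = c("reduced", "resnet18"),
                         pool_input = 2,
                         widths = c(8, 16, 24, 32),
                         branch_hidden = 32,
                         dual_branch = TRUE,
                         bc_method = c("softmax", "sumpos"),
                         bc_temperature = 0.002,
                         init_seed = 1L) {
  input_mode <- match.arg(input_mode)
  backbone <- match.arg(backbone)
  bc_method <- match.arg(bc_method)
  stopifnot(input_length >= 8, pool_input >= 1, length(widths) >= 1,
            bc_temperature > 0)
  if (input_mode == "rpm_2d" && backbone == "reduced" &&
      input_length %% pool_input != 0)
    stop("pool_input must divide input_length")
  structure(list(input_length = as.integer(input_length),
                 input_mode = input_mode, backbone = backbone,
                 pool_input = as.integer(pool_input), widths = as.integer(widths),
                 branch_hidden = as.integer(branch_hidden),
                 dual_branch = dual_branch, bc_method = bc_method,
                 bc_temperature = bc_temperature,
                 init_seed = as.integer(init_seed)),
            class = "sers_model_config")
}

#' Training protocol configuration
#'
#' Defaults follow the reference protocol: Nadam with initial learning rate
#' 0.001, MAE loss, up to 400 epochs with batch size 32, learning-rate
#' reduction on validation plateau (patience 25, factor 0.1) and early
#' stopping (patience 30). H2O2 labels are divided by `h2o2_scale` during
#' optimization so both metabolites contribute comparably to the summed MAE;
#' predictions are returned on the original uM scale.
#'
#' @param lr Initial learning rate.
#' @param epochs Maximum epochs.
#' @param batch_size Minibatch size.
#' @param lr_patience,lr_factor Plateau patience (epochs) and multiplicative
#'   LR reduction factor.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping.
#' @param h2o2_scale Internal label scale for the H2O2 channel (uM per
#'   unit).
#' @param bc_warmup Fraction of the epoch budget trained with the
#'   batch-correlation layers held at identity before they are switched on
#'   (models without batch correlation ignore it). Freshly initialized
#'   features are almost parallel, so the cosine-weighted update would
#'   collapse every feature onto the batch mean and stall training; the
#'   warm-up first learns discriminative features, then the joint phase
#'   (with a fresh optimizer state) adapts them to the mixing.
#' @param seed Seed driving weight re-initialization and batch order.
#' @return A `sers_train_config`.
#' @export
train_config <- function(lr = 0.001, epochs = 400, batch_size = 32,
                         lr_patience = 25, lr_factor = 0.1,
                         early_stop_patience = 30, h2o2_scale = 10,
                         bc_warmup = 0.75, seed = 1L) {
  stopifnot(lr > 0, epochs >= 1, batch_size >= 1, lr_patience >= 1,
            lr_factor > 0, lr_factor < 1, early_stop_patience >= 1,
            h2o2_scale > 0, bc_warmup >= 0, bc_warmup <= 1)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_patience = as.integer(lr_patience), lr_factor = lr_factor,
                 early_stop_patience = as.integer(early_stop_patience),
                 h2o2_scale = h2o2_scale, bc_warmup = bc_warmup,
                 seed = as.integer(seed)),
            class = "sers_train_config")
}

build_backbone_2d <- function(cfg) {
  if (cfg$backbone == "reduced") {
    layers <- list()
    if (cfg$pool_input > 1) layers <- c(layers, list(layer_avgpool2d(cfg$pool_input)))
    ch <- 1L
    for (w in cfg$widths) {
      layers <- c(layers, list(layer_conv2d(ch, w, 3, 2, 1), layer_relu()))
      ch <- w
    }
    layers <- c(layers, list(
      layer_resblock2d(ch, ch, 1),
      layer_global_avgpool2d()))
    list(layers = layers, feature_dim = ch, channels = 1L)
  } else {
    layers <- list(
      layer_conv2d(3, 64, 7, 2, 3), layer_relu(),
      layer_maxpool2d(3, 2, 1),
      layer_resblock2d(64, 64, 1), layer_resblock2d(64, 64, 1),
      layer_resblock2d(64, 128, 2), layer_resblock2d(128, 128, 1),
      layer_resblock2d(128, 256, 2), layer_resblock2d(256, 256, 1),
      layer_resblock2d(256, 512, 2), layer_resblock2d(512, 512, 1),
      layer_global_avgpool2d())
    list(layers = layers, feature_dim = 512L, channels = 3L)
  }
}

build_backbone_1d <- function(cfg) {
  layers <- list()
  ch <- 1L
  for (w in cfg$widths) {
    layers <- c(layers, list(layer_conv1d(ch, w, 5, 2, 2), layer_relu()))
    ch <- w
  }
  layers <- c(layers, list(layer_resblock1d(ch, ch, 1),
                           layer_global_avgpool1d()))
  list(layers = layers, feature_dim = ch, channels = 1L)
}

build_branch <- function(cfg, feature_dim) {
  layers <- list()
  d <- feature_dim
  if (cfg$branch_hidden > 0) {
    layers <- c(layers, list(layer_dense(d, cfg$branch_hidden), layer_relu()))
    d <- cfg$branch_hidden
  }
  layers <- c(layers, list(
    layer_batch_correlation(cfg$bc_method, cfg$bc_temperature),
    layer_dense(d, 1)))
  layers
}

#' Build a concentration-regression model
#'
#' Instantiates the network described by a [model_config()], with weights
#' drawn from a He-normal initialization seeded by `cfg$init_seed`. The
#' returned model maps a batch of preprocessed spectra (RPM conversion
#' happens inside the forward pass for 2D modes) to an N x 2 matrix of
#' predicted concentrations.
#'
#' @param cfg A `sers_model_config`.
#' @return A `sers_model` (mutable environment).
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "sers_model_config"))
  old <- local_seed(cfg$init_seed)
  on.exit(restore_seed(old))
  bb <- if (cfg$input_mode == "rpm_2d") build_backbone_2d(cfg) else build_backbone_1d(cfg)
  m <- new.env(parent = emptyenv())
  m$cfg <- cfg
  m$backbone <- bb$layers
  m$feature_dim <- bb$feature_dim
  m$channels <- bb$channels
  if (cfg$dual_branch) {
    m$branches <- list(gsh = build_branch(cfg, bb$feature_dim),
                       h2o2 = build_branch(cfg, bb$feature_dim))
    m$head <- NULL
  } else {
    m$branches <- NULL
    m$head <- list(layer_dense(bb$feature_dim, 2))
  }
  m$trained <- FALSE
  m$history <- NULL
  class(m) <- "sers_model"
  m
}

#' Build one of the two reference baselines
#'
#' `"resnet_1d"` consumes raw preprocessed spectra; `"resnet_2d"` consumes
#' RPM images. Both use a single shared fully connected head with two
#' outputs and no batch correlation -- i.e. the 2D baseline is the DBCNet
#' topology minus the dual branches.
#'
#' @param kind `"resnet_1d"` or `"resnet_2d"`.
#' @param input_length Spectrum length M.
#' @param ... Further arguments passed to [model_config()].
#' @return A `sers_model`.
#' @export
build_baseline <- function(kind = c("resnet_1d", "resnet_2d"), input_length, ...) {
  kind <- match.arg(kind)
  cfg <- model_config(input_length,
                      input_mode = if (kind == "resnet_1d") "raw_1d" else "rpm_2d",
                      dual_branch = FALSE, ...)
  build_model(cfg)
}

all_model_layers <- function(model) {
  c(model$backbone,
    if (!is.null(model$branches)) c(model$branches$gsh, model$branches$h2o2),
    if (!is.null(model$head)) model$head)
}

#' @export
print.sers_model <- function(x, ...) {
  cat(sprintf("<sers_model> %s %s backbone, %s, %d parameters, %s\n",
              x$cfg$input_mode, x$cfg$backbone,
              if (x$cfg$dual_branch) sprintf("dual-branch (bc=%s)", x$cfg$bc_method)
              else "single head",
              n_params(all_model_layers(x)),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# Convert raw spectra rows to the network's input tensor.
model_input <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$cfg$input_length)
    stop(sprintf("model expects %d-point spectra, got %d",
                 model$cfg$input_length, ncol(x)))
  if (model$cfg$input_mode == "raw_1d") {
    dim(x) <- c(nrow(x), ncol(x), 1)
    return(x)
  }
  a <- rpm_batch(x)
  d <- dim(a)
  if (model$channels == 1) {
    dim(a) <- c(d, 1)
    a
  } else {
    out <- array(0, c(d, model$channels))
    for (c in seq_len(model$channels)) out[, , , c] <- a
    out
  }
}

#' Forward pass of a model (any training state)
#'
#' Low-level forward used by training and prediction; exposed so the
#' network's I/O contract can be exercised without training.
#'
#' @param model A `sers_model`.
#' @param x N x M matrix of preprocessed spectra.
#' @param training Logical; training mode.
#' @param bc_mode `"batch"` applies batch correlation across the rows of
#'   `x`; `"identity"` makes it degenerate to the identity (per-sample
#'   behavior).
#' @return N x 2 matrix of internal-scale predictions.
#' @export
model_forward <- function(model, x, training = FALSE, bc_mode = "batch") {
  set_bc_mode(model, bc_mode)
  h <- model_input(model, x)
  for (l in model$backbone) h <- l$forward(h, training)
  if (!is.null(model$branches)) {
    p1 <- h; for (l in model$branches$gsh) p1 <- l$forward(p1, training)
    p2 <- h; for (l in model$branches$h2o2) p2 <- l$forward(p2, training)
    cbind(p1[, 1], p2[, 1])
  } else {
    for (l in model$head) h <- l$forward(h, training)
    h
  }
}

set_bc_mode <- function(model, bc_mode) {
  for (l in all_model_layers(model))
    if (l$kind == "batch_correlation") l$bc_mode <- bc_mode
  invisible(NULL)
}

model_backward <- function(model, dpred) {
  if (!is.null(model$branches)) {
    d1 <- matrix(dpred[, 1], ncol = 1)
    for (l in rev(model$branches$gsh)) d1 <- l$backward(d1)
    d2 <- matrix(dpred[, 2], ncol = 1)
    for (l in rev(model$branches$h2o2)) d2 <- l$backward(d2)
    dh <- d1 + d2
  } else {
    dh <- dpred
    for (l in rev(model$head)) dh <- l$backward(dh)
  }
  for (l in rev(model$backbone)) dh <- l$backward(dh)
  invisible(NULL)
}

scale_labels <- function(y, tcfg) cbind(y[, 1], y[, 2] / tcfg$h2o2_scale)
unscale_preds <- function(p, h2o2_scale) cbind(c_gsh = p[, 1], c_h2o2 = p[, 2] * h2o2_scale)

batched_loss <- function(model, x, y, batch_size, bc_mode) {
  n <- nrow(x)
  tot <- 0
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    pred <- model_forward(model, x[b, , drop = FALSE], training = FALSE, bc_mode = bc_mode)
    tot <- tot + sum(abs(pred - y[b, , drop = FALSE]))
  }
  tot / (n * 2)
}

#' Train a model with the reference protocol
#'
#' Minimizes the summed per-metabolite mean absolute error with Nadam,
#' re-initializing the weights from `tcfg$seed` so one integer reproduces
#' initialization and batch order. Validation loss is tracked every epoch
#' (with the same batch-correlation regime as training); the learning rate
#' is cut by `lr_factor` after `lr_patience` epochs without improvement,
#' training stops after `early_stop_patience` such epochs, and the weights
#' of the best validation epoch are restored at the end.
#'
#' @param model A `sers_model` (modified in place and returned).
#' @param x N x M matrix of preprocessed spectra.
#' @param y N x 2 label matrix (GSH mM, H2O2 uM), no missing values among
#'   the rows used.
#' @param split A `sers_split` (only `train` and `val` are used).
#' @param tcfg A `sers_train_config`.
#' @param reinit Re-initialize weights from `tcfg$seed` (default TRUE).
#' @param verbose Print per-epoch losses.
#' @return The trained model; `model$history` holds a data.frame with
#'   per-epoch `train_loss`, `val_loss` and `lr`.
#' @export
train_model <- function(model, x, y, split, tcfg = train_config(),
                        reinit = TRUE, verbose = FALSE) {
  stopifnot(inherits(model, "sers_model"), inherits(tcfg, "sers_train_config"))
  x <- as.matrix(x); y <- as.matrix(y)
  if (anyNA(y[c(split$train, split$val), ]))
    stop("training requires both concentration labels for all train/val records")
  if (length(split$train) == 0 || length(split$val) == 0)
    stop("train and val sets must be non-empty")

  old <- local_seed(tcfg$seed)
  on.exit(restore_seed(old))
  if (reinit) reinit_model(model)

  ys <- scale_labels(y, tcfg)
  xt <- x[split$train, , drop = FALSE]; yt <- ys[split$train, , drop = FALSE]
  xv <- x[split$val, , drop = FALSE];  yv <- ys[split$val, , drop = FALSE]

  layers <- all_model_layers(model)
  has_bc <- any(vapply(layers, function(l) l$kind == "batch_correlation", logical(1)))
  warmup <- if (has_bc && tcfg$bc_warmup > 0 && tcfg$bc_warmup < 1)
    floor(tcfg$epochs * tcfg$bc_warmup) else 0
  opt <- nadam_state(layers)
  lr <- tcfg$lr
  best_val <- Inf; best_snap <- NULL; best_epoch <- 0
  wait_lr <- 0; wait_stop <- 0
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), lr = numeric(0))

  n <- nrow(xt)
  for (epoch in seq_len(tcfg$epochs)) {
    bc_mode <- if (epoch <= warmup) "identity" else "batch"
    if (has_bc && warmup > 0 && epoch == warmup + 1) {
      # joint phase: fresh optimizer state and learning rate; validation
      # tracking restarts because the objective regime changed
      opt <- nadam_state(layers)
      lr <- tcfg$lr
      best_val <- Inf; wait_lr <- 0; wait_stop <- 0
    }
    idx <- sample.int(n)
    tot <- 0
    for (b in split(idx, ceiling(seq_along(idx) / tcfg$batch_size))) {
      xb <- xt[b, , drop = FALSE]; yb <- yt[b, , drop = FALSE]
      pred <- model_forward(model, xb, training = TRUE, bc_mode = bc_mode)
      err <- pred - yb
      if (any(!is.finite(err))) stop("training diverged: non-finite loss")
      tot <- tot + sum(abs(err))
      dpred <- sign(err) / length(err)
      model_backward(model, dpred)
      opt <- nadam_step(opt, lr)
    }
    train_loss <- tot / (n * 2)
    val_loss <- batched_loss(model, xv, yv, tcfg$batch_size, bc_mode = bc_mode)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = train_loss,
                                   val_loss = val_loss, lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f  lr %g", epoch, train_loss, val_loss, lr))
    if (val_loss < best_val - 1e-9) {
      best_val <- val_loss; best_epoch <- epoch
      best_snap <- snapshot_params(layers)
      wait_lr <- 0; wait_stop <- 0
    } else {
      wait_lr <- wait_lr + 1; wait_stop <- wait_stop + 1
      if (wait_lr >= tcfg$lr_patience) {
        lr <- lr * tcfg$lr_factor
        wait_lr <- 0
      }
      if (wait_stop >= tcfg$early_stop_patience) break
    }
  }
  if (!is.null(best_snap)) restore_params(layers, best_snap)
  model$trained <- TRUE
  model$history <- hist
  model$best_epoch <- best_epoch
  model$h2o2_scale <- tcfg$h2o2_scale
  invisible(model)
}

reinit_model <- function(model) {
  for (l in flatten_layers(all_model_layers(model))) {
    if (l$kind %in% c("conv2d", "conv1d")) {
      l$W <- matrix(he_init(length(l$W), nrow(l$W)), nrow(l$W), ncol(l$W))
      l$b <- numeric(length(l$b))
    } else if (l$kind == "dense") {
      l$W <- matrix(he_init(length(l$W), nrow(l$W)), nrow(l$W), ncol(l$W))
      l$b <- numeric(length(l$b))
    }
  }
  invisible(model)
}

#' Predict concentrations for preprocessed spectra
#'
#' @param object A trained `sers_model`.
#' @param x N x M matrix of preprocessed spectra (same preprocessing as
#'   training), or a list of `sers_labeled_spectrum`.
#' @param mode `"per_sample"` (default): batch correlation degenerates to
#'   the identity, so each spectrum's prediction is independent of whatever
#'   else is in the batch -- the right behavior for isolated tissue points.
#'   `"cohort"`: batch correlation is applied across batches of `batch_size`
#'   rows, the regime the network sees during training and the one used to
#'   evaluate held-out calibration data.
#' @param batch_size Rows per forward batch.
#' @param ... Unused.
#' @return N x 2 matrix with columns `c_gsh` (mM) and `c_h2o2` (uM).
#' @export
predict.sers_model <- function(object, x, mode = c("per_sample", "cohort"),
                               batch_size = 32, ...) {
  mode <- match.arg(mode)
  if (!object$trained) stop("model is untrained; call train_model() first")
  if (is.list(x) && !is.matrix(x)) x <- spectra_to_matrix(x)$x
  x <- as.matrix(x)
  n <- nrow(x)
  out <- matrix(0, n, 2)
  bc <- if (mode == "per_sample") "identity" else "batch"
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    out[b, ] <- model_forward(object, x[b, , drop = FALSE],
                              training = FALSE, bc_mode = bc)
  }
  unscale_preds(out, object$h2o2_scale %||% 10)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a model checkpoint as JSON
#'
#' The checkpoint stores the model configuration, training state and every
#' parameter tensor as plain JSON, so a trained model round-trips through
#' text. `load_model()` refuses nothing by itself, but `predict()` on the
#' restored model still enforces the input length recorded in its
#' configuration, so mismatched preprocessing fails loudly.
#'
#' @param model A `sers_model`.
#' @param path Checkpoint path (`.json`).
#' @return `path` (save) or the restored `sers_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sers_model"))
  flat <- flatten_layers(all_model_layers(model))
  params <- lapply(flat, function(l)
    stats::setNames(lapply(l$param_names, function(p)
      list(dim = dim(l[[p]]) %||% length(l[[p]]), data = as.vector(l[[p]]))),
      l$param_names))
  jsonlite::write_json(list(cfg = unclass(model$cfg), trained = model$trained,
                            h2o2_scale = model$h2o2_scale %||% 10,
                            params = params),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  j <- jsonlite::read_json(path)  # no simplification: parameter lists stay lists
  cfg_args <- lapply(j$cfg, function(v) if (is.list(v)) unlist(v) else v)
  cfg <- do.call(model_config, cfg_args)
  model <- build_model(cfg)
  flat <- flatten_layers(all_model_layers(model))
  if (length(flat) != length(j$params)) stop("checkpoint does not match architecture")
  for (i in seq_along(flat)) {
    for (p in flat[[i]]$param_names) {
      v <- j$params[[i]][[p]]
      val <- as.numeric(unlist(v$data))
      dims <- as.integer(unlist(v$dim))
      if (length(val) != prod(dims)) stop("checkpoint does not match architecture")
      if (length(dims) > 1) dim(val) <- dims
      assign(p, val, envir = flat[[i]])
    }
  }
  model$trained <- isTRUE(j$trained[[1]])
  model$h2o2_scale <- as.numeric(j$h2o2_scale[[1]])
  model
}
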