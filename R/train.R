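#' Default inverse-power weight exponent per architecture
#'
#' The exponents that produced the fastest-growing validation learning curves
#' in the study's tuning runs: 0.1 (U-Net), 0.005 (FC-DenseNet) and 0.2
#' (DeepLabv3+).
#'
#' @param architecture architecture name.
#' @return scalar exponent.
#' @export
default_weight_exponent <- function(architecture) {
  switch(architecture, unet = 0.1, fc_densenet = 0.005,
         deeplabv3plus = 0.2,
         stop("unknown architecture: ", architecture, call. = FALSE))
}

#' Batch size scaled inversely with tile area
#'
#' @param tile_size tile side length in pixels.
#' @param batch_at_1024 reference batch size at 1024 px tiles (the study used
#'   4 for U-Net and DeepLabv3+, 1 for FC-DenseNet).
#' @return integer batch size `batch_at_1024 * (1024 / tile_size)^2`.
#' @export
auto_batch_size <- function(tile_size, batch_at_1024 = 4L)
  max(1L, as.integer(round(batch_at_1024 * (1024 / tile_size)^2)))

#' Training configuration
#'
#' Defaults are the study's settings: Adam with initial learning rate 1e-4,
#' beta1 = 0.9, beta2 = 0.999, at most 300 epochs, early stopping after 40
#' consecutive epochs without improvement of validation mIoU, and batch size
#' scaled inversely with tile area.
#'
#' @param tile_size training tile side length.
#' @param batch_size tiles per optimiser step; `NULL` auto-sets it via
#'   [auto_batch_size()].
#' @param max_epochs epoch cap.
#' @param patience epochs without validation improvement before stopping.
#' @param learning_rate Adam initial learning rate.
#' @param adam_beta1,adam_beta2 Adam moment decay rates.
#' @param weight_exponent inverse-power weighting exponent; `NULL` uses the
#'   architecture default at train time.
#' @param augment an [augment_params()] object for on-the-fly augmentation, or
#'   `NULL` for none.
#' @param seed seed governing tile order and augmentation draws.
#' @return a `train_config` list.
#' @export
train_config <- function(tile_size = 512L, batch_size = NULL,
                         max_epochs = 300L, patience = 40L,
                         learning_rate = 1e-4, adam_beta1 = 0.9,
                         adam_beta2 = 0.999, weight_exponent = NULL,
                         augment = NULL, seed = 1L) {
  if (max_epochs < 1) stop("'max_epochs' must be >= 1", call. = FALSE)
  if (patience < 1) stop("'patience' must be >= 1", call. = FALSE)
  structure(list(tile_size = as.integer(tile_size),
                 batch_size = if (is.null(batch_size)) NULL
                              else as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, weight_exponent = weight_exponent,
                 augment = augment, seed = as.integer(seed)),
            class = "train_config")
}

one_hot <- function(mask, class_ids) {
  idx <- match(as.vector(mask), class_ids)
  if (anyNA(idx)) stop("mask contains ids outside the class table",
                       call. = FALSE)
  K <- length(class_ids)
  oh <- matrix(0, length(idx), K)
  oh[cbind(seq_along(idx), idx)] <- 1
  array(oh, c(nrow(mask), ncol(mask), K))
}

# loss and gradient w.r.t. logits for one tile
tile_loss_grad <- function(model, image, mask, class_ids, w) {
  fw <- net_forward(model$nodes, model$params, image / 255, keep_cache = TRUE)
  z <- fw$out
  d <- dim(z)
  npx <- d[1] * d[2]
  p <- softmax_rows(matrix(z, npx, d[3]))
  idx <- match(as.vector(mask), class_ids)
  pc <- p[cbind(seq_len(npx), idx)]
  wc <- w[idx]
  loss <- mean(wc * -log(pmax(pc, 1e-7)))
  dlog <- p * (wc / npx)
  sel <- cbind(seq_len(npx), idx)
  dlog[sel] <- dlog[sel] - wc / npx
  grads <- net_backward(model$nodes, model$params, fw, array(dlog, d))
  list(loss = loss, grads = grads)
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (i in seq_along(b))
    if (!is.null(b[[i]])) {
      a[[i]]$W <- a[[i]]$W + b[[i]]$W
      a[[i]]$b <- a[[i]]$b + b[[i]]$b
    }
  a
}

scale_grads <- function(g, f) {
  for (i in seq_along(g))
    if (!is.null(g[[i]])) {
      g[[i]]$W <- g[[i]]$W * f
      g[[i]]$b <- g[[i]]$b * f
    }
  g
}

#' Train a segmentation model
#'
#' Minimises the weighted categorical cross-entropy with Adam, tracking mean
#' intersection over union on whole validation scenes after every epoch.
#' Training stops at `max_epochs` or once `patience` consecutive epochs have
#' passed without a new best validation mIoU. Validation inference uses the
#' base tile grid only (a single zero-offset layer); the full 16-layer
#' majority vote is reserved for test-time prediction.
#'
#' Model parameters are snapshotted at the end of every epoch, so any epoch
#' can be restored with [model_at_epoch()].
#'
#' @param model a `segmentation_model` from [build_model()].
#' @param train_tiles non-empty list of tiles (from [tile_scene()]).
#' @param val_scenes non-empty list of `labeled_scene`s.
#' @param weights a [compute_class_weights()] table aligned with the class
#'   table order.
#' @param config a [train_config()].
#' @param class_ids class id of each model output channel; defaults to the
#'   class-table order of the first validation scene.
#' @param verbose print a line per epoch.
#' @return a `training_log`: `history` data frame (`epoch`, `train_loss`,
#'   `val_miou`), per-epoch `checkpoints`, the final `model`, `best_epoch`
#'   (raw argmax; see [select_best_epoch()] for the smoothed choice).
#' @export
train <- function(model, train_tiles, val_scenes, weights, config,
                  class_ids = NULL, verbose = FALSE) {
  if (length(train_tiles) < 1L) stop("empty training set", call. = FALSE)
  if (length(val_scenes) < 1L) stop("empty validation set", call. = FALSE)
  class_ids <- class_ids %||% val_scenes[[1]]$class_table$class_id
  if (length(class_ids) != model$config$n_classes)
    stop("model n_classes does not match the class table", call. = FALSE)
  w <- if (inherits(weights, "class_weight_table")) weights$w
       else as.numeric(weights)
  batch <- config$batch_size %||% auto_batch_size(config$tile_size)
  state <- adam_init(model$params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_miou = numeric(0))
  checkpoints <- list()
  best <- -Inf
  wait <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(config$seed * 1000L + epoch,
                     sample(length(train_tiles)))
    losses <- numeric(0)
    acc <- NULL
    in_batch <- 0L
    for (j in seq_along(ord)) {
      tl <- train_tiles[[ord[j]]]
      img <- tl$image; msk <- tl$mask
      if (!is.null(config$augment)) {
        au <- augment_pair(img, msk, config$augment,
                           config$seed * 100000L + epoch * 1000L + j)
        img <- au$image; msk <- au$mask
      }
      lg <- tile_loss_grad(model, img, msk, class_ids, w)
      losses <- c(losses, lg$loss)
      acc <- add_grads(acc, lg$grads)
      in_batch <- in_batch + 1L
      if (in_batch == batch || j == length(ord)) {
        st <- adam_step(model$params, scale_grads(acc, 1 / in_batch), state,
                        config$learning_rate, config$adam_beta1,
                        config$adam_beta2)
        model$params <- st$params
        state <- st$state
        acc <- NULL
        in_batch <- 0L
      }
    }
    vm <- mean(vapply(val_scenes, function(sc) {
      pred <- predict_scene(model, sc, config$tile_size, fractions = 0)
      miou(match(sc$mask, class_ids) - 1L, match(pred, class_ids) - 1L,
           length(class_ids))
    }, numeric(1)))
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_miou = vm))
    checkpoints[[epoch]] <- model$params
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val mIoU %.4f", epoch,
                      mean(losses), vm))
    if (vm > best) {
      best <- vm
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  structure(list(history = history, checkpoints = checkpoints, model = model,
                 class_ids = class_ids, config = config,
                 best_epoch = history$epoch[which.max(history$val_miou)]),
            class = "training_log")
}

#' Restore the model as it was after a given epoch
#' @param log a `training_log` from [train()].
#' @param epoch epoch index (1-based, as logged).
#' @return a `segmentation_model` carrying that epoch's parameters.
#' @export
model_at_epoch <- function(log, epoch) {
  if (epoch < 1L || epoch > length(log$checkpoints))
    stop("no checkpoint for epoch ", epoch, call. = FALSE)
  m <- log$model
  m$params <- log$checkpoints[[epoch]]
  m
}

#' Select the best epoch from a smoothed learning curve
#'
#' Fits a degree-2 local polynomial regression (LOESS) to validation mIoU
#' versus epoch to damp small-scale fluctuations, and returns the logged epoch
#' at which the smoothed curve is maximal. Ties break toward the earliest
#' epoch.
#'
#' @param log a `training_log`, or a data frame with columns `epoch` and
#'   `val_miou`.
#' @param smoothing_span LOESS span as a fraction of the points.
#' @return the selected epoch index.
#' @export
select_best_epoch <- function(log, smoothing_span = 0.3) {
  h <- if (inherits(log, "training_log")) log$history else log
  if (nrow(h) < 3L) stop("need at least 3 logged epochs", call. = FALSE)
  fit <- tryCatch(
    suppressWarnings(loess(val_miou ~ epoch, data = h, degree = 2,
                           span = smoothing_span)),
    error = function(e)
      stop(sprintf(
        "LOESS fit failed with span %.3f (%s); try a larger smoothing_span",
        smoothing_span, conditionMessage(e)), call. = FALSE))
  sm <- predict(fit, newdata = h)
  if (anyNA(sm))
    stop("LOESS produced missing fits; try a larger smoothing_span",
         call. = FALSE)
  h$epoch[which(sm >= max(sm) - 1e-12)[1]]
}

#' Export a training history as CSV
#' @param log a `training_log`.
#' @param path output file.
#' @export
write_training_log <- function(log, path) {
  write.csv(log$history, path, row.names = FALSE)
  invisible(path)
}
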