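# Training engine: seeded SGD with momentum, polynomial learning-rate
# decay, best-validation-mIoU checkpointing, evaluation, and the
# lambda-sweep harness.

#' Training configuration
#'
#' Defaults follow the standard recipe for this family of networks:
#' SGD with momentum 0.9, base learning rate 1e-2, weight decay 1e-4 on
#' convolution weights, polynomial decay with power 0.9, 150 epochs at
#' batch size 8.
#'
#' @param epochs Number of passes over the training split (default 150).
#' @param batch_size Mini-batch size (default 8).
#' @param lr Base learning rate (default 0.01).
#' @param momentum SGD momentum (default 0.9).
#' @param weight_decay L2 penalty on convolution weights (default 1e-4).
#' @param poly_power Exponent of the polynomial schedule
#'   `lr * (1 - iter/total)^power` (default 0.9).
#' @param seed Integer seed covering initialisation, shuffling,
#'   augmentation and dropout.
#' @param augment Apply random flip/rotation to training samples
#'   (default TRUE; never applied to validation or test).
#' @param net A [network_config()].
#' @param loss A [loss_config()]; set `lambda` to 1 for pure Dice, 0 for
#'   pure Focal. `loss = "ce"` uses plain pixelwise cross-entropy (the
#'   ablation baseline, equivalent to `loss_config(0, alpha = 1, gamma =
#'   0)`).
#' @return List with class `train_config`.
#' @export
train_config <- function(epochs = 150L, batch_size = 8L, lr = 0.01,
                         momentum = 0.9, weight_decay = 1e-4,
                         poly_power = 0.9, seed = 1L, augment = TRUE,
                         net = network_config(), loss = loss_config()) {
  if (epochs < 1L || batch_size < 1L)
    stop_config("epochs and batch_size must be >= 1")
  if (identical(loss, "ce")) loss <- loss_config(0, alpha = 1, gamma = 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 momentum = momentum, weight_decay = weight_decay,
                 poly_power = poly_power, seed = as.integer(seed),
                 augment = isTRUE(augment), net = net, loss = loss),
            class = "train_config")
}

load_split <- function(index, split, side) {
  rows <- which(index$split == split)
  lapply(rows, function(i) load_pair(index$image[i], index$mask[i], side))
}

stack_batch <- function(samples) {
  S <- dim(samples[[1]]$image)[2]
  N <- length(samples)
  x <- array(0, c(3, S, S, N))
  g <- array(0L, c(S, S, N))
  for (i in seq_len(N)) {
    x[, , , i] <- samples[[i]]$image
    g[, , i] <- samples[[i]]$mask
  }
  list(x = x, gt = g)
}

predict_batch <- function(net, x) {
  logits <- vm_forward_logits(net, x, training = FALSE)
  d <- dim(logits)
  L <- matrix(logits, nrow = d[1])
  array(max.col(t(L), ties.method = "first") - 1L, d[2:4])
}

eval_counts <- function(net, samples, batch_size = 8L) {
  cc <- NULL
  per_image <- numeric(length(samples))
  i <- 1L
  while (i <= length(samples)) {
    j <- min(i + batch_size - 1L, length(samples))
    b <- stack_batch(samples[i:j])
    pred <- predict_batch(net, b$x)
    for (k in seq_len(j - i + 1L)) {
      ci <- confusion_counts(pred[, , k], b$gt[, , k],
                             K = net$cfg$num_classes)
      m <- compute_metrics(ci)
      per_image[i + k - 1L] <- m$fg_iou
      cc <- if (is.null(cc)) ci else add_counts(cc, ci)
    }
    i <- j + 1L
  }
  list(cc = cc, per_image = per_image)
}

#' Train the segmentation network
#'
#' Seeded end-to-end training minimising the mixed loss; the parameter set
#' with the best validation mIoU is retained. Aborts with diagnostics if
#' the loss becomes non-finite.
#'
#' @param cfg A [train_config()].
#' @param index A `dataset_index` with non-empty train and val splits.
#' @param verbose Print one line per epoch.
#' @return Object of class `seg_run`: `net` (best parameters), `history`
#'   (epoch, lr, train loss, val mIoU, val foreground IoU), `best_epoch`,
#'   `cfg`, `wall_time` seconds.
#' @export
train_model <- function(cfg, index, verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  side <- cfg$net$input_side
  if (!any(index$split == "train") || !any(index$split == "val"))
    stop_config("index needs non-empty train and val splits")
  train_set <- load_split(index, "train", side)
  val_set <- load_split(index, "val", side)
  run <- local_seed(cfg$seed, {
    net <- make_network(cfg$net, seed = cfg$seed)
    # exclusive copies: the compiled executor updates parameters and
    # optimizer state in place
    net$params <- lapply(net$params, function(a) a + 0)
    vel <- lapply(net$params, function(a) numeric(length(a)))
    wd_mask <- endsWith(names(net$params), ".w")
    n_train <- length(train_set)
    steps_per_epoch <- ceiling(n_train / cfg$batch_size)
    total_steps <- cfg$epochs * steps_per_epoch
    step <- 0L
    history <- data.frame()
    best <- list(miou = -Inf)
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n_train)
      epoch_loss <- 0
      for (bi in seq_len(steps_per_epoch)) {
        ids <- perm[((bi - 1L) * cfg$batch_size + 1L):
                      min(bi * cfg$batch_size, n_train)]
        samples <- train_set[ids]
        if (cfg$augment) samples <- lapply(samples, augment_sample)
        b <- stack_batch(samples)
        lr <- cfg$lr * (1 - step / total_steps)^cfg$poly_power
        vm <- vm_get(net, dim(b$x)[4], dim(b$x)[2])
        lg <- cpp_vm_train_step(
          vm$ptr, net$params, vm_buffers(net, vm), vel, b$x, b$gt,
          cfg$loss$lambda, cfg$loss$alpha, cfg$loss$gamma, cfg$loss$eps,
          identical(cfg$loss$dice_mode, "image"), lr, cfg$momentum,
          cfg$weight_decay, wd_mask)
        if (!is.finite(lg$loss))
          stop(sprintf(
            "training diverged: non-finite loss at epoch %d step %d (dice %.4g focal %.4g)",
            epoch, bi, lg$dice, lg$focal))
        epoch_loss <- epoch_loss + lg$loss
        step <- step + 1L
      }
      ev <- eval_counts(net, val_set, cfg$batch_size)
      m <- compute_metrics(ev$cc)
      history <- rbind(history, data.frame(
        epoch = epoch, lr = lr, train_loss = epoch_loss / steps_per_epoch,
        val_miou = m$miou, val_fg_iou = m$fg_iou))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val mIoU %.2f  fg IoU %.2f",
                        epoch, epoch_loss / steps_per_epoch, m$miou,
                        m$fg_iou))
      if (is.finite(m$miou) && m$miou > best$miou)
        best <- list(miou = m$miou, epoch = epoch,
                     params = lapply(net$params, function(a) a + 0),
                     buffers = buffers_to_list(net$buffers))
    }
    net$params <- best$params
    net$buffers <- params_to_env(best$buffers)
    # release the training executor's activation/gradient buffers;
    # evaluation compiles a lean forward-only program on demand
    rm(list = ls(net$cache), envir = net$cache)
    list(net = net, history = history, best_epoch = best$epoch)
  })
  structure(c(run, list(cfg = cfg,
                        wall_time = proc.time()[["elapsed"]] - t0)),
            class = "seg_run")
}

#' Evaluate a model on one split
#'
#' Accumulates confusion counts over the split and reports the pooled
#' metrics plus per-image foreground IoU for failure inspection. Optionally
#' writes a CSV row (percentages, 2 decimals).
#'
#' @param model A `capseg_net`, a `seg_run`, a checkpoint path, or (for
#'   harness self-tests) a function `function(sample) mask` used as the
#'   predictor.
#' @param index A `dataset_index`.
#' @param split One of `"val"`, `"test"`, `"train"`.
#' @param side Image side; defaults to the model's configured input side.
#' @param out_csv Optional CSV path.
#' @return List of class `seg_eval`: `report` ([compute_metrics()] output),
#'   `per_image` data frame, `split`, `n_images`.
#' @export
evaluate_model <- function(model, index, split = "val", side = NULL,
                           out_csv = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (inherits(model, "seg_run")) model <- model$net
  if (!split %in% index$split)
    stop_config("split '%s' is empty in this index", split)
  if (is.function(model)) {
    side <- side %||% 97L
    samples <- load_split(index, split, side)
    cc <- NULL
    per_image <- numeric(length(samples))
    for (i in seq_along(samples)) {
      pred <- model(samples[[i]])
      ci <- confusion_counts(pred, samples[[i]]$mask, K = 2L)
      per_image[i] <- compute_metrics(ci)$fg_iou
      cc <- if (is.null(cc)) ci else add_counts(cc, ci)
    }
    ev <- list(cc = cc, per_image = per_image)
  } else {
    side <- side %||% model$cfg$input_side
    samples <- load_split(index, split, side)
    ev <- eval_counts(model, samples)
  }
  report <- compute_metrics(ev$cc)
  stems <- index$stem[index$split == split]
  out <- structure(list(report = report,
                        per_image = data.frame(stem = stems,
                                               fg_iou = ev$per_image),
                        split = split, n_images = length(samples)),
                   class = "seg_eval")
  if (!is.null(out_csv)) {
    df <- cbind(data.frame(split = split, n_images = length(samples)),
                round(as.data.frame(report), 2))
    utils::write.csv(df, out_csv, row.names = FALSE)
  }
  out
}

#' Sweep the Dice/Focal trade-off factor
#'
#' Trains one model per lambda value with a shared seed and identical data
#' order, recording the best validation mIoU of each run. Duplicate lambdas
#' are dropped (first occurrence kept); the result is sorted by lambda.
#'
#' @param cfg A [train_config()]; its loss lambda is overridden per run.
#' @param lambdas Numeric vector of lambda values in `[0, 1]`.
#' @param index A `dataset_index`.
#' @param out_csv Optional CSV path for the (lambda, mIoU) table.
#' @return Data frame with columns `lambda`, `val_miou`, `val_fg_iou`,
#'   sorted by `lambda` ascending.
#' @export
lambda_sweep <- function(cfg, lambdas, index, out_csv = NULL) {
  if (any(lambdas < 0 | lambdas > 1))
    stop_config("lambda values must lie in [0, 1]")
  lambdas <- lambdas[!duplicated(lambdas)]
  rows <- lapply(lambdas, function(lam) {
    cfg$loss$lambda <- lam
    run <- train_model(cfg, index)
    h <- run$history
    data.frame(lambda = lam,
               val_miou = max(h$val_miou),
               val_fg_iou = h$val_fg_iou[which.max(h$val_miou)])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$lambda), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Predict a segmentation mask for one image file
#'
#' @param model A `capseg_net`, `seg_run` or checkpoint path.
#' @param image_path Input image.
#' @param out_path Optional output PNG ({0, 255}).
#' @param side Inference side; defaults to the model's input side.
#' @return The predicted mask (integer matrix), invisibly if written.
#' @export
predict_mask <- function(model, image_path, out_path = NULL, side = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (inherits(model, "seg_run")) model <- model$net
  side <- side %||% model$cfg$input_side
  img <- read_image_array(image_path)
  if (any(dim(img)[1:2] != side))
    img <- EBImage::resize(img, w = side, h = side, filter = "bilinear")
  x <- (aperm(img, c(3, 1, 2)) - 0.5) / 0.5
  pred <- predict_batch(model, array(x, c(dim(x), 1L)))[, , 1]
  if (!is.null(out_path)) {
    write_mask_png(pred, out_path)
    return(invisible(pred))
  }
  pred
}

#' Save / load a model or run checkpoint
#'
#' The checkpoint stores parameters, running statistics and the full
#' configuration, which together reproduce evaluation exactly.
#'
#' @param model A `capseg_net` or `seg_run`.
#' @param path Checkpoint file (RDS).
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "seg_run")) model <- model$net
  saveRDS(list(cfg = model$cfg, params = model$params,
               buffers = buffers_to_list(model$buffers)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns the restored `capseg_net`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_io("no checkpoint at '%s'", path)
  ck <- readRDS(path)
  net <- make_network(ck$cfg, seed = 1L)
  net$params <- ck$params
  net$buffers <- params_to_env(ck$buffers)
  net
}
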