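# Training: optimizers, the plateau/early-stop schedule controller,
# the model fitting loop, checkpointing and evaluation.

#' Training configuration
#'
#' Defaults follow the canonical protocol for this task family: Dice loss
#' for segmentation and focal loss for classification, early stopping and
#' plateau learning-rate reduction both with patience 25, epoch caps of
#' 2000 (segmentation) and 1000 (classification), best-validation-loss
#' checkpointing and full seeding.
#'
#' @param task "segmentation" or "classification".
#' @param optimizer one of "Adam", "AdamW", "RMSprop", "SGD", "Adagrad".
#' @param learning_rate,weight_decay optimizer settings.
#' @param batch_size minibatch size.
#' @param max_epochs epoch cap; defaults to 2000/1000 by task.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (default 25).
#' @param lr_plateau_patience epochs without improvement before the learning
#'   rate is multiplied by `lr_factor` (default 25).
#' @param lr_factor plateau reduction factor (default 0.1).
#' @param betas Adam/AdamW moment decay pair.
#' @param focal_alpha,focal_gamma focal-loss parameters (classification).
#' @param weighted_sampling draw training batches with class-balanced
#'   replacement sampling (default TRUE for classification).
#' @param augment apply the training augmentation policy (default TRUE).
#' @param resize_to model input side; passed to the augmentation policies.
#' @param seed run seed; all sub-streams derive from it.
#' @return a `train_config` list.
#' @export
train_config <- function(task = c("segmentation", "classification"),
                         optimizer = c("Adam", "AdamW", "RMSprop", "SGD", "Adagrad"),
                         learning_rate = 1e-3, weight_decay = 0,
                         batch_size = 8L, max_epochs = NULL,
                         early_stop_patience = 25L, lr_plateau_patience = 25L,
                         lr_factor = 0.1, betas = c(0.9, 0.999),
                         focal_alpha = 1, focal_gamma = 0,
                         weighted_sampling = NULL, augment = TRUE,
                         resize_to = 64L, seed = 1L) {
  task <- match.arg(task)
  optimizer <- match.arg(optimizer)
  if (learning_rate <= 0 || batch_size < 1) stop_invalid("rates and sizes must be positive")
  if (early_stop_patience < 1 || lr_plateau_patience < 1) stop_invalid("patience must be >= 1")
  if (is.null(max_epochs)) max_epochs <- if (task == "segmentation") 2000L else 1000L
  if (is.null(weighted_sampling)) weighted_sampling <- task == "classification"
  structure(list(task = task, optimizer = optimizer,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 lr_plateau_patience = as.integer(lr_plateau_patience),
                 lr_factor = lr_factor, betas = betas,
                 focal_alpha = focal_alpha, focal_gamma = focal_gamma,
                 weighted_sampling = weighted_sampling, augment = augment,
                 resize_to = as.integer(resize_to), seed = as.integer(seed)),
            class = "train_config")
}

## ---- optimizers -----------------------------------------------------------

make_optimizer <- function(config, params) {
  state <- new.env(parent = emptyenv())
  state$t <- 0L
  state$m <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  state$v <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  kind <- config$optimizer
  b1 <- config$betas[1]; b2 <- config$betas[2]
  wd <- config$weight_decay
  eps <- 1e-8
  function(params, grads, lr) {
    state$t <- state$t + 1L
    for (nm in names(params)) {
      gfull <- grads[[nm]]
      if (is.null(gfull)) next
      p <- params[[nm]]
      gv <- as.numeric(gfull)
      if (wd > 0 && kind != "AdamW") gv <- gv + wd * as.numeric(p)
      upd <- switch(kind,
        SGD = lr * gv,
        Adagrad = {
          state$v[[nm]] <- state$v[[nm]] + gv^2
          lr * gv / (sqrt(as.numeric(state$v[[nm]])) + eps)
        },
        RMSprop = {
          state$v[[nm]] <- 0.99 * state$v[[nm]] + 0.01 * gv^2
          lr * gv / (sqrt(as.numeric(state$v[[nm]])) + eps)
        },
        Adam = ,
        AdamW = {
          state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gv
          state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gv^2
          mh <- as.numeric(state$m[[nm]]) / (1 - b1^state$t)
          vh <- as.numeric(state$v[[nm]]) / (1 - b2^state$t)
          lr * mh / (sqrt(vh) + eps)
        })
      if (wd > 0 && kind == "AdamW") upd <- upd + lr * wd * as.numeric(p)
      params[[nm]] <- p - array(upd, dim(p) %||% length(p))
    }
    params
  }
}

## ---- schedule controller --------------------------------------------------

#' Run the training schedule (early stopping + plateau learning rate)
#'
#' The controller around any per-epoch worker: after each epoch it reads the
#' validation loss, reduces the learning rate by `lr_factor` once
#' `lr_plateau_patience` consecutive epochs bring no improvement, stops after
#' `early_stop_patience` such epochs, and tracks the epoch with minimum
#' validation loss for checkpointing. Exposed separately so the control
#' contracts can be exercised with scripted loss sequences.
#'
#' @param epoch_fn `function(epoch, lr)` running one epoch and returning the
#'   validation loss (scalar) or a list with `val_loss` and optional extras
#'   retained in the log.
#' @param config a [train_config()] (only the schedule fields are used).
#' @param on_best optional `function(epoch)` called when a new best
#'   validation loss is seen (used to snapshot parameters).
#' @return list with `log` (data frame: epoch, lr, val_loss, improved),
#'   `best_epoch`, `best_val_loss`, `stopped_early`.
#' @export
run_training_schedule <- function(epoch_fn, config, on_best = NULL) {
  lr <- config$learning_rate
  best <- Inf; best_epoch <- 0L
  wait <- 0L; lr_wait <- 0L
  rows <- list()
  stopped <- FALSE
  for (epoch in seq_len(config$max_epochs)) {
    res <- epoch_fn(epoch, lr)
    vl <- if (is.list(res)) res$val_loss else res
    if (!is.finite(vl)) stop("non-finite validation loss at epoch ", epoch)
    improved <- vl < best
    if (improved) {
      best <- vl; best_epoch <- epoch
      wait <- 0L; lr_wait <- 0L
      if (!is.null(on_best)) on_best(epoch)
    } else {
      wait <- wait + 1L
      lr_wait <- lr_wait + 1L
      if (lr_wait >= config$lr_plateau_patience) {
        lr <- lr * config$lr_factor
        lr_wait <- 0L
      }
    }
    rows[[epoch]] <- data.frame(epoch = epoch, lr = lr, val_loss = vl,
                                improved = improved)
    if (wait >= config$early_stop_patience) { stopped <- TRUE; break }
  }
  list(log = do.call(rbind, rows), best_epoch = best_epoch,
       best_val_loss = best, stopped_early = stopped)
}

## ---- batch assembly -------------------------------------------------------

seg_batch <- function(samples, idx, policy, train) {
  xs <- lapply(idx, function(i) augment_segmentation(samples[[i]], policy, train))
  s <- policy$resize_to
  B <- length(idx)
  x <- array(0, c(B, 3L, s, s))
  y <- array(0, c(B, 1L, s, s))
  for (b in seq_len(B)) {
    x[b, , , ] <- xs[[b]]$x
    y[b, 1L, , ] <- xs[[b]]$mask
  }
  list(x = x, y = y)
}

cls_batch <- function(samples, idx, policy, train) {
  xs <- lapply(idx, function(i) augment_classification(samples[[i]], policy, train))
  s <- policy$resize_to
  B <- length(idx)
  x <- array(0, c(B, 3L, s, s))
  for (b in seq_len(B)) x[b, , , ] <- xs[[b]]$x
  list(x = x, labels = vapply(xs, function(z) as.integer(z$label), integer(1)) + 1L)
}

loss_and_grads <- function(net, batch, config, training = TRUE) {
  g <- ag_graph()
  pn <- lapply(net$params, function(v) ag_leaf(g, v))
  out <- net$forward(g, pn, ag_leaf(g, batch$x), training)
  loss <- if (config$task == "segmentation") {
    ag_dice_loss(g, out, batch$y)
  } else {
    ag_focal_loss(g, out, batch$labels, alpha = config$focal_alpha,
                  gamma = config$focal_gamma)
  }
  if (training) {
    ag_backward(g, loss)
    grads <- lapply(pn, function(nd) nd$grad)
  } else grads <- NULL
  list(loss = as.numeric(loss$value), grads = grads)
}

## ---- model fitting --------------------------------------------------------

#' Fit a segmentation or classification network
#'
#' Minibatch gradient training of a `seg_network` or `cls_network` under the
#' configured optimizer, loss (Dice for segmentation, focal for
#' classification), plateau learning-rate schedule and early stopping; the
#' parameter state with minimum validation loss is retained. Every source of
#' randomness (shuffling or weighted sampling, augmentation draws, dropout)
#' derives from `config$seed`, so identical seeds give identical runs.
#'
#' @param model a `seg_network` or `cls_network`.
#' @param data list with `train` and `val` sample lists (each sample:
#'   `image` + `mask` for segmentation, `image` + `label` for
#'   classification).
#' @param config a [train_config()].
#' @param verbose print a line per epoch.
#' @return an object of class `femseg_fit`: the trained model (best
#'   checkpoint), training log and checkpoint metadata.
#' @export
train_model <- function(model, data, config, verbose = FALSE) {
  is_seg <- config$task == "segmentation"
  if (is_seg && !inherits(model, "seg_network")) {
    stop_invalid("segmentation task requires a seg_network")
  }
  if (!is_seg && !inherits(model, "cls_network")) {
    stop_invalid("classification task requires a cls_network")
  }
  if (!length(data$train) || !length(data$val)) {
    stop_invalid("training requires non-empty train and val splits")
  }
  policy <- if (is_seg) {
    # padding minima never exceed the model input side, so small inputs are
    # not padded up only to be shrunk again by the resize
    seg_aug_policy(resize_to = config$resize_to,
                   pad_min_height = min(32L, config$resize_to),
                   pad_min_width = min(256L, config$resize_to))
  } else cls_aug_policy(resize_to = config$resize_to)
  params <- model$params
  opt <- make_optimizer(config, params)
  ntr <- length(data$train)
  labels <- if (!is_seg) vapply(data$train, function(s) as.integer(s$label), integer(1)) else NULL
  best_params <- params
  epoch_worker <- function(epoch, lr) {
    idx <- with_seed(sub_seed(config$seed, paste0("order-", epoch)), {
      if (config$weighted_sampling && !is_seg) {
        w <- make_class_weights(labels)
        sample(ntr, ntr, replace = TRUE, prob = w)
      } else sample(ntr)
    })
    tr_loss <- 0; nb <- 0L
    with_seed(sub_seed(config$seed, paste0("epoch-", epoch)), {
      for (start in seq(1L, ntr, by = config$batch_size)) {
        bidx <- idx[start:min(start + config$batch_size - 1L, ntr)]
        batch <- if (is_seg) seg_batch(data$train, bidx, policy, config$augment)
                 else cls_batch(data$train, bidx, policy, config$augment)
        lg <- loss_and_grads(list(params = params, forward = model$forward),
                             batch, config, training = TRUE)
        if (!is.finite(lg$loss)) stop("non-finite training loss at epoch ", epoch)
        params <<- opt(params, lg$grads, lr)
        tr_loss <- tr_loss + lg$loss; nb <- nb + 1L
      }
    })
    val_loss <- validation_loss(list(params = params, forward = model$forward),
                                data$val, config, policy)
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  train %.4f  val %.4f",
                      epoch, lr, tr_loss / max(nb, 1L), val_loss))
    }
    list(val_loss = val_loss, train_loss = tr_loss / max(nb, 1L))
  }
  sched <- run_training_schedule(epoch_worker, config,
                                 on_best = function(epoch) best_params <<- params)
  model$params <- best_params
  structure(list(model = model, config = config, log = sched$log,
                 checkpoint = list(epoch = sched$best_epoch,
                                   val_loss = sched$best_val_loss,
                                   config_hash = config_hash(config),
                                   seed = config$seed),
                 stopped_early = sched$stopped_early),
            class = "femseg_fit")
}

validation_loss <- function(net, val_samples, config, policy) {
  is_seg <- config$task == "segmentation"
  total <- 0; n <- 0L
  for (start in seq(1L, length(val_samples), by = config$batch_size)) {
    bidx <- start:min(start + config$batch_size - 1L, length(val_samples))
    batch <- if (is_seg) seg_batch(val_samples, bidx, policy, train = FALSE)
             else cls_batch(val_samples, bidx, policy, train = FALSE)
    lg <- loss_and_grads(net, batch, config, training = FALSE)
    total <- total + lg$loss * length(bidx)
    n <- n + length(bidx)
  }
  total / n
}

config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% .Machine$integer.max)
}

#' Evaluate a fitted model on a data split
#'
#' Segmentation: per-image Dice/IoU/pixel accuracy averaged over images plus
#' pooled pixel-level AUC. Classification: confusion matrix and per-class /
#' macro precision, recall and F1. Deterministic (evaluation mode).
#'
#' @param fit a [train_model()] result (or a raw network).
#' @param samples list of samples of the matching task.
#' @param task "segmentation" or "classification"; defaults to the fit's
#'   task.
#' @param resize_to evaluation input side; defaults to the fit's.
#' @return a `metrics_report` or `class_report`.
#' @export
evaluate_model <- function(fit, samples, task = NULL, resize_to = NULL) {
  if (!length(samples)) stop_invalid("empty evaluation split")
  net <- if (inherits(fit, "femseg_fit")) fit$model else fit
  cfg <- if (inherits(fit, "femseg_fit")) fit$config else NULL
  if (is.null(task)) task <- cfg$task %||% "segmentation"
  if (is.null(resize_to)) resize_to <- cfg$resize_to %||% 64L
  if (task == "segmentation") {
    policy <- seg_aug_policy(resize_to = resize_to)
    probs <- list(); masks <- list()
    for (i in seq_along(samples)) {
      b <- seg_batch(samples, i, policy, train = FALSE)
      p <- forward_network(net, b$x, probs = TRUE)
      probs[[i]] <- p[1, 1, , ]
      masks[[i]] <- b$y[1, 1, , ]
    }
    segmentation_metrics(probs, masks)
  } else {
    policy <- cls_aug_policy(resize_to = resize_to)
    pred <- integer(length(samples)); truth <- integer(length(samples))
    for (i in seq_along(samples)) {
      b <- cls_batch(samples, i, policy, train = FALSE)
      g <- ag_graph()
      pn <- lapply(net$params, function(v) ag_leaf(g, v))
      z <- net$forward(g, pn, ag_leaf(g, b$x), FALSE)$value
      pred[i] <- which.max(z[1, ]) - 1L
      truth[i] <- b$labels[1] - 1L
    }
    classification_report(truth, pred, n_classes = max(3L, max(truth, pred) + 1L),
                          class_names = c("benign", "normal", "malignant"))
  }
}

#' Save / load a training checkpoint
#'
#' The checkpoint keeps the best parameter state together with its metadata
#' (epoch, validation loss, config hash, seed).
#'
#' @param fit a `femseg_fit`.
#' @param path file path (`.rds`).
#' @return `save_checkpoint` invisibly returns `path`; `load_checkpoint`
#'   returns the `femseg_fit`.
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(fit, path)
  meta <- fit$checkpoint
  jsonlite::write_json(meta, sub("\\.rds$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

## ---- S3 methods for the fit object ---------------------------------------

#' @export
print.femseg_fit <- function(x, ...) {
  cat(sprintf("femseg fit: %s (%s)\n", x$config$task,
              if (!is.null(x$model$config$decoder_kind)) x$model$config$decoder_kind
              else x$model$config$backbone_name))
  cat(sprintf("  epochs run %d, best epoch %d (val loss %.4f)%s\n",
              nrow(x$log), x$checkpoint$epoch, x$checkpoint$val_loss,
              if (x$stopped_early) ", stopped early" else ""))
  invisible(x)
}

#' @export
summary.femseg_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  optimizer %s, lr %.2e, batch %d, seed %d\n",
              object$config$optimizer, object$config$learning_rate,
              object$config$batch_size, object$config$seed))
  cat(sprintf("  parameters: %d\n",
              sum(vapply(object$model$params, length, numeric(1)))))
  invisible(object)
}

#' @export
coef.femseg_fit <- function(object, ...) object$model$params

#' Predict from a fitted model
#'
#' Segmentation: probability maps (and thresholded masks). Classification:
#' class labels and probabilities.
#'
#' @param object a `femseg_fit`.
#' @param newdata list of samples (each with `image`).
#' @param type "prob" or "mask"/"class".
#' @param ... unused.
#' @return list of probability maps / masks, or a data frame of labels.
#' @export
predict.femseg_fit <- function(object, newdata, type = c("prob", "mask", "class"), ...) {
  type <- match.arg(type)
  cfg <- object$config
  if (cfg$task == "segmentation") {
    policy <- seg_aug_policy(resize_to = cfg$resize_to)
    out <- lapply(newdata, function(s) {
      b <- seg_batch(list(s), 1L, policy, train = FALSE)
      p <- forward_network(object$model, b$x, probs = TRUE)[1, 1, , ]
      if (type == "mask") (p >= 0.5) * 1 else p
    })
    out
  } else {
    policy <- cls_aug_policy(resize_to = cfg$resize_to)
    res <- lapply(newdata, function(s) {
      b <- cls_batch(list(utils::modifyList(s, list(label = s$label %||% 0L))), 1L, policy, FALSE)
      g <- ag_graph()
      pn <- lapply(object$model$params, function(v) ag_leaf(g, v))
      z <- object$model$forward(g, pn, ag_leaf(g, b$x), FALSE)$value[1, ]
      p <- exp(z - max(z)); p <- p / sum(p)
      p
    })
    probs <- do.call(rbind, res)
    data.frame(label = max.col(probs) - 1L, probs)
  }
}

#' Plot training curves of a fit
#'
#' @param x a `femseg_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.femseg_fit <- function(x, ...) {
  graphics::plot(x$log$epoch, x$log$val_loss, type = "l", xlab = "epoch",
                 ylab = "validation loss", ...)
  graphics::abline(v = x$checkpoint$epoch, lty = 2, col = "grey50")
  invisible(x)
}

#' Paired FEM ablation run
#'
#' Trains FADeepLabV3 and baseline DeepLabV3 under one seed on the same data
#' and reports both evaluations side by side.
#'
#' @param data list with `train`, `val` (and optionally `test`) segmentation
#'   samples.
#' @param config a [train_config()] for segmentation.
#' @param encoder_kind encoder for both models.
#' @param output_stride encoder output stride.
#' @return list with `fadeeplabv3` and `deeplabv3`, each holding `fit` and
#'   `metrics` (validation split).
#' @export
ablate_fem <- function(data, config, encoder_kind = "tiny", output_stride = 8L) {
  runs <- list()
  for (dk in c("fadeeplabv3", "deeplabv3")) {
    net <- build_segmenter(seg_config(dk, encoder_kind = encoder_kind,
                                      output_stride = output_stride,
                                      seed = config$seed))
    fit <- train_model(net, data, config)
    runs[[dk]] <- list(fit = fit,
                       metrics = evaluate_model(fit, data$val))
  }
  runs
}
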