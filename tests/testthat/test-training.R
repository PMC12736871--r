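# Gradient correctness of the engine on composite paths, end-to-end seeded
# determinism, evaluation contracts and the fit-object interface.

test_that("autograd gradients match finite differences through a FEM + conv path", {
  set.seed(15)
  ag <- femseg:::ag_graph
  leaf <- femseg:::ag_leaf
  x <- array(stats::rnorm(1 * 4 * 6 * 6), c(1, 4, 6, 6))
  p <- fem_params(4L, rho = 2L, seed = 8, zero_init_fusion = FALSE,
                  p_band = 0, p_residual = 0)
  mfull <- femseg:::masks_full(make_band_masks(6, 6))
  fem_cfg <- p[c("C", "rho", "groups", "p_band", "p_residual")]
  run <- function(xv, wv) {
    g <- ag()
    pn <- lapply(p$weights, function(v) leaf(g, v))
    names(pn) <- paste0("fem.", names(p$weights))
    pn[["fem.low.w"]] <- leaf(g, wv)
    out <- femseg:::ag_fem(g, leaf(g, xv), pn, "fem.", fem_cfg, mfull, FALSE)
    loss <- femseg:::ag_node(g, sum(out$value^2), list(out),
                             function(gr) list(2 * out$value * as.numeric(gr)))
    list(g = g, loss = loss, x = NULL, pn = pn)
  }
  g <- ag()
  pn <- lapply(p$weights, function(v) leaf(g, v))
  names(pn) <- paste0("fem.", names(p$weights))
  xn <- leaf(g, x)
  out <- femseg:::ag_fem(g, xn, pn, "fem.", fem_cfg, mfull, FALSE)
  loss <- femseg:::ag_node(g, sum(out$value^2), list(out),
                           function(gr) list(2 * out$value * as.numeric(gr)))
  femseg:::ag_backward(g, loss)
  fval <- function(xv, wv) {
    p2 <- p
    p2$weights[["low.w"]] <- wv
    y <- fem_forward(xv, p2, make_band_masks(6, 6))
    sum(y^2)
  }
  eps <- 1e-5
  for (i in c(1, 40, 100)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    fd <- (fval(xp, p$weights$low.w) - fval(xm, p$weights$low.w)) / (2 * eps)
    expect_lt(abs(fd - xn$grad[i]), 1e-4 * (1 + abs(fd)))
  }
  w0 <- p$weights$low.w
  for (i in c(1, 5)) {
    wp <- w0; wp[i] <- wp[i] + eps
    wm <- w0; wm[i] <- wm[i] - eps
    fd <- (fval(x, wp) - fval(x, wm)) / (2 * eps)
    expect_lt(abs(fd - pn[["fem.low.w"]]$grad[i]), 1e-4 * (1 + abs(fd)))
  }
})

tiny_seg_data <- function(seed = 1L, n = 8L, size = 32L) {
  classes <- rep(c("benign", "malignant"), length.out = n)
  samples <- lapply(seq_len(n), function(i) {
    generate_phantom(phantom_config(image_size = c(size, size), class = classes[i],
                                    lesion_area_range = c(0.08, 0.2),
                                    seed = femseg::sub_seed(seed, paste0("t", i))))
  })
  ntr <- max(2L, floor(0.75 * n))
  list(train = samples[seq_len(ntr)], val = samples[(ntr + 1L):n])
}

test_that("two training runs with one seed are identical end to end", {
  data <- tiny_seg_data(3L)
  cfg <- train_config("segmentation", optimizer = "Adam", learning_rate = 3e-3,
                      batch_size = 4L, max_epochs = 3L, resize_to = 32L, seed = 5L)
  run <- function() {
    net <- build_segmenter(seg_config("fadeeplabv3", encoder_kind = "tiny",
                                      output_stride = 8L, seed = 5L))
    train_model(net, data, cfg)
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$log, f2$log)
  expect_identical(f1$model$params, f2$model$params)
  expect_equal(f1$checkpoint$val_loss, min(f1$log$val_loss))
  expect_equal(f1$log$val_loss[f1$checkpoint$epoch], f1$checkpoint$val_loss)
})

test_that("every optimizer takes a finite step that changes the parameters", {
  data <- tiny_seg_data(7L, n = 4L)
  for (opt in c("SGD", "Adagrad", "RMSprop", "AdamW")) {
    cfg <- train_config("segmentation", optimizer = opt, learning_rate = 1e-3,
                        weight_decay = 1e-4, batch_size = 4L, max_epochs = 1L,
                        resize_to = 32L, seed = 2L)
    net <- build_segmenter(seg_config("deeplabv3", encoder_kind = "tiny",
                                      output_stride = 8L, seed = 2L))
    fit <- train_model(net, data, cfg)
    expect_true(all(is.finite(fit$log$val_loss)), info = opt)
    expect_false(identical(fit$model$params, net$params), info = opt)
  }
})

test_that("evaluation returns perfect scores for an oracle model and 0.5 AUC for ties", {
  data <- tiny_seg_data(9L, n = 4L)
  oracle <- structure(list(params = list(),
                           forward = NULL), class = "seg_network")
  # oracle: logits = +-10 exactly at the ground truth of each image
  policy <- seg_aug_policy(resize_to = 32L, pad_min_height = 32L, pad_min_width = 32L)
  masks <- lapply(data$val, function(s) augment_segmentation(s, policy, train = FALSE)$mask)
  i <- 0L
  oracle$forward <- function(g, pn, x, training = FALSE) {
    i <<- i + 1L
    m <- masks[[i]]
    femseg:::ag_leaf(g, array((m * 2 - 1) * 10, c(1, 1, dim(m))))
  }
  rep1 <- evaluate_model(oracle, data$val, task = "segmentation", resize_to = 32L)
  expect_equal(rep1$dice, 1)
  expect_equal(rep1$iou, 1)
  expect_equal(rep1$pixel_accuracy, 1)
  expect_equal(rep1$auc, 1)

  flat <- structure(list(params = list(),
                         forward = function(g, pn, x, training = FALSE) {
                           d <- dim(x$value)
                           femseg:::ag_leaf(g, array(0, c(d[1], 1L, d[3], d[4])))
                         }), class = "seg_network")
  rep2 <- evaluate_model(flat, data$val, task = "segmentation", resize_to = 32L)
  expect_equal(rep2$auc, 0.5)
  expect_error(evaluate_model(flat, list(), task = "segmentation"), "empty")
})

test_that("evaluation of a toy split equals image-by-image hand computation", {
  set.seed(12)
  masks <- lapply(1:3, function(i) {
    m <- matrix(0, 16, 16); m[(2 * i):(5 * i), 3:9] <- 1; m
  })
  probs <- lapply(masks, function(m) pmin(pmax(m * 0.7 + 0.15 +
    matrix(stats::rnorm(256, 0, 0.05), 16, 16), 0), 1))
  rep3 <- segmentation_metrics(probs, masks)
  expect_equal(rep3$dice,
               mean(mapply(function(p, m) dice_coefficient((p >= 0.5) * 1, m), probs, masks)))
  expect_equal(rep3$iou, mean(mapply(iou_score, probs, masks)))
  expect_equal(rep3$pixel_accuracy, mean(mapply(pixel_accuracy, probs, masks)))
  expect_equal(rep3$auc, auc_score(unlist(probs), unlist(masks)))
})

test_that("classification training runs, evaluates and predicts", {
  set.seed(6)
  samples <- lapply(1:12, function(i) {
    cls <- c("benign", "normal", "malignant")[(i - 1) %% 3 + 1]
    generate_phantom(phantom_config(image_size = c(32L, 32L), class = cls,
                                    seed = femseg::sub_seed(4L, paste0("c", i))))
  })
  data <- list(train = samples[1:9], val = samples[10:12])
  net <- attach_classifier_head(cls_config("tiny", seed = 3L))
  cfg <- train_config("classification", optimizer = "Adam", learning_rate = 1e-3,
                      batch_size = 4L, max_epochs = 2L, focal_alpha = 0.5,
                      focal_gamma = 2, resize_to = 32L, seed = 3L)
  fit <- train_model(net, data, cfg)
  expect_s3_class(fit, "femseg_fit")
  rep4 <- suppressWarnings(evaluate_model(fit, data$val))
  expect_s3_class(rep4, "class_report")
  expect_equal(sum(rep4$confusion), 3)
  pred <- predict(fit, data$val)
  expect_equal(nrow(pred), 3L)
  expect_true(all(pred$label %in% 0:2))
})

test_that("the fit object supports print, summary, coef, plot and checkpoints", {
  data <- tiny_seg_data(11L, n = 4L)
  cfg <- train_config("segmentation", optimizer = "Adam", learning_rate = 3e-3,
                      batch_size = 4L, max_epochs = 2L, resize_to = 32L, seed = 8L)
  net <- build_segmenter(seg_config("deeplabv3", encoder_kind = "tiny",
                                    output_stride = 8L, seed = 8L))
  fit <- train_model(net, data, cfg)
  expect_output(print(fit), "femseg fit: segmentation")
  expect_output(summary(fit), "parameters")
  expect_type(coef(fit), "list")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
  masks <- predict(fit, data$val, type = "mask")
  expect_true(all(masks[[1]] %in% c(0, 1)))

  ckpt <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, ckpt)
  fit2 <- load_checkpoint(ckpt)
  expect_identical(fit2$model$params, fit$model$params)
  expect_true(file.exists(sub("\\.rds$", ".json", ckpt)))
})

test_that("the FEM ablation harness produces a paired report under one seed", {
  data <- tiny_seg_data(13L, n = 6L)
  cfg <- train_config("segmentation", optimizer = "Adam", learning_rate = 3e-3,
                      batch_size = 4L, max_epochs = 2L, resize_to = 32L, seed = 21L)
  runs <- ablate_fem(data, cfg)
  expect_named(runs, c("fadeeplabv3", "deeplabv3"))
  for (r in runs) {
    expect_s3_class(r$fit, "femseg_fit")
    expect_s3_class(r$metrics, "metrics_report")
  }
})
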