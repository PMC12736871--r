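# Seeded random hyperparameter search with within-trial pruning.

#' Hyperparameter search space
#'
#' Default spaces follow the tuning protocol for this task family.
#' Segmentation: learning rate and weight decay log-uniform in
#' `[1e-5, 1e-3]`, batch size in \{4, 8, 16\}, optimizer in \{Adam, AdamW,
#' RMSprop, SGD, Adagrad\}, image size in \{256, 288, 320\}, epoch budget in
#' `[10, 100]`. Classification: learning rate and weight decay log-uniform
#' in `[1e-5, 1e-1]`, batch size in \{8, 16, 32\}, focal `alpha` in
#' `[0.3, 0.75]`, focal `gamma` in `[3, 5]`, optimizer in \{SGD, Adam,
#' RMSprop, AdamW\}. 50 trials; a trial is pruned after 10 epochs without
#' validation improvement.
#'
#' @param task "segmentation" or "classification".
#' @param n_trials trial budget (default 50).
#' @param prune_patience epochs without improvement before pruning
#'   (default 10).
#' @return an `hpo_space` list of samplers and bounds.
#' @export
hpo_space <- function(task = c("segmentation", "classification"),
                      n_trials = 50L, prune_patience = 10L) {
  task <- match.arg(task)
  if (n_trials < 1L) stop_invalid("trial budget must be >= 1")
  sp <- if (task == "segmentation") {
    list(lr = c(1e-5, 1e-3), weight_decay = c(1e-5, 1e-3),
         batch_size = c(4L, 8L, 16L),
         optimizer = c("Adam", "AdamW", "RMSprop", "SGD", "Adagrad"),
         image_size = c(256L, 288L, 320L), epochs = c(10L, 100L),
         encoder = c("resnet18", "tiny"))
  } else {
    list(lr = c(1e-5, 1e-1), weight_decay = c(1e-5, 1e-1),
         batch_size = c(8L, 16L, 32L),
         optimizer = c("SGD", "Adam", "RMSprop", "AdamW"),
         focal_alpha = c(0.3, 0.75), focal_gamma = c(3, 5))
  }
  structure(c(sp, list(task = task, n_trials = as.integer(n_trials),
                       prune_patience = as.integer(prune_patience))),
            class = "hpo_space")
}

sample_trial <- function(space) {
  logu <- function(b) exp(stats::runif(1, log(b[1]), log(b[2])))
  cfg <- list(lr = logu(space$lr), weight_decay = logu(space$weight_decay),
              batch_size = sample(space$batch_size, 1L),
              optimizer = sample(space$optimizer, 1L))
  if (space$task == "segmentation") {
    cfg$image_size <- sample(space$image_size, 1L)
    cfg$epochs <- sample(seq(space$epochs[1], space$epochs[2]), 1L)
    cfg$encoder <- sample(space$encoder, 1L)
  } else {
    cfg$focal_alpha <- stats::runif(1, space$focal_alpha[1], space$focal_alpha[2])
    cfg$focal_gamma <- stats::runif(1, space$focal_gamma[1], space$focal_gamma[2])
  }
  cfg
}

#' Random hyperparameter search with trial pruning
#'
#' Samples `n_trials` configurations from the space (log-uniform on rates),
#' evaluates each with the supplied objective and minimizes the best
#' validation loss. The objective returns the per-epoch validation-loss
#' trajectory of the trial; a trial is pruned as soon as `prune_patience`
#' consecutive epochs bring no improvement, mirroring per-epoch pruning of
#' dubious trials.
#'
#' @param space an [hpo_space()].
#' @param objective `function(trial_config)` returning a numeric vector of
#'   per-epoch validation losses (or a single final loss). For model-based
#'   searches wrap [train_model()]; the default used by [hpo_train_objective()]
#'   does exactly that.
#' @param seed integer seed for the sampler.
#' @return list with `best` (trial config + `value`), `trials` (data frame:
#'   trial id, sampled fields, best value, epochs run, status).
#' @export
hpo_search <- function(space, objective, seed = 1L) {
  trials <- list()
  best <- NULL
  with_seed(sub_seed(seed, "hpo"), {
    for (tr in seq_len(space$n_trials)) {
      cfg <- sample_trial(space)
      losses <- objective(cfg)
      bestv <- Inf; wait <- 0L; ran <- 0L; status <- "completed"
      for (e in seq_along(losses)) {
        ran <- e
        if (losses[e] < bestv) { bestv <- losses[e]; wait <- 0L }
        else {
          wait <- wait + 1L
          if (wait >= space$prune_patience) { status <- "pruned"; break }
        }
      }
      row <- c(list(trial = tr), cfg,
               list(value = bestv, epochs_run = ran, status = status))
      trials[[tr]] <- as.data.frame(row, stringsAsFactors = FALSE)
      if (status == "completed" && (is.null(best) || bestv < best$value)) {
        best <- c(cfg, list(value = bestv, trial = tr))
      }
    }
  })
  tab <- do.call(rbind, trials)
  if (is.null(best)) {
    completed <- tab[tab$status == "completed", ]
    if (!nrow(completed)) {
      warning("all trials pruned; returning the best pruned trial", call. = FALSE)
      i <- which.min(tab$value)
      best <- list(value = tab$value[i], trial = tab$trial[i])
    }
  }
  list(best = best, trials = tab)
}

#' Build a training objective for the hyperparameter search
#'
#' Wraps [train_model()] so each trial trains the configured model on the
#' given data and reports its per-epoch validation losses.
#'
#' @param data list with `train` and `val` sample lists.
#' @param task "segmentation" or "classification".
#' @param base_config a [train_config()] supplying the non-searched fields.
#' @param builder `function(trial_config)` returning a fresh network; by
#'   default a tiny-encoder FADeepLabV3 (segmentation) or tiny-backbone
#'   classifier.
#' @return an objective function for [hpo_search()].
#' @export
hpo_train_objective <- function(data, task, base_config = NULL, builder = NULL) {
  if (is.null(base_config)) base_config <- train_config(task = task, max_epochs = 10L)
  if (is.null(builder)) {
    builder <- if (task == "segmentation") {
      function(cfg) build_segmenter(seg_config("fadeeplabv3", encoder_kind = "tiny",
                                               output_stride = 8L,
                                               seed = base_config$seed))
    } else {
      function(cfg) attach_classifier_head(cls_config("tiny", seed = base_config$seed))
    }
  }
  function(cfg) {
    tc <- base_config
    tc$learning_rate <- cfg$lr
    tc$weight_decay <- cfg$weight_decay
    tc$batch_size <- cfg$batch_size
    tc$optimizer <- cfg$optimizer
    if (!is.null(cfg$focal_alpha)) tc$focal_alpha <- cfg$focal_alpha
    if (!is.null(cfg$focal_gamma)) tc$focal_gamma <- cfg$focal_gamma
    fit <- train_model(builder(cfg), data, tc)
    fit$log$val_loss
  }
}
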