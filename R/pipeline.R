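# Data pipeline: stratified splitting, augmentation policies and
# imbalance-aware weighted sampling.

#' Stratified train/validation/test split
#'
#' Per class of size `n`: `n_val = floor(r_val * n)`,
#' `n_test = floor(r_test * n)`, remainder to training, so class proportions
#' are preserved in every split; assignment of individuals is a seeded
#' permutation. With the default 80:10:10 ratios and class counts
#' 436/210/132 this reproduces per-class (train, val, test) of
#' (350, 43, 43), (168, 21, 21) and (106, 13, 13).
#'
#' @param labels vector of class labels (one per sample), or a named vector
#'   of class counts (then only the count table is returned).
#' @param ratios numeric `(train, val, test)` summing to 1; default
#'   `c(0.8, 0.1, 0.1)`.
#' @param seed integer permutation seed.
#' @return if `labels` are per-sample: list with `assignment` (factor of
#'   "train"/"val"/"test" per sample) and `counts` (class x split matrix);
#'   if counts: the `counts` matrix alone.
#' @export
stratified_split <- function(labels, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  if (abs(sum(ratios) - 1) > 1e-9) stop_invalid("split ratios must sum to 1")
  counts_only <- !is.null(names(labels)) && is.numeric(labels)
  tab <- if (counts_only) as.integer(labels) else as.integer(table(labels))
  cls <- if (counts_only) names(labels) else names(table(labels))
  if (any(tab < 3L)) stop_invalid("every class needs at least 3 samples")
  n_val <- as.integer(floor(ratios[2] * tab))
  n_test <- as.integer(floor(ratios[3] * tab))
  n_train <- tab - n_val - n_test
  counts <- cbind(train = n_train, val = n_val, test = n_test)
  rownames(counts) <- cls
  if (counts_only) return(counts)
  assignment <- character(length(labels))
  with_seed(sub_seed(seed, "split"), {
    for (k in seq_along(cls)) {
      idx <- which(as.character(labels) == cls[k])
      idx <- sample(idx)
      assignment[idx[seq_len(n_train[k])]] <- "train"
      assignment[idx[n_train[k] + seq_len(n_val[k])]] <- "val"
      assignment[idx[n_train[k] + n_val[k] + seq_len(n_test[k])]] <- "test"
    }
  })
  list(assignment = factor(assignment, levels = c("train", "val", "test")),
       counts = counts)
}

#' Per-sample weights for imbalance-aware sampling
#'
#' Weight of a sample is the reciprocal of its class frequency, so that
#' weighted sampling with replacement draws every class uniformly in
#' expectation.
#'
#' @param labels vector of class labels, one per sample.
#' @return numeric weights, one per sample.
#' @export
make_class_weights <- function(labels) {
  tab <- table(labels)
  if (any(tab == 0)) stop_invalid("empty class in labels")
  as.numeric(1 / tab[as.character(labels)])
}

#' Draw a weighted bootstrap sample of indices
#'
#' Replacement sampling driven by [make_class_weights()]; expected per-class
#' draw frequency is uniform.
#'
#' @param labels class labels, one per sample.
#' @param n number of draws (default `length(labels)`).
#' @param seed integer seed.
#' @return integer indices into `labels`.
#' @export
weighted_sample_indices <- function(labels, n = length(labels), seed = 1L) {
  w <- make_class_weights(labels)
  with_seed(sub_seed(seed, "sampler"),
            sample(seq_along(labels), n, replace = TRUE, prob = w))
}

## ---- augmentation ---------------------------------------------------------

#' Segmentation augmentation policy
#'
#' Training-time policy: horizontal/vertical flips and brightness/contrast
#' jitter each with probability 0.4, zero padding to a minimum height of 32
#' and minimum width of 256, resize to a square side from \{256, 288, 320\}
#' and ImageNet channel normalisation (means 0.485/0.456/0.406, stds
#' 0.229/0.224/0.225). Geometric operations are applied jointly to image and
#' mask; photometric ones to the image only. The validation/test path resizes
#' and normalises only.
#'
#' @param hflip_p,vflip_p,brightness_contrast_p operation probabilities.
#' @param pad_min_height,pad_min_width constant-zero padding minima.
#' @param resize_to output side in pixels.
#' @param normalize_mean,normalize_sd channel normalisation constants.
#' @return an `aug_policy_seg` list.
#' @export
seg_aug_policy <- function(hflip_p = 0.4, vflip_p = 0.4,
                           brightness_contrast_p = 0.4,
                           pad_min_height = 32L, pad_min_width = 256L,
                           resize_to = 256L,
                           normalize_mean = c(0.485, 0.456, 0.406),
                           normalize_sd = c(0.229, 0.224, 0.225)) {
  structure(list(hflip_p = hflip_p, vflip_p = vflip_p,
                 brightness_contrast_p = brightness_contrast_p,
                 pad_min_height = as.integer(pad_min_height),
                 pad_min_width = as.integer(pad_min_width),
                 resize_to = as.integer(resize_to),
                 normalize_mean = normalize_mean, normalize_sd = normalize_sd),
            class = "aug_policy_seg")
}

#' Classification augmentation policy
#'
#' Training-time policy: horizontal/vertical flips, 90-degree rotations and
#' brightness/contrast jitter each with probability 0.5, grayscale replicated
#' to RGB, resize to the backbone's input side (224 by default, 299 for
#' inception-style models) and normalisation to mean 0.5 / sd 0.5 (range
#' approximately `[-1, 1]`).
#'
#' @param hflip_p,vflip_p,rot90_p,brightness_contrast_p operation
#'   probabilities.
#' @param resize_to input side in pixels.
#' @param grayscale_to_rgb replicate single-channel input to 3 channels.
#' @param normalize_mean,normalize_sd scalar normalisation constants.
#' @return an `aug_policy_cls` list.
#' @export
cls_aug_policy <- function(hflip_p = 0.5, vflip_p = 0.5, rot90_p = 0.5,
                           brightness_contrast_p = 0.5, resize_to = 224L,
                           grayscale_to_rgb = TRUE,
                           normalize_mean = 0.5, normalize_sd = 0.5) {
  structure(list(hflip_p = hflip_p, vflip_p = vflip_p, rot90_p = rot90_p,
                 brightness_contrast_p = brightness_contrast_p,
                 resize_to = as.integer(resize_to),
                 grayscale_to_rgb = grayscale_to_rgb,
                 normalize_mean = normalize_mean, normalize_sd = normalize_sd),
            class = "aug_policy_cls")
}

#' Horizontal / vertical flip of a matrix image
#'
#' Involutions: applying the same flip twice restores the input exactly.
#'
#' @param m matrix (H x W).
#' @return flipped matrix.
#' @export
flip_h <- function(m) m[, ncol(m):1, drop = FALSE]

#' @rdname flip_h
#' @export
flip_v <- function(m) m[nrow(m):1, , drop = FALSE]

rot90k <- function(m, k) {
  k <- k %% 4L
  for (i in seq_len(k)) m <- t(m[nrow(m):1, , drop = FALSE])
  m
}

pad_to_min <- function(m, min_h, min_w) {
  H <- nrow(m); W <- ncol(m)
  if (H >= min_h && W >= min_w) return(m)
  out <- matrix(0, max(H, min_h), max(W, min_w))
  oy <- (nrow(out) - H) %/% 2L
  ox <- (ncol(out) - W) %/% 2L
  out[oy + seq_len(H), ox + seq_len(W)] <- m
  out
}

resize_matrix <- function(m, oh, ow, nearest = FALSE) {
  if (nearest) {
    ri <- pmin(pmax(round((seq_len(oh) - 0.5) * nrow(m) / oh + 0.5), 1L), nrow(m))
    ci <- pmin(pmax(round((seq_len(ow) - 0.5) * ncol(m) / ow + 0.5), 1L), ncol(m))
    return(m[ri, ci, drop = FALSE])
  }
  bilinear_matrix(oh, nrow(m)) %*% m %*% t(bilinear_matrix(ow, ncol(m)))
}

brightness_contrast <- function(m, limit = 0.2) {
  b <- stats::runif(1, -limit, limit)
  c <- 1 + stats::runif(1, -limit, limit)
  pmin(pmax((m - mean(m)) * c + mean(m) + b, 0), 1)
}

gray_to_stack <- function(m, means, sds) {
  k <- length(means)
  out <- array(0, c(k, nrow(m), ncol(m)))
  for (i in seq_len(k)) out[i, , ] <- (m - means[i]) / sds[i]
  out
}

#' Augment a segmentation sample
#'
#' Geometric operations are applied jointly to image and mask; photometric
#' operations to the image only; the mask stays binary (nearest-neighbour
#' resize). With `train = FALSE` only resize and normalisation are applied.
#'
#' @param sample list with `image` (matrix in `[0, 1]`) and binary `mask`.
#' @param policy a [seg_aug_policy()].
#' @param train apply the random operations (default TRUE).
#' @return list with `x` (array `(3, S, S)`, normalised), `mask` (binary
#'   `S x S`) and `ops` (character vector of applied random operations).
#' @export
augment_segmentation <- function(sample, policy = seg_aug_policy(), train = TRUE) {
  img <- sample$image; mask <- sample$mask
  ops <- character()
  if (train) {
    if (stats::runif(1) < policy$hflip_p) {
      img <- flip_h(img); mask <- flip_h(mask); ops <- c(ops, "hflip")
    }
    if (stats::runif(1) < policy$vflip_p) {
      img <- flip_v(img); mask <- flip_v(mask); ops <- c(ops, "vflip")
    }
    if (stats::runif(1) < policy$brightness_contrast_p) {
      img <- brightness_contrast(img); ops <- c(ops, "brightness_contrast")
    }
    img <- pad_to_min(img, policy$pad_min_height, policy$pad_min_width)
    mask <- pad_to_min(mask, policy$pad_min_height, policy$pad_min_width)
  }
  s <- policy$resize_to
  img <- resize_matrix(img, s, s)
  mask <- resize_matrix(mask, s, s, nearest = TRUE)
  list(x = gray_to_stack(img, policy$normalize_mean, policy$normalize_sd),
       mask = (mask > 0.5) * 1, ops = ops)
}

#' Augment a classification sample
#'
#' The label never changes; grayscale input is replicated to three channels
#' when the policy requests it. With `train = FALSE` only resize and
#' normalisation are applied.
#'
#' @param sample list with `image` (matrix in `[0, 1]`) and integer `label`.
#' @param policy a [cls_aug_policy()].
#' @param train apply the random operations (default TRUE).
#' @return list with `x` (array `(3, S, S)` normalised to about `[-1, 1]`),
#'   `label` and `ops`.
#' @export
augment_classification <- function(sample, policy = cls_aug_policy(), train = TRUE) {
  img <- sample$image
  ops <- character()
  if (train) {
    if (stats::runif(1) < policy$hflip_p) { img <- flip_h(img); ops <- c(ops, "hflip") }
    if (stats::runif(1) < policy$vflip_p) { img <- flip_v(img); ops <- c(ops, "vflip") }
    if (stats::runif(1) < policy$rot90_p) {
      k <- sample.int(3L, 1L)
      img <- rot90k(img, k); ops <- c(ops, paste0("rot", 90L * k))
    }
    if (stats::runif(1) < policy$brightness_contrast_p) {
      img <- brightness_contrast(img); ops <- c(ops, "brightness_contrast")
    }
  }
  s <- policy$resize_to
  img <- resize_matrix(img, s, s)
  k <- if (policy$grayscale_to_rgb) 3L else 1L
  x <- gray_to_stack(img, rep(policy$normalize_mean, k), rep(policy$normalize_sd, k))
  list(x = x, label = sample$label, ops = ops)
}
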