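# Evaluation metrics and losses: Dice (coefficient and loss), IoU, pixel
# accuracy, ROC AUC, confusion matrix with per-class and macro
# precision/recall/F1, and focal loss.

check_pair <- function(pred, truth) {
  if (!identical(dim(as.array(pred)), dim(as.array(truth)))) {
    stop_invalid("prediction and truth shapes differ")
  }
  if (!all(truth %in% c(0, 1))) stop_invalid("truth mask must be binary")
  invisible(NULL)
}

#' Dice similarity coefficient
#'
#' `(2|X∩Y| + eps) / (|X| + |Y| + eps)`. Accepts binary masks or probability
#' maps (soft Dice, summing `p_i g_i` over pixels). Two empty masks score 1.
#'
#' @param pred predicted mask or probability map.
#' @param truth binary ground-truth mask of the same shape.
#' @param smooth smoothing constant `eps` (default 1e-6).
#' @return value in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, truth, smooth = 1e-6) {
  check_pair(pred, truth)
  inter <- sum(pred * truth)
  tot <- sum(pred) + sum(truth)
  if (tot == 0) return(1)
  (2 * inter + smooth) / (tot + smooth)
}

#' Dice loss `1 - DSC`
#'
#' @inheritParams dice_coefficient
#' @return value in `[0, 1]`.
#' @export
dice_loss <- function(pred, truth, smooth = 1e-6) 1 - dice_coefficient(pred, truth, smooth)

#' Intersection over union (Jaccard index)
#'
#' Probability inputs are thresholded at 0.5 first. Two empty masks score 1.
#'
#' @inheritParams dice_coefficient
#' @return value in `[0, 1]`.
#' @export
iou_score <- function(pred, truth) {
  check_pair(pred, truth)
  p <- pred >= 0.5
  t <- truth > 0.5
  uni <- sum(p | t)
  if (uni == 0) return(1)
  sum(p & t) / uni
}

#' Pixel accuracy
#'
#' Proportion of correctly classified pixels, both classes counted.
#'
#' @inheritParams dice_coefficient
#' @return value in `[0, 1]`.
#' @export
pixel_accuracy <- function(pred, truth) {
  check_pair(pred, truth)
  mean((pred >= 0.5) == (truth > 0.5))
}

#' Area under the ROC curve
#'
#' Computed as the normalised Mann-Whitney U statistic over the pooled
#' score set: the probability that a random positive outscores a random
#' negative, ties counted 1/2.
#'
#' @param scores numeric scores or probability map(s).
#' @param truth binary labels of the same length.
#' @return value in `[0, 1]`.
#' @export
auc_score <- function(scores, truth) {
  s <- as.numeric(scores)
  y <- as.numeric(truth)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0) {
    stop_invalid("AUC undefined: pooled truth contains a single class")
  }
  r <- rank(s, ties.method = "average")
  (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Confusion matrix and per-class classification report
#'
#' Counts with rows = true class and columns = predicted class; one-vs-rest
#' precision, recall and F1 per class; macro scores as unweighted means;
#' accuracy as trace over total. Zero-denominator cells yield 0 with a
#' warning.
#'
#' @param true_labels,predicted_labels integer labels in `[0, n_classes)` or
#'   factors with identical levels.
#' @param n_classes number of classes (inferred from the data when missing).
#' @param class_names optional class labels for the report.
#' @return an object of class `class_report`: list with `confusion` (matrix),
#'   `per_class` (data frame of precision/recall/F1/support), `macro_precision`,
#'   `macro_recall`, `macro_f1` and `accuracy`.
#' @export
classification_report <- function(true_labels, predicted_labels, n_classes = NULL,
                                  class_names = NULL) {
  if (length(true_labels) != length(predicted_labels)) {
    stop_invalid("label vectors have different lengths")
  }
  t <- as.integer(true_labels); p <- as.integer(predicted_labels)
  if (is.null(n_classes)) n_classes <- max(t, p) + 1L
  if (any(t < 0 | t >= n_classes | p < 0 | p >= n_classes)) {
    stop_invalid("labels must lie in [0, n_classes)")
  }
  if (is.null(class_names)) class_names <- as.character(seq_len(n_classes) - 1L)
  cm <- matrix(0L, n_classes, n_classes, dimnames = list(true = class_names,
                                                         predicted = class_names))
  for (i in seq_along(t)) cm[t[i] + 1L, p[i] + 1L] <- cm[t[i] + 1L, p[i] + 1L] + 1L
  prec <- rec <- f1 <- numeric(n_classes)
  warned <- FALSE
  for (k in seq_len(n_classes)) {
    tp <- cm[k, k]; fp <- sum(cm[, k]) - tp; fn <- sum(cm[k, ]) - tp
    if (tp + fp == 0 || tp + fn == 0 || tp == 0) {
      if ((tp + fp == 0 || tp + fn == 0) && !warned) {
        warning("zero denominator in precision/recall; reporting 0", call. = FALSE)
        warned <- TRUE
      }
    }
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[k] <- if (prec[k] + rec[k] > 0) 2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  structure(list(
    confusion = cm,
    per_class = data.frame(class = class_names, precision = prec, recall = rec,
                           f1 = f1, support = rowSums(cm)),
    macro_precision = mean(prec), macro_recall = mean(rec), macro_f1 = mean(f1),
    accuracy = sum(diag(cm)) / length(t)), class = "class_report")
}

#' @export
print.class_report <- function(x, ...) {
  cat("Confusion matrix (rows = true, columns = predicted):\n")
  print(x$confusion)
  cat("\nPer-class metrics:\n")
  print(x$per_class, row.names = FALSE, digits = 4)
  cat(sprintf("\nmacro precision %.4f  macro recall %.4f  macro F1 %.4f  accuracy %.4f\n",
              x$macro_precision, x$macro_recall, x$macro_f1, x$accuracy))
  invisible(x)
}

#' Focal loss
#'
#' `FL = -sum_c alpha_c (1-p_c)^gamma y_c log(p_c)`, averaged over the batch.
#' With `gamma = 0` and `alpha = 1` it reduces to categorical cross-entropy.
#' Probabilities for the true class are floored at 1e-12.
#'
#' @param probs matrix `(B, K)` of predicted class probabilities (rows sum
#'   to 1) or a single probability vector.
#' @param labels integer true classes in `1..K` (or 0-based when
#'   `zero_based = TRUE`).
#' @param alpha scalar class weight in `(0, 1]` or length-K per-class vector.
#' @param gamma focusing exponent `>= 0`.
#' @param zero_based interpret labels as 0-based.
#' @return non-negative scalar loss.
#' @export
focal_loss <- function(probs, labels, alpha = 1, gamma = 0, zero_based = FALSE) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  if (gamma < 0) stop_invalid("gamma must be >= 0")
  labels <- as.integer(labels) + if (zero_based) 1L else 0L
  K <- ncol(probs)
  if (length(alpha) == 1L) alpha <- rep(alpha, K)
  u <- probs[cbind(seq_len(nrow(probs)), labels)]
  if (any(u <= 0)) {
    warning("true-class probability of 0 clamped to 1e-12", call. = FALSE)
    u <- pmax(u, 1e-12)
  }
  mean(-alpha[labels] * (1 - u)^gamma * log(u))
}

#' Segmentation metrics over a set of image pairs
#'
#' Per-image Dice, IoU and pixel accuracy averaged across images (the
#' empty-vs-empty convention scores 1), and pixel-level AUC pooled across
#' all images of the split.
#'
#' @param prob_list list of probability maps.
#' @param mask_list list of binary ground-truth masks.
#' @return an object of class `metrics_report`: list with `pixel_accuracy`,
#'   `dice`, `iou`, `auc` and `n_images`.
#' @export
segmentation_metrics <- function(prob_list, mask_list) {
  stopifnot(length(prob_list) == length(mask_list), length(prob_list) > 0)
  dice <- mapply(function(p, m) dice_coefficient((p >= 0.5) * 1, m), prob_list, mask_list)
  iou <- mapply(iou_score, prob_list, mask_list)
  pa <- mapply(pixel_accuracy, prob_list, mask_list)
  pooled_s <- unlist(lapply(prob_list, as.numeric))
  pooled_t <- unlist(lapply(mask_list, as.numeric))
  auc <- if (sum(pooled_t == 1) > 0 && sum(pooled_t == 0) > 0) {
    auc_score(pooled_s, pooled_t)
  } else NA_real_
  structure(list(pixel_accuracy = mean(pa), dice = mean(dice), iou = mean(iou),
                 auc = auc, n_images = length(prob_list)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Segmentation metrics over %d images:\n", x$n_images))
  cat(sprintf("  pixel accuracy %.4f   Dice %.4f   IoU %.4f   AUC %s\n",
              x$pixel_accuracy, x$dice, x$iou,
              if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc)))
  invisible(x)
}

#' Write a classification report to CSV / JSON
#'
#' The confusion matrix is written as a labelled CSV grid (rows true,
#' columns predicted); the scalar metrics and per-class table go to JSON.
#'
#' @param report a [classification_report()] result.
#' @param csv_path,json_path output paths (either may be NULL to skip).
#' @return invisibly, the report.
#' @export
write_class_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame.matrix(report$confusion), csv_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      per_class = report$per_class,
      macro_precision = report$macro_precision,
      macro_recall = report$macro_recall,
      macro_f1 = report$macro_f1,
      accuracy = report$accuracy), json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

#' Write a segmentation metrics report to JSON
#'
#' @param report a [segmentation_metrics()] result (or a named list of them,
#'   one per split).
#' @param json_path output path.
#' @return invisibly, the report.
#' @export
write_metrics_report <- function(report, json_path) {
  jsonlite::write_json(unclass_deep(report), json_path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
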