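# Metric and loss definitions against hand-counted and enumerated oracles.

test_that("Dice coefficient matches direct set counting", {
  a <- matrix(0, 4, 4); b <- matrix(0, 4, 4)
  a[1, 1:3] <- 1          # |X| = 3
  b[1, 2:4] <- 1          # |Y| = 3, overlap = 2
  expect_equal(dice_coefficient(a, b), 2 * 2 / 6, tolerance = 1e-6)
  expect_equal(dice_coefficient(b, b), 1, tolerance = 1e-6)
  d <- matrix(0, 4, 4); d[4, ] <- 1
  expect_equal(dice_coefficient(a, d), 0, tolerance = 1e-5)
  expect_equal(dice_coefficient(matrix(0, 3, 3), matrix(0, 3, 3)), 1)
  expect_equal(dice_loss(b, b), 0, tolerance = 1e-6)
  expect_error(dice_coefficient(a, matrix(0, 3, 3)), "shapes")
})

test_that("IoU matches direct counting and the Dice identity", {
  a <- matrix(0, 4, 4); b <- matrix(0, 4, 4)
  a[1, 1:3] <- 1; b[1, 2:4] <- 1   # intersection 2, union 4
  expect_equal(iou_score(a, b), 0.5)
  expect_equal(iou_score(b, b), 1)
  expect_equal(dice_coefficient(a, b), 2 * 0.5 / 1.5, tolerance = 1e-6)
})

test_that("Dice equals 2*IoU/(1+IoU) on 1000 random binary mask pairs", {
  set.seed(21)
  for (i in 1:1000) {
    p <- random_mask_pair()
    if (sum(p$a) + sum(p$b) == 0) next
    iou <- iou_score(p$a, p$b)
    expect_lt(abs(dice_coefficient(p$a, p$b, smooth = 0) - 2 * iou / (1 + iou)), 1e-9)
  }
})

test_that("pixel accuracy counts both classes", {
  a <- matrix(0, 4, 4); a[1:2, ] <- 1
  b <- a
  b[1, 1:2] <- 0; b[4, 3:4] <- 1    # 4 disagreements
  expect_equal(pixel_accuracy(a, b), 12 / 16)
  expect_equal(pixel_accuracy(a, a), 1)
  expect_equal(pixel_accuracy(a, 1 - a), 0)
})

test_that("AUC is the Mann-Whitney statistic and matches pair enumeration", {
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_score(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(auc_score(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  set.seed(33)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 2)             # rounded scores exercise ties
    expect_equal(auc_score(s, y), pairwise_auc(s, y), tolerance = 1e-12)
  }
  expect_error(auc_score(c(0.1, 0.2), c(1, 1)), "single class")
})

test_that("classification report matches a hand-counted 3-class table", {
  truth <- rep(0:2, each = 5)
  pred <- truth
  pred[1] <- 1                      # one benign -> normal
  pred[11:12] <- 0                  # two malignant -> benign
  rep3 <- classification_report(truth, pred, n_classes = 3)
  expect_equal(as.vector(rep3$confusion),
               as.vector(matrix(c(4, 0, 2, 1, 5, 0, 0, 0, 3), 3, 3)))
  expect_equal(rep3$per_class$precision, c(4 / 6, 5 / 6, 1))
  expect_equal(rep3$per_class$recall, c(4 / 5, 1, 3 / 5))
  expect_equal(rep3$per_class$f1,
               c(2 * (4 / 6) * (4 / 5) / (4 / 6 + 4 / 5),
                 2 * (5 / 6) / (5 / 6 + 1),
                 2 * 0.6 / 1.6))
  expect_equal(rep3$accuracy, 12 / 15)
  expect_equal(rep3$macro_f1, mean(rep3$per_class$f1))
  # conservation: row sums = true counts, column sums = predicted counts
  expect_equal(rowSums(rep3$confusion), table(factor(truth, 0:2)) |> as.vector() |> setNames(c("0", "1", "2")))
  expect_equal(as.vector(colSums(rep3$confusion)), as.vector(table(factor(pred, 0:2))))

  perfect <- classification_report(truth, truth, 3)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$per_class$f1, rep(1, 3))
  expect_error(classification_report(0:2, 0:1), "lengths")
})

test_that("focal loss reduces to cross-entropy at gamma 0 and matches hand values", {
  p <- matrix(c(0.5, 0.3, 0.2), 1)
  expect_equal(focal_loss(p, 1L, alpha = 1, gamma = 0), -log(0.5), tolerance = 1e-9)
  expect_equal(focal_loss(matrix(c(0.999999999, 1e-9 / 2, 1e-9 / 2), 1), 1L, gamma = 2),
               0, tolerance = 1e-8)
  expect_equal(focal_loss(matrix(c(0.8, 0.1, 0.1), 1), 1L, alpha = 0.5, gamma = 2),
               0.5 * 0.2^2 * -log(0.8), tolerance = 1e-9)
  set.seed(4)
  for (i in 1:20) {
    pm <- matrix(stats::runif(15), 5)
    pm <- pm / rowSums(pm)
    lb <- sample(3, 5, replace = TRUE)
    ce <- mean(-log(pm[cbind(1:5, lb)]))
    expect_lt(abs(focal_loss(pm, lb, alpha = 1, gamma = 0) - ce), 1e-9)
    expect_gte(focal_loss(pm, lb, alpha = 0.5, gamma = 3), 0)
  }
  expect_warning(focal_loss(matrix(c(0, 1), 1), 1L), "clamped")
})

test_that("segmentation metrics aggregate per image and pool AUC", {
  m1 <- matrix(0, 4, 4); m1[1:2, 1:2] <- 1
  m2 <- matrix(0, 4, 4); m2[3:4, 3:4] <- 1
  p1 <- m1 * 0.9 + 0.05             # near-perfect
  p2 <- matrix(0.05, 4, 4)          # all background
  rep2 <- segmentation_metrics(list(p1, p2), list(m1, m2))
  expect_equal(rep2$dice, mean(c(1, dice_coefficient(matrix(0, 4, 4), m2))))
  expect_equal(rep2$iou, mean(c(1, 0)))
  expect_equal(rep2$auc, auc_score(c(p1, p2), c(m1, m2)))
  expect_equal(rep2$n_images, 2L)
})

test_that("reports serialise to CSV and JSON", {
  rep3 <- classification_report(rep(0:2, each = 4), rep(0:2, each = 4), 3,
                                class_names = c("benign", "normal", "malignant"))
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_class_report(rep3, csv, js)
  grid <- utils::read.csv(csv, row.names = 1)
  expect_equal(as.matrix(grid), matrix(diag(4L, 3), 3, 3,
               dimnames = list(c("benign", "normal", "malignant"),
                               c("benign", "normal", "malignant"))))
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$accuracy, 1)
})
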