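# Network builders: shape contracts, structural properties and the
# FEM-residual equivalence between FADeepLabV3 and DeepLabV3.

tiny_cfg <- function(dk, ...) seg_config(dk, encoder_kind = "tiny", seed = 11L, ...)

test_that("all four segmentation builders preserve input resolution", {
  x <- array(stats::rnorm(1 * 3 * 64 * 64), c(1, 3, 64, 64))
  for (dk in c("unet", "unetpp", "deeplabv3", "fadeeplabv3")) {
    net <- build_segmenter(tiny_cfg(dk))
    out <- forward_network(net, x)
    expect_equal(dim(out), c(1L, 1L, 64L, 64L), info = dk)
    # deterministic forward in evaluation mode
    expect_identical(out, forward_network(net, x), info = dk)
  }
})

test_that("U-Net with a zeroed final projection emits all-zero logits", {
  net <- build_unet(tiny_cfg("unet"))
  net$params[["head.proj.w"]][] <- 0
  net$params[["head.proj.b"]][] <- 0
  out <- forward_network(net, array(0, c(1, 3, 32, 32)))
  expect_true(all(out == 0))
})

test_that("U-Net++ accurate mode averages its branches; fast mode selects the deepest", {
  x <- array(stats::rnorm(1 * 3 * 32 * 32), c(1, 3, 32, 32))
  net <- build_unetpp(tiny_cfg("unetpp"))
  g <- femseg:::ag_graph()
  pn <- lapply(net$params, function(v) femseg:::ag_leaf(g, v))
  branches <- net$branch_forward(g, pn, femseg:::ag_leaf(g, x))
  acc <- forward_network(net, x)
  expect_lt(max(abs(acc - Reduce(`+`, lapply(branches, `[[`, "value")) / 3)), 1e-6)

  fast <- build_unetpp(seg_config("unetpp", encoder_kind = "tiny",
                                  unetpp_mode = "fast", seed = 11L))
  expect_identical(forward_network(fast, x), branches[[3]]$value)
})

test_that("ASPP has five branches at the configured atrous rates", {
  net <- build_deeplabv3(tiny_cfg("deeplabv3"))
  nms <- names(net$params)
  branch_convs <- c("aspp.b1.w", "aspp.r6.w", "aspp.r12.w", "aspp.r18.w", "aspp.img.w")
  expect_true(all(branch_convs %in% nms))
  expect_equal(sum(grepl("^aspp\\.(b1|r[0-9]+|img)\\.w$", nms)), 5L)
  # atrous kernels are 3x3, the 1x1 and image branches 1x1
  expect_equal(dim(net$params[["aspp.r12.w"]])[3:4], c(3L, 3L))
  expect_equal(dim(net$params[["aspp.b1.w"]])[3:4], c(1L, 1L))
  expect_error(seg_config("deeplabv3", aspp_rates = c(12, 6, 18)), "increasing")
})

test_that("FADeepLabV3 with zero-initialised fusion equals DeepLabV3 bit-for-bit", {
  x <- array(stats::rnorm(1 * 3 * 64 * 64), c(1, 3, 64, 64))
  netf <- build_fadeeplabv3(tiny_cfg("fadeeplabv3"))
  netd <- build_deeplabv3(tiny_cfg("deeplabv3"))
  shared <- intersect(names(netf$params), names(netd$params))
  for (nm in shared) expect_identical(netf$params[[nm]], netd$params[[nm]])
  expect_identical(forward_network(netf, x), forward_network(netd, x))
  # FEM attaches at the deepest stage: its channel count matches stage 4
  expect_equal(netf$fem_cfg$C, 64L)
})

test_that("the ResNet18-style staged encoder satisfies the four-stage contract", {
  cfg <- seg_config("deeplabv3", encoder_kind = "resnet18", seed = 2L)
  net <- build_deeplabv3(cfg)
  x <- array(stats::rnorm(1 * 3 * 64 * 64), c(1, 3, 64, 64))
  out <- forward_network(net, x)
  expect_equal(dim(out), c(1L, 1L, 64L, 64L))
  # stage channels 64/128/256/512 visible in the parameter shapes
  expect_equal(dim(net$params[["enc.l1b1.c1.w"]])[1], 64L)
  expect_equal(dim(net$params[["enc.l4b1.c1.w"]])[1], 512L)
})

test_that("classifier-head surgery produces 3 logits, is idempotent and respects feature dims", {
  net <- attach_classifier_head(cls_config("tiny", seed = 3L))
  x <- array(stats::rnorm(2 * 3 * 32 * 32), c(2, 3, 32, 32))
  g <- femseg:::ag_graph()
  pn <- lapply(net$params, function(v) femseg:::ag_leaf(g, v))
  z <- net$forward(g, pn, femseg:::ag_leaf(g, x))$value
  expect_equal(dim(z), c(2L, 3L))

  net2 <- attach_classifier_head(net)  # replace the head again
  expect_identical(names(net2$params), names(net$params))
  expect_identical(dim(net2$params[["head.w"]]), dim(net$params[["head.w"]]))
  body <- setdiff(names(net$params), c("head.w", "head.b"))
  for (nm in body) expect_identical(net2$params[[nm]], net$params[[nm]])

  # a user-registered micro backbone with feature dim 16 gets a 3x16 head
  register_backbone("micro16", function(st, prefix, pretrained = FALSE) {
    femseg:::p_conv(st, paste0(prefix, "c"), 16L, 3L, 3L)
    list(feature_dim = 16L,
         forward = function(g, pn, x, training = FALSE) {
           h <- femseg:::f_conv(g, pn, paste0(prefix, "c"), x, stride = 2L, pad = 1L)
           pooled <- femseg:::ag_global_avg_pool(g, femseg:::ag_relu(g, h))
           d <- dim(pooled$value)
           femseg:::ag_node(g, matrix(pooled$value, d[1], d[2]), list(pooled),
                            function(gr) list(array(gr, d)))
         })
  })
  m <- attach_classifier_head(cls_config("micro16", seed = 4L))
  expect_equal(dim(m$params[["head.w"]]), c(3L, 16L))
  expect_error(attach_classifier_head(cls_config("nope")), "unknown backbone")
  expect_error(attach_classifier_head(cls_config("tiny", pretrained = TRUE)), "pretrained")
})
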