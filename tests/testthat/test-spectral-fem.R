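# Frequency-domain feature enhancement: masks, spectra, band splitting,
# refinement, fusion and the residual forward pass.

test_that("band masks form an exact binary partition with DC in the low band", {
  for (hw in list(c(8L, 8L), c(7L, 9L), c(16L, 15L))) {
    m <- make_band_masks(hw[1], hw[2])
    expect_true(all(m$low + m$mid + m$high == 1))
    expect_true(all(m$low %in% c(0, 1) & m$mid %in% c(0, 1) & m$high %in% c(0, 1)))
    expect_equal(m$low[1, 1], 1)
  }
  expect_error(make_band_masks(8, 8, c(0.7, 0.3)), "cutoffs")
  expect_error(make_band_masks(0, 8), "positive")
})

test_that("band counts match exhaustive enumeration of the radial rule", {
  H <- 8L; W <- 8L
  m <- make_band_masks(H, W, c(1 / 3, 2 / 3))
  wf <- W %/% 2L + 1L
  counts <- c(low = 0L, mid = 0L, high = 0L)
  for (u in seq_len(H)) for (v in seq_len(wf)) {
    r <- bin_radius(u, v, H, W)
    k <- if (r < 1 / 3) "low" else if (r < 2 / 3) "mid" else "high"
    counts[k] <- counts[k] + 1L
  }
  expect_equal(sum(m$low), as.numeric(counts["low"]))
  expect_equal(sum(m$mid), as.numeric(counts["mid"]))
  expect_equal(sum(m$high), as.numeric(counts["high"]))
})

test_that("forward spectrum has the half-spectrum width and matches the direct DFT", {
  x <- array(stats::rnorm(2 * 256), c(1, 1, 2, 256))
  expect_equal(dim(forward_spectrum(x))[4], 129L)

  cmap <- array(0.7, c(1, 1, 6, 4))
  sp <- forward_spectrum(cmap)
  expect_equal(Re(sp[1, 1, 1, 1]), 0.7 * 24, tolerance = 1e-6)
  expect_lt(max(Mod(sp[1, 1, , ][-1])), 1e-6)

  set.seed(42)
  x <- array(stats::rnorm(16), c(1, 1, 4, 4))
  expect_lt(max(Mod(forward_spectrum(x)[1, 1, , ] - naive_dft2_half(x[1, 1, , ]))), 1e-6)

  expect_error(forward_spectrum(array(c(NA, 1, 2, 3), c(1, 1, 2, 2))), "finite")
})

test_that("inverse spectrum round-trips odd and even widths", {
  set.seed(7)
  for (hw in list(c(5L, 7L), c(6L, 6L), c(4L, 9L))) {
    x <- array(stats::rnorm(2 * 3 * hw[1] * hw[2]), c(2, 3, hw[1], hw[2]))
    expect_lt(max(abs(inverse_spectrum(forward_spectrum(x), hw) - x)), 1e-5)
  }
})

test_that("band splitting is mask-consistent, conservative and energy-selective", {
  set.seed(3)
  x <- array(stats::rnorm(2 * 2 * 8 * 8), c(2, 2, 8, 8))
  m <- make_band_masks(8, 8)

  # identity mask: everything into 'low'
  mid <- m
  mid$low <- matrix(1, 8, 5); mid$mid <- matrix(0, 8, 5); mid$high <- matrix(0, 8, 5)
  bs <- band_split(x, mid)
  expect_lt(max(abs(bs$low - x)), 1e-5)
  expect_lt(max(abs(bs$mid)), 1e-10)
  expect_lt(max(abs(bs$high)), 1e-10)

  bs <- band_split(x, m)
  expect_lt(max(abs(bs$low + bs$mid + bs$high - x)), 1e-5)

  # a pure cosine at a high-band bin concentrates its energy in 'high'
  wf <- 5L
  hb <- which(m$high == 1, arr.ind = TRUE)
  hb <- hb[hb[, 2] > 1 & hb[, 2] < wf, , drop = FALSE][1, ]  # interior column
  u <- hb[1] - 1L; v <- hb[2] - 1L
  grid <- outer(0:7, 0:7, function(h, w) cos(2 * pi * (u * h / 8 + v * w / 8)))
  xc <- array(grid, c(1, 1, 8, 8))
  bs <- band_split(xc, m)
  etot <- sum(xc^2)
  expect_gte(sum(bs$high^2), 0.99 * etot)
  expect_lte(sum(bs$low^2) + sum(bs$mid^2), 0.01 * etot)

  expect_error(band_split(x, make_band_masks(4, 4)), "masks built")
})

test_that("band refinement reduces channels, is deterministic in eval mode and normalises", {
  set.seed(5)
  p <- fem_params(512L, rho = 4L, seed = 2)
  x <- array(stats::rnorm(1 * 512 * 3 * 3), c(1, 512, 3, 3))
  y <- refine_band(x, p, "low")
  expect_equal(dim(y), c(1L, 128L, 3L, 3L))
  expect_identical(y, refine_band(x, p, "low"))

  # rho = 1, identity convolution, unit gains: pure per-group standardisation
  p1 <- fem_params(8L, rho = 1L, groups = 2L, seed = 3)
  p1$weights[["mid.w"]] <- array(diag(8), c(8, 8, 1, 1))
  p1$weights[["mid.b"]] <- numeric(8)
  x <- array(stats::rnorm(2 * 8 * 4 * 4), c(2, 8, 4, 4))
  got <- refine_band(x, p1, "mid")
  want <- x
  for (b in 1:2) for (grp in 1:2) {
    ch <- (grp - 1) * 4 + 1:4
    sl <- x[b, ch, , ]
    want[b, ch, , ] <- (sl - mean(sl)) / sqrt(mean((sl - mean(sl))^2) + 1e-5)
  }
  expect_lt(max(abs(got - want)), 1e-5)

  expect_error(refine_band(array(0, c(1, 4, 2, 2)), p, "low"), "channels")
})

test_that("band fusion restores channel dimensionality", {
  p <- fem_params(512L, rho = 4L, seed = 1, zero_init_fusion = FALSE)
  f <- array(stats::rnorm(1 * 128 * 2 * 2), c(1, 128, 2, 2))
  out <- fuse_bands(f, f, f, p)
  expect_equal(dim(out), c(1L, 512L, 2L, 2L))

  # all-zero inputs: output is the bias path of the two layers
  z <- array(0, dim(f))
  p$weights[["fuse1.b"]] <- runif(256) - 0.5
  p$weights[["fuse2.b"]] <- runif(512) - 0.5
  got <- fuse_bands(z, z, z, p)
  h <- pmax(p$weights[["fuse1.b"]], 0)
  want <- as.numeric(matrix(p$weights[["fuse2.w"]], 512, 256) %*% h) + p$weights[["fuse2.b"]]
  expect_equal(got[1, , 1, 1], want, tolerance = 1e-10)

  # zero final layer annihilates any input
  p$weights[["fuse2.w"]][] <- 0
  p$weights[["fuse2.b"]][] <- 0
  expect_true(all(fuse_bands(f, f, f, p) == 0))

  expect_error(fuse_bands(f, f, array(0, c(1, 128, 3, 3)), p), "shapes")
})

test_that("FEM forward is a residual refinement with exact zero-init identity", {
  set.seed(9)
  p <- fem_params(8L, rho = 4L, seed = 4)             # fusion zero-initialised
  x <- array(stats::rnorm(2 * 8 * 8 * 8), c(2, 8, 8, 8))
  expect_identical(fem_forward(x, p), x)

  for (hw in list(c(7L, 7L), c(8L, 8L), c(15L, 17L), c(32L, 31L))) {
    x <- array(stats::rnorm(8 * hw[1] * hw[2]), c(1, 8, hw[1], hw[2]))
    expect_equal(dim(fem_forward(x, p)), dim(x))
  }

  # live fusion: forward equals the manual composition of the stages
  pl <- fem_params(8L, rho = 4L, seed = 6, zero_init_fusion = FALSE)
  x <- array(stats::rnorm(1 * 8 * 6 * 6), c(1, 8, 6, 6))
  m <- make_band_masks(6, 6)
  bands <- band_split(x, m)
  manual <- x + fuse_bands(refine_band(bands$low, pl, "low"),
                           refine_band(bands$mid, pl, "mid"),
                           refine_band(bands$high, pl, "high"), pl)
  expect_lt(max(abs(fem_forward(x, pl, m) - manual)), 1e-6)
})

test_that("FEM trainable parameter count matches the closed form", {
  for (C in c(64L, 512L)) {
    p <- fem_params(C, rho = 4L, seed = 1)
    expect_equal(fem_param_count(p), fem_param_count(C, rho = 4L))
  }
  expect_error(fem_params(10L, rho = 4L), "divisible")
})
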