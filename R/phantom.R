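# Synthetic breast-ultrasound phantoms: speckled grayscale images with
# hypoechoic lesions and ground-truth masks, mimicking the appearance and
# class structure of clinical B-mode scans (normal = no lesion, benign =
# smooth elliptical lesion, malignant = irregular star-convex lesion), plus
# a BUSI-style on-disk dataset writer/reader.

gaussian_blur_mat <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  half <- max(1L, ceiling(3 * sigma))
  idx <- seq_len(n)
  A <- matrix(0, n, n)
  for (i in idx) {
    j <- pmax(1L, i - half):pmin(n, i + half)
    w <- exp(-((j - i)^2) / (2 * sigma^2))
    A[i, j] <- w / sum(w)
  }
  A
}

blur2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  gaussian_blur_mat(nrow(m), sigma) %*% m %*% t(gaussian_blur_mat(ncol(m), sigma))
}

# Smooth random field in [-1, 1]-ish range: coarse normal grid, bilinear
# upsampled to (H, W).
smooth_field <- function(H, W, coarse = 8L) {
  gmat <- matrix(stats::rnorm(coarse * coarse), coarse, coarse)
  up <- bilinear_matrix(H, coarse) %*% gmat %*% t(bilinear_matrix(W, coarse))
  up / max(abs(up), 1e-9)
}

#' Phantom generator configuration
#'
#' Defaults emulate the qualitative character of breast ultrasound: speckled
#' background around mid-gray, hypoechoic (darker) lesions covering a few
#' percent of the image, low contrast and blur-softened boundaries.
#'
#' @param image_size integer pair `(H, W)`, default `c(256, 256)`.
#' @param class "normal", "benign" or "malignant".
#' @param lesion_area_range fraction of image area `(a_min, a_max)`, default
#'   `c(0.05, 0.15)`.
#' @param contrast_drop lesion-vs-background intensity gap in `(0, 1)`,
#'   default 0.35.
#' @param speckle multiplicative speckle scale, default 0.35.
#' @param blur_sigma boundary-softening Gaussian width in pixels, default 1.5.
#' @param irregularity malignant boundary perturbation amplitude, default 0.35.
#' @param seed integer seed; the phantom is deterministic given the seed.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(image_size = c(256L, 256L),
                           class = c("benign", "malignant", "normal"),
                           lesion_area_range = c(0.05, 0.15),
                           contrast_drop = 0.35, speckle = 0.35,
                           blur_sigma = 1.5, irregularity = 0.35, seed = 1L) {
  class <- match.arg(class)
  a <- lesion_area_range
  if (!(a[1] > 0 && a[1] < a[2] && a[2] < 1)) {
    stop_invalid("lesion_area_range must satisfy 0 < a_min < a_max < 1")
  }
  if (!(contrast_drop > 0 && contrast_drop < 1)) {
    stop_invalid("contrast_drop must lie in (0, 1)")
  }
  structure(list(image_size = as.integer(image_size), class = class,
                 lesion_area_range = a, contrast_drop = contrast_drop,
                 speckle = speckle, blur_sigma = blur_sigma,
                 irregularity = irregularity, seed = as.integer(seed)),
            class = "phantom_config")
}

# Star-convex lesion support: radius r(theta) from an ellipse base modulated
# by random low-order harmonics (amplitude = irregularity; 0 for benign),
# rescaled so the enclosed area matches the sampled target.
lesion_mask <- function(H, W, area_frac, irregularity) {
  target <- area_frac * H * W
  cy <- stats::runif(1, 0.32, 0.68) * H
  cx <- stats::runif(1, 0.32, 0.68) * W
  ecc <- stats::runif(1, 0.6, 1)          # axis ratio
  ang <- stats::runif(1, 0, pi)
  nh <- 3:7
  amp <- irregularity * stats::runif(length(nh), 0.2, 1)
  pha <- stats::runif(length(nh), 0, 2 * pi)
  rfun <- function(theta) {
    base <- 1 / sqrt((cos(theta - ang)^2) / 1 + (sin(theta - ang)^2) / ecc^2)
    mod <- 1 + colSums(amp * sin(outer(nh, theta) + pha))
    base * pmax(mod, 0.2)
  }
  th <- seq(0, 2 * pi, length.out = 721L)[-721L]
  r <- rfun(th)
  # area of a polar region is (1/2) integral r^2 dtheta; scale to target
  scale <- sqrt(target / (0.5 * sum(r^2) * (2 * pi / length(th))))
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  theta <- atan2(yy, xx)
  rad <- sqrt(yy^2 + xx^2)
  rb <- scale * rfun(theta)
  (rad <= matrix(rb, H, W)) * 1
}

#' Generate one synthetic ultrasound phantom
#'
#' Background is a smooth low-frequency intensity field; for non-normal
#' classes a hypoechoic lesion of the class's shape family (smooth ellipse
#' for benign, irregular star-convex polygon for malignant) is composited
#' with a subtractive intensity drop, multiplicative speckle is applied and
#' the boundary is softened by Gaussian blur. The returned mask is the
#' pre-blur lesion support. Deterministic given `config$seed`.
#'
#' @param config a [phantom_config()].
#' @return list with `image` (matrix `H x W` in `[0, 1]`), `mask` (binary
#'   matrix), `class` and `label` (benign = 0, normal = 1, malignant = 2).
#' @export
generate_phantom <- function(config) {
  H <- config$image_size[1]; W <- config$image_size[2]
  with_seed(config$seed, {
    bg <- 0.5 + 0.12 * smooth_field(H, W)
    mask <- matrix(0, H, W)
    if (config$class != "normal") {
      a <- config$lesion_area_range
      # sample the target area from the interior of the band so that
      # pixelisation cannot push the realised area outside it
      margin <- 0.08 * (a[2] - a[1])
      af <- stats::runif(1, a[1] + margin, a[2] - margin)
      irr <- if (config$class == "malignant") config$irregularity else 0
      mask <- lesion_mask(H, W, af, irr)
    }
    soft <- blur2d(mask, config$blur_sigma)
    img <- bg - config$contrast_drop * soft
    # Rayleigh-like multiplicative speckle: squared, lightly smoothed
    # Gaussian field with unit mean
    sp <- blur2d(matrix(stats::rnorm(H * W), H, W), 0.8)
    sp <- sp^2 / mean(sp^2)
    img <- img * (1 + config$speckle * (sp - 1))
    img <- pmin(pmax(img, 0.02), 1)
    label <- c(benign = 0L, normal = 1L, malignant = 2L)[[config$class]]
    list(image = img, mask = mask, class = config$class, label = label)
  })
}

#' Generate a BUSI-style synthetic dataset on disk
#'
#' Writes `<class>/<class> (i).png` and `<class>/<class> (i)_mask.png` 8-bit
#' grayscale PNG files (normal-class masks are all-zero images, for pipeline
#' symmetry) and a JSON manifest. Default counts are a quarter-scale version
#' of the 436/210/132 benign/malignant/normal imbalance of the BUSI corpus.
#'
#' @param root output directory (created if needed).
#' @param counts named integer vector of per-class sample counts.
#' @param image_size integer pair `(H, W)`.
#' @param seed integer seed; per-sample seeds are derived from it.
#' @param config_overrides named list of [phantom_config()] fields applied
#'   to every sample.
#' @return a `dataset_manifest`: list with `counts`, `files` (data frame of
#'   path/class/label), `seed` and `image_size`.
#' @export
generate_dataset <- function(root,
                             counts = c(benign = 109L, malignant = 52L, normal = 33L),
                             image_size = c(256L, 256L), seed = 7L,
                             config_overrides = list()) {
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(root)) stop("cannot create dataset root: ", root)
  rows <- list()
  for (cls in names(counts)) {
    cdir <- file.path(root, cls)
    dir.create(cdir, showWarnings = FALSE)
    for (i in seq_len(counts[[cls]])) {
      cfg_args <- utils::modifyList(
        list(image_size = image_size, class = cls,
             seed = sub_seed(seed, paste0(cls, "-", i))),
        config_overrides)
      ph <- generate_phantom(do.call(phantom_config, cfg_args))
      img8 <- round(ph$image * 255) / 255
      ipath <- file.path(cdir, sprintf("%s (%d).png", cls, i))
      mpath <- file.path(cdir, sprintf("%s (%d)_mask.png", cls, i))
      png::writePNG(img8, ipath)
      png::writePNG(ph$mask, mpath)
      rows[[length(rows) + 1L]] <- data.frame(
        image = ipath, mask = mpath, class = cls, label = ph$label,
        stringsAsFactors = FALSE)
    }
  }
  files <- do.call(rbind, rows)
  manifest <- structure(list(counts = as.list(counts), files = files,
                             seed = seed, image_size = as.integer(image_size)),
                        class = "dataset_manifest")
  jsonlite::write_json(list(counts = as.list(counts), seed = seed,
                            image_size = image_size,
                            files = files), file.path(root, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' Read a BUSI-style dataset directory
#'
#' Expects per-class folders of PNG images with `_mask` companions; multiple
#' `_mask_*` files for one image are unioned. Class labels are parsed from
#' file names (benign = 0, normal = 1, malignant = 2).
#'
#' @param root dataset directory.
#' @param load_images read pixel data (default TRUE); otherwise only the
#'   file table is returned.
#' @return list with `samples` (each `image`, `mask`, `class`, `label`) and
#'   `files` data frame.
#' @export
read_busi_dataset <- function(root, load_images = TRUE) {
  classes <- intersect(list.dirs(root, recursive = FALSE, full.names = FALSE),
                       c("benign", "malignant", "normal"))
  if (!length(classes)) stop_invalid("no class folders found under %s", root)
  label_map <- c(benign = 0L, normal = 1L, malignant = 2L)
  rows <- list(); samples <- list()
  for (cls in classes) {
    all_png <- list.files(file.path(root, cls), pattern = "\\.png$", full.names = TRUE)
    imgs <- all_png[!grepl("_mask", basename(all_png))]
    for (ip in imgs) {
      stem <- sub("\\.png$", "", basename(ip))
      mpaths <- all_png[grepl(paste0("^", gsub("([][()^$.|?*+{}\\\\])", "\\\\\\1", stem),
                                     "_mask"), basename(all_png))]
      rows[[length(rows) + 1L]] <- data.frame(
        image = ip, mask = paste(mpaths, collapse = ";"), class = cls,
        label = label_map[[cls]], stringsAsFactors = FALSE)
      if (load_images) {
        img <- png::readPNG(ip)
        if (length(dim(img)) == 3L) img <- img[, , 1]
        mk <- matrix(0, nrow(img), ncol(img))
        for (mp in mpaths) {
          m1 <- png::readPNG(mp)
          if (length(dim(m1)) == 3L) m1 <- m1[, , 1]
          mk <- pmax(mk, (m1 > 0.5) * 1)
        }
        samples[[length(samples) + 1L]] <- list(image = img, mask = mk,
                                                class = cls, label = label_map[[cls]])
      }
    }
  }
  list(samples = samples, files = do.call(rbind, rows))
}

# Compactness perimeter^2 / (4 pi area) of a binary mask; perimeter counted
# as boundary pixels (mask pixels with a 4-neighbour outside).
mask_compactness <- function(mask) {
  m <- mask > 0.5
  if (!any(m)) return(NA_real_)
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1), 2:(W + 1)] <- m
  inner <- pad[2:(H + 1), 2:(W + 1)]
  nb <- pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  per <- sum(inner & !nb)
  per^2 / (4 * pi * sum(inner))
}
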