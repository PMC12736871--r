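# Frequency-domain feature enhancement module (FEM).
#
# Deep encoder features X (B, C, H, W) are taken to the frequency domain with
# a real-input 2-D Fourier transform (half spectrum, width floor(W/2)+1),
# partitioned into low/mid/high radial bands by binary masks, reconstructed
# band-by-band, refined per band (1x1 conv -> group norm -> dropout), fused
# across bands by a two-layer 1x1 bottleneck, and added back residually:
#   Y = X + Dropout(Fuse(Refine(low), Refine(mid), Refine(high))).

#' Build binary low/mid/high frequency band masks over the half spectrum
#'
#' Bins are classified by their normalised radial frequency
#' `r = sqrt((|f_y|/0.5)^2 + (f_x/0.5)^2) / sqrt(2)`, where `f_y` is the
#' signed vertical frequency of a row in standard transform ordering and
#' `f_x in [0, 0.5]` the non-negative horizontal frequency of a column.
#' The three masks partition the grid exactly: low `r < c1`,
#' mid `c1 <= r < c2`, high `r >= c2`; the DC bin always lands in `low`.
#'
#' @param H,W spatial size of the feature map the masks are built for.
#' @param cutoffs numeric pair `(c1, c2)` of normalised radial cutoffs,
#'   `0 < c1 < c2 <= 1`. Default `c(1/3, 2/3)`.
#' @return an object of class `band_masks`: list with binary `low`, `mid`,
#'   `high` matrices of size `H x (floor(W/2)+1)` and the `cutoffs`.
#' @export
make_band_masks <- function(H, W, cutoffs = c(1 / 3, 2 / 3)) {
  if (length(H) != 1L || length(W) != 1L || H < 1 || W < 1) {
    stop_invalid("H and W must be positive integers")
  }
  c1 <- cutoffs[1]; c2 <- cutoffs[2]
  if (!(c1 > 0 && c1 < c2 && c2 <= 1)) {
    stop_invalid("cutoffs must satisfy 0 < c1 < c2 <= 1")
  }
  H <- as.integer(H); W <- as.integer(W)
  wf <- W %/% 2L + 1L
  u0 <- 0:(H - 1L)
  fy <- ifelse(u0 < ceiling(H / 2), u0 / H, (u0 - H) / H)   # in [-0.5, 0.5)
  fx <- (0:(wf - 1L)) / W                                   # in [0, 0.5]
  ny <- abs(fy) / 0.5
  nx <- fx / 0.5
  r <- sqrt(outer(ny^2, nx^2, `+`)) / sqrt(2)
  low <- (r < c1) * 1
  mid <- (r >= c1 & r < c2) * 1
  high <- (r >= c2) * 1
  structure(list(low = low, mid = mid, high = high,
                 cutoffs = c(c1, c2), H = H, W = W),
            class = "band_masks")
}

# Expand a half-spectrum mask (H x Wf) to the full H x W spectral grid using
# Hermitian symmetry, so masking can be applied to the full transform.
full_mask <- function(mask_half, H, W) {
  wf <- W %/% 2L + 1L
  out <- matrix(0, H, W)
  out[, seq_len(wf)] <- mask_half
  if (W > wf) {
    for (v in (wf + 1L):W) {
      vm <- W - v + 2L                       # mirrored column in the half grid
      um <- c(1L, if (H > 1L) H:2L)          # row u -> (H - u + 2) mod H
      out[, v] <- mask_half[um, vm]
    }
  }
  out
}

masks_full <- function(masks) {
  lapply(masks[c("low", "mid", "high")], full_mask, H = masks$H, W = masks$W)
}

#' Real-input 2-D Fourier transform of a feature map (half spectrum)
#'
#' Unnormalised forward transform over the last two axes; the inverse carries
#' the `1/(H*W)` factor. Only the non-redundant half of the last axis is
#' returned, width `floor(W/2)+1`.
#'
#' @param x real array `(B, C, H, W)` (lower-dimensional input is promoted).
#' @return complex array `(B, C, H, floor(W/2)+1)`.
#' @export
forward_spectrum <- function(x) {
  x <- as_nchw(x)
  check_finite(x, "feature map")
  d <- dim(x)
  wf <- d[4] %/% 2L + 1L
  out <- array(complex(real = 0), c(d[1], d[2], d[3], wf))
  for (b in seq_len(d[1])) for (cc in seq_len(d[2])) {
    f <- stats::fft(array(x[b, cc, , ], d[3:4]))
    out[b, cc, , ] <- f[, seq_len(wf)]
  }
  out
}

#' Inverse of [forward_spectrum()] with explicit output size
#'
#' Reconstructs the full spectrum from the half spectrum via Hermitian
#' symmetry and applies the normalised inverse transform, so odd widths
#' round-trip exactly.
#'
#' @param spec complex array `(B, C, H, floor(W/2)+1)`.
#' @param out_size integer pair `(H, W)`.
#' @return real array `(B, C, H, W)`.
#' @export
inverse_spectrum <- function(spec, out_size) {
  d <- dim(spec)
  H <- as.integer(out_size[1]); W <- as.integer(out_size[2])
  wf <- W %/% 2L + 1L
  if (d[3] != H || d[4] != wf) stop_invalid("spectrum size inconsistent with out_size")
  out <- array(0, c(d[1], d[2], H, W))
  um <- c(1L, if (H > 1L) H:2L)
  for (b in seq_len(d[1])) for (cc in seq_len(d[2])) {
    full <- matrix(complex(real = 0), H, W)
    full[, seq_len(wf)] <- spec[b, cc, , ]
    if (W > wf) {
      for (v in (wf + 1L):W) full[, v] <- Conj(spec[b, cc, um, W - v + 2L])
    }
    out[b, cc, , ] <- Re(stats::fft(full, inverse = TRUE)) / (H * W)
  }
  out
}

# Band-limited reconstruction with a full-grid mask, plain-array fast path.
band_project_raw <- function(x, mfull) {
  d <- dim(x)
  out <- array(0, d)
  for (b in seq_len(d[1])) for (cc in seq_len(d[2])) {
    f <- stats::fft(array(x[b, cc, , ], d[3:4]))
    out[b, cc, , ] <- Re(stats::fft(f * mfull, inverse = TRUE)) / (d[3] * d[4])
  }
  out
}

#' Split a feature map into band-limited spatial components
#'
#' Each component is `irFFT2(mask * rFFT2(X))` with explicit output size
#' `(H, W)`; by linearity of the transform and the exact mask partition,
#' `low + mid + high` reconstructs `X`.
#'
#' @param x real array `(B, C, H, W)`.
#' @param masks a [make_band_masks()] object built for `(H, W)`.
#' @return list of real arrays `low`, `mid`, `high`, each shaped like `x`.
#' @export
band_split <- function(x, masks) {
  x <- as_nchw(x)
  d <- dim(x)
  if (masks$H != d[3] || masks$W != d[4]) {
    stop_invalid("masks built for (%d, %d) but feature map is (%d, %d)",
                 masks$H, masks$W, d[3], d[4])
  }
  mf <- masks_full(masks)
  lapply(mf, function(m) band_project_raw(x, m))
}

#' Initialise FEM parameters
#'
#' Per-band 1x1 convolutions reduce `C` to `C/rho` channels, each followed by
#' group normalisation (`groups` groups) and dropout; a two-layer 1x1 fusion
#' bottleneck (`3C/rho -> C/2 -> C`, rectifier in between) restores the
#' channel dimensionality. The final fusion layer is zero-initialised so the
#' module starts as an exact identity residual.
#'
#' @param C channel count of the feature map the FEM attaches to.
#' @param rho channel reduction ratio per band (default 4); must divide `C`.
#' @param groups group-norm group count; default `min(8, C/rho)` adjusted to
#'   the largest divisor of `C/rho` not exceeding 8.
#' @param p_band,p_residual dropout rates after band refinement and before
#'   the residual addition (defaults 0.1).
#' @param zero_init_fusion zero-initialise the final fusion layer (default
#'   TRUE).
#' @param seed integer seed for weight initialisation.
#' @return an object of class `fem_params`.
#' @export
fem_params <- function(C, rho = 4L, groups = NULL, p_band = 0.1,
                       p_residual = 0.1, zero_init_fusion = TRUE, seed = 1L) {
  if (C %% rho) stop_invalid("C (%d) must be divisible by rho (%d)", C, rho)
  cr <- C %/% rho
  if (is.null(groups)) {
    groups <- min(8L, cr)
    while (cr %% groups) groups <- groups - 1L
  }
  if (cr %% groups) stop_invalid("C/rho (%d) must be divisible by groups (%d)", cr, groups)
  if (p_band < 0 || p_band >= 1 || p_residual < 0 || p_residual >= 1) {
    stop_invalid("dropout rates must lie in [0, 1)")
  }
  ch <- C %/% 2L
  p <- with_seed(seed, {
    pr <- list()
    for (band in c("low", "mid", "high")) {
      pr[[paste0(band, ".w")]] <- he_init(cr, C, 1L)
      pr[[paste0(band, ".b")]] <- numeric(cr)
      pr[[paste0(band, ".gamma")]] <- rep(1, cr)
      pr[[paste0(band, ".beta")]] <- numeric(cr)
    }
    pr[["fuse1.w"]] <- he_init(ch, 3L * cr, 1L)
    pr[["fuse1.b"]] <- numeric(ch)
    pr[["fuse2.w"]] <- if (zero_init_fusion) array(0, c(C, ch, 1L, 1L)) else he_init(C, ch, 1L)
    pr[["fuse2.b"]] <- numeric(C)
    pr
  })
  structure(list(weights = p, C = C, rho = rho, groups = groups,
                 p_band = p_band, p_residual = p_residual),
            class = "fem_params")
}

#' Trainable parameter count of a FEM
#'
#' Closed form: `3(C*C/rho + C/rho) + 3*2*(C/rho) + (3C/rho*C/2 + C/2) +
#' (C/2*C + C)`.
#'
#' @param params a `fem_params` object, or a channel count `C` (then `rho`
#'   is taken from the second argument).
#' @param rho reduction ratio when `params` is a channel count.
#' @return integer parameter count.
#' @export
fem_param_count <- function(params, rho = 4L) {
  if (inherits(params, "fem_params")) {
    return(sum(vapply(params$weights, length, numeric(1))))
  }
  C <- params
  cr <- C / rho
  3 * (C * cr + cr) + 3 * 2 * cr + (3 * cr * (C / 2) + C / 2) + ((C / 2) * C + C)
}

conv1x1_raw <- function(x, w, b) conv2d_fwd(x, w, b)$out

#' Refine one band-limited component
#'
#' Applies the band's 1x1 convolution (`C -> C/rho`), group normalisation and
#' dropout (active only while `training`).
#'
#' @param xk band-limited feature map `(B, C, H, W)`.
#' @param params a [fem_params()] object.
#' @param band one of "low", "mid", "high".
#' @param training logical; enables dropout.
#' @return real array `(B, C/rho, H, W)`.
#' @export
refine_band <- function(xk, params, band = c("low", "mid", "high"),
                        training = FALSE) {
  band <- match.arg(band)
  xk <- as_nchw(xk)
  if (dim(xk)[2] != params$C) {
    stop_invalid("feature map has %d channels, FEM expects %d", dim(xk)[2], params$C)
  }
  w <- params$weights
  y <- conv1x1_raw(xk, w[[paste0(band, ".w")]], w[[paste0(band, ".b")]])
  y <- groupnorm_fwd(y, w[[paste0(band, ".gamma")]], w[[paste0(band, ".beta")]],
                     params$groups)$out
  if (training && params$p_band > 0) {
    keep <- array(stats::runif(length(y)) >= params$p_band, dim(y)) / (1 - params$p_band)
    y <- y * keep
  }
  y
}

#' Fuse refined band components
#'
#' Concatenates the three `C/rho`-channel bands, applies the first fusion
#' layer (1x1, rectifier) and the second fusion layer (1x1) restoring `C`
#' channels.
#'
#' @param f_low,f_mid,f_high refined bands `(B, C/rho, H, W)`.
#' @param params a [fem_params()] object.
#' @return real array `(B, C, H, W)`.
#' @export
fuse_bands <- function(f_low, f_mid, f_high, params) {
  f_low <- as_nchw(f_low); f_mid <- as_nchw(f_mid); f_high <- as_nchw(f_high)
  if (!identical(dim(f_low), dim(f_mid)) || !identical(dim(f_low), dim(f_high))) {
    stop_invalid("band shapes differ")
  }
  d <- dim(f_low)
  cat3 <- array(0, c(d[1], 3L * d[2], d[3], d[4]))
  cat3[, seq_len(d[2]), , ] <- f_low
  cat3[, d[2] + seq_len(d[2]), , ] <- f_mid
  cat3[, 2L * d[2] + seq_len(d[2]), , ] <- f_high
  w <- params$weights
  h <- conv1x1_raw(cat3, w[["fuse1.w"]], w[["fuse1.b"]])
  h <- h * (h > 0)
  conv1x1_raw(h, w[["fuse2.w"]], w[["fuse2.b"]])
}

#' Full FEM forward pass
#'
#' `Y = X + Dropout(fuse_bands(refine_band(band_split(X))))`. The module
#' refines rather than replaces features: with the final fusion layer zeroed
#' it is the identity map.
#'
#' @param x feature map `(B, C, H, W)`.
#' @param params a [fem_params()] object.
#' @param masks optional [make_band_masks()] object for `(H, W)`; built with
#'   default cutoffs when absent.
#' @param training logical; enables the two dropout sites.
#' @return array shaped like `x`.
#' @export
fem_forward <- function(x, params, masks = NULL, training = FALSE) {
  x <- as_nchw(x)
  d <- dim(x)
  if (is.null(masks)) masks <- make_band_masks(d[3], d[4])
  bands <- band_split(x, masks)
  f <- fuse_bands(refine_band(bands$low, params, "low", training),
                  refine_band(bands$mid, params, "mid", training),
                  refine_band(bands$high, params, "high", training),
                  params)
  if (training && params$p_residual > 0) {
    keep <- array(stats::runif(length(f)) >= params$p_residual, dim(f)) /
      (1 - params$p_residual)
    f <- f * keep
  }
  x + f
}

# Differentiable FEM used inside networks; pn is a named list of leaf nodes
# mirroring fem_params$weights (prefixed), mfull the precomputed full masks.
ag_fem <- function(g, x, pn, prefix, fem_cfg, mfull, training = FALSE) {
  bands <- list()
  for (band in c("low", "mid", "high")) {
    xb <- ag_band_project(g, x, mfull[[band]])
    y <- ag_conv2d(g, xb, pn[[paste0(prefix, band, ".w")]],
                   pn[[paste0(prefix, band, ".b")]])
    y <- ag_groupnorm(g, y, pn[[paste0(prefix, band, ".gamma")]],
                      pn[[paste0(prefix, band, ".beta")]], fem_cfg$groups)
    bands[[band]] <- ag_dropout(g, y, fem_cfg$p_band, training)
  }
  h <- ag_concat(g, bands)
  h <- ag_conv2d(g, h, pn[[paste0(prefix, "fuse1.w")]], pn[[paste0(prefix, "fuse1.b")]])
  h <- ag_relu(g, h)
  h <- ag_conv2d(g, h, pn[[paste0(prefix, "fuse2.w")]], pn[[paste0(prefix, "fuse2.b")]])
  h <- ag_dropout(g, h, fem_cfg$p_residual, training)
  ag_add(g, x, h)
}
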