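# Reverse-mode automatic differentiation over dense (B, C, H, W) arrays.
#
# Design: a graph environment holds a tape (creation-ordered list of nodes).
# Each node is an environment with $value, $grad, $parents and $backfn; the
# tape order is a valid topological order, so backpropagation is a single
# reverse sweep. Parameters enter a forward pass as leaf nodes wrapping plain
# arrays; after ag_backward() their gradients are read off the leaves.
# Everything is batch-last-free: layout is (B, C, H, W) throughout, matching
# the feature-map convention used by the spectral module.

ag_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$tape <- list()
  g$n <- 0L
  g
}

ag_node <- function(g, value, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  g$n <- g$n + 1L
  nd$id <- g$n
  g$tape[[g$n]] <- nd
  nd
}

ag_leaf <- function(g, value) ag_node(g, value)

ag_accum <- function(nd, grad) {
  if (is.null(nd$grad)) nd$grad <- grad else nd$grad <- nd$grad + grad
}

# Backward sweep from a scalar (or any) node; seeds with 1s.
ag_backward <- function(g, node) {
  node$grad <- array(1, dim = if (is.null(dim(node$value))) length(node$value) else dim(node$value))
  for (i in rev(seq_len(g$n))) {
    nd <- g$tape[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (j in seq_along(nd$parents)) {
      if (!is.null(gs[[j]])) ag_accum(nd$parents[[j]], gs[[j]])
    }
  }
  invisible(NULL)
}

## ---- elementwise ----------------------------------------------------------

ag_add <- function(g, a, b) {
  ag_node(g, a$value + b$value, list(a, b), function(gr) list(gr, gr))
}

ag_relu <- function(g, a) {
  m <- a$value > 0
  ag_node(g, a$value * m, list(a), function(gr) list(gr * m))
}

ag_sigmoid <- function(g, a) {
  s <- 1 / (1 + exp(-a$value))
  ag_node(g, s, list(a), function(gr) list(gr * s * (1 - s)))
}

ag_dropout <- function(g, a, p, training = FALSE) {
  if (!training || p <= 0) return(a)
  keep <- array(stats::runif(length(a$value)) >= p, dim = dim(a$value)) / (1 - p)
  ag_node(g, a$value * keep, list(a), function(gr) list(gr * keep))
}

## ---- structural -----------------------------------------------------------

ag_concat <- function(g, nodes) {
  vals <- lapply(nodes, function(n) n$value)
  d1 <- dim(vals[[1]])
  chans <- vapply(vals, function(v) dim(v)[2], integer(1))
  out <- array(0, c(d1[1], sum(chans), d1[3], d1[4]))
  at <- 0L
  for (v in vals) {
    out[, at + seq_len(dim(v)[2]), , ] <- v
    at <- at + dim(v)[2]
  }
  ag_node(g, out, nodes, function(gr) {
    at <- 0L
    lapply(chans, function(cc) {
      sl <- gr[, at + seq_len(cc), , , drop = FALSE]
      at <<- at + cc
      sl
    })
  })
}

ag_scale <- function(g, a, s) {
  ag_node(g, a$value * s, list(a), function(gr) list(gr * s))
}

ag_mean_of <- function(g, nodes) {
  k <- length(nodes)
  out <- Reduce(`+`, lapply(nodes, function(n) n$value)) / k
  ag_node(g, out, nodes, function(gr) rep(list(gr / k), k))
}

## ---- convolution ----------------------------------------------------------

pad_hw <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2], d[3] + 2L * pad, d[4] + 2L * pad))
  out[, , pad + seq_len(d[3]), pad + seq_len(d[4])] <- x
  out
}

# 2-D convolution (cross-correlation), weight (Cout, Cin, k, k).
# Implemented as k*k shifted GEMMs; supports stride, zero padding, dilation.
conv2d_fwd <- function(x, w, b = NULL, stride = 1L, pad = 0L, dilation = 1L) {
  d <- dim(x); B <- d[1]; C <- d[2]
  k <- dim(w)[3]; cout <- dim(w)[1]
  if (dim(w)[2] != C) stop_invalid("conv2d: input has %d channels, weight expects %d", C, dim(w)[2])
  xp <- pad_hw(x, pad)
  hp <- dim(xp)[3]; wp <- dim(xp)[4]
  span <- (k - 1L) * dilation + 1L
  oh <- (hp - span) %/% stride + 1L
  ow <- (wp - span) %/% stride + 1L
  if (oh < 1L || ow < 1L) stop_invalid("conv2d: spatial size too small for kernel")
  acc <- matrix(if (is.null(b)) 0 else b, nrow = cout, ncol = B * oh * ow)
  for (kh in seq_len(k)) {
    hs <- (kh - 1L) * dilation + 1L + (seq_len(oh) - 1L) * stride
    for (kw in seq_len(k)) {
      ws <- (kw - 1L) * dilation + 1L + (seq_len(ow) - 1L) * stride
      sl <- xp[, , hs, ws, drop = FALSE]
      m <- matrix(aperm(sl, c(2L, 1L, 3L, 4L)), nrow = C)
      acc <- acc + matrix(w[, , kh, kw], cout, C) %*% m
    }
  }
  list(out = aperm(array(acc, c(cout, B, oh, ow)), c(2L, 1L, 3L, 4L)),
       xp = xp, oh = oh, ow = ow)
}

conv2d_bwd <- function(gr, xp, w, stride, pad, dilation, oh, ow) {
  d <- dim(xp); B <- d[1]; C <- d[2]
  k <- dim(w)[3]; cout <- dim(w)[1]
  gm <- matrix(aperm(gr, c(2L, 1L, 3L, 4L)), nrow = cout)
  dxp <- array(0, d)
  dw <- array(0, dim(w))
  for (kh in seq_len(k)) {
    hs <- (kh - 1L) * dilation + 1L + (seq_len(oh) - 1L) * stride
    for (kw in seq_len(k)) {
      ws <- (kw - 1L) * dilation + 1L + (seq_len(ow) - 1L) * stride
      sl <- xp[, , hs, ws, drop = FALSE]
      m <- matrix(aperm(sl, c(2L, 1L, 3L, 4L)), nrow = C)
      dw[, , kh, kw] <- gm %*% t(m)
      dsl <- t(matrix(w[, , kh, kw], cout, C)) %*% gm  # C x (B*oh*ow)
      dxp[, , hs, ws] <- dxp[, , hs, ws, drop = FALSE] +
        aperm(array(dsl, c(C, B, oh, ow)), c(2L, 1L, 3L, 4L))
    }
  }
  dx <- if (pad > 0L) {
    dxp[, , pad + seq_len(d[3] - 2L * pad), pad + seq_len(d[4] - 2L * pad), drop = FALSE]
  } else dxp
  list(dx = dx, dw = dw, db = rowSums(gm))
}

ag_conv2d <- function(g, x, w, b = NULL, stride = 1L, pad = 0L, dilation = 1L) {
  f <- conv2d_fwd(x$value, w$value, if (is.null(b)) NULL else b$value,
                  stride, pad, dilation)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(g, f$out, parents, function(gr) {
    bw <- conv2d_bwd(gr, f$xp, w$value, stride, pad, dilation, f$oh, f$ow)
    if (is.null(b)) list(bw$dx, bw$dw) else list(bw$dx, bw$dw, bw$db)
  })
}

# Transposed convolution with kernel size == stride (non-overlapping tiles);
# the form used by the U-Net decoder (2x2, stride 2).
ag_conv_transpose2d <- function(g, x, w, b = NULL, stride = 2L) {
  xv <- x$value; wv <- w$value
  d <- dim(xv); B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  k <- dim(wv)[3]
  if (k != stride) stop_invalid("conv_transpose2d: kernel size must equal stride here")
  cout <- dim(wv)[2]  # weight layout (Cin, Cout, k, k)
  out <- array(0, c(B, cout, H * stride, W * stride))
  if (!is.null(b)) for (cc in seq_len(cout)) out[, cc, , ] <- b$value[cc]
  xm <- matrix(aperm(xv, c(2L, 1L, 3L, 4L)), nrow = C)  # C x (B*H*W)
  for (kh in seq_len(k)) {
    hs <- kh + (seq_len(H) - 1L) * stride
    for (kw in seq_len(k)) {
      ws <- kw + (seq_len(W) - 1L) * stride
      o <- t(matrix(wv[, , kh, kw], C, cout)) %*% xm  # cout x (B*H*W)
      out[, , hs, ws] <- out[, , hs, ws, drop = FALSE] +
        aperm(array(o, c(cout, B, H, W)), c(2L, 1L, 3L, 4L))
    }
  }
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(g, out, parents, function(gr) {
    dx <- array(0, d)
    dw <- array(0, dim(wv))
    dxm <- matrix(0, C, B * H * W)
    for (kh in seq_len(k)) {
      hs <- kh + (seq_len(H) - 1L) * stride
      for (kw in seq_len(k)) {
        ws <- kw + (seq_len(W) - 1L) * stride
        gsl <- gr[, , hs, ws, drop = FALSE]
        gm <- matrix(aperm(gsl, c(2L, 1L, 3L, 4L)), nrow = cout)
        dw[, , kh, kw] <- xm %*% t(gm)
        dxm <- dxm + matrix(wv[, , kh, kw], C, cout) %*% gm
      }
    }
    dx <- aperm(array(dxm, c(C, B, H, W)), c(2L, 1L, 3L, 4L))
    db <- if (is.null(b)) NULL else {
      gm <- matrix(aperm(gr, c(2L, 1L, 3L, 4L)), nrow = cout)
      rowSums(gm)
    }
    if (is.null(b)) list(dx, dw) else list(dx, dw, db)
  })
}

## ---- pooling and resizing -------------------------------------------------

ag_maxpool2 <- function(g, x) {
  xv <- x$value
  d <- dim(xv)
  if (d[3] %% 2L || d[4] %% 2L) stop_invalid("maxpool2: H and W must be even")
  oh <- d[3] %/% 2L; ow <- d[4] %/% 2L
  hs <- seq(1L, d[3], by = 2L); ws <- seq(1L, d[4], by = 2L)
  offs <- list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  best <- xv[, , hs, ws, drop = FALSE]
  arg <- array(1L, dim(best))
  for (j in 2:4) {
    sl <- xv[, , hs + offs[[j]][1], ws + offs[[j]][2], drop = FALSE]
    m <- sl > best
    best[m] <- sl[m]
    arg[m] <- j
  }
  ag_node(g, best, list(x), function(gr) {
    dx <- array(0, d)
    for (j in 1:4) {
      m <- (arg == j) * gr
      dx[, , hs + offs[[j]][1], ws + offs[[j]][2]] <-
        dx[, , hs + offs[[j]][1], ws + offs[[j]][2], drop = FALSE] + m
    }
    list(dx)
  })
}

# Interpolation matrix (n_out x n_in) for 1-D bilinear resize with
# half-pixel (align_corners = FALSE) sampling.
bilinear_matrix <- function(n_out, n_in) {
  A <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    s <- (i - 0.5) * scale - 0.5  # 0-based source coordinate
    h0 <- floor(s)
    t <- s - h0
    lo <- min(max(h0, 0), n_in - 1)
    hi <- min(max(h0 + 1, 0), n_in - 1)
    A[i, lo + 1] <- A[i, lo + 1] + (1 - t)
    A[i, hi + 1] <- A[i, hi + 1] + t
  }
  A
}

resize_hw <- function(xv, oh, ow, Ah = NULL, Aw = NULL) {
  d <- dim(xv)
  if (is.null(Ah)) Ah <- bilinear_matrix(oh, d[3])
  if (is.null(Aw)) Aw <- bilinear_matrix(ow, d[4])
  m <- Ah %*% matrix(aperm(xv, c(3L, 1L, 2L, 4L)), nrow = d[3])
  y <- aperm(array(m, c(oh, d[1], d[2], d[4])), c(2L, 3L, 1L, 4L))
  m <- Aw %*% matrix(aperm(y, c(4L, 1L, 2L, 3L)), nrow = d[4])
  aperm(array(m, c(ow, d[1], d[2], oh)), c(2L, 3L, 4L, 1L))
}

ag_upsample_bilinear <- function(g, x, oh, ow) {
  d <- dim(x$value)
  Ah <- bilinear_matrix(oh, d[3]); Aw <- bilinear_matrix(ow, d[4])
  out <- resize_hw(x$value, oh, ow, Ah, Aw)
  ag_node(g, out, list(x), function(gr) {
    list(resize_hw(gr, d[3], d[4], t(Ah), t(Aw)))
  })
}

ag_global_avg_pool <- function(g, x) {
  d <- dim(x$value)
  out <- array(apply(x$value, c(1, 2), mean), c(d[1], d[2], 1L, 1L))
  ag_node(g, out, list(x), function(gr) {
    dx <- array(0, d)
    for (hh in seq_len(d[3])) for (ww in seq_len(d[4])) {
      dx[, , hh, ww] <- gr[, , 1L, 1L] / (d[3] * d[4])
    }
    list(dx)
  })
}

ag_broadcast_hw <- function(g, x, oh, ow) {
  d <- dim(x$value)
  out <- array(0, c(d[1], d[2], oh, ow))
  for (hh in seq_len(oh)) for (ww in seq_len(ow)) out[, , hh, ww] <- x$value[, , 1L, 1L]
  ag_node(g, out, list(x), function(gr) {
    list(array(apply(gr, c(1, 2), sum), c(d[1], d[2], 1L, 1L)))
  })
}

## ---- normalisation --------------------------------------------------------

groupnorm_fwd <- function(x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x); B <- d[1]; C <- d[2]
  if (C %% groups) stop_invalid("groupnorm: C (%d) not divisible by groups (%d)", C, groups)
  cg <- C %/% groups
  xhat <- array(0, d); isd <- matrix(0, B, groups)
  for (b in seq_len(B)) for (gidx in seq_len(groups)) {
    ch <- (gidx - 1L) * cg + seq_len(cg)
    sl <- x[b, ch, , , drop = FALSE]
    mu <- mean(sl)
    v <- mean((sl - mu)^2)
    isd[b, gidx] <- 1 / sqrt(v + eps)
    xhat[b, ch, , ] <- (sl - mu) * isd[b, gidx]
  }
  out <- xhat
  for (cc in seq_len(C)) out[, cc, , ] <- xhat[, cc, , ] * gamma[cc] + beta[cc]
  list(out = out, xhat = xhat, isd = isd)
}

ag_groupnorm <- function(g, x, gamma, beta, groups, eps = 1e-5) {
  f <- groupnorm_fwd(x$value, gamma$value, beta$value, groups, eps)
  d <- dim(x$value); B <- d[1]; C <- d[2]; cg <- C %/% groups
  ag_node(g, f$out, list(x, gamma, beta), function(gr) {
    dgamma <- numeric(C); dbeta <- numeric(C)
    for (cc in seq_len(C)) {
      dgamma[cc] <- sum(gr[, cc, , ] * f$xhat[, cc, , ])
      dbeta[cc] <- sum(gr[, cc, , ])
    }
    dxh <- gr
    for (cc in seq_len(C)) dxh[, cc, , ] <- gr[, cc, , ] * gamma$value[cc]
    dx <- array(0, d)
    for (b in seq_len(B)) for (gidx in seq_len(groups)) {
      ch <- (gidx - 1L) * cg + seq_len(cg)
      xh <- f$xhat[b, ch, , , drop = FALSE]
      dh <- dxh[b, ch, , , drop = FALSE]
      m1 <- mean(dh); m2 <- mean(dh * xh)
      dx[b, ch, , ] <- (dh - m1 - xh * m2) * f$isd[b, gidx]
    }
    list(dx, dgamma, dbeta)
  })
}

## ---- spectral projection --------------------------------------------------

# Band-limited reconstruction irFFT2(mask * rFFT2(x)) as a differentiable op.
# The operator is an orthogonal projection onto the masked Fourier modes, so
# it is self-adjoint: the backward pass applies the same projection to the
# incoming gradient.
ag_band_project <- function(g, x, mask_full) {
  out <- band_project_raw(x$value, mask_full)
  ag_node(g, out, list(x), function(gr) list(band_project_raw(gr, mask_full)))
}

## ---- dense / losses -------------------------------------------------------

ag_linear <- function(g, x, w, b) {
  out <- x$value %*% t(w$value)
  out <- sweep(out, 2L, b$value, `+`)
  ag_node(g, out, list(x, w, b), function(gr) {
    list(gr %*% w$value, t(gr) %*% x$value, colSums(gr))
  })
}

# Soft Dice loss on logits; per-image Dice over all pixels, mean(1 - dice).
ag_dice_loss <- function(g, logits, target, smooth = 1e-6) {
  z <- logits$value
  p <- 1 / (1 + exp(-z))
  d <- dim(z); B <- d[1]
  loss <- 0
  numer <- numeric(B); denom <- numeric(B)
  for (b in seq_len(B)) {
    pb <- p[b, , , ]; tb <- target[b, , , ]
    numer[b] <- 2 * sum(pb * tb) + smooth
    denom[b] <- sum(pb) + sum(tb) + smooth
    loss <- loss + (1 - numer[b] / denom[b])
  }
  loss <- loss / B
  ag_node(g, loss, list(logits), function(gr) {
    gs <- as.numeric(gr)
    dz <- array(0, d)
    for (b in seq_len(B)) {
      pb <- p[b, , , ]; tb <- target[b, , , ]
      ddice_dp <- (2 * tb * denom[b] - numer[b]) / denom[b]^2
      dz[b, , , ] <- -(gs / B) * ddice_dp * pb * (1 - pb)
    }
    list(dz)
  })
}

# Focal loss on class logits (B x K), integer labels in 1..K.
ag_focal_loss <- function(g, logits, labels, alpha = 1, gamma = 0) {
  z <- logits$value
  B <- nrow(z); K <- ncol(z)
  zs <- z - apply(z, 1, max)
  ez <- exp(zs)
  p <- ez / rowSums(ez)
  if (length(alpha) == 1L) alpha <- rep(alpha, K)
  iy <- cbind(seq_len(B), labels)
  u <- pmax(p[iy], 1e-12)
  a <- alpha[labels]
  li <- -a * (1 - u)^gamma * log(u)
  loss <- mean(li)
  ag_node(g, loss, list(logits), function(gr) {
    gs <- as.numeric(gr)
    dz <- matrix(0, B, K)
    # dL/du for each sample, then chain through softmax: du/dz_k = u*(delta - p_k)
    dLdu <- a * gamma * (1 - u)^(pmax(gamma - 1, 0)) * log(u) - a * (1 - u)^gamma / u
    if (gamma == 0) dLdu <- -a / u
    for (b in seq_len(B)) {
      delta <- numeric(K); delta[labels[b]] <- 1
      dz[b, ] <- (gs / B) * dLdu[b] * u[b] * (delta - p[b, ])
    }
    list(dz)
  })
}
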