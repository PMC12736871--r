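# Segmentation and classification network builders on the autograd engine.
#
# A network object holds a flat named list of parameter arrays and a forward
# closure `function(g, pn, x, training)` where `pn` is the corresponding list
# of leaf nodes. Builders share a staged-encoder contract: four feature
# stages with declared channel counts and strides, the deepest optionally
# passed through the FEM (FADeepLabV3) before the ASPP decoder.

gn_groups <- function(C) {
  g <- min(8L, C)
  while (C %% g) g <- g - 1L
  g
}

# parameter-store helpers (env with $p named list)
p_new <- function() {
  e <- new.env(parent = emptyenv())
  e$p <- list()
  e
}
p_conv <- function(st, name, cout, cin, k) {
  st$p[[paste0(name, ".w")]] <- he_init(cout, cin, k)
  st$p[[paste0(name, ".b")]] <- numeric(cout)
}
p_convT <- function(st, name, cin, cout, k) {
  fan <- cin * k * k
  st$p[[paste0(name, ".w")]] <- array(stats::rnorm(cin * cout * k * k, sd = sqrt(2 / fan)),
                                      c(cin, cout, k, k))
  st$p[[paste0(name, ".b")]] <- numeric(cout)
}
p_gn <- function(st, name, C) {
  st$p[[paste0(name, ".gamma")]] <- rep(1, C)
  st$p[[paste0(name, ".beta")]] <- numeric(C)
}

f_conv <- function(g, pn, name, x, stride = 1L, pad = 0L, dil = 1L) {
  ag_conv2d(g, x, pn[[paste0(name, ".w")]], pn[[paste0(name, ".b")]],
            stride = stride, pad = pad, dilation = dil)
}
f_convT <- function(g, pn, name, x, stride = 2L) {
  ag_conv_transpose2d(g, x, pn[[paste0(name, ".w")]], pn[[paste0(name, ".b")]],
                      stride = stride)
}
f_gn <- function(g, pn, name, x, groups) {
  ag_groupnorm(g, x, pn[[paste0(name, ".gamma")]], pn[[paste0(name, ".beta")]], groups)
}
# conv -> group norm -> rectifier
f_cgr <- function(g, pn, name, x, groups, stride = 1L, pad = 0L, dil = 1L) {
  ag_relu(g, f_gn(g, pn, name, f_conv(g, pn, name, x, stride, pad, dil), groups))
}
p_cgr <- function(st, name, cout, cin, k) {
  p_conv(st, name, cout, cin, k)
  p_gn(st, name, cout)
}

## ---- staged encoders ------------------------------------------------------

# Tiny four-stage encoder for CPU-scale work: channels 8/16/32/64,
# strides 2/4/8/16 (deepest possibly atrous-substituted by output_stride).
encoder_tiny <- function(st, prefix, in_channels = 3L, output_stride = 16L) {
  ch <- c(8L, 16L, 32L, 64L)
  strides <- c(2L, 4L, 8L, 16L)
  last_stride <- 2L; last_dil <- 1L
  if (output_stride == 8L) { last_stride <- 1L; last_dil <- 2L; strides[4] <- 8L }
  cin <- in_channels
  for (i in 1:4) p_cgr(st, paste0(prefix, "s", i), ch[i], if (i == 1) cin else ch[i - 1], 3L)
  list(
    channels = ch, strides = strides,
    forward = function(g, pn, x, training = FALSE) {
      s <- vector("list", 4L)
      h <- x
      for (i in 1:4) {
        stride <- if (i == 4L) last_stride else 2L
        dil <- if (i == 4L) last_dil else 1L
        h <- f_cgr(g, pn, paste0(prefix, "s", i), h, gn_groups(ch[i]),
                   stride = stride, pad = dil, dil = dil)
        s[[i]] <- h
      }
      s
    })
}

# ResNet18-style staged encoder (two basic blocks per stage, group norm,
# random initialisation; pretrained passthrough is not shipped).
encoder_resnet18 <- function(st, prefix, in_channels = 3L, output_stride = 16L) {
  ch <- c(64L, 128L, 256L, 512L)
  strides <- c(4L, 8L, 16L, 32L)
  stage_stride <- c(1L, 2L, 2L, 2L)
  stage_dil <- c(1L, 1L, 1L, 1L)
  if (output_stride <= 16L) { stage_stride[4] <- 1L; stage_dil[4] <- 2L; strides[4] <- 16L }
  if (output_stride <= 8L) {
    stage_stride[3] <- 1L; stage_dil[3] <- 2L; stage_dil[4] <- 4L
    strides[3] <- 8L; strides[4] <- 8L
  }
  p_cgr(st, paste0(prefix, "stem"), 64L, in_channels, 7L)
  for (i in 1:4) for (blk in 1:2) {
    cin <- if (blk == 1L) (if (i == 1L) 64L else ch[i - 1]) else ch[i]
    nm <- paste0(prefix, "l", i, "b", blk)
    p_cgr(st, paste0(nm, ".c1"), ch[i], cin, 3L)
    p_conv(st, paste0(nm, ".c2"), ch[i], ch[i], 3L)
    p_gn(st, paste0(nm, ".c2"), ch[i])
    if (blk == 1L && (cin != ch[i] || stage_stride[i] != 1L)) {
      p_conv(st, paste0(nm, ".down"), ch[i], cin, 1L)
      p_gn(st, paste0(nm, ".down"), ch[i])
    }
  }
  basic_block <- function(g, pn, nm, x, cout, stride, dil, has_down) {
    h <- f_cgr(g, pn, paste0(nm, ".c1"), x, gn_groups(cout),
               stride = stride, pad = dil, dil = dil)
    h <- f_gn(g, pn, paste0(nm, ".c2"),
              f_conv(g, pn, paste0(nm, ".c2"), h, 1L, dil, dil), gn_groups(cout))
    sk <- if (has_down) {
      f_gn(g, pn, paste0(nm, ".down"),
           f_conv(g, pn, paste0(nm, ".down"), x, stride, 0L, 1L), gn_groups(cout))
    } else x
    ag_relu(g, ag_add(g, h, sk))
  }
  list(
    channels = ch, strides = strides,
    forward = function(g, pn, x, training = FALSE) {
      h <- f_cgr(g, pn, paste0(prefix, "stem"), x, gn_groups(64L), stride = 2L, pad = 3L)
      h <- ag_maxpool2(g, h)
      s <- vector("list", 4L)
      for (i in 1:4) {
        for (blk in 1:2) {
          nm <- paste0(prefix, "l", i, "b", blk)
          cin <- if (blk == 1L) (if (i == 1L) 64L else ch[i - 1]) else ch[i]
          stridei <- if (blk == 1L) stage_stride[i] else 1L
          has_down <- blk == 1L && (cin != ch[i] || stage_stride[i] != 1L)
          h <- basic_block(g, pn, nm, h, ch[i], stridei, stage_dil[i], has_down)
        }
        s[[i]] <- h
      }
      s
    })
}

build_encoder <- function(st, kind, in_channels = 3L, output_stride = 16L) {
  switch(kind,
         tiny = encoder_tiny(st, "enc.", in_channels, output_stride),
         resnet18 = encoder_resnet18(st, "enc.", in_channels, output_stride),
         stop_invalid("unknown encoder kind '%s'", kind))
}

#' Segmentation model configuration
#'
#' @param decoder_kind one of "unet", "unetpp", "deeplabv3", "fadeeplabv3".
#' @param encoder_kind "resnet18" (default) or "tiny" (a small four-stage
#'   encoder for CPU-scale experiments). Both satisfy the staged-encoder
#'   contract: four feature stages with declared channel counts.
#' @param num_classes number of logit channels (1 = binary lesion mask).
#' @param aspp_rates strictly increasing atrous rates, default `c(6, 12, 18)`.
#' @param output_stride ratio of input to deepest feature resolution; one of
#'   8, 16 (default), 32.
#' @param unetpp_mode "accurate" (branch outputs averaged) or "fast" (single
#'   deepest-supervision branch).
#' @param fem optional list of FEM settings (`rho`, `cutoffs`, `p_band`,
#'   `p_residual`, `groups`); required decoder input for "fadeeplabv3".
#' @param pretrained request pretrained encoder weights (not shipped; must
#'   remain FALSE).
#' @param seed integer seed for weight initialisation.
#' @return a `seg_config` list.
#' @export
seg_config <- function(decoder_kind = c("unet", "unetpp", "deeplabv3", "fadeeplabv3"),
                       encoder_kind = "resnet18", num_classes = 1L,
                       aspp_rates = c(6L, 12L, 18L), output_stride = 16L,
                       unetpp_mode = c("accurate", "fast"), fem = list(),
                       pretrained = FALSE, seed = 1L) {
  decoder_kind <- match.arg(decoder_kind)
  unetpp_mode <- match.arg(unetpp_mode)
  if (any(diff(aspp_rates) <= 0)) stop_invalid("aspp_rates must be strictly increasing")
  if (!output_stride %in% c(8L, 16L, 32L)) stop_invalid("output_stride must be 8, 16 or 32")
  if (isTRUE(pretrained)) stop_invalid("pretrained weights are not shipped with this package")
  structure(list(decoder_kind = decoder_kind, encoder_kind = encoder_kind,
                 num_classes = as.integer(num_classes), aspp_rates = aspp_rates,
                 output_stride = as.integer(output_stride),
                 unetpp_mode = unetpp_mode, fem = fem, seed = as.integer(seed)),
            class = "seg_config")
}

new_seg_network <- function(config, st, forward) {
  structure(list(config = config, params = st$p, forward = forward),
            class = "seg_network")
}

## ---- U-Net ----------------------------------------------------------------

#' Build a U-Net segmentation network
#'
#' Encoder stages feed a mirrored decoder; each decoder level upsamples by 2
#' with a transposed convolution, concatenates the matching encoder stage
#' (exactly two sources per level) and applies two 3x3 convolution + group
#' norm + rectifier blocks. Remaining stride to full resolution is recovered
#' with further transposed convolutions, and a final 1x1 projection emits
#' per-pixel logits at input resolution.
#'
#' @param config a [seg_config()] with `decoder_kind = "unet"`.
#' @return a `seg_network` object.
#' @export
build_unet <- function(config) {
  if (config$decoder_kind != "unet") stop_invalid("config$decoder_kind must be 'unet'")
  st <- p_new()
  with_seed(sub_seed(config$seed, "unet-init"), {
    enc <- build_encoder(st, config$encoder_kind, output_stride = 32L)
    ch <- enc$channels; sr <- enc$strides
    if (length(ch) < 4L) stop_invalid("encoder must expose 4 stages")
    for (lvl in 3:1) {
      p_convT(st, paste0("dec", lvl, ".up"), ch[lvl + 1], ch[lvl], 2L)
      p_cgr(st, paste0("dec", lvl, ".c1"), ch[lvl], 2L * ch[lvl], 3L)
      p_cgr(st, paste0("dec", lvl, ".c2"), ch[lvl], ch[lvl], 3L)
    }
    n_up <- as.integer(round(log2(sr[1])))
    cprev <- ch[1]
    for (u in seq_len(n_up)) {
      cnext <- max(16L, cprev %/% 2L)
      p_convT(st, paste0("head.up", u), cprev, cnext, 2L)
      p_cgr(st, paste0("head.c", u), cnext, cnext, 3L)
      cprev <- cnext
    }
    p_conv(st, "head.proj", config$num_classes, cprev, 1L)
  })
  forward <- function(g, pn, x, training = FALSE) {
      s <- enc$forward(g, pn, x, training)
      ch <- enc$channels
      h <- s[[4]]
      for (lvl in 3:1) {
        up <- f_convT(g, pn, paste0("dec", lvl, ".up"), h)
        h <- ag_concat(g, list(up, s[[lvl]]))
        h <- f_cgr(g, pn, paste0("dec", lvl, ".c1"), h, gn_groups(ch[lvl]), pad = 1L)
        h <- f_cgr(g, pn, paste0("dec", lvl, ".c2"), h, gn_groups(ch[lvl]), pad = 1L)
      }
      n_up <- as.integer(round(log2(enc$strides[1])))
      for (u in seq_len(n_up)) {
        h <- f_convT(g, pn, paste0("head.up", u), h)
        cc <- dim(h$value)[2]
        h <- f_cgr(g, pn, paste0("head.c", u), h, gn_groups(cc), pad = 1L)
      }
      f_conv(g, pn, "head.proj", h)
  }
  new_seg_network(config, st, forward)
}

## ---- U-Net++ --------------------------------------------------------------

#' Build a U-Net++ segmentation network
#'
#' Nested dense skip pathways: node `X[i,j]` receives the concatenation of
#' all same-level predecessors `X[i,0..j-1]` plus the upsampled deeper node
#' `X[i+1,j-1]`. Deep supervision attaches a 1x1 segmentation head to every
#' top-level node `X[0,j]`; in "accurate" mode the branch outputs are
#' averaged, in "fast" mode the deepest-supervision branch alone is returned.
#'
#' @param config a [seg_config()] with `decoder_kind = "unetpp"`.
#' @return a `seg_network` object.
#' @export
build_unetpp <- function(config) {
  if (config$decoder_kind != "unetpp") stop_invalid("config$decoder_kind must be 'unetpp'")
  st <- p_new()
  with_seed(sub_seed(config$seed, "unetpp-init"), {
    enc <- build_encoder(st, config$encoder_kind, output_stride = 32L)
    ch <- enc$channels
    for (i in 0:2) for (j in 1:(3 - i)) {
      nm <- sprintf("x%d%d", i, j)
      p_convT(st, paste0(nm, ".up"), ch[i + 2], ch[i + 1], 2L)
      cin <- j * ch[i + 1] + ch[i + 1]   # j same-level inputs + upsampled
      p_cgr(st, paste0(nm, ".c1"), ch[i + 1], cin, 3L)
      p_cgr(st, paste0(nm, ".c2"), ch[i + 1], ch[i + 1], 3L)
    }
    for (j in 1:3) p_conv(st, sprintf("head%d", j), config$num_classes, ch[1], 1L)
  })
  forward <- function(g, pn, x, training = FALSE) {
    s <- enc$forward(g, pn, x, training)
    ch <- enc$channels
    node <- list()
    for (i in 0:3) node[[sprintf("%d.0", i)]] <- s[[i + 1]]
    for (j in 1:3) for (i in 0:(3 - j)) {
      nm <- sprintf("x%d%d", i, j)
      up <- f_convT(g, pn, paste0(nm, ".up"), node[[sprintf("%d.%d", i + 1, j - 1)]])
      preds <- lapply(0:(j - 1), function(jj) node[[sprintf("%d.%d", i, jj)]])
      h <- ag_concat(g, c(preds, list(up)))
      h <- f_cgr(g, pn, paste0(nm, ".c1"), h, gn_groups(ch[i + 1]), pad = 1L)
      h <- f_cgr(g, pn, paste0(nm, ".c2"), h, gn_groups(ch[i + 1]), pad = 1L)
      node[[sprintf("%d.%d", i, j)]] <- h
    }
    d <- dim(x$value)
    branches <- lapply(1:3, function(j) {
      lg <- f_conv(g, pn, sprintf("head%d", j), node[[sprintf("0.%d", j)]])
      ag_upsample_bilinear(g, lg, d[3], d[4])
    })
    if (config$unetpp_mode == "accurate") ag_mean_of(g, branches) else branches[[3]]
  }
  net <- new_seg_network(config, st, forward)
  net$branch_forward <- function(g, pn, x, training = FALSE) {
    # all branch maps, for deep supervision and the averaging contract
    s <- enc$forward(g, pn, x, training)
    ch <- enc$channels
    node <- list()
    for (i in 0:3) node[[sprintf("%d.0", i)]] <- s[[i + 1]]
    for (j in 1:3) for (i in 0:(3 - j)) {
      nm <- sprintf("x%d%d", i, j)
      up <- f_convT(g, pn, paste0(nm, ".up"), node[[sprintf("%d.%d", i + 1, j - 1)]])
      preds <- lapply(0:(j - 1), function(jj) node[[sprintf("%d.%d", i, jj)]])
      h <- ag_concat(g, c(preds, list(up)))
      h <- f_cgr(g, pn, paste0(nm, ".c1"), h, gn_groups(ch[i + 1]), pad = 1L)
      h <- f_cgr(g, pn, paste0(nm, ".c2"), h, gn_groups(ch[i + 1]), pad = 1L)
      node[[sprintf("%d.%d", i, j)]] <- h
    }
    d <- dim(x$value)
    lapply(1:3, function(j) {
      lg <- f_conv(g, pn, sprintf("head%d", j), node[[sprintf("0.%d", j)]])
      ag_upsample_bilinear(g, lg, d[3], d[4])
    })
  }
  net
}

## ---- DeepLabV3 / FADeepLabV3 ---------------------------------------------

aspp_channels_for <- function(cdeep) max(32L, cdeep %/% 2L)

init_aspp <- function(st, cdeep, A, rates, num_classes) {
  p_cgr(st, "aspp.b1", A, cdeep, 1L)
  for (i in seq_along(rates)) p_cgr(st, paste0("aspp.r", rates[i]), A, cdeep, 3L)
  p_cgr(st, "aspp.img", A, cdeep, 1L)
  p_cgr(st, "aspp.proj", A, 5L * A, 1L)
  p_conv(st, "head.cls", num_classes, A, 1L)
}

forward_aspp <- function(g, pn, deep, A, rates, num_classes, in_hw) {
  d <- dim(deep$value)
  br <- list(f_cgr(g, pn, "aspp.b1", deep, gn_groups(A)))
  for (r in rates) {
    br[[length(br) + 1L]] <- f_cgr(g, pn, paste0("aspp.r", r), deep, gn_groups(A),
                                   pad = as.integer(r), dil = as.integer(r))
  }
  img <- ag_global_avg_pool(g, deep)
  img <- f_cgr(g, pn, "aspp.img", img, gn_groups(A))
  br[[length(br) + 1L]] <- ag_broadcast_hw(g, img, d[3], d[4])
  h <- ag_concat(g, br)
  h <- f_cgr(g, pn, "aspp.proj", h, gn_groups(A))
  lg <- f_conv(g, pn, "head.cls", h)
  ag_upsample_bilinear(g, lg, in_hw[1], in_hw[2])
}

build_deeplab_family <- function(config, with_fem) {
  st <- p_new()
  fem_cfg <- NULL
  with_seed(sub_seed(config$seed, "deeplab-init"), {
    enc <- build_encoder(st, config$encoder_kind, output_stride = config$output_stride)
    cdeep <- enc$channels[4]
    A <- config$fem$aspp_channels
    if (is.null(A)) A <- aspp_channels_for(cdeep)
    if (with_fem) {
      rho <- config$fem$rho %||% 4L
      if (cdeep %% rho) stop_invalid("FEM rho (%d) must divide deepest channels (%d)", rho, cdeep)
      fp <- fem_params(cdeep, rho = rho, groups = config$fem$groups,
                       p_band = config$fem$p_band %||% 0.1,
                       p_residual = config$fem$p_residual %||% 0.1,
                       zero_init_fusion = config$fem$zero_init_fusion %||% TRUE,
                       seed = sub_seed(config$seed, "fem-init"))
      for (nm in names(fp$weights)) st$p[[paste0("fem.", nm)]] <- fp$weights[[nm]]
      fem_cfg <- fp[c("C", "rho", "groups", "p_band", "p_residual")]
      fem_cfg$cutoffs <- config$fem$cutoffs %||% c(1 / 3, 2 / 3)
    }
    init_aspp(st, cdeep, A, config$aspp_rates, config$num_classes)
  })
  A_used <- if (is.null(config$fem$aspp_channels)) aspp_channels_for(enc$channels[4]) else config$fem$aspp_channels
  mask_cache <- new.env(parent = emptyenv())
  forward <- function(g, pn, x, training = FALSE) {
    s <- enc$forward(g, pn, x, training)
    deep <- s[[4]]
    if (with_fem) {
      dd <- dim(deep$value)
      key <- paste(dd[3], dd[4], sep = "x")
      if (is.null(mask_cache[[key]])) {
        mask_cache[[key]] <- masks_full(make_band_masks(dd[3], dd[4], fem_cfg$cutoffs))
      }
      deep <- ag_fem(g, deep, pn, "fem.", fem_cfg, mask_cache[[key]], training)
    }
    d <- dim(x$value)
    forward_aspp(g, pn, deep, A_used, config$aspp_rates, config$num_classes, d[3:4])
  }
  net <- new_seg_network(config, st, forward)
  net$fem_cfg <- fem_cfg
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a DeepLabV3 segmentation network
#'
#' Atrous spatial pyramid pooling over the deepest encoder stage with five
#' branches: a 1x1 convolution, three 3x3 atrous convolutions at the
#' configured rates, and global average pooling followed by a 1x1 convolution
#' and upsampling. Branch outputs are concatenated, projected by 1x1
#' convolution, mapped to class logits and bilinearly upsampled to input
#' resolution.
#'
#' @param config a [seg_config()] with `decoder_kind = "deeplabv3"`.
#' @return a `seg_network` object.
#' @export
build_deeplabv3 <- function(config) {
  if (config$decoder_kind != "deeplabv3") stop_invalid("config$decoder_kind must be 'deeplabv3'")
  build_deeplab_family(config, with_fem = FALSE)
}

#' Build a FADeepLabV3 segmentation network
#'
#' Identical to [build_deeplabv3()] except that the deepest encoder stage is
#' passed through the frequency-domain feature enhancement module
#' ([fem_forward()]) before the ASPP decoder. With the FEM's final fusion
#' layer zero-initialised (the default) the network is functionally
#' identical to DeepLabV3 at initialisation.
#'
#' @param config a [seg_config()] with `decoder_kind = "fadeeplabv3"`.
#' @return a `seg_network` object.
#' @export
build_fadeeplabv3 <- function(config) {
  if (config$decoder_kind != "fadeeplabv3") stop_invalid("config$decoder_kind must be 'fadeeplabv3'")
  build_deeplab_family(config, with_fem = TRUE)
}

#' Build any configured segmentation network
#'
#' Dispatches on `config$decoder_kind`.
#'
#' @param config a [seg_config()].
#' @return a `seg_network` object.
#' @export
build_segmenter <- function(config) {
  switch(config$decoder_kind,
         unet = build_unet(config),
         unetpp = build_unetpp(config),
         deeplabv3 = build_deeplabv3(config),
         fadeeplabv3 = build_fadeeplabv3(config))
}

#' Run a segmentation network on an image batch
#'
#' @param net a `seg_network`.
#' @param x array `(B, 3, H, W)` (or `(3, H, W)`).
#' @param training logical; enables dropout.
#' @param probs return sigmoid probabilities instead of logits.
#' @return array `(B, num_classes, H, W)`.
#' @export
forward_network <- function(net, x, training = FALSE, probs = FALSE) {
  x <- as_nchw(x)
  g <- ag_graph()
  pn <- lapply(net$params, function(v) ag_leaf(g, v))
  out <- net$forward(g, pn, ag_leaf(g, x), training)
  v <- out$value
  if (probs) v <- 1 / (1 + exp(-v))
  v
}

## ---- classification backbones --------------------------------------------

.backbone_registry <- new.env(parent = emptyenv())

#' Register a classification backbone constructor
#'
#' A constructor is `function(st, prefix, pretrained)` returning
#' `list(feature_dim, forward)` where `forward(g, pn, x, training)` maps an
#' image batch `(B, 3, H, W)` to pooled features `(B, feature_dim)`.
#'
#' @param name registry key.
#' @param constructor the constructor function.
#' @export
register_backbone <- function(name, constructor) {
  assign(name, constructor, envir = .backbone_registry)
  invisible(name)
}

backbone_tiny <- function(st, prefix, pretrained = FALSE) {
  enc <- encoder_tiny(st, prefix, output_stride = 16L)
  list(feature_dim = 64L,
       forward = function(g, pn, x, training = FALSE) {
         s <- enc$forward(g, pn, x, training)
         pooled <- ag_global_avg_pool(g, s[[4]])
         d <- dim(pooled$value)
         ag_node(g, matrix(pooled$value, d[1], d[2]), list(pooled), function(gr) {
           list(array(gr, d))
         })
       })
}

backbone_resnet18_cls <- function(st, prefix, pretrained = FALSE) {
  enc <- encoder_resnet18(st, prefix, output_stride = 32L)
  list(feature_dim = 512L,
       forward = function(g, pn, x, training = FALSE) {
         s <- enc$forward(g, pn, x, training)
         pooled <- ag_global_avg_pool(g, s[[4]])
         d <- dim(pooled$value)
         ag_node(g, matrix(pooled$value, d[1], d[2]), list(pooled), function(gr) {
           list(array(gr, d))
         })
       })
}

#' Classification model configuration
#'
#' @param backbone_name registry key ("tiny", "resnet18", or any
#'   user-registered backbone).
#' @param num_classes number of output classes (default 3:
#'   benign/normal/malignant).
#' @param pretrained request pretrained weights (not shipped; must be FALSE).
#' @param seed integer seed for initialisation.
#' @return a `cls_config` list.
#' @export
cls_config <- function(backbone_name = "resnet18", num_classes = 3L,
                       pretrained = FALSE, seed = 1L) {
  structure(list(backbone_name = backbone_name, num_classes = as.integer(num_classes),
                 pretrained = isTRUE(pretrained), seed = as.integer(seed)),
            class = "cls_config")
}

#' Attach a fresh classifier head to a backbone
#'
#' Builds (or rebuilds) the backbone named in the config and replaces its
#' final fully connected layer with a freshly initialised linear layer with
#' `num_classes` outputs; all other weights are untouched. Applying the
#' operation to an existing network replaces only the head, so the surgery
#' is idempotent in architecture.
#'
#' @param config a [cls_config()], or an existing `cls_network` whose head
#'   should be replaced.
#' @return a `cls_network` object.
#' @export
attach_classifier_head <- function(config) {
  if (inherits(config, "cls_network")) {
    net <- config
    fd <- net$feature_dim
    k <- net$config$num_classes
    with_seed(sub_seed(net$config$seed, "head-init"), {
      net$params[["head.w"]] <- matrix(stats::rnorm(k * fd, sd = sqrt(1 / fd)), k, fd)
      net$params[["head.b"]] <- numeric(k)
    })
    return(net)
  }
  ctor <- switch(config$backbone_name,
                 tiny = backbone_tiny,
                 resnet18 = backbone_resnet18_cls,
                 if (exists(config$backbone_name, envir = .backbone_registry)) {
                   get(config$backbone_name, envir = .backbone_registry)
                 } else {
                   stop_invalid("unknown backbone '%s'", config$backbone_name)
                 })
  if (config$pretrained) stop_invalid("pretrained weights are not shipped with this package")
  st <- p_new()
  bb <- with_seed(sub_seed(config$seed, "backbone-init"),
                  ctor(st, "bb.", config$pretrained))
  fd <- bb$feature_dim
  k <- config$num_classes
  with_seed(sub_seed(config$seed, "head-init"), {
    st$p[["head.w"]] <- matrix(stats::rnorm(k * fd, sd = sqrt(1 / fd)), k, fd)
    st$p[["head.b"]] <- numeric(k)
  })
  forward <- function(g, pn, x, training = FALSE) {
    feats <- bb$forward(g, pn, x, training)
    ag_linear(g, feats, pn[["head.w"]], pn[["head.b"]])
  }
  structure(list(config = config, params = st$p, forward = forward,
                 feature_dim = fd),
            class = "cls_network")
}
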