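# ---- convolutional backbones ------------------------------------------
#
# Faithful (architecture-level) implementations of the three feature
# extractors used by the classifiers: MobileNetV2 (inverted residual
# blocks with depthwise separable convolutions, 1,280 pooled features),
# DenseNet121 (densely connected blocks, 1,024 pooled features) and
# EfficientNetB0 (compound-scaled MBConv blocks with squeeze-excitation,
# 1,280 pooled features). Backbones are always frozen: weights are either
# randomly initialized (He for convolutions, identity batch-norm) from a
# seed, or supplied by the user. Convolutions run through float32
# im2col+GEMM kernels (src/conv_ops.cpp).

.he_conv <- function(k, cin, cout)
  matrix(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
         k * k * cin, cout)

.bn_init <- function(c)
  list(gamma = rep(1, c), beta = rep(0, c), mean = rep(0, c), var = rep(1, c))

.apply_bn <- function(x, bn, eps = 1e-3) {
  sc <- bn$gamma / sqrt(bn$var + eps)
  sh <- bn$beta - bn$mean * sc
  d <- dim(x)
  x * rep(sc, each = d[1] * d[2]) + rep(sh, each = d[1] * d[2])
}

.relu <- function(x) pmax(x, 0)
.relu6 <- function(x) pmin(pmax(x, 0), 6)
.swish <- function(x) x / (1 + exp(-x))

.conv <- function(x, w, k, stride = 1L, pad = (k - 1L) %/% 2L)
  .cpp_conv2d(x, w, as.integer(k), as.integer(stride), as.integer(pad))

.dwconv <- function(x, w, k, stride = 1L, pad = (k - 1L) %/% 2L)
  .cpp_depthwise(x, w, as.integer(k), as.integer(stride), as.integer(pad))

#' Global average pooling of a feature map
#'
#' Reduces each channel of an H x W x C feature tensor to its spatial
#' mean, yielding one value per channel.
#'
#' @param x H x W x C numeric array.
#' @return numeric vector of length C.
#' @export
global_avg_pool <- function(x) {
  d <- dim(x)
  colMeans(matrix(x, d[1] * d[2], d[3]))
}

# ---- MobileNetV2 -------------------------------------------------------

.mbv2_blocks <- list(  # expansion t, output channels c, repeats n, stride s
  list(t = 1, c = 16, n = 1, s = 1), list(t = 6, c = 24, n = 2, s = 2),
  list(t = 6, c = 32, n = 3, s = 2), list(t = 6, c = 64, n = 4, s = 2),
  list(t = 6, c = 96, n = 3, s = 1), list(t = 6, c = 160, n = 3, s = 2),
  list(t = 6, c = 320, n = 1, s = 1))

#' Random-frozen MobileNetV2 weights
#'
#' @param seed integer seed for the He-normal initialization.
#' @return weight list consumed by [backbone_forward()].
#' @export
mobilenet_v2_weights <- function(seed = 1L) with_seed(seed, {
  wts <- list(arch = "mobilenet_v2",
              stem = list(w = .he_conv(3, 3, 32), bn = .bn_init(32)))
  cin <- 32
  blocks <- list()
  for (g in .mbv2_blocks) for (i in seq_len(g$n)) {
    s <- if (i == 1) g$s else 1
    exp_c <- cin * g$t
    blk <- list(stride = s, use_res = (s == 1 && cin == g$c),
                expand = if (g$t > 1) list(w = .he_conv(1, cin, exp_c),
                                           bn = .bn_init(exp_c)),
                dw = list(w = matrix(stats::rnorm(9 * exp_c, 0, sqrt(2 / 9)),
                                     9, exp_c), bn = .bn_init(exp_c)),
                project = list(w = .he_conv(1, exp_c, g$c), bn = .bn_init(g$c)))
    blocks[[length(blocks) + 1L]] <- blk
    cin <- g$c
  }
  wts$blocks <- blocks
  wts$head <- list(w = .he_conv(1, cin, 1280), bn = .bn_init(1280))
  wts
})

.mbv2_forward <- function(wts, x) {
  x <- .relu6(.apply_bn(.conv(x, wts$stem$w, 3, 2), wts$stem$bn))
  for (blk in wts$blocks) {
    inp <- x
    if (!is.null(blk$expand))
      x <- .relu6(.apply_bn(.conv(x, blk$expand$w, 1), blk$expand$bn))
    x <- .relu6(.apply_bn(.dwconv(x, blk$dw$w, 3, blk$stride), blk$dw$bn))
    x <- .apply_bn(.conv(x, blk$project$w, 1), blk$project$bn)
    if (blk$use_res) x <- x + inp
  }
  x <- .relu6(.apply_bn(.conv(x, wts$head$w, 1), wts$head$bn))
  global_avg_pool(x)
}

# ---- DenseNet121 -------------------------------------------------------

#' Random-frozen DenseNet121 weights
#'
#' Dense blocks of 6/12/24/16 bottleneck layers, growth rate 32,
#' half-width transitions; final width 1,024.
#'
#' @param seed integer seed.
#' @return weight list consumed by [backbone_forward()].
#' @export
densenet121_weights <- function(seed = 1L) with_seed(seed, {
  growth <- 32L
  wts <- list(arch = "densenet121",
              stem = list(w = .he_conv(7, 3, 64), bn = .bn_init(64)))
  cin <- 64L
  blocks <- list()
  for (nl in c(6L, 12L, 24L, 16L)) {
    layers <- list()
    for (i in seq_len(nl)) {
      layers[[i]] <- list(bn1 = .bn_init(cin),
                          w1 = .he_conv(1, cin, 4L * growth),
                          bn2 = .bn_init(4L * growth),
                          w2 = .he_conv(3, 4L * growth, growth))
      cin <- cin + growth
    }
    blocks[[length(blocks) + 1L]] <- layers
    if (length(blocks) < 4L) {
      cout <- cin %/% 2L
      blocks[[length(blocks)]] <- list(layers = layers,
                                       transition = list(bn = .bn_init(cin),
                                                         w = .he_conv(1, cin, cout)))
      cin <- cout
    } else {
      blocks[[length(blocks)]] <- list(layers = layers, transition = NULL)
    }
  }
  wts$blocks <- blocks
  wts$final_bn <- .bn_init(cin)
  wts
})

.densenet_forward <- function(wts, x) {
  x <- .relu(.apply_bn(.conv(x, wts$stem$w, 7, 2, 3), wts$stem$bn))
  x <- .cpp_pool(x, 3L, 2L, 1L, TRUE)
  for (blk in wts$blocks) {
    for (ly in blk$layers) {
      y <- .relu(.apply_bn(x, ly$bn1))
      y <- .conv(y, ly$w1, 1)
      y <- .relu(.apply_bn(y, ly$bn2))
      y <- .conv(y, ly$w2, 3)
      d <- dim(x)
      x <- array(c(x, y), c(d[1], d[2], d[3] + dim(y)[3]))
    }
    if (!is.null(blk$transition)) {
      x <- .relu(.apply_bn(x, blk$transition$bn))
      x <- .conv(x, blk$transition$w, 1)
      x <- .cpp_pool(x, 2L, 2L, 0L, FALSE)
    }
  }
  x <- .relu(.apply_bn(x, wts$final_bn))
  global_avg_pool(x)
}

# ---- EfficientNetB0 ----------------------------------------------------

.effb0_blocks <- list(  # expansion t, kernel k, channels c, repeats n, stride s
  list(t = 1, k = 3, c = 16, n = 1, s = 1), list(t = 6, k = 3, c = 24, n = 2, s = 2),
  list(t = 6, k = 5, c = 40, n = 2, s = 2), list(t = 6, k = 3, c = 80, n = 3, s = 2),
  list(t = 6, k = 5, c = 112, n = 3, s = 1), list(t = 6, k = 5, c = 192, n = 4, s = 2),
  list(t = 6, k = 3, c = 320, n = 1, s = 1))

#' Random-frozen EfficientNetB0 weights
#'
#' MBConv blocks with squeeze-excitation (ratio 0.25) and swish
#' activation; the B0 variant fixes the compound-scaling coefficients, so
#' depth/width/resolution carry no free parameters here. Final width 1,280.
#'
#' @param seed integer seed.
#' @return weight list consumed by [backbone_forward()].
#' @export
efficientnet_b0_weights <- function(seed = 1L) with_seed(seed, {
  wts <- list(arch = "efficientnet_b0",
              stem = list(w = .he_conv(3, 3, 32), bn = .bn_init(32)))
  cin <- 32L
  blocks <- list()
  for (g in .effb0_blocks) for (i in seq_len(g$n)) {
    s <- if (i == 1) g$s else 1L
    exp_c <- as.integer(cin * g$t)
    se_c <- max(1L, as.integer(round(cin * 0.25)))
    blk <- list(stride = s, k = g$k, use_res = (s == 1 && cin == g$c),
                expand = if (g$t > 1) list(w = .he_conv(1, cin, exp_c),
                                           bn = .bn_init(exp_c)),
                dw = list(w = matrix(stats::rnorm(g$k^2 * exp_c, 0,
                                                  sqrt(2 / g$k^2)),
                                     g$k^2, exp_c), bn = .bn_init(exp_c)),
                se = list(w1 = matrix(stats::rnorm(exp_c * se_c, 0,
                                                   sqrt(2 / exp_c)), exp_c, se_c),
                          b1 = rep(0, se_c),
                          w2 = matrix(stats::rnorm(se_c * exp_c, 0,
                                                   sqrt(2 / se_c)), se_c, exp_c),
                          b2 = rep(0, exp_c)),
                project = list(w = .he_conv(1, exp_c, g$c), bn = .bn_init(g$c)))
    blocks[[length(blocks) + 1L]] <- blk
    cin <- g$c
  }
  wts$blocks <- blocks
  wts$head <- list(w = .he_conv(1, cin, 1280), bn = .bn_init(1280))
  wts
})

.effb0_forward <- function(wts, x) {
  x <- .swish(.apply_bn(.conv(x, wts$stem$w, 3, 2), wts$stem$bn))
  for (blk in wts$blocks) {
    inp <- x
    if (!is.null(blk$expand))
      x <- .swish(.apply_bn(.conv(x, blk$expand$w, 1), blk$expand$bn))
    x <- .swish(.apply_bn(.dwconv(x, blk$dw$w, blk$k, blk$stride), blk$dw$bn))
    z <- global_avg_pool(x)
    a <- .swish(drop(z %*% blk$se$w1) + blk$se$b1)
    gate <- 1 / (1 + exp(-(drop(a %*% blk$se$w2) + blk$se$b2)))
    d <- dim(x)
    x <- x * rep(gate, each = d[1] * d[2])
    x <- .apply_bn(.conv(x, blk$project$w, 1), blk$project$bn)
    if (blk$use_res) x <- x + inp
  }
  x <- .swish(.apply_bn(.conv(x, wts$head$w, 1), wts$head$bn))
  global_avg_pool(x)
}

# ---- shared entry point ------------------------------------------------

#' Feature dimension of a backbone
#' @param arch backbone name.
#' @return pooled feature length.
#' @export
backbone_feature_dim <- function(arch) {
  switch(arch,
         mobilenet_v2 = 1280L, densenet121 = 1024L,
         efficientnet_b0 = 1280L,
         stop("unknown backbone: ", arch))
}

# Per-architecture input normalization, following each backbone's
# published preprocessing convention; input in [0,1].
.preprocess_input <- function(x, arch) {
  if (arch == "mobilenet_v2") return(x * 2 - 1)
  mu <- c(0.485, 0.456, 0.406); sdv <- c(0.229, 0.224, 0.225)
  for (ch in 1:3) x[, , ch] <- (x[, , ch] - mu[ch]) / sdv[ch]
  x
}

#' Run a frozen backbone on one image
#'
#' @param wts weight list from one of the `*_weights()` constructors.
#' @param img H x W x 3 image in `[0,1]` or `[0,255]`, 224 x 224.
#' @return pooled feature vector (1,280 for MobileNetV2/EfficientNetB0,
#'   1,024 for DenseNet121).
#' @export
backbone_forward <- function(wts, img) {
  assert_rgb(img)
  d <- dim(img)
  if (d[1] != 224L || d[2] != 224L)
    stop("backbone input must be 224x224x3, got ", d[1], "x", d[2])
  x <- img / raster_scale(img)
  x <- .preprocess_input(x, wts$arch)
  switch(wts$arch,
         mobilenet_v2 = .mbv2_forward(wts, x),
         densenet121 = .densenet_forward(wts, x),
         efficientnet_b0 = .effb0_forward(wts, x),
         stop("unknown backbone: ", wts$arch))
}
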