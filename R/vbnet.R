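# The 2D VB-Net: a fully convolutional 5-level encoder-decoder for
# thick-slice axial MRI, with bottleneck-residual blocks, strided-conv
# down-sampling, transposed-conv up-sampling, per-level skip connections
# (concatenation) and a two-convolution output head producing per-class
# probabilities.  Being fully convolutional, it accepts any in-plane size
# divisible by 2^(levels-1); the crop size only fixes the training patches.

#' Configuration of the 2D VB-Net
#'
#' The default configuration has 5 levels with channel widths
#' 16/32/64/128/256, bottleneck reduction 4, encoder block counts
#' (1, 2, 3, 3, 3) and decoder block counts (1, 1, 2, 2) - the decoder
#' carries fewer bottleneck blocks than the encoder at the deep levels, a
#' trimming that keeps the model light.  With 3 input modalities and 3
#' output classes this totals 1,079,235 trainable parameters (~1.08 M).
#'
#' @param in_channels input channels (default 3: T1w, T2w, FLAIR).
#' @param out_channels output classes (default 3: background, WMH, other
#'   lesion).
#' @param levels encoder depth; level 1 is full resolution.
#' @param channels feature maps per level (non-decreasing with depth).
#' @param bottleneck_ratio channel reduction factor inside bottleneck
#'   blocks.
#' @param enc_blocks bottleneck-residual blocks per encoder level.
#' @param dec_blocks bottleneck-residual blocks per decoder level
#'   (levels 1 .. levels-1).
#' @param crop_size training patch edge in voxels; must be divisible by
#'   `2^(levels - 1)`.
#' @param bn_momentum,bn_eps batch-normalization running-statistics
#'   momentum and variance floor.
#' @return object of class `vbnet_config`.
#' @export
vbnet_config <- function(in_channels = 3L, out_channels = 3L,
                         levels = 5L,
                         channels = c(16L, 32L, 64L, 128L, 256L),
                         bottleneck_ratio = 4L,
                         enc_blocks = c(1L, 2L, 3L, 3L, 3L),
                         dec_blocks = c(1L, 1L, 2L, 2L),
                         crop_size = 256L,
                         bn_momentum = 0.1, bn_eps = 1e-5) {
  stopifnot(levels >= 2L, length(channels) == levels,
            all(diff(channels) >= 0),
            length(enc_blocks) == levels,
            length(dec_blocks) == levels - 1L,
            all(channels %% bottleneck_ratio == 0))
  if (crop_size %% 2^(levels - 1) != 0)
    stop("crop_size must be divisible by 2^(levels - 1)")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 levels = as.integer(levels),
                 channels = as.integer(channels),
                 bottleneck_ratio = as.integer(bottleneck_ratio),
                 enc_blocks = as.integer(enc_blocks),
                 dec_blocks = as.integer(dec_blocks),
                 crop_size = as.integer(crop_size),
                 bn_momentum = bn_momentum, bn_eps = bn_eps),
            class = "vbnet_config")
}

#' A reduced configuration for CPU-scale experiments
#'
#' Three levels, widths 8/16/32, bottleneck ratio 2, single blocks, 64-voxel
#' patches: small enough to train on a desktop CPU while exercising every
#' structural element of the full network.
#'
#' @param ... overrides passed to [vbnet_config()].
#' @export
vbnet_tiny_config <- function(...) {
  args <- list(levels = 3L, channels = c(8L, 16L, 32L),
               bottleneck_ratio = 2L, enc_blocks = c(1L, 1L, 1L),
               dec_blocks = c(1L, 1L), crop_size = 64L)
  do.call(vbnet_config, utils::modifyList(args, list(...)))
}

# --- graph construction -----------------------------------------------------

new_builder <- function(config) {
  env <- new.env()
  env$nodes <- list(list(id = "input", op = "input", inputs = character(0)))
  env$shapes <- list()
  env$config <- config
  env
}

add_node <- function(b, id, op, inputs, args = list(), params = list()) {
  node <- c(list(id = id, op = op, inputs = inputs, args = args), params)
  b$nodes[[length(b$nodes) + 1L]] <- node
  id
}

add_conv <- function(b, id, input, k, cin, cout, stride = 1L, pad = NULL) {
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  wn <- paste0(id, ".w"); bn <- paste0(id, ".b")
  b$shapes[[wn]] <- c(k, k, cin, cout)
  b$shapes[[bn]] <- cout
  add_node(b, id, "conv", input,
           args = list(stride = as.integer(stride), pad = as.integer(pad)),
           params = list(w = wn, b = bn))
}

add_tconv <- function(b, id, input, k, cin, cout, stride) {
  wn <- paste0(id, ".w"); bn <- paste0(id, ".b")
  b$shapes[[wn]] <- c(k, k, cout, cin)   # stored in virtual-conv orientation
  b$shapes[[bn]] <- cout
  add_node(b, id, "tconv", input,
           args = list(k = as.integer(k), stride = as.integer(stride)),
           params = list(w = wn, b = bn))
}

add_bn <- function(b, id, input, c) {
  gn <- paste0(id, ".gamma"); be <- paste0(id, ".beta")
  rm_ <- paste0(id, ".rmean"); rv <- paste0(id, ".rvar")
  b$shapes[[gn]] <- c; b$shapes[[be]] <- c
  add_node(b, id, "bn", input,
           args = list(momentum = b$config$bn_momentum, eps = b$config$bn_eps),
           params = list(gamma = gn, beta = be, rm = rm_, rv = rv))
}

add_prelu <- function(b, id, input, c) {
  an <- paste0(id, ".a")
  b$shapes[[an]] <- c
  add_node(b, id, "prelu", input, params = list(a = an))
}

# conv -> batch norm -> PReLU
add_cbr <- function(b, prefix, input, k, cin, cout, stride = 1L) {
  x <- add_conv(b, paste0(prefix, "_conv"), input, k, cin, cout, stride)
  x <- add_bn(b, paste0(prefix, "_bn"), x, cout)
  add_prelu(b, paste0(prefix, "_act"), x, cout)
}

# bottleneck-residual block: 1x1 reduce, 3x3, 1x1 expand, residual addition
add_bottleneck <- function(b, prefix, input, c, ratio) {
  m <- c %/% ratio
  x <- add_cbr(b, paste0(prefix, "_reduce"), input, 1L, c, m)
  x <- add_cbr(b, paste0(prefix, "_mid"), x, 3L, m, m)
  x <- add_conv(b, paste0(prefix, "_expand_conv"), x, 1L, m, c)
  x <- add_bn(b, paste0(prefix, "_expand_bn"), x, c)
  x <- add_node(b, paste0(prefix, "_res"), "add", c(x, input))
  add_prelu(b, paste0(prefix, "_act"), x, c)
}

#' Build the 2D VB-Net from a configuration
#'
#' Contraction path: an input convolution followed, per level, by
#' bottleneck-residual blocks and a 2x2 stride-2 convolution down to the
#' next level.  Expansion path: 2x2 stride-2 transposed convolutions, a skip
#' concatenation with the same-level encoder output fused by a 3x3
#' convolution, and further bottleneck-residual blocks.  The output head
#' appends two convolutions (3x3 then 1x1) and a channel softmax, so the
#' per-voxel class probabilities sum to 1 at the input resolution.
#'
#' @param config a [vbnet_config()].
#' @param seed integer seed for Kaiming weight initialization.
#' @return object of class `vbnet`: `config`, `nodes`, `params`, `buffers`.
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "vbnet_config"))
  b <- new_builder(config)
  ch <- config$channels
  L <- config$levels
  r <- config$bottleneck_ratio

  x <- add_cbr(b, "stem", "input", 3L, config$in_channels, ch[1])
  enc_out <- character(L)
  for (l in seq_len(L)) {
    for (k in seq_len(config$enc_blocks[l]))
      x <- add_bottleneck(b, sprintf("enc%d_blk%d", l, k), x, ch[l], r)
    enc_out[l] <- x
    if (l < L)
      x <- add_cbr(b, sprintf("down%d", l), x, 2L, ch[l], ch[l + 1],
                   stride = 2L)
  }
  for (l in rev(seq_len(L - 1L))) {
    x <- add_tconv(b, sprintf("up%d_tconv", l), x, 2L, ch[l + 1], ch[l], 2L)
    x <- add_bn(b, sprintf("up%d_bn", l), x, ch[l])
    x <- add_prelu(b, sprintf("up%d_act", l), x, ch[l])
    x <- add_node(b, sprintf("skip%d", l), "concat", c(x, enc_out[l]))
    x <- add_cbr(b, sprintf("fuse%d", l), x, 3L, 2L * ch[l], ch[l])
    for (k in seq_len(config$dec_blocks[l]))
      x <- add_bottleneck(b, sprintf("dec%d_blk%d", l, k), x, ch[l], r)
  }
  x <- add_cbr(b, "head1", x, 3L, ch[1], ch[1])
  x <- add_conv(b, "head2", x, 1L, ch[1], config$out_channels)
  add_node(b, "probs", "softmax", x)

  net <- structure(list(config = config, nodes = b$nodes,
                        params = list(), buffers = list()),
                   class = "vbnet")
  init_network(net, b$shapes, seed)
}

# Kaiming-normal initialization for convolution kernels; PReLU slopes start
# at 0.25, batch-norm at identity with unit running variance
init_network <- function(net, shapes, seed) {
  with_seed(seed, {
    params <- list()
    buffers <- list()
    for (nm in names(shapes)) {
      shp <- shapes[[nm]]
      if (grepl("\\.w$", nm)) {
        fan_in <- if (grepl("tconv", nm)) prod(shp[c(1, 2)]) * shp[4]
                  else prod(shp[1:3])
        params[[nm]] <- array(rnorm(prod(shp), 0, sqrt(2 / fan_in)), shp)
      } else if (grepl("\\.b$", nm) || grepl("\\.beta$", nm)) {
        params[[nm]] <- numeric(shp)
      } else if (grepl("\\.gamma$", nm)) {
        params[[nm]] <- rep(1, shp)
      } else if (grepl("\\.a$", nm)) {
        params[[nm]] <- rep(0.25, shp)
      }
    }
    for (node in net$nodes) {
      if (!is.null(node$rm)) {
        cwidth <- length(params[[node$gamma]])
        buffers[[node$rm]] <- numeric(cwidth)
        buffers[[node$rv]] <- rep(1, cwidth)
      }
    }
    net$params <- params
    net$buffers <- buffers
    net
  })
}

#' Forward pass of the network
#'
#' @param net a [build_network()] result.
#' @param x input array `(H, W, in_channels, N)`; H and W must be divisible
#'   by `2^(levels - 1)`.
#' @param train use batch statistics (TRUE) or running statistics (FALSE)
#'   in the normalization layers.
#' @return array `(H, W, out_channels, N)` of per-voxel class
#'   probabilities.
#' @export
vbnet_forward <- function(net, x, train = FALSE) {
  d <- dim(x)
  div <- 2^(net$config$levels - 1)
  if (d[1] %% div != 0 || d[2] %% div != 0)
    stop(sprintf("input size %dx%d not divisible by %d", d[1], d[2], div))
  net_forward(net, x, train = train, keep = FALSE)$output
}

#' Count trainable parameters of a configuration analytically
#'
#' Closed-form accounting of every convolution kernel, bias, normalization
#' affine pair and PReLU slope implied by the configuration, without
#' instantiating the network.  `count_parameters(net)` on a built network
#' enumerates the instantiated tensors instead; the two must agree exactly.
#'
#' @param x a `vbnet_config` or a built `vbnet`.
#' @return integer parameter count.
#' @export
count_parameters <- function(x) UseMethod("count_parameters")

#' @export
count_parameters.vbnet <- function(x) {
  as.integer(sum(vapply(x$params, length, numeric(1))))
}

#' @export
count_parameters.vbnet_config <- function(x) {
  conv_n <- function(k, cin, cout) k * k * cin * cout + cout
  bn_n <- function(c) 2 * c
  cbr_n <- function(k, cin, cout) conv_n(k, cin, cout) + bn_n(cout) + cout
  block_n <- function(c, r) {
    m <- c %/% r
    cbr_n(1, c, m) + cbr_n(3, m, m) + conv_n(1, m, c) + bn_n(c) + c
  }
  ch <- x$channels; L <- x$levels; r <- x$bottleneck_ratio
  total <- cbr_n(3, x$in_channels, ch[1])
  for (l in seq_len(L)) {
    total <- total + x$enc_blocks[l] * block_n(ch[l], r)
    if (l < L) total <- total + cbr_n(2, ch[l], ch[l + 1])
  }
  for (l in seq_len(L - 1L)) {
    total <- total + conv_n(2, ch[l + 1], ch[l]) + bn_n(ch[l]) + ch[l] # up
    total <- total + cbr_n(3, 2 * ch[l], ch[l])                       # fuse
    total <- total + x$dec_blocks[l] * block_n(ch[l], r)
  }
  total <- total + cbr_n(3, ch[1], ch[1]) +
    conv_n(1, ch[1], x$out_channels)
  as.integer(total)
}
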