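# The U-shaped volumetric generator and the 3-layer conditional
# discriminator. The generator halves (D, H, W) four times with channel
# schedule b, 2b, 4b, 8b, 16b (defaults 16..256, so a 256x256 input reaches
# a 256-channel D/16 x 16 x 16 bottleneck); decoding upsamples by linear
# interpolation and concatenates encoder features, which pass through a
# multi-axis attention block first when use_ma is on.

conv_block <- function(in_ch, out_ch) {
  nn_seq(nn_conv(in_ch, out_ch), nn_bn(out_ch), nn_relu(),
         nn_conv(out_ch, out_ch), nn_bn(out_ch), nn_relu())
}

#' Build the segmentation generator
#'
#' @param in_channels input channels (1 = the windowed CT; 2 duplicates the
#'   CT into a second conditioning channel).
#' @param out_channels output probability channels (1; sigmoid head).
#' @param base_channels first-stage width `b`; the bottleneck has `16 * b`
#'   channels (256 at the default `b = 16`).
#' @param use_ma gate encoder skips with multi-axis attention?
#' @param seed optional seed for weight initialisation.
#' @return a generator module; run with [generator_forward()].
#' @export
generator <- function(in_channels = 1L, out_channels = 1L,
                      base_channels = 16L, use_ma = TRUE, seed = NULL) {
  b <- as.integer(base_channels)
  with_seed(seed, {
    ch <- list(
      stem = conv_block(in_channels, b),
      enc2 = conv_block(b, 2L * b),
      enc3 = conv_block(2L * b, 4L * b),
      enc4 = conv_block(4L * b, 8L * b),
      bott = conv_block(8L * b, 16L * b),
      pool1 = nn_maxpool2(), pool2 = nn_maxpool2(),
      pool3 = nn_maxpool2(), pool4 = nn_maxpool2(),
      up4 = nn_upsample2(), up3 = nn_upsample2(),
      up2 = nn_upsample2(), up1 = nn_upsample2(),
      dec4 = conv_block(24L * b, 8L * b),
      dec3 = conv_block(12L * b, 4L * b),
      dec2 = conv_block(6L * b, 2L * b),
      dec1 = conv_block(3L * b, b),
      head = nn_conv(b, out_channels, k = c(1L, 1L, 1L)),
      sig = nn_sigmoid())
    # zero-init the head: the initial output is exactly 0.5 everywhere, so
    # the first overlap-loss gradients set each voxel's polarity instead of
    # inheriting a random all-negative head (a spurious basin where the
    # soft loss improves while every voxel stays below threshold)
    ch$head$params$W[] <- 0
    ch$head$params$b[] <- 0
    if (use_ma) {
      ch$ma1 <- ma_block(b)
      ch$ma2 <- ma_block(2L * b)
      ch$ma3 <- ma_block(4L * b)
      ch$ma4 <- ma_block(8L * b)
    }
    new_module("generator", .children = ch,
               in_channels = as.integer(in_channels),
               out_channels = as.integer(out_channels),
               base_channels = b, use_ma = isTRUE(use_ma))
  })
}

#' @export
nn_forward.nn_generator <- function(mod, x, train = TRUE) {
  x <- as_feature_map(x)
  d <- dim(x)
  if (d[1] != mod$in_channels)
    abort_cfg("generator expects ", mod$in_channels, " input channels")
  if (any(d[2:4] %% 16L != 0L))
    abort_cfg("generator input D,H,W must be divisible by 16 (pad first)")
  ch <- mod$children
  e1 <- nn_forward(ch$stem, x, train)
  e2 <- nn_forward(ch$enc2, nn_forward(ch$pool1, e1, train), train)
  e3 <- nn_forward(ch$enc3, nn_forward(ch$pool2, e2, train), train)
  e4 <- nn_forward(ch$enc4, nn_forward(ch$pool3, e3, train), train)
  bt <- nn_forward(ch$bott, nn_forward(ch$pool4, e4, train), train)
  mod$bottleneck_dim <- dim(bt)
  skip <- function(e, ma) if (mod$use_ma) nn_forward(ch[[ma]], e, train) else e
  d4 <- nn_forward(ch$dec4,
                   cat_channels(skip(e4, "ma4"), nn_forward(ch$up4, bt, train)),
                   train)
  d3 <- nn_forward(ch$dec3,
                   cat_channels(skip(e3, "ma3"), nn_forward(ch$up3, d4, train)),
                   train)
  d2 <- nn_forward(ch$dec2,
                   cat_channels(skip(e2, "ma2"), nn_forward(ch$up2, d3, train)),
                   train)
  d1 <- nn_forward(ch$dec1,
                   cat_channels(skip(e1, "ma1"), nn_forward(ch$up1, d2, train)),
                   train)
  nn_forward(ch$sig, nn_forward(ch$head, d1, train), train)
}

#' @export
nn_backward.nn_generator <- function(mod, dy) {
  ch <- mod$children
  b <- mod$base_channels
  dskip_bwd <- function(ds, ma) if (mod$use_ma) nn_backward(ch[[ma]], ds) else ds

  dd1 <- nn_backward(ch$head, nn_backward(ch$sig, dy))
  dc1 <- nn_backward(ch$dec1, dd1)
  p1 <- split_channels(dc1, b)
  de1 <- dskip_bwd(p1[[1]], "ma1")
  dd2 <- nn_backward(ch$up1, p1[[2]])
  dc2 <- nn_backward(ch$dec2, dd2)
  p2 <- split_channels(dc2, 2L * b)
  de2 <- dskip_bwd(p2[[1]], "ma2")
  dd3 <- nn_backward(ch$up2, p2[[2]])
  dc3 <- nn_backward(ch$dec3, dd3)
  p3 <- split_channels(dc3, 4L * b)
  de3 <- dskip_bwd(p3[[1]], "ma3")
  dd4 <- nn_backward(ch$up3, p3[[2]])
  dc4 <- nn_backward(ch$dec4, dd4)
  p4 <- split_channels(dc4, 8L * b)
  de4 <- dskip_bwd(p4[[1]], "ma4")
  dbt <- nn_backward(ch$up4, p4[[2]])

  de4 <- de4 + nn_backward(ch$pool4, nn_backward(ch$bott, dbt))
  de3 <- de3 + nn_backward(ch$pool3, nn_backward(ch$enc4, de4))
  de2 <- de2 + nn_backward(ch$pool2, nn_backward(ch$enc3, de3))
  de1 <- de1 + nn_backward(ch$pool1, nn_backward(ch$enc2, de2))
  nn_backward(ch$stem, de1)
}

#' Run the generator on a feature map
#'
#' @param x input `[in_channels, D, H, W]`, spatial dims divisible by 16.
#' @param gen a [generator()].
#' @param train training mode flag.
#' @return probability map `[out_channels, D, H, W]`, values in (0, 1).
#' @export
generator_forward <- function(x, gen, train = FALSE) nn_forward(gen, x, train)

#' Build the conditional discriminator
#'
#' Three stride-2 convolution blocks (each followed by dropout 0.5), global
#' average pooling, a fully connected layer and a sigmoid that scores the
#' probability that the label channel is a real annotation for the
#' conditioning CT.
#'
#' @param condition_channels channels of the conditioning CT input.
#' @param label_channels channels of the (real or generated) label map.
#' @param layer_channels widths of the three downsampling layers.
#' @param dropout_rate dropout probability in `[0, 1)`.
#' @param seed optional seed for weight initialisation.
#' @return a discriminator module; run with [discriminator_forward()].
#' @export
discriminator <- function(condition_channels = 1L, label_channels = 1L,
                          layer_channels = c(32L, 64L, 128L),
                          dropout_rate = 0.5, seed = NULL) {
  if (length(layer_channels) != 3L)
    abort_cfg("the discriminator has exactly 3 downsampling layers")
  if (dropout_rate < 0 || dropout_rate >= 1)
    abort_cfg("dropout_rate must be in [0, 1)")
  in_ch <- condition_channels + label_channels
  lc <- as.integer(layer_channels)
  with_seed(seed, {
    body <- nn_seq(
      nn_conv(in_ch, lc[1], stride = c(2L, 2L, 2L)), nn_relu(),
      nn_dropout(dropout_rate),
      nn_conv(lc[1], lc[2], stride = c(2L, 2L, 2L)), nn_relu(),
      nn_dropout(dropout_rate),
      nn_conv(lc[2], lc[3], stride = c(2L, 2L, 2L)), nn_relu(),
      nn_dropout(dropout_rate),
      nn_gap(), nn_dense(lc[3], 1L), nn_sigmoid())
    new_module("discriminator", .children = list(body = body),
               condition_channels = as.integer(condition_channels),
               label_channels = as.integer(label_channels))
  })
}

#' @export
nn_forward.nn_discriminator <- function(mod, x, train = TRUE) {
  nn_forward(mod$children$body, x, train)
}

#' @export
nn_backward.nn_discriminator <- function(mod, dy) {
  nn_backward(mod$children$body, dy)
}

#' Score a (CT, label) pair with the discriminator
#'
#' @param ct conditioning CT `[condition_channels, D, H, W]`.
#' @param label probability/label map `[label_channels, D, H, W]`.
#' @param disc a [discriminator()].
#' @param train training mode (enables dropout).
#' @return scalar in (0, 1).
#' @export
discriminator_forward <- function(ct, label, disc, train = FALSE) {
  if (!identical(dim(ct)[2:4], dim(label)[2:4]))
    abort_cfg("CT and label maps must be spatially aligned")
  nn_forward(disc, cat_channels(ct, label), train)
}
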