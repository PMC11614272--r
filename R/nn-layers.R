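# Layer zoo. All feature maps are [C, D, H, W] double arrays for a single
# sample; batching is handled by the training steps (gradients accumulate
# across per-sample backward passes).

as_feature_map <- function(x) {
  if (length(dim(x)) != 4L) abort_cfg("feature map must be rank-4 [C,D,H,W]")
  storage.mode(x) <- "double"
  x
}

# ---- convolution ----------------------------------------------------------

#' Convolution layer (exact, im2col + GEMM)
#'
#' 3D cross-correlation with per-axis kernel size, stride and zero padding;
#' 2D convolutions on projected maps are the `k = c(1, 3, 3)` case. He
#' initialisation.
#'
#' @param in_ch,out_ch channel counts.
#' @param k integer length-3 kernel size `(kd, kh, kw)`.
#' @param stride integer length-3 stride.
#' @param pad integer length-3 zero padding; default keeps spatial shape
#'   for odd kernels at stride 1.
#' @return a conv module.
#' @export
nn_conv <- function(in_ch, out_ch, k = c(3L, 3L, 3L), stride = c(1L, 1L, 1L),
                    pad = (k - 1L) %/% 2L) {
  k <- as.integer(k); stride <- as.integer(stride); pad <- as.integer(pad)
  fan_in <- in_ch * prod(k)
  W <- matrix(rnorm(out_ch * fan_in, 0, sqrt(2 / fan_in)), out_ch, fan_in)
  b <- numeric(out_ch)
  new_module("conv",
             .params = list(W = W, b = b),
             in_ch = in_ch, out_ch = out_ch, k = k, stride = stride, pad = pad)
}

#' @export
nn_forward.nn_conv <- function(mod, x, train = TRUE) {
  x <- as_feature_map(x)
  if (dim(x)[1] != mod$in_ch)
    abort_cfg("conv expected ", mod$in_ch, " channels, got ", dim(x)[1])
  mod$x <- if (train) x  # backward caches are only kept in training mode
  .conv3d_fwd_cpp(x, dim(x), mod$params$W, mod$params$b, mod$k, mod$pad,
                  mod$stride)
}

#' @export
nn_backward.nn_conv <- function(mod, dy) {
  storage.mode(dy) <- "double"
  r <- .conv3d_bwd_cpp(mod$x, dim(mod$x), mod$params$W, dy, mod$k, mod$pad,
                       mod$stride)
  mod$grads$W <- mod$grads$W + r$dW
  mod$grads$b <- mod$grads$b + r$db
  r$dx
}

# ---- normalization --------------------------------------------------------

# Channel-wise normalization over the spatial extent. With batch size 2
# handled sample-by-sample this equals instance normalization; running
# moments are tracked but per-call statistics are also used at inference
# by default (use_running = FALSE) so train/eval behaviour coincides.
nn_bn <- function(ch, eps = 1e-5, momentum = 0.1, use_running = FALSE) {
  new_module("bn",
             .params = list(gamma = rep(1, ch), beta = numeric(ch)),
             .buffers = list(running_mean = numeric(ch),
                            running_var = rep(1, ch)),
             ch = ch, eps = eps, momentum = momentum,
             use_running = use_running)
}

#' @export
nn_forward.nn_bn <- function(mod, x, train = TRUE) {
  d <- dim(x)
  xm <- matrix(x, d[1])
  if (train || !mod$use_running) {
    mu <- rowMeans(xm)
    va <- rowMeans(xm * xm) - mu * mu
    if (train) {
      m <- mod$momentum
      mod$buffers$running_mean <- (1 - m) * mod$buffers$running_mean + m * mu
      mod$buffers$running_var <- (1 - m) * mod$buffers$running_var + m * va
    }
  } else {
    mu <- mod$buffers$running_mean
    va <- mod$buffers$running_var
  }
  invstd <- 1 / sqrt(va + mod$eps)
  xhat <- (xm - mu) * invstd
  if (train) {
    mod$xhat <- xhat; mod$invstd <- invstd; mod$dims <- d
    mod$stats_mode <- TRUE
  }
  y <- mod$params$gamma * xhat + mod$params$beta
  array(y, d)
}

#' @export
nn_backward.nn_bn <- function(mod, dy) {
  d <- mod$dims
  dym <- matrix(dy, d[1])
  mod$grads$gamma <- mod$grads$gamma + rowSums(dym * mod$xhat)
  mod$grads$beta <- mod$grads$beta + rowSums(dym)
  dxhat <- dym * mod$params$gamma
  if (mod$stats_mode) {
    dx <- mod$invstd * (dxhat - rowMeans(dxhat) -
                          mod$xhat * rowMeans(dxhat * mod$xhat))
  } else {
    dx <- mod$invstd * dxhat
  }
  array(dx, d)
}

# ---- pointwise ------------------------------------------------------------

nn_relu <- function() new_module("relu")

#' @export
nn_forward.nn_relu <- function(mod, x, train = TRUE) {
  if (train) {
    mod$mask <- x > 0
    x * mod$mask
  } else {
    x * (x > 0)
  }
}

#' @export
nn_backward.nn_relu <- function(mod, dy) dy * mod$mask

nn_sigmoid <- function() new_module("sigmoid")

#' @export
nn_forward.nn_sigmoid <- function(mod, x, train = TRUE) {
  y <- 1 / (1 + exp(-x))
  if (train) mod$y <- y
  y
}

#' @export
nn_backward.nn_sigmoid <- function(mod, dy) dy * mod$y * (1 - mod$y)

nn_dropout <- function(p = 0.5) new_module("dropout", p = p)

#' @export
nn_forward.nn_dropout <- function(mod, x, train = TRUE) {
  if (!train || mod$p <= 0) {
    mod$mask <- NULL
    return(x)
  }
  mask <- array((runif(length(x)) >= mod$p) / (1 - mod$p),
                dim(x) %||% length(x))
  mod$mask <- mask
  x * mask
}

#' @export
nn_backward.nn_dropout <- function(mod, dy) {
  if (is.null(mod$mask)) dy else dy * mod$mask
}

# ---- pooling and upsampling ----------------------------------------------

nn_maxpool2 <- function() new_module("maxpool2")

#' @export
nn_forward.nn_maxpool2 <- function(mod, x, train = TRUE) {
  d <- dim(x)
  if (any(d[2:4] %% 2L != 0L)) abort_cfg("maxpool needs even spatial dims")
  storage.mode(x) <- "double"
  r <- .maxpool2_fwd_cpp(x, d)
  if (train) {
    mod$arg <- r$arg
    mod$in_dims <- d
  }
  r$y
}

#' @export
nn_backward.nn_maxpool2 <- function(mod, dy) {
  storage.mode(dy) <- "double"
  .maxpool2_bwd_cpp(dy, mod$arg, mod$in_dims)
}

# Linear x2 upsampling along each spatial axis (half-voxel aligned): even
# outputs take 0.75*x[i] + 0.25*x[i-1], odd take 0.75*x[i] + 0.25*x[i+1],
# clamped at the ends.
nn_upsample2 <- function() new_module("upsample2")

#' @export
nn_forward.nn_upsample2 <- function(mod, x, train = TRUE) {
  storage.mode(x) <- "double"
  for (axis in 2:4) x <- .up2_axis_fwd_cpp(x, dim(x), axis)
  x
}

#' @export
nn_backward.nn_upsample2 <- function(mod, dy) {
  storage.mode(dy) <- "double"
  for (axis in 4:2) dy <- .up2_axis_bwd_cpp(dy, dim(dy), axis)
  dy
}

# ---- dense head -----------------------------------------------------------

nn_gap <- function() new_module("gap")

#' @export
nn_forward.nn_gap <- function(mod, x, train = TRUE) {
  d <- dim(x)
  mod$dims <- d
  rowMeans(matrix(x, d[1]))
}

#' @export
nn_backward.nn_gap <- function(mod, dy) {
  d <- mod$dims
  n <- prod(d[2:4])
  array(matrix(dy / n, d[1], n), d)
}

nn_dense <- function(in_n, out_n) {
  W <- matrix(rnorm(out_n * in_n, 0, sqrt(2 / in_n)), out_n, in_n)
  new_module("dense",
             .params = list(W = W, b = numeric(out_n)))
}

#' @export
nn_forward.nn_dense <- function(mod, x, train = TRUE) {
  mod$x <- as.numeric(x)
  drop(mod$params$W %*% mod$x + mod$params$b)
}

#' @export
nn_backward.nn_dense <- function(mod, dy) {
  dy <- as.numeric(dy)
  mod$grads$W <- mod$grads$W + outer(dy, mod$x)
  mod$grads$b <- mod$grads$b + dy
  drop(crossprod(mod$params$W, dy))
}

# ---- composition ----------------------------------------------------------

nn_seq <- function(...) {
  mods <- list(...)
  if (length(mods) == 1L && is.list(mods[[1]]) &&
      !inherits(mods[[1]], "nn_module"))
    mods <- mods[[1]]
  names(mods) <- sprintf("m%02d", seq_along(mods))
  new_module("seq", .children = mods)
}

#' @export
nn_forward.nn_seq <- function(mod, x, train = TRUE) {
  for (ch in mod$children) x <- nn_forward(ch, x, train)
  x
}

#' @export
nn_backward.nn_seq <- function(mod, dy) {
  for (ch in rev(mod$children)) dy <- nn_backward(ch, dy)
  dy
}

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[2:4]))
  out[seq_len(da[1]), , , ] <- a
  out[da[1] + seq_len(db[1]), , , ] <- b
  out
}

split_channels <- function(x, c1) {
  list(x[seq_len(c1), , , , drop = FALSE],
       x[-seq_len(c1), , , , drop = FALSE])
}
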