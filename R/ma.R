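# Multi-axis attention: each of the three anatomical planes gets a slice
# feature projection (FP) branch that pools the volume along one axis,
# refines the 2D projection with convolutions, and produces a per-channel
# gate; the three gates are fused with learnable weights constrained to the
# probability simplex by a softmax.

MA_AXES <- c("axial", "sagittal", "coronal")

# [C,D,H,W] axis index reduced by each projection
axis_index <- function(axis) {
  switch(match.arg(axis, MA_AXES), axial = 2L, sagittal = 4L, coronal = 3L)
}

drop_axis <- function(x, axis4) {
  d <- dim(x)
  array(x, d[-axis4])
}

# max + mean pooling along the reduced axis, with argmax kept for backward
reduce_maxmean <- function(x, axis4) {
  r <- .axis_maxmean_fwd_cpp(x, dim(x), axis4)
  list(K = array(r$K, dim(x)[-axis4]), arg = r$arg,
       n = dim(x)[axis4], axis4 = axis4, in_dim = dim(x))
}

reduce_maxmean_bwd <- function(dK, red) {
  storage.mode(dK) <- "double"
  .axis_maxmean_bwd_cpp(dK, red$arg, red$in_dim, red$axis4)
}

#' Slice feature projection: shared key/query map
#'
#' Projects a `[C, D, H, W]` feature map onto one anatomical plane by
#' summing its max- and mean-reductions along the plane's normal axis:
#' `K = Q = Max(x) + Mean(x)`. Axial reduces depth (shape `[C, H, W]`),
#' sagittal reduces width (`[C, D, H]`), coronal reduces height
#' (`[C, D, W]`).
#'
#' @param x feature map `[C, D, H, W]`.
#' @param axis one of `"axial"`, `"sagittal"`, `"coronal"`.
#' @return the projected map.
#' @export
project_kq <- function(x, axis = "axial") {
  x <- as_feature_map(x)
  reduce_maxmean(x, axis_index(axis))$K
}

expand_axis <- function(A3, axis4, full_dim) {
  storage.mode(A3) <- "double"
  .axis_expand_cpp(A3, as.integer(full_dim), axis4)
}

collapse_axis <- function(R4, axis4) {
  storage.mode(R4) <- "double"
  array(.axis_collapse_cpp(R4, dim(R4), axis4), dim(R4)[-axis4])
}

#' Slice feature projection block
#'
#' One FP branch: the projected key is refined by two 3x3 convolutions,
#' concatenated with the query, fused by two 1x1 convolutions and
#' replicated along the reduced axis into an attention matrix `R`; a 1x1x1
#' convolution of the input gives the value `V`. The stacked pair
#' `(R * V, x)` is summed and spatially averaged into a per-channel gate.
#'
#' @param ch channel count the block operates on.
#' @param axis projection plane, see [project_kq()].
#' @return an FP module; run it with [fp_forward()] or [nn_forward()].
#' @export
fp_block <- function(ch, axis = "axial") {
  axis <- match.arg(axis, MA_AXES)
  new_module("fp",
             .children = list(
               vconv = nn_conv(ch, ch, k = c(1L, 1L, 1L)),
               k1 = nn_conv(ch, ch, k = c(1L, 3L, 3L)),
               k2 = nn_conv(ch, ch, k = c(1L, 3L, 3L)),
               f1 = nn_conv(2L * ch, ch, k = c(1L, 1L, 1L)),
               f2 = nn_conv(ch, ch, k = c(1L, 1L, 1L))),
             ch = ch, axis = axis)
}

#' @export
nn_forward.nn_fp <- function(mod, x, train = TRUE) {
  x <- as_feature_map(x)
  if (dim(x)[1] != mod$ch) abort_cfg("FP block built for ", mod$ch,
                                     " channels, got ", dim(x)[1])
  ax <- axis_index(mod$axis)
  red <- reduce_maxmean(x, ax)
  C <- dim(x)[1]
  ab <- dim(red$K)[-1]
  K4 <- array(red$K, c(C, 1L, ab))
  Kp <- nn_forward(mod$children$k2,
                   nn_forward(mod$children$k1, K4, train), train)
  cat4 <- cat_channels(Kp, K4)
  A4 <- nn_forward(mod$children$f2,
                   nn_forward(mod$children$f1, cat4, train), train)
  A3 <- array(A4, c(C, ab))
  R <- expand_axis(A3, ax, dim(x))
  V <- nn_forward(mod$children$vconv, x, train)
  if (train) {
    mod$red <- red; mod$R <- R; mod$V <- V; mod$x_dim <- dim(x)
  }
  rowMeans(matrix(R * V + x, C))
}

#' @export
nn_backward.nn_fp <- function(mod, dy) {
  # dy: gradient w.r.t. the per-channel gate, length C
  d <- mod$x_dim; C <- d[1]; n_sp <- prod(d[2:4])
  ax <- axis_index(mod$axis)
  G <- array(matrix(as.numeric(dy) / n_sp, C, n_sp), d)
  dR <- G * mod$V
  dV <- G * mod$R
  dx <- G                                    # the "+ x" branch
  dx <- dx + nn_backward(mod$children$vconv, dV)
  dA3 <- collapse_axis(dR, ax)
  ab <- dim(dA3)[-1]
  dA4 <- array(dA3, c(C, 1L, ab))
  dcat <- nn_backward(mod$children$f1,
                      nn_backward(mod$children$f2, dA4))
  parts <- split_channels(dcat, C)
  dK4 <- nn_backward(mod$children$k1,
                     nn_backward(mod$children$k2, parts[[1]])) + parts[[2]]
  dx + reduce_maxmean_bwd(array(dK4, c(C, ab)), mod$red)
}

#' Run a slice feature projection block
#'
#' @param x feature map `[C, D, H, W]`.
#' @param block an [fp_block()].
#' @param train training mode flag.
#' @return the per-channel gate as a `[C, 1, 1, 1]` array.
#' @export
fp_forward <- function(x, block, train = TRUE) {
  g <- nn_forward(block, x, train)
  array(g, c(length(g), 1L, 1L, 1L))
}

#' Fusion weights on the probability simplex
#'
#' The three per-plane gates are fused with weights `beta = softmax(logits)`
#' so `beta >= 0` and `sum(beta) = 1` hold exactly after every optimizer
#' update of the unconstrained logits.
#'
#' @param logits numeric length-3 unconstrained parameters.
#' @return list with `logits` and simplex `weights`.
#' @export
normalize_fusion_weights <- function(logits) {
  if (length(logits) != 3L || any(!is.finite(logits)))
    abort_cfg("logits must be 3 finite numbers")
  z <- exp(logits - max(logits))
  list(logits = as.numeric(logits), weights = as.numeric(z / sum(z)))
}

#' Multi-axis attention block
#'
#' Fuses the axial, sagittal and coronal FP gates with learnable simplex
#' weights and applies the fused gate multiplicatively:
#' `y = sum_a beta_a * gate_a(x) * x`, preserving the input shape.
#'
#' @param ch channel count.
#' @return an MA module; run it with [ma_forward()] or [nn_forward()].
#' @export
ma_block <- function(ch) {
  new_module("ma",
             .params = list(logits = numeric(3L)),
             .children = list(axial = fp_block(ch, "axial"),
                             sagittal = fp_block(ch, "sagittal"),
                             coronal = fp_block(ch, "coronal")),
             ch = ch)
}

#' @export
nn_forward.nn_ma <- function(mod, x, train = TRUE) {
  x <- as_feature_map(x)
  beta <- normalize_fusion_weights(mod$params$logits)$weights
  gates <- lapply(mod$children, nn_forward, x = x, train = train)
  y <- 0
  for (i in 1:3) y <- y + beta[i] * gates[[i]] * x  # gate recycles over C
  if (train) {
    mod$x <- x; mod$beta <- beta; mod$gates <- gates
  }
  y
}

#' @export
nn_backward.nn_ma <- function(mod, dy) {
  x <- mod$x; beta <- mod$beta
  C <- dim(x)[1]
  dx <- 0
  dbeta <- numeric(3)
  dyx <- rowSums(matrix(dy * x, C))
  for (i in 1:3) {
    g <- mod$gates[[i]]
    dx <- dx + beta[i] * g * dy
    dbeta[i] <- sum(dyx * g)
    dg <- beta[i] * dyx
    dx <- dx + nn_backward(mod$children[[i]], dg)
  }
  dlogits <- beta * (dbeta - sum(beta * dbeta))
  mod$grads$logits <- mod$grads$logits + dlogits
  dx
}

#' Run a multi-axis attention block
#'
#' @inheritParams fp_forward
#' @param block an [ma_block()].
#' @return gated feature map, same shape as `x`.
#' @export
ma_forward <- function(x, block, train = TRUE) nn_forward(block, x, train)

#' @rdname normalize_fusion_weights
#' @param block an [ma_block()].
#' @export
fusion_weights <- function(block) normalize_fusion_weights(block$params$logits)
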