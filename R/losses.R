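#' Tversky loss parameters
#'
#' Asymmetric overlap weights: `alpha` scales false positives, `beta` false
#' negatives. The defaults 0.7/0.3 penalise false negatives less harshly in
#' relative recall terms and were tuned for the liver/tumor task;
#' `alpha = beta = 0.5` recovers soft Dice.
#'
#' @param alpha false-positive weight (>= 0).
#' @param beta false-negative weight (>= 0).
#' @param smooth small positive constant guarding the empty-foreground case.
#' @export
tversky_params <- function(alpha = 0.7, beta = 0.3, smooth = 1e-6) {
  if (alpha < 0 || beta < 0 || smooth <= 0)
    abort_cfg("alpha, beta must be >= 0 and smooth > 0")
  structure(list(alpha = alpha, beta = beta, smooth = smooth),
            class = "tversky_params")
}

check_pair <- function(y, g) {
  if (!identical(dim(y) %||% length(y), dim(g) %||% length(g)))
    abort_cfg("reference and prediction must share a shape")
}

#' Tversky index and loss
#'
#' `tversky_index()` computes `TP / (TP + alpha*FP + beta*FN)` with
#' `TP = sum(y*g)`, `FP = sum((1-y)*g)`, `FN = sum(y*(1-g))`, smoothing
#' added to numerator and denominator; `tversky_loss()` is `1 - index`,
#' zero iff the prediction is perfect.
#'
#' @param y binary reference mask (array or vector).
#' @param g predicted probabilities in `[0, 1]`, same shape.
#' @param p a [tversky_params()].
#' @return scalar in `[0, 1]`.
#' @export
tversky_index <- function(y, g, p = tversky_params()) {
  check_pair(y, g)
  tp <- sum(y * g)
  fp <- sum((1 - y) * g)
  fn <- sum(y * (1 - g))
  (tp + p$smooth) / (tp + p$alpha * fp + p$beta * fn + p$smooth)
}

#' @rdname tversky_index
#' @export
tversky_loss <- function(y, g, p = tversky_params()) {
  1 - tversky_index(y, g, p)
}

# d(tversky_loss)/dg, used by the generator step.
tversky_loss_grad <- function(y, g, p = tversky_params()) {
  tp <- sum(y * g)
  fp <- sum((1 - y) * g)
  fn <- sum(y * (1 - g))
  num <- tp + p$smooth
  den <- tp + p$alpha * fp + p$beta * fn + p$smooth
  dq <- y + p$alpha * (1 - y) - p$beta * y  # d den / dg_i
  -(y * den - num * dq) / den^2
}

#' Adversarial losses
#'
#' Two readings of the adversarial objective are provided. `"nolog"` drops
#' the logarithms (the Wasserstein-motivated form): the discriminator
#' minimises `-mean(D_real) + mean(D_fake)` and the generator
#' `-mean(D_fake)`. `"bce"` is the ones/zeros cross-entropy form. No
#' gradient penalty or weight clipping is applied in either mode.
#'
#' @param d_real,d_fake discriminator scores in (0, 1), one per batch item.
#' @param mode `"nolog"` (default) or `"bce"`.
#' @return scalar loss (to minimise).
#' @export
discriminator_loss <- function(d_real, d_fake, mode = c("nolog", "bce")) {
  mode <- match.arg(mode)
  if (length(d_real) == 0L || length(d_fake) == 0L)
    abort_cfg("empty score batch")
  if (mode == "nolog") {
    -mean(d_real) + mean(d_fake)
  } else {
    eps <- 1e-7
    mean(-log(pmax(d_real, eps))) + mean(-log(pmax(1 - d_fake, eps)))
  }
}

#' @param y,g,p reference mask, generated probabilities and
#'   [tversky_params()] for the segmentation term.
#' @param lambda weight of the Tversky term (default 1, the unweighted sum).
#' @rdname discriminator_loss
#' @export
generator_loss <- function(d_fake, y, g, p = tversky_params(),
                           mode = c("nolog", "bce"), lambda = 1) {
  mode <- match.arg(mode)
  if (lambda < 0) abort_cfg("lambda must be >= 0")
  if (length(d_fake) == 0L) abort_cfg("empty score batch")
  adv <- if (mode == "nolog") -mean(d_fake)
         else mean(-log(pmax(d_fake, 1e-7)))
  adv + lambda * tversky_loss(y, g, p)
}

# d(adversarial generator term)/d d_fake
generator_adv_grad <- function(d_fake, mode = "nolog") {
  n <- length(d_fake)
  if (mode == "nolog") rep(-1 / n, n)
  else -1 / (n * pmax(d_fake, 1e-7))
}

# d(discriminator loss)/d d_real and d d_fake
discriminator_loss_grads <- function(d_real, d_fake, mode = "nolog") {
  nr <- length(d_real); nf <- length(d_fake)
  if (mode == "nolog") {
    list(d_real = rep(-1 / nr, nr), d_fake = rep(1 / nf, nf))
  } else {
    list(d_real = -1 / (nr * pmax(d_real, 1e-7)),
         d_fake = 1 / (nf * pmax(1 - d_fake, 1e-7)))
  }
}
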