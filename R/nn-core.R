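# Minimal module system for the networks: every layer is an environment
# holding named parameter arrays, matching gradient accumulators, optional
# non-trained buffers, and named child modules. Forward passes cache what
# the hand-written backward pass needs; nn_backward() returns the gradient
# w.r.t. the input and accumulates parameter gradients in place.

new_module <- function(.kind, .params = list(), .buffers = list(),
                       .children = list(), ...) {
  e <- new.env(parent = emptyenv())
  e$kind <- .kind
  e$params <- .params
  e$grads <- lapply(.params, function(p) p * 0)
  e$buffers <- .buffers
  e$children <- .children
  extra <- list(...)
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = e)
  class(e) <- c(paste0("nn_", .kind), "nn_module")
  e
}

#' Forward / backward pass through a network module
#'
#' @param mod a module built by one of the `nn_*()` constructors or
#'   [generator()] / [discriminator()].
#' @param x input array (layer-dependent shape, usually `[C, D, H, W]`).
#' @param train logical; training mode enables dropout and per-call
#'   normalization statistics.
#' @return `nn_forward()` returns the layer output; `nn_backward()` takes
#'   the gradient w.r.t. that output and returns the gradient w.r.t. `x`,
#'   accumulating parameter gradients inside `mod`.
#' @export
nn_forward <- function(mod, x, train = TRUE) UseMethod("nn_forward")

#' @param dy gradient of a scalar loss w.r.t. the module output.
#' @rdname nn_forward
#' @export
nn_backward <- function(mod, dy) UseMethod("nn_backward")

# Flat list of parameter slots (module env + name), for the optimizer.
module_parameters <- function(mod) {
  out <- list()
  if (length(mod$params)) {
    for (nm in names(mod$params))
      out[[length(out) + 1L]] <- list(env = mod, name = nm)
  }
  for (ch in mod$children) out <- c(out, module_parameters(ch))
  out
}

#' Count trainable parameters of a network
#'
#' @param mod a module.
#' @return total number of trainable scalar parameters.
#' @export
count_parameters <- function(mod) {
  sum(vapply(module_parameters(mod),
             function(s) length(s$env$params[[s$name]]), numeric(1)))
}

zero_grad <- function(mod) {
  for (s in module_parameters(mod))
    s$env$grads[[s$name]][] <- 0
  invisible(mod)
}

# Serializable parameter/buffer state (nested named lists).
module_state <- function(mod) {
  st <- list(params = mod$params, buffers = mod$buffers)
  st$children <- lapply(mod$children, module_state)
  st
}

module_load_state <- function(mod, st) {
  for (nm in names(st$params)) mod$params[[nm]] <- st$params[[nm]]
  for (nm in names(st$buffers)) mod$buffers[[nm]] <- st$buffers[[nm]]
  for (nm in names(st$children))
    module_load_state(mod$children[[nm]], st$children[[nm]])
  invisible(mod)
}

# Deterministic checksum of all parameters, used to assert freezing.
module_checksum <- function(mod) {
  ps <- module_parameters(mod)
  sum(vapply(ps, function(s) sum(s$env$params[[s$name]] *
                                   seq_along(s$env$params[[s$name]])),
             numeric(1)))
}

#' AdamW optimizer
#'
#' Adam with decoupled weight decay, the optimizer used for both networks.
#'
#' @param mod module whose parameters are optimized.
#' @param lr learning rate (default 2e-4).
#' @param betas first/second moment decay rates.
#' @param eps numerical stabilizer.
#' @param weight_decay decoupled weight-decay coefficient.
#' @return an optimizer object; advance it with [optim_step()].
#' @export
optim_adamw <- function(mod, lr = 2e-4, betas = c(0.9, 0.999), eps = 1e-8,
                        weight_decay = 1e-2) {
  slots <- module_parameters(mod)
  state <- lapply(slots, function(s) {
    p <- s$env$params[[s$name]]
    list(m = p * 0, v = p * 0)  # moment buffers mirror parameter shape
  })
  e <- new.env(parent = emptyenv())
  e$slots <- slots; e$state <- state; e$lr <- lr; e$betas <- betas
  e$eps <- eps; e$weight_decay <- weight_decay; e$t <- 0L
  class(e) <- "cgan_optim"
  e
}

#' @param opt an optimizer from [optim_adamw()].
#' @rdname optim_adamw
#' @export
optim_step <- function(opt) {
  opt$t <- opt$t + 1L
  b1 <- opt$betas[1]; b2 <- opt$betas[2]
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  for (i in seq_along(opt$slots)) {
    s <- opt$slots[[i]]
    g <- s$env$grads[[s$name]]
    st <- opt$state[[i]]
    st$m <- b1 * st$m + (1 - b1) * g
    st$v <- b2 * st$v + (1 - b2) * g * g
    opt$state[[i]] <- st
    p <- s$env$params[[s$name]]
    upd <- (st$m / bc1) / (sqrt(st$v / bc2) + opt$eps) + opt$weight_decay * p
    s$env$params[[s$name]] <- p - opt$lr * upd
  }
  invisible(opt)
}

#' @rdname optim_adamw
#' @param value new learning rate.
#' @export
optim_set_lr <- function(opt, value) {
  opt$lr <- value
  invisible(opt)
}
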