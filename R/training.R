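#' Training configuration
#'
#' Hyperparameters of the alternating adversarial optimisation. Defaults
#' follow the reference schedule: AdamW at learning rate 2e-4, batch size
#' 2, at most 300 epochs, halve the learning rate after 30 epochs without
#' validation-Dice improvement, stop after 60 stale epochs.
#'
#' @param lr initial learning rate.
#' @param weight_decay decoupled AdamW weight decay.
#' @param batch_size cases per alternating step.
#' @param max_epochs epoch cap.
#' @param plateau_patience stale epochs before each learning-rate halving.
#' @param stop_patience stale epochs before early stopping
#'   (`>= plateau_patience`).
#' @param improve_eps minimum Dice gain that counts as improvement.
#' @param crop_depth training-time random depth crop (divisible by 16).
#' @param loss_mode adversarial mode, `"nolog"` or `"bce"`.
#' @param tversky a [tversky_params()].
#' @param lambda weight of the Tversky term in the generator loss.
#' @param use_cgan train adversarially? `FALSE` drops the discriminator
#'   (the plain U-shaped baseline).
#' @param use_ma gate skip connections with multi-axis attention?
#' @param in_channels,base_channels generator architecture knobs.
#' @param max_steps optional cap on alternating steps (for smoke runs).
#' @param target_dice optional validation Dice at which training stops.
#' @param seed RNG seed for the whole run.
#' @export
train_config <- function(lr = 2e-4, weight_decay = 1e-2, batch_size = 2L,
                         max_epochs = 300L, plateau_patience = 30L,
                         stop_patience = 60L, improve_eps = 1e-5,
                         crop_depth = 32L, loss_mode = c("nolog", "bce"),
                         tversky = tversky_params(), lambda = 1,
                         use_cgan = TRUE, use_ma = TRUE, in_channels = 1L,
                         base_channels = 16L, max_steps = NULL,
                         target_dice = NULL, seed = 1L) {
  loss_mode <- match.arg(loss_mode)
  if (stop_patience < plateau_patience)
    abort_cfg("stop_patience must be >= plateau_patience")
  if (crop_depth %% 16L != 0L)
    abort_cfg("crop_depth must be divisible by 16")
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 plateau_patience = as.integer(plateau_patience),
                 stop_patience = as.integer(stop_patience),
                 improve_eps = improve_eps,
                 crop_depth = as.integer(crop_depth),
                 loss_mode = loss_mode, tversky = tversky, lambda = lambda,
                 use_cgan = isTRUE(use_cgan), use_ma = isTRUE(use_ma),
                 in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 max_steps = max_steps, target_dice = target_dice,
                 seed = seed),
            class = "train_config")
}

# One training case is list(image = [D,H,W] in [0,1], mask = binary [D,H,W]).
as_net_input <- function(image, in_channels) {
  x <- array(image, c(1L, dim(image)))
  if (in_channels == 2L) x <- cat_channels(x, x)  # duplicated CT condition
  x
}

crop_case <- function(case, crop_depth) {
  d <- dim(case$image)[1]
  if (d > crop_depth) {
    s <- sample.int(d - crop_depth + 1L, 1L)
    idx <- s:(s + crop_depth - 1L)
    case$image <- case$image[idx, , , drop = FALSE]
    case$mask <- case$mask[idx, , , drop = FALSE]
  } else if (d %% 16L != 0L) {
    case$image <- pad_depth(case$image)
    case$mask <- pad_depth(case$mask)
  }
  case
}

#' One generator update on a batch
#'
#' Runs the generator on each case, scores the fake labels with the (frozen)
#' discriminator, and updates only the generator's parameters with the
#' combined adversarial + Tversky loss.
#'
#' @param batch list of cases (`image`, `mask`).
#' @param gen,disc the two networks; `disc = NULL` trains without the
#'   adversarial term.
#' @param cfg a [train_config()].
#' @param opt_g the generator's optimizer.
#' @return named list of scalar losses (`g_loss`, `adv`, `tversky`).
#' @export
generator_step <- function(batch, gen, disc, cfg, opt_g) {
  zero_grad(gen)
  if (!is.null(disc)) zero_grad(disc)
  n <- length(batch)
  adv_terms <- numeric(n); tv_terms <- numeric(n)
  for (i in seq_len(n)) {
    cs <- batch[[i]]
    x <- as_net_input(cs$image, gen$in_channels)
    g <- nn_forward(gen, x, train = TRUE)
    y <- array(cs$mask, dim(g))
    tv_terms[i] <- tversky_loss(y, g, cfg$tversky)
    dg <- (cfg$lambda / n) * tversky_loss_grad(y, g, cfg$tversky)
    if (!is.null(disc)) {
      ct <- x[seq_len(disc$condition_channels), , , , drop = FALSE]
      df <- nn_forward(disc, cat_channels(ct, g), train = TRUE)
      adv_terms[i] <- if (cfg$loss_mode == "nolog") -df
                      else -log(max(df, 1e-7))
      # d(batch adv loss)/d df for this sample, chained through D into g;
      # D's own parameter gradients are discarded (it is not stepped here)
      ddf <- generator_adv_grad(df, cfg$loss_mode)
      din <- nn_backward(disc, ddf)
      dg <- dg + split_channels(din, disc$condition_channels)[[2]]
    }
    nn_backward(gen, dg)
  }
  if (any(!is.finite(tv_terms)) || any(!is.finite(adv_terms)))
    abort_cfg("non-finite generator loss; aborting")
  optim_step(opt_g)
  list(g_loss = mean(adv_terms) + cfg$lambda * mean(tv_terms),
       adv = mean(adv_terms), tversky = mean(tv_terms))
}

#' One discriminator update on a batch
#'
#' Scores real and generated labels (both conditioned on the CT) and
#' updates only the discriminator; the generator is run purely as a frozen
#' sampler of fake labels.
#'
#' @inheritParams generator_step
#' @param opt_d the discriminator's optimizer.
#' @return named list with `d_loss`, `d_real`, `d_fake`.
#' @export
discriminator_step <- function(batch, gen, disc, cfg, opt_d) {
  zero_grad(disc)
  n <- length(batch)
  d_real <- numeric(n); d_fake <- numeric(n)
  for (i in seq_len(n)) {
    cs <- batch[[i]]
    x <- as_net_input(cs$image, gen$in_channels)
    ct <- x[seq_len(disc$condition_channels), , , , drop = FALSE]
    g <- nn_forward(gen, x, train = FALSE)   # detached fake labels
    y <- array(cs$mask, dim(g))

    dr <- nn_forward(disc, cat_channels(ct, y), train = TRUE)
    grads <- discriminator_loss_grads(dr, 0.5, cfg$loss_mode)
    nn_backward(disc, grads$d_real / n * 1)  # per-sample real term
    d_real[i] <- dr

    dfk <- nn_forward(disc, cat_channels(ct, g), train = TRUE)
    grads <- discriminator_loss_grads(0.5, dfk, cfg$loss_mode)
    nn_backward(disc, grads$d_fake / n * 1)  # per-sample fake term
    d_fake[i] <- dfk
  }
  if (any(!is.finite(d_real)) || any(!is.finite(d_fake)))
    abort_cfg("non-finite discriminator score; aborting")
  optim_step(opt_d)
  list(d_loss = discriminator_loss(d_real, d_fake, cfg$loss_mode),
       d_real = mean(d_real), d_fake = mean(d_fake))
}

#' Predict a probability volume
#'
#' Pads depth to a multiple of 16 (reflect), runs the generator in
#' evaluation mode, and un-pads.
#'
#' @param gen a trained [generator()].
#' @param image `[D, H, W]` array already windowed and scaled to `[0, 1]`.
#' @return `[D, H, W]` array of foreground probabilities.
#' @export
predict_probs <- function(gen, image) {
  padded <- pad_depth(image)
  od <- attr(padded, "orig_depth")
  x <- as_net_input(padded, gen$in_channels)
  g <- nn_forward(gen, x, train = FALSE)
  unpad_depth(array(g[1, , , ], dim(padded)), od)
}

#' Validation Dice
#'
#' Mean over cases of the (mean over target classes of the) Dice between
#' the binarised prediction and the reference mask. Accepts one generator
#' plus cases with `$mask`, or a named list of per-class generators plus
#' cases with `$masks` (a matching named list).
#'
#' @param nets a generator or named list of generators.
#' @param val_set nonempty list of cases.
#' @param threshold binarisation threshold (default 0.5).
#' @return mean Dice in `[0, 1]`.
#' @export
validate <- function(nets, val_set, threshold = 0.5) {
  if (length(val_set) == 0L) abort_cfg("validation set is empty")
  single <- inherits(nets, "nn_module")
  per_case <- vapply(val_set, function(cs) {
    if (single) {
      pr <- predict_probs(nets, cs$image) >= threshold
      dice(pr, cs$mask != 0)
    } else {
      mean(vapply(names(nets), function(cl) {
        pr <- predict_probs(nets[[cl]], cs$image) >= threshold
        dice(pr, cs$masks[[cl]] != 0)
      }, numeric(1)))
    }
  }, numeric(1))
  mean(per_case)
}

#' Fit the conditional adversarial segmentation model
#'
#' Alternates one generator and one discriminator update per batch,
#' validates each epoch, halves the learning rate after
#' `plateau_patience` stale epochs, stops after `stop_patience` stale
#' epochs or `max_epochs`, and keeps the best-validation parameter state.
#'
#' @param train_set,val_set nonempty lists of cases
#'   (`image` in `[0,1]`, binary `mask`).
#' @param cfg a [train_config()].
#' @param run_dir optional directory for the best checkpoint and history.
#' @param gen,disc optionally pre-built networks (else built from `cfg`).
#' @param verbose print a progress line every `verbose` epochs (0 = quiet).
#' @return a `cgan_fit` object: the trained networks (best state restored),
#'   a per-epoch `history` tibble, and the best validation Dice.
#' @export
fit_cgan <- function(train_set, val_set, cfg = train_config(),
                     run_dir = NULL, gen = NULL, disc = NULL, verbose = 0L) {
  if (length(train_set) == 0L) abort_cfg("training set is empty")
  if (length(val_set) == 0L) abort_cfg("validation set is empty")
  set.seed(cfg$seed)
  if (is.null(gen))
    gen <- generator(in_channels = cfg$in_channels,
                     base_channels = cfg$base_channels, use_ma = cfg$use_ma)
  disc_ch <- if (cfg$use_cgan) {
    if (is.null(disc)) disc <- discriminator(condition_channels = gen$in_channels)
    disc
  } else NULL

  opt_g <- optim_adamw(gen, lr = cfg$lr, weight_decay = cfg$weight_decay)
  opt_d <- if (cfg$use_cgan) optim_adamw(disc_ch, lr = cfg$lr,
                                         weight_decay = cfg$weight_decay)

  best_val <- -Inf; best_state <- NULL; best_epoch <- 0L
  stale <- 0L; lr_now <- cfg$lr; steps <- 0L; bad_epochs <- 0L
  hist <- list()

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(length(train_set))
    gl <- list(g_loss = NA_real_, adv = NA_real_, tversky = NA_real_)
    dl <- list(d_loss = NA_real_, d_real = NA_real_, d_fake = NA_real_)
    epoch_ok <- TRUE
    for (b0 in seq(1L, length(ord), by = cfg$batch_size)) {
      ids <- ord[b0:min(length(ord), b0 + cfg$batch_size - 1L)]
      batch <- lapply(train_set[ids], crop_case, crop_depth = cfg$crop_depth)
      gl <- tryCatch(generator_step(batch, gen, disc_ch, cfg, opt_g),
                     error = function(e) {
                       epoch_ok <<- FALSE
                       list(g_loss = NaN, adv = NaN, tversky = NaN)
                     })
      if (cfg$use_cgan && epoch_ok)
        dl <- discriminator_step(batch, gen, disc_ch, cfg, opt_d)
      steps <- steps + 1L
      if (!is.null(cfg$max_steps) && steps >= cfg$max_steps) break
    }
    bad_epochs <- if (epoch_ok) 0L else bad_epochs + 1L
    if (bad_epochs >= 3L)
      abort_cfg("training diverged: non-finite losses in 3 consecutive epochs")

    val <- validate(gen, val_set)
    if (val > best_val + cfg$improve_eps) {
      best_val <- val; best_epoch <- epoch; stale <- 0L
      best_state <- list(gen = module_state(gen),
                         disc = if (cfg$use_cgan) module_state(disc_ch))
    } else {
      stale <- stale + 1L
      if (stale %% cfg$plateau_patience == 0L) {
        lr_now <- lr_now / 2
        optim_set_lr(opt_g, lr_now)
        if (cfg$use_cgan) optim_set_lr(opt_d, lr_now)
      }
    }
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch, steps = steps, g_loss = gl$g_loss, adv = gl$adv,
      tversky = gl$tversky, d_loss = dl$d_loss, d_real = dl$d_real,
      d_fake = dl$d_fake, val_dice = val, lr = lr_now,
      best_val = max(best_val, val))
    if (verbose > 0L && epoch %% verbose == 0L)
      message(sprintf("epoch %4d  step %5d  tversky %.4f  d_loss %7.4f  val %.4f  lr %.2e",
                      epoch, steps, gl$tversky, dl$d_loss, val, lr_now))
    if (stale >= cfg$stop_patience) break
    if (!is.null(cfg$target_dice) && val >= cfg$target_dice) break
    if (!is.null(cfg$max_steps) && steps >= cfg$max_steps) break
  }

  if (!is.null(best_state)) {
    module_load_state(gen, best_state$gen)
    if (cfg$use_cgan && !is.null(best_state$disc))
      module_load_state(disc_ch, best_state$disc)
  }
  res <- structure(list(gen = gen, disc = disc_ch,
                        history = do.call(rbind, hist),
                        best_val = best_val, best_epoch = best_epoch,
                        steps = steps, config = cfg),
                   class = "cgan_fit")
  if (!is.null(run_dir)) {
    dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
    save_checkpoint(res, file.path(run_dir, "best_checkpoint.rds"))
    write.csv(res$history, file.path(run_dir, "history.csv"),
              row.names = FALSE)
    yaml::write_yaml(cfg[setdiff(names(cfg), "tversky")],
                     file.path(run_dir, "config_snapshot.yaml"))
  }
  res
}

#' Save / load a training checkpoint
#'
#' The checkpoint carries the training config, both networks' parameter
#' states, the best epoch and its validation Dice, so reloading reproduces
#' the recorded metric exactly.
#'
#' @param fit a `cgan_fit`.
#' @param path destination `.rds` file.
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(list(config = fit$config, gen_state = module_state(fit$gen),
               disc_state = if (!is.null(fit$disc)) module_state(fit$disc),
               best_epoch = fit$best_epoch, best_val = fit$best_val,
               steps = fit$steps),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- ck$config
  gen <- generator(in_channels = cfg$in_channels,
                   base_channels = cfg$base_channels, use_ma = cfg$use_ma)
  module_load_state(gen, ck$gen_state)
  disc <- NULL
  if (!is.null(ck$disc_state)) {
    disc <- discriminator(condition_channels = cfg$in_channels)
    module_load_state(disc, ck$disc_state)
  }
  structure(list(gen = gen, disc = disc, history = NULL,
                 best_val = ck$best_val, best_epoch = ck$best_epoch,
                 steps = ck$steps, config = cfg),
            class = "cgan_fit")
}

#' @export
print.cgan_fit <- function(x, ...) {
  cat(sprintf("<cgan_fit> %d epochs (%d steps), best val Dice %.4f at epoch %d\n",
              if (is.null(x$history)) NA_integer_ else nrow(x$history),
              x$steps, x$best_val, x$best_epoch))
  invisible(x)
}

#' @export
tidy.cgan_fit <- function(x, ...) {
  if (is.null(x$history)) return(tibble::tibble())
  x$history
}

#' @export
glance.cgan_fit <- function(x, ...) {
  tibble::tibble(epochs = if (is.null(x$history)) NA_integer_
                          else nrow(x$history),
                 steps = x$steps, best_val_dice = x$best_val,
                 best_epoch = x$best_epoch,
                 params_gen = count_parameters(x$gen),
                 params_disc = if (is.null(x$disc)) 0
                               else count_parameters(x$disc))
}
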