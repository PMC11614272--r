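#' Plot a training run
#'
#' Base-graphics view of the loss and validation-Dice traces.
#'
#' @param x a `cgan_fit`.
#' @param ... ignored.
#' @export
plot.cgan_fit <- function(x, ...) {
  h <- x$history
  if (is.null(h) || nrow(h) == 0L) abort_cfg("fit has no history")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$tversky, type = "l", xlab = "epoch",
                 ylab = "Tversky loss", main = "training loss")
  graphics::plot(h$epoch, h$val_dice, type = "l", xlab = "epoch",
                 ylab = "validation Dice", main = "validation")
  invisible(x)
}

#' ggplot2 view of a training run
#'
#' @param object a `cgan_fit`.
#' @param ... ignored.
#' @return a ggplot with Tversky-loss and validation-Dice traces.
#' @exportS3Method ggplot2::autoplot
autoplot.cgan_fit <- function(object, ...) {
  h <- object$history
  if (is.null(h) || nrow(h) == 0L) abort_cfg("fit has no history")
  long <- rbind(
    data.frame(epoch = h$epoch, value = h$tversky, trace = "Tversky loss"),
    data.frame(epoch = h$epoch, value = h$val_dice, trace = "validation Dice"))
  ggplot2::ggplot(long, ggplot2::aes(x = epoch, y = value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~trace, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}
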