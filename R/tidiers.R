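#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a fitted model
#'
#' @param x a `sen_fit`.
#' @param ... unused.
#' @return per-epoch tibble: `epoch`, `train_total`, `train_nll`,
#'   `train_penalty`, `val_nll`, `lr`.
#' @export
tidy.sen_fit <- function(x, ...) x$history

#' One-row summary of a fitted model
#'
#' @param x a `sen_fit`.
#' @param ... unused.
#' @return tibble with `n_genes`, `n_parameters`, `epochs_run`,
#'   `stop_reason`, `best_val_nll`, `final_train_total`, `final_penalty`.
#' @export
glance.sen_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    n_genes = length(x$genes),
    n_parameters = n_learnable(x$params),
    epochs_run = nrow(h),
    stop_reason = x$stop_reason,
    best_val_nll = x$best_val_nll,
    final_train_total = h$train_total[nrow(h)],
    final_penalty = h$train_penalty[nrow(h)]
  )
}

#' Plot training curves
#'
#' @param object a `sen_fit`.
#' @param ... unused.
#' @return a ggplot of train/validation loss across epochs.
#' @export
autoplot.sen_fit <- function(object, ...) {
  h <- object$history
  df <- rbind(
    data.frame(epoch = h$epoch, loss = h$train_total, curve = "train total"),
    data.frame(epoch = h$epoch, loss = h$val_nll, curve = "validation NLL")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = epoch, y = loss,
                                   colour = curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the senescence score distribution
#'
#' Histogram of continuous scores; when the scores have been binarized
#' the senescent cells are colored and the score cutoff drawn.
#'
#' @param object a `sen_scores` tibble.
#' @param bins histogram bins.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sen_scores <- function(object, bins = 50, ...) {
  df <- as.data.frame(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = score))
  if ("senescent" %in% names(df)) {
    p <- p + ggplot2::geom_histogram(
      ggplot2::aes(fill = senescent), bins = bins)
    cutoff <- attr(object, "cutoff")
    if (!is.null(cutoff) && !is.na(cutoff))
      p <- p + ggplot2::geom_vline(xintercept = cutoff, linetype = 2)
  } else {
    p <- p + ggplot2::geom_histogram(bins = bins)
  }
  p + ggplot2::labs(x = "senescence score", y = "cells") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
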