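# broom-style tidiers and ggplot2 autoplot methods.

#' Tidy a fitted model's training history
#'
#' @param x A `kinedep_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `loss`, `accuracy`.
#' @export
tidy.kinedep_fit <- function(x, ...) x$history

#' One-row summary of a fit
#'
#' @param x A `kinedep_fit`.
#' @param ... Unused.
#' @return Tibble with `epochs`, `final_loss`, `final_accuracy`,
#'   `n_parameters`, `n_classes`, `classifier`.
#' @export
glance.kinedep_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    epochs = nrow(x$history), final_loss = last$loss,
    final_accuracy = last$accuracy,
    n_parameters = n_parameters(x$model),
    n_classes = x$model_config$n_classes,
    classifier = x$model_config$classifier
  )
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Tibble of per-class support and recall plus the overall metrics
#'   repeated per row for convenience.
#' @export
tidy.eval_report <- function(x, ...) {
  tibble::tibble(
    class_name = rownames(x$confusion),
    support = rowSums(x$confusion),
    recall = as.numeric(x$per_class_recall)
  )
}

#' One-row summary of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Tibble with `n`, `accuracy`, `sensitivity`, `specificity`,
#'   `precision`.
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(n = x$n, accuracy = x$accuracy,
                 sensitivity = x$sensitivity,
                 specificity = x$specificity, precision = x$precision)
}

#' Plot a training history
#'
#' Loss and training accuracy per epoch.
#'
#' @param object A `kinedep_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kinedep_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("loss", "accuracy"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training history") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report's confusion matrix
#'
#' Heatmap of counts, rows = true class, columns = predicted class.
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev(rownames(object$confusion))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("Confusion matrix (accuracy %.1f%%)",
                                  object$accuracy)) +
    ggplot2::theme_minimal()
}
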