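# broom-style tidiers and ggplot2 autoplot methods.

#' Tidy a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return Long tibble: `class`, `metric`, `value`.
#' @export
tidy.metrics_report <- function(x, ...) {
  x$per_class |>
    dplyr::select(-"degenerate") |>
    tidyr::pivot_longer(-"class", names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
}

#' One-row summary of a metrics report
#'
#' @inheritParams tidy.metrics_report
#' @return Tibble with `accuracy`, macro-averaged metrics and `n`.
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy,
    macro_recall = mean(x$per_class$recall),
    macro_precision = mean(x$per_class$precision),
    macro_f1 = mean(x$per_class$f1),
    macro_auc = mean(x$per_class$auc),
    n = x$n)
}

#' Tidy cross-validation results
#'
#' @param x An `stvit_cv`.
#' @param ... Unused.
#' @return Tibble of per-fold per-class metrics plus fold accuracy.
#' @export
tidy.stvit_cv <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$fold_reports), function(f) {
    td <- tidy(x$fold_reports[[f]])
    td$fold <- f
    td$fold_accuracy <- x$fold_reports[[f]]$accuracy
    td
  }))
}

#' One-row summary of a cross-validation run
#'
#' @inheritParams tidy.stvit_cv
#' @return Tibble with the fold-averaged metrics.
#' @export
glance.stvit_cv <- function(x, ...) {
  out <- glance(x$mean_report)
  out$k <- length(x$fold_reports)
  out
}

#' Tidy a training fit's loss curve
#'
#' @param x An `stvit_fit`.
#' @param ... Unused.
#' @return The `epoch`/`loss` tibble.
#' @export
tidy.stvit_fit <- function(x, ...) x$loss_curve

#' Plot a training loss curve
#'
#' @param object An `stvit_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stvit_fit <- function(object, ...) {
  ggplot2::ggplot(object$loss_curve,
                  ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "epoch", y = "mean training cross-entropy") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix as a heatmap
#'
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metrics_report <- function(object, ...) {
  cm <- object$confusion
  df <- tibble::tibble(
    truth = factor(rep(rownames(cm), ncol(cm)), levels = rownames(cm)),
    pred = factor(rep(colnames(cm), each = nrow(cm)), levels = colnames(cm)),
    n = as.vector(cm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::scale_y_discrete(limits = rev(rownames(cm))) +
    ggplot2::labs(x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}

#' Plot one-vs-rest ROC curves
#'
#' @param object The list returned by [roc_curves()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot_roc <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               color = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
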