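# Confusion-matrix statistics, one-vs-rest metrics and ROC/AUC.

#' Confusion matrix of multi-class predictions
#'
#' Rows are true classes, columns predicted classes, in the order of
#' `levels` (default the fixed DILI class order).
#'
#' @param truth,pred Equal-length label vectors (characters or factors).
#' @param levels Class order; defaults to [dili_levels()] when the labels
#'   are DILI labels, otherwise to the union of observed levels.
#' @return Integer matrix with classes as dimnames.
#' @export
compute_confusion <- function(truth, pred, levels = NULL) {
  if (length(truth) != length(pred)) {
    stopf("truth (%d) and pred (%d) differ in length", length(truth),
          length(pred))
  }
  if (is.null(levels)) {
    obs <- unique(c(as.character(truth), as.character(pred)))
    levels <- if (all(obs %in% dili_levels())) dili_levels() else sort(obs)
  }
  truth <- factor(as.character(truth), levels = levels)
  pred <- factor(as.character(pred), levels = levels)
  if (anyNA(truth) || anyNA(pred)) stopf("labels outside the class order")
  cm <- table(truth = truth, pred = pred)
  matrix(as.integer(cm), nrow(cm), ncol(cm), dimnames = dimnames(cm))
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 P R / (P + R)`; defined as 0 when `P + R = 0`.
#'
#' @param precision,recall Rates in `[0, 1]` (vectorized).
#' @return F1 values.
#' @export
#' @examples
#' f1_score(0.7971, 0.9016)
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Recover integer counts behind printed one-vs-rest rates
#'
#' Published per-class recall and precision are rounded from integer
#' count ratios (TP/(TP+FN) and TP/(TP+FP)). Given the two printed rates,
#' this finds the smallest true-positive count and denominators that
#' reproduce both to their printed precision, allowing downstream
#' quantities (such as F1) to be computed from the exact fractions rather
#' than the rounded rates.
#'
#' @param recall,precision Printed rates (4 decimal places typical).
#' @param max_n Largest denominator considered (default 1000).
#' @param digits Printed precision (default 4).
#' @return List with `tp`, `recall_den`, `precision_den`, and the exact
#'   `recall`, `precision` and `f1` implied by the counts.
#' @export
#' @examples
#' reconstruct_ovr_counts(0.9016, 0.7971)  # 55/61 and 55/69 -> F1 0.8462
reconstruct_ovr_counts <- function(recall, precision, max_n = 1000,
                                   digits = 4) {
  tol <- 0.5 * 10^(-digits)
  for (tp in seq_len(max_n)) {
    rden <- round(tp / recall)
    pden <- round(tp / precision)
    if (rden < tp || pden < tp || rden > max_n || pden > max_n) next
    if (abs(tp / rden - recall) <= tol && abs(tp / pden - precision) <= tol) {
      r <- tp / rden
      p <- tp / pden
      return(list(tp = tp, recall_den = rden, precision_den = pden,
                  recall = r, precision = p, f1 = f1_score(p, r)))
    }
  }
  stopf("no integer counts <= %d reproduce recall %g / precision %g",
        max_n, recall, precision)
}

#' Per-class one-vs-rest metrics from a confusion matrix
#'
#' For each class c (treated as positive, all others negative):
#' recall = TP/(TP+FN), specificity = TN/(TN+FP), precision = TP/(TP+FP),
#' F1 the harmonic mean; overall accuracy = trace/total. Zero-denominator
#' rates are reported as 0 and flagged.
#'
#' @param cm Confusion matrix from [compute_confusion()].
#' @param auc Optional named per-class AUC vector (e.g. from [roc_curves()])
#'   to carry in the report.
#' @return A `metrics_report`: list with `confusion`, `per_class` tibble
#'   (class, recall, specificity, precision, f1, auc, degenerate flag),
#'   `accuracy` and `n`.
#' @export
compute_metrics <- function(cm, auc = NULL) {
  if (is.null(dim(cm)) || nrow(cm) != ncol(cm)) stopf("cm must be square")
  total <- sum(cm)
  if (total == 0) stopf("empty confusion matrix")
  classes <- rownames(cm) %||% paste0("class", seq_len(nrow(cm)))
  rate <- function(num, den) if (den > 0) num / den else 0
  rows <- lapply(seq_len(nrow(cm)), function(c) {
    tp <- cm[c, c]
    fn <- sum(cm[c, -c])
    fp <- sum(cm[-c, c])
    tn <- total - tp - fn - fp
    prec <- rate(tp, tp + fp)
    rec <- rate(tp, tp + fn)
    tibble::tibble(
      class = classes[c],
      recall = rec,
      specificity = rate(tn, tn + fp),
      precision = prec,
      f1 = f1_score(prec, rec),
      auc = if (is.null(auc)) NA_real_ else unname(auc[classes[c]]),
      degenerate = (tp + fn == 0) || (tp + fp == 0) || (tn + fp == 0))
  })
  structure(list(
    confusion = cm,
    per_class = dplyr::bind_rows(rows),
    accuracy = sum(diag(cm)) / total,
    n = total
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d, accuracy = %.4f\n", x$n, x$accuracy))
  print(x$per_class)
  invisible(x)
}

#' One-vs-rest ROC curves and AUC
#'
#' For each class, sweeps thresholds over that class's predicted probability
#' (tied scores grouped, stepping both axes at once) and integrates the
#' curve by the trapezoid rule. A class with no positives or no negatives is
#' flagged and its AUC is `NA`.
#'
#' @param truth Label vector.
#' @param probs n x K matrix of class probabilities, columns in class order
#'   (rows must sum to 1).
#' @param levels Class order; default as in [compute_confusion()].
#' @return List with `curves` (tibble class/threshold/fpr/tpr) and `auc`
#'   (named vector).
#' @export
roc_curves <- function(truth, probs, levels = NULL) {
  probs <- as.matrix(probs)
  if (nrow(probs) != length(truth)) stopf("probs rows must match truth")
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    stopf("probability rows must sum to 1")
  }
  if (is.null(levels)) {
    levels <- if (all(as.character(truth) %in% dili_levels()) &&
                  ncol(probs) == 3) dili_levels()
              else colnames(probs) %||% paste0("class", seq_len(ncol(probs)))
  }
  curves <- list()
  auc <- setNames(rep(NA_real_, length(levels)), levels)
  for (ci in seq_along(levels)) {
    pos <- as.character(truth) == levels[ci]
    np <- sum(pos)
    nn <- sum(!pos)
    if (np == 0 || nn == 0) {
      warning(sprintf("class %s is degenerate (no %s); AUC undefined",
                      levels[ci], if (np == 0) "positives" else "negatives"))
      next
    }
    sc <- probs[, ci]
    thr <- sort(unique(sc), decreasing = TRUE)
    tp <- vapply(thr, function(t) sum(pos & sc >= t), numeric(1))
    fp <- vapply(thr, function(t) sum(!pos & sc >= t), numeric(1))
    tpr <- c(0, tp / np)
    fpr <- c(0, fp / nn)
    curves[[levels[ci]]] <- tibble::tibble(
      class = levels[ci], threshold = c(Inf, thr), fpr = fpr, tpr = tpr)
    auc[ci] <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  }
  list(curves = dplyr::bind_rows(curves), auc = auc)
}

#' Score predictions into a metrics report
#'
#' @param truth,pred Label vectors.
#' @param probs Optional probability matrix for per-class AUC.
#' @param levels Class order.
#' @return A `metrics_report`.
#' @export
evaluate_predictions <- function(truth, pred, probs = NULL, levels = NULL) {
  cm <- compute_confusion(truth, pred, levels)
  auc <- NULL
  if (!is.null(probs)) {
    auc <- suppressWarnings(roc_curves(truth, probs,
                                       levels = rownames(cm)))$auc
  }
  compute_metrics(cm, auc = auc)
}

# Fold-averaged report: metric columns are arithmetic means across folds;
# the confusion matrix is the pooled sum (kept for reference).
mean_metrics_report <- function(reports) {
  per <- dplyr::bind_rows(lapply(reports, `[[`, "per_class")) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(dplyr::across(c("recall", "specificity", "precision",
                                     "f1", "auc"),
                                   ~ mean(.x, na.rm = TRUE)),
                     degenerate = any(.data$degenerate), .groups = "drop")
  per <- per[match(rownames(reports[[1]]$confusion), per$class), ]
  structure(list(
    confusion = Reduce(`+`, lapply(reports, `[[`, "confusion")),
    per_class = per,
    accuracy = mean(vapply(reports, `[[`, numeric(1), "accuracy")),
    n = sum(vapply(reports, `[[`, numeric(1), "n"))
  ), class = "metrics_report")
}
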