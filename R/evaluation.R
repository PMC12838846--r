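#' Confusion matrix from label vectors
#'
#' Builds the K x K count matrix with rows indexed by true class and columns by
#' predicted class: `counts[i, j]` is the number of samples of true class
#' `i - 1` predicted as class `j - 1`.
#'
#' @param true,pred Equal-length 0-based class label vectors (values in
#'   `[0, K)`).
#' @param n_classes Number of classes K.
#' @param class_names Optional class names in index order; defaults to
#'   [default_class_names()].
#' @return An object of class `confusion_matrix` wrapping the integer count
#'   matrix (`$counts`) and `$class_names`.
#' @export
#' @examples
#' confusion_matrix(c(0, 0, 1), c(0, 1, 1), n_classes = 2)
confusion_matrix <- function(true, pred, n_classes, class_names = NULL) {
  check_number(n_classes, "n_classes", min = 2, integerish = TRUE)
  true <- as_label_int(true, n_classes, "true")
  pred <- as_label_int(pred, n_classes, "pred")
  if (length(true) != length(pred)) abort_bad_arg("`true` and `pred` must have equal length.")
  if (is.null(class_names)) class_names <- default_class_names(n_classes)
  counts <- matrix(0L, n_classes, n_classes,
                   dimnames = list(true = class_names, pred = class_names))
  for (i in seq_along(true)) {
    counts[true[i] + 1L, pred[i] + 1L] <- counts[true[i] + 1L, pred[i] + 1L] + 1L
  }
  structure(list(counts = counts, class_names = class_names),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> (rows = true, cols = predicted)\n")
  print(x$counts)
  invisible(x)
}

#' Metrics report from a confusion matrix
#'
#' One-vs-rest per-class precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and F1
#' (their harmonic mean), plus accuracy, error rate, macro (unweighted mean)
#' and support-weighted aggregates — all in percent. Support-weighted recall
#' is identical to accuracy before rounding (each correct prediction is
#' counted once in both). A class that never occurs or is never predicted gets
#' metric 0 with a warning. Reported values are rounded to 2 decimals;
#' unrounded values are kept alongside.
#'
#' @param cm A [confusion_matrix()].
#' @return An object of class `metrics_report` with `per_class` (tibble:
#'   class, support, precision, recall, f1) and aggregate fields `accuracy`,
#'   `error_rate`, `macro_f1`, `weighted_f1`, `weighted_precision`,
#'   `weighted_recall` (percent, 2 decimals) plus a `raw` list of unrounded
#'   values.
#' @export
metrics_from_cm <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  M <- cm$counts
  total <- sum(M)
  if (total == 0) abort_bad_arg("confusion matrix is empty.")
  K <- nrow(M)
  tp <- unname(diag(M))
  support <- unname(rowSums(M))
  predicted <- unname(colSums(M))
  if (any(support == 0) || any(predicted == 0)) {
    warning("class with zero support or zero predictions; its metrics are set to 0.")
  }
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  w <- support / total
  raw <- list(
    accuracy = 100 * sum(tp) / total,
    macro_f1 = 100 * mean(f1),
    weighted_f1 = 100 * sum(w * f1),
    weighted_precision = 100 * sum(w * precision),
    # support-weighted recall telescopes to trace/total; computing it that way
    # keeps the identity with accuracy exact in floating point
    weighted_recall = 100 * sum(tp) / total
  )
  raw$error_rate <- 100 - raw$accuracy
  per_class <- tibble::tibble(
    class = cm$class_names,
    support = as.integer(support),
    precision = round_half_up(100 * precision, 2),
    recall = round_half_up(100 * recall, 2),
    f1 = round_half_up(100 * f1, 2)
  )
  structure(
    list(per_class = per_class,
         accuracy = round_half_up(raw$accuracy, 2),
         error_rate = round_half_up(raw$error_rate, 2),
         macro_f1 = round_half_up(raw$macro_f1, 2),
         weighted_f1 = round_half_up(raw$weighted_f1, 2),
         weighted_precision = round_half_up(raw$weighted_precision, 2),
         weighted_recall = round_half_up(raw$weighted_recall, 2),
         n = total, raw = raw),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d  accuracy %.2f%%  error %.2f%%  weighted F1 %.2f%%  macro F1 %.2f%%\n",
              x$n, x$accuracy, x$error_rate, x$weighted_f1, x$macro_f1))
  print(as.data.frame(x$per_class))
  invisible(x)
}

#' Tidy per-class metrics
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return The per-class tibble (class, support, precision, recall, f1).
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' One-row aggregate metrics
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return A one-row tibble with accuracy, error rate and the weighted/macro
#'   aggregates, in percent.
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(n = x$n, accuracy = x$accuracy, error_rate = x$error_rate,
                 macro_f1 = x$macro_f1, weighted_f1 = x$weighted_f1,
                 weighted_precision = x$weighted_precision,
                 weighted_recall = x$weighted_recall)
}

#' Accuracy (percent) from correct/total counts
#'
#' @param correct Number of correct predictions (`0 <= correct <= total`).
#' @param total Number of evaluated samples (> 0).
#' @return `100 * correct / total`, rounded half-up to 2 decimals.
#' @export
#' @examples
#' accuracy_from_counts(623, 636)  # 97.96
accuracy_from_counts <- function(correct, total) {
  check_number(total, "total", min = 1, integerish = TRUE)
  check_number(correct, "correct", min = 0, max = total, integerish = TRUE)
  round_half_up(100 * correct / total, 2)
}

#' Heat-map of a confusion matrix
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- as.data.frame(as.table(object$counts))
  names(df) <- c("true", "pred", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$true, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev(object$class_names)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true", fill = "count") +
    ggplot2::theme_minimal()
}

#' Training-curve plot
#' @param object A `fusion_fit` or `mlp_fit`.
#' @param ... Unused.
#' @return A ggplot object with loss and validation macro F1 per epoch.
#' @export
autoplot.fusion_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, c("loss", "val_macro_f1"),
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.fusion_fit
#' @export
autoplot.mlp_fit <- autoplot.fusion_fit
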