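#' F1 score from precision and recall
#'
#' Harmonic mean `2 * P * R / (P + R)`, on whatever scale (fraction or
#' percent) the inputs share.
#'
#' @param precision,recall numeric (vectors recycle).
#' @return numeric F1.
#' @export
f1_from_pr <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Score pooled cross-validation predictions
#'
#' Computes the standard one-vs-rest confusion counts per class and derives
#' accuracy, precision, recall and F1 (all in percent), macro averages
#' (unweighted class means), the fold-wise standard error of each class's F1
#' (sample SD across folds / sqrt(k)), and the row-normalized confusion
#' matrix in percent.
#'
#' @param predictions factor of predicted labels (pooled over validation
#'   folds).
#' @param labels factor of true labels, same length and levels.
#' @param fold integer fold id per sample (for the F1 standard errors); may
#'   be `NULL` to skip them.
#' @return a `state_report`.
#' @export
score_predictions <- function(predictions, labels, fold = NULL) {
  lv_in <- unique(c(if (is.factor(labels)) levels(labels),
                    if (is.factor(predictions)) levels(predictions),
                    as.character(labels), as.character(predictions)))
  lv <- levels(state_factor(lv_in))
  labels <- factor(as.character(labels), levels = lv)
  predictions <- factor(as.character(predictions), levels = lv)
  if (length(predictions) != length(labels)) {
    stop_eeg("predictions and labels differ in length", "shape")
  }
  for (cls in lv) {
    if (!any(labels == cls) && !any(predictions == cls)) {
      stop_eeg(sprintf("class '%s' absent from both labels and predictions;
metrics undefined", cls), "undefined_metric")
    }
  }
  counts <- table(truth = labels, prediction = predictions)
  per_class <- purrr::map_dfr(lv, function(cls) {
    tp <- sum(predictions == cls & labels == cls)
    fp <- sum(predictions == cls & labels != cls)
    fn <- sum(predictions != cls & labels == cls)
    prec <- if (tp + fp == 0) 0 else 100 * tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else 100 * tp / (tp + fn)
    tibble::tibble(class = cls, precision = prec, recall = rec,
                   f1 = f1_from_pr(prec, rec))
  })
  if (!is.null(fold)) {
    se <- vapply(lv, function(cls) {
      f1s <- vapply(sort(unique(fold)), function(f) {
        sel <- fold == f
        tp <- sum(predictions[sel] == cls & labels[sel] == cls)
        fp <- sum(predictions[sel] == cls & labels[sel] != cls)
        fn <- sum(predictions[sel] != cls & labels[sel] == cls)
        prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
        rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
        f1_from_pr(prec, rec)
      }, numeric(1))
      sd(f1s) / sqrt(length(f1s))
    }, numeric(1))
    per_class$se_f1 <- unname(se)
  }
  conf <- 100 * prop.table(counts, margin = 1)
  structure(list(
    per_class = per_class,
    accuracy = 100 * mean(predictions == labels),
    macro = list(precision = mean(per_class$precision),
                 recall = mean(per_class$recall),
                 f1 = mean(per_class$f1)),
    confusion = conf, counts = counts,
    k = if (is.null(fold)) NA_integer_ else length(unique(fold))),
    class = "state_report")
}

#' @export
print.state_report <- function(x, ...) {
  cat(sprintf("<state_report> accuracy %.1f%%, macro F1 %.1f%%\n",
              x$accuracy, x$macro$f1))
  print(as.data.frame(x$per_class), digits = 3)
  invisible(x)
}

#' @export
tidy.state_report <- function(x, ...) x$per_class

#' @export
glance.state_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy,
                 macro_precision = x$macro$precision,
                 macro_recall = x$macro$recall,
                 macro_f1 = x$macro$f1)
}

#' @export
autoplot.state_report <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  names(df) <- c("truth", "prediction", "percent")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prediction, y = .data$truth,
                                   fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$percent)),
                       size = 3) +
    ggplot2::scale_y_discrete(limits = rev(rownames(object$confusion))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Predicted state", y = "True state",
                  fill = "% of row") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL

#' Serialize a state report to JSON
#'
#' @param report a `state_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(per_class = report$per_class,
              accuracy = report$accuracy,
              macro = report$macro,
              confusion_percent = as.data.frame(report$confusion))
  jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
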