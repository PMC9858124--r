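# Classification performance: confusion counts, the five standard scores,
# and model x modality comparison tables.

#' Confusion counts with Tremor as the positive class
#'
#' @param y_true,y_pred Vectors of binary labels (`"tremor"`/`"no_tremor"`,
#'   factors or characters) of equal length.
#' @param positive Positive-class label (default `"tremor"`).
#' @return A `confusion_counts` object: `tp`, `tn`, `fp`, `fn`, `n`.
#' @export
confusion_counts <- function(y_true, y_pred, positive = "tremor") {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  lev <- unique(c(y_true, y_pred))
  if (length(lev) > 2) stop("labels must be binary; got: ",
                            paste(lev, collapse = ", "))
  tp <- sum(y_true == positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn, n = length(y_true)),
            class = "confusion_counts")
}

#' The five classification scores from confusion counts
#'
#' precision = TP/(TP+FP); accuracy = (TP+TN)/n; recall = TP/(TP+FN);
#' specificity = TN/(TN+FP); f1 = harmonic mean of precision and recall.
#' A ratio with zero denominator is reported as 0 and flagged in
#' `$undefined` rather than erroring, so batch reports stay total.
#'
#' @param counts A `confusion_counts` object (or a prediction pair via
#'   `confusion_counts()`).
#' @param model,modality Optional provenance tags carried into the report.
#' @return A `metrics_report`: the five scores, the counts, provenance, and
#'   `undefined` (names of zero-denominator metrics, if any).
#' @export
classification_metrics <- function(counts, model = NA_character_,
                                   modality = NA_character_) {
  stopifnot(inherits(counts, "confusion_counts"))
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe_div(counts$tp, counts$tp + counts$fp)
  recall <- safe_div(counts$tp, counts$tp + counts$fn)
  specificity <- safe_div(counts$tn, counts$tn + counts$fp)
  accuracy <- safe_div(counts$tp + counts$tn, counts$n)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  vals <- c(precision = precision, recall = recall,
            specificity = specificity, accuracy = accuracy, f1 = f1)
  undefined <- names(vals)[is.na(vals)]
  vals[is.na(vals)] <- 0
  structure(c(as.list(vals),
              list(counts = counts, model = model, modality = modality,
                   undefined = undefined)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  hdr <- if (!is.na(x$model)) sprintf(" [%s / %s]", x$model, x$modality) else ""
  cat(sprintf(
    "Metrics%s: precision %.3f  recall %.3f  specificity %.3f  accuracy %.3f  f1 %.3f\n",
    hdr, x$precision, x$recall, x$specificity, x$accuracy, x$f1))
  if (length(x$undefined)) {
    cat("  (zero-denominator, reported as 0:",
        paste(x$undefined, collapse = ", "), ")\n")
  }
  invisible(x)
}

#' Model x modality comparison report
#'
#' Collects per-evaluation metric reports into a long table, an F1 matrix
#' (model x modality), and mean +/- SD aggregates across modalities per
#' model and across models per modality. The SD uses the population (n)
#' normalisation.
#'
#' @param reports A list of `metrics_report` objects with distinct
#'   (model, modality) pairs.
#' @return A `comparison_report`: `table` (long data frame), `f1_matrix`,
#'   `by_model` and `by_modality` (mean +/- population SD of F1).
#' @export
compare_reports <- function(reports) {
  if (!length(reports)) stop("empty report collection")
  stopifnot(all(vapply(reports, inherits, logical(1), "metrics_report")))
  keys <- vapply(reports, function(r) paste(r$model, r$modality, sep = "|"),
                 character(1))
  if (anyDuplicated(keys)) stop("duplicate (model, modality) pairs")
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(model = r$model, modality = r$modality,
               precision = r$precision, recall = r$recall,
               specificity = r$specificity, accuracy = r$accuracy, f1 = r$f1)
  }))
  models <- unique(tab$model)
  modalities <- unique(tab$modality)
  f1m <- matrix(NA_real_, length(models), length(modalities),
                dimnames = list(models, modalities))
  for (i in seq_len(nrow(tab))) f1m[tab$model[i], tab$modality[i]] <- tab$f1[i]
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  by_model <- data.frame(
    model = models,
    f1_mean = vapply(models, function(m) mean(tab$f1[tab$model == m]), 0),
    f1_sd = vapply(models, function(m) sd_pop(tab$f1[tab$model == m]), 0),
    row.names = NULL)
  by_modality <- data.frame(
    modality = modalities,
    f1_mean = vapply(modalities, function(m) mean(tab$f1[tab$modality == m]), 0),
    f1_sd = vapply(modalities, function(m) sd_pop(tab$f1[tab$modality == m]), 0),
    row.names = NULL)
  structure(list(table = tab, f1_matrix = f1m, by_model = by_model,
                 by_modality = by_modality, sd_type = "population"),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("F1 by model and modality:\n")
  print(round(x$f1_matrix, 3))
  cat("\nMean +/- SD (population) across modalities per model:\n")
  print(transform(x$by_model, f1_mean = round(f1_mean, 3),
                  f1_sd = round(f1_sd, 3)))
  invisible(x)
}

#' Grouped-bar plot of classification scores
#'
#' One panel per modality, grouped bars per model over the five metrics.
#' Requires ggplot2.
#'
#' @param report A `comparison_report`.
#' @return A ggplot object.
#' @export
plot_metric_bars <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_metric_bars requires the ggplot2 package")
  }
  tab <- report$table
  long <- do.call(rbind, lapply(
    c("precision", "recall", "specificity", "accuracy", "f1"),
    function(m) data.frame(model = tab$model, modality = tab$modality,
                           metric = m, score = tab[[m]])))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$score,
                                     fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~modality) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "score") +
    ggplot2::theme_minimal()
}
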