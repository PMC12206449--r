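#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the package's result
#' objects: training curves for models, a confusion heatmap for metrics
#' reports, per-fold metric bars for cross-validation results, and a
#' top-probe saliency bar chart for attributions.
#'
#' @param object A package result object.
#' @param top_n Probes to show for attribution results.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom rlang .data
#' @name autoplot_methods
NULL

#' @rdname autoplot_methods
#' @export
autoplot.trained_model <- function(object, ...) {
  log <- tidyr::pivot_longer(object$training_log, c("train_loss", "val_loss"),
                             names_to = "set", values_to = "loss")
  ggplot2::ggplot(log, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                    colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "Training curves", x = "Epoch",
                  y = "Cross-entropy loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot_methods
#' @export
autoplot.metrics_report <- function(object, ...) {
  df <- tibble::as_tibble(as.table(object$confusion), .name_repair = "minimal")
  names(df) <- c("truth", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = sprintf("Confusion matrix (weighted MCC %.3f)",
                                  object$weighted_mcc),
                  x = "Predicted", y = "True") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot_methods
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy(object),
                            c("weighted_mcc", "weighted_f1", "accuracy"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(title = "Per-fold cross-validation metrics", x = "Fold",
                  y = "Value", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot_methods
#' @export
autoplot.attribution_result <- function(object, top_n = 20, ...) {
  df <- utils::head(object$saliency, top_n)
  df$probe_id <- factor(df$probe_id, levels = rev(df$probe_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$saliency, y = .data$probe_id)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(title = sprintf("Top %d probes for class '%s'", nrow(df),
                                  object$target_class),
                  x = "Saliency (mean ||grad x input||)", y = NULL) +
    ggplot2::theme_minimal()
}
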