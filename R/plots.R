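#' Heatmap of a confusion matrix
#'
#' @param report an [evaluate()] result.
#' @return a ggplot object.
#' @export
plot_confusion <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_confusion requires ggplot2", call. = FALSE)
  }
  cm <- unclass(report$confusion)
  df <- expand.grid(actual = report$class_names, predicted = report$class_names)
  df$count <- as.vector(cm)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$actual,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev(report$class_names)) +
    ggplot2::labs(title = paste(report$scenario, report$partition, sep = " / ")) +
    ggplot2::theme_minimal()
}

#' Classes x leads heatmap of lead importances
#'
#' @param importances named list of `lead_importance` (as from
#'   [per_class_importance()]).
#' @return a ggplot object.
#' @export
plot_lead_importance <- function(importances) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_lead_importance requires ggplot2", call. = FALSE)
  }
  df <- do.call(rbind, lapply(importances, function(li) {
    data.frame(class = li$class_label, lead = factor(ECG_LEADS, ECG_LEADS),
               importance = as.numeric(li$importance))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lead, y = .data$class,
                                   fill = .data$importance)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "ECG lead", y = NULL, fill = "importance") +
    ggplot2::theme_minimal()
}
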