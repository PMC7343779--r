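#' Plot per-profile metric distributions
#'
#' Histograms of the per-profile metric means, faceted by metric, with the
#' radiality angle on its natural radian scale.
#'
#' @param object A `profile_metrics` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.profile_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    dplyr::all_of(c("angle_r", "perp_pd", "parl_pd", "md", "fa")),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "profiles",
                  title = "Per-profile cortical metric distributions")
}

#' Plot regional feature values
#'
#' Dot plot of one metric's regional values, whole brain highlighted.
#'
#' @param object A `region_features` tibble from [aggregate_regions()].
#' @param metric Metric to show (default `"angle_r"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.region_features <- function(object, metric = "angle_r", ...) {
  d <- dplyr::filter(as_tibble(object), .data$metric == !!metric,
                     !is.na(.data$value))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value,
                                  y = stats::reorder(.data$region, .data$value),
                                  colour = .data$region == "whole brain")) +
    ggplot2::geom_point(size = 2, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "firebrick")) +
    ggplot2::labs(x = metric, y = NULL, title = "Regional values")
}

#' Plot classifier-selection win counts
#'
#' @param object A `selection_result` from [select_classifier()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.selection_result <- function(object, ...) {
  d <- dplyr::mutate(object$wins, model = factor(.data$model, levels = object$models))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data$wins)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = sprintf("wins out of %d runs", object$n_runs),
                  title = "Cross-validated classifier selection")
}

#' Plot a confusion matrix as a heatmap
#'
#' @param object A `metric_report` from [confusion_metrics()] or a
#'   `classification_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.metric_report <- function(object, ...) {
  cm <- object$counts
  d <- as_tibble(as.table(cm), .name_repair = "minimal")
  names(d) <- c("predicted", "true", "n")
  d$predicted <- factor(d$predicted, levels = rev(rownames(cm)))
  d$true <- factor(d$true, levels = colnames(cm))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$true, y = .data$predicted,
                                  fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_fill_viridis_c(guide = "none") +
    ggplot2::labs(title = sprintf("Confusion matrix (accuracy %.1f%%)",
                                  object$accuracy),
                  x = "true class", y = "predicted class")
}

#' @exportS3Method
autoplot.classification_report <- function(object, ...) {
  autoplot(object$metrics, ...)
}
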