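#' Plot an annotated series
#'
#' Draws the signal with detected (or planted) events shaded and anchors
#' marked, one colour per event type.
#'
#' @param object an [annotated_series()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.annotated_series <- function(object, ...) {
  df <- tidy(object$series)
  ev <- object$events
  sp <- object$series$sampling_period_ms
  p <- ggplot(df, aes(x = .data$time_ms, y = .data$value)) +
    geom_line(linewidth = 0.3, colour = "grey30")
  if (nrow(ev) > 0) {
    shade <- dplyr::mutate(ev, xmin = .data$start * sp, xmax = .data$end * sp)
    p <- p +
      geom_rect(
        data = shade,
        aes(xmin = .data$xmin, xmax = .data$xmax, fill = .data$event_type),
        ymin = -Inf, ymax = Inf, alpha = 0.25, inherit.aes = FALSE
      ) +
      geom_vline(
        data = shade, aes(xintercept = .data$anchor_ms, colour = .data$event_type),
        linetype = "dotted", show.legend = FALSE
      )
  }
  p + labs(x = "time (ms)", y = "value",
           title = object$series$series_id, fill = "event type") +
    theme_minimal()
}

#' Heatmap of a pairwise similarity matrix
#'
#' @param S matrix from [pairwise_similarity_matrix()].
#' @return a ggplot object.
#' @export
plot_similarity_matrix <- function(S) {
  df <- tibble::as_tibble(as.table(S), .name_repair = ~ c("a", "b", "similarity"))
  ggplot(df, aes(x = .data$a, y = .data$b, fill = .data$similarity)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "similarity") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, hjust = 1))
}

#' Plot cross-validation accuracy per class
#'
#' @param object a [cross_validate()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot(object$per_class,
         aes(x = .data$class_label, y = .data$accuracy)) +
    geom_col(fill = "steelblue", width = 0.6) +
    geom_hline(yintercept = object$overall_accuracy, linetype = "dashed") +
    coord_cartesian(ylim = c(0, 100)) +
    labs(x = NULL, y = "accuracy (%)",
         title = sprintf("%d-fold cross-validation (overall %.1f%%)",
                         object$k, object$overall_accuracy)) +
    theme_minimal()
}
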