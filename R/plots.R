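# ggplot2 visualisations.

#' Plot a temporal pain profile
#'
#' Raw and emotion-weighted pain scores over time, with the pain-level
#' thresholds as horizontal guides — the weighted curve sits below the raw
#' one for positive expressions (weight < 1) and above it for negative ones.
#'
#' @param object A `pain_profile` from [temporal_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pain_profile <- function(object, ...) {
  thr <- attr(object, "thresholds") %||% default_pain_thresholds()
  long <- tidyr::pivot_longer(as_tibble(object), c("ps", "plew"),
                              names_to = "score", values_to = "value")
  long$score <- factor(long$score, levels = c("ps", "plew"),
                       labels = c("raw (PLE)", "weighted (PLEw)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     color = .data$score)) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                        color = "grey75", linewidth = 0.3) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(values = c("raw (PLE)" = "#3366bb",
                                           "weighted (PLEw)" = "#cc3333")) +
    ggplot2::labs(x = "time (s)", y = "pain score", color = NULL,
                  title = "Temporal pain profile") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix heat map
#'
#' @param object A `confusion_matrix` from [confusion()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy(object)
  df$truth <- factor(df$truth, levels = rev(rownames(object)))
  df$pred <- factor(df$pred, levels = colnames(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7bb6") +
    ggplot2::labs(x = "predicted", y = "true", fill = "count",
                  title = "Expression confusion matrix") +
    ggplot2::theme_minimal()
}

#' Plot a landmark set with its AU zones
#'
#' Scatters the mesh points (y axis flipped to image orientation) and
#' colors the members of each configured AU zone.
#'
#' @param lm A `landmark_set`.
#' @param config A `zone_config`.
#' @return A ggplot object.
#' @export
plot_zones <- function(lm, config = default_zone_config()) {
  zt <- zone_table(config)
  pts <- as_tibble(lm)
  pts$au_id <- zt$au_id[match(pts$point, zt$point)]
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(data = pts[is.na(pts$au_id), ],
                        color = "grey80", size = 0.5) +
    ggplot2::geom_point(data = pts[!is.na(pts$au_id), ],
                        ggplot2::aes(color = .data$au_id), size = 1.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(color = "AU zone", title = frame_id(lm)) +
    ggplot2::theme_minimal()
}
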