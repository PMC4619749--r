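# ggplot2 displays for the main result types.

#' Plot a belief trajectory
#'
#' Posterior belief means per state component over trials.
#'
#' @param object A `wcst_beliefs` from [run_filter()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wcst_beliefs <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial, y = .data$mean,
                                   color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$level), ncol = 1,
                        scales = "free_y") +
    ggplot2::labs(x = "trial", y = "posterior mean relevance",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot model-selection probabilities
#'
#' Bar chart of the protected exceedance probabilities with the 0.95
#' confidence threshold line.
#'
#' @param object A `wcst_bms`.
#' @param threshold Confidence threshold to draw (default 0.95).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wcst_bms <- function(object, threshold = 0.95, ...) {
  df <- tidy(object)
  df$model <- factor(df$model, levels = df$model)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$protected_xp)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        color = "darkorange") +
    ggplot2::labs(x = NULL, y = "protected exceedance probability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot an expected-response trajectory
#'
#' Modal model responses with the 95% probability band, overlaid with the
#' observed responses, per visual feature.
#'
#' @param trajectory Output of [expected_response_trajectory()].
#' @return A ggplot object.
#' @export
plot_response_trajectory <- function(trajectory) {
  ggplot2::ggplot(trajectory, ggplot2::aes(x = .data$trial,
                                           color = .data$feature,
                                           fill = .data$feature)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line(ggplot2::aes(y = .data$response)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 0.8) +
    ggplot2::labs(x = "trial", y = "fraction of money",
                  color = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
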