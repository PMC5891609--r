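#' Accuracy and RT curves across the noise grid
#'
#' Line plots of the condition summary: accuracy (or mean RT over correct
#' trials) as a function of noise sd, one line per feedback setting, with
#' +/- 1 standard-error bars.
#'
#' @param summary a [summarize_conditions()] tibble.
#' @return a ggplot object.
#' @export
plot_accuracy <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(
    x = .data$sd, y = .data$accuracy,
    colour = .data$feedback, group = .data$feedback
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$accuracy - .data$se_accuracy,
      ymax = .data$accuracy + .data$se_accuracy
    ), width = 0.03) +
    ggplot2::scale_colour_manual(
      values = c("TRUE" = "#00662c", "FALSE" = "#b2182b"),
      labels = c("TRUE" = "feedback", "FALSE" = "no feedback"),
      name = NULL
    ) +
    ggplot2::labs(x = "noise SD", y = "proportion correct") +
    ggplot2::theme_minimal()
}

#' @rdname plot_accuracy
#' @export
plot_rt <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(
    x = .data$sd, y = .data$mean_rt,
    colour = .data$feedback, group = .data$feedback
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_rt - .data$se_rt,
      ymax = .data$mean_rt + .data$se_rt
    ), width = 0.03) +
    ggplot2::scale_colour_manual(
      values = c("TRUE" = "#00662c", "FALSE" = "#b2182b"),
      labels = c("TRUE" = "feedback", "FALSE" = "no feedback"),
      name = NULL
    ) +
    ggplot2::labs(x = "noise SD", y = "mean RT over correct trials (cycles)") +
    ggplot2::theme_minimal()
}

#' Identity-line scatter of paired item RTs
#'
#' One point per word recognized correctly under both feedback settings;
#' points below the identity line were recognized faster with feedback.
#' The caption carries the three class percentages.
#'
#' @param comparison a [compare_items()] result.
#' @return a ggplot object.
#' @export
plot_item_comparison <- function(comparison) {
  items <- comparison$items
  pct <- comparison$percentages
  lab <- sprintf("faster with feedback %.0f%% / without %.0f%% / equal %.0f%%",
                 pct["faster_with"], pct["faster_without"], pct["equal"])
  ggplot2::ggplot(items, ggplot2::aes(
    x = .data$rt_nofeedback, y = .data$rt_feedback, colour = .data$class
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "RT without feedback (cycles)", y = "RT with feedback (cycles)",
      title = sprintf("noise SD = %g (n = %d)", comparison$sd, comparison$n),
      caption = lab, colour = NULL
    ) +
    ggplot2::theme_minimal()
}
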