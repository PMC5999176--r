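#' Plot a stepped-wedge switching schedule
#'
#' Tile diagram of strategy by hospital and period, the standard
#' visualization of a stepped-wedge design.
#'
#' @param object An `fh_schedule` tibble from [build_schedule()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' ggplot2::autoplot(build_schedule(trial_design()))
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.fh_schedule <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(.data$period),
    y = factor(.data$hospital, levels = rev(sort(unique(.data$hospital)))),
    fill = .data$strategy
  )) +
    ggplot2::geom_tile(color = "white", linewidth = 0.8) +
    ggplot2::scale_fill_manual(
      values = c(control = "grey80", intervention = "#2C7FB8")
    ) +
    ggplot2::labs(x = "Period", y = "Hospital", fill = "Strategy",
                  title = "Stepped-wedge switching schedule") +
    ggplot2::theme_minimal()
}

#' Plot the referral criteria matched by a history
#'
#' @param object A `referral_result` from [evaluate_history()].
#' @param ... Unused.
#' @return A ggplot object: one bar per criterion, filled when matched.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.referral_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$criterion), y = as.numeric(.data$matched),
    fill = .data$group, alpha = .data$matched
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.25),
                                guide = "none") +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(
      x = "Referral criterion", y = NULL, fill = "Group",
      title = paste("Recommendation:", object$recommendation)
    ) +
    ggplot2::theme_minimal()
}

#' Forest-style plot of a logit-linear fit
#'
#' Shows the conditional odds ratio of the intervention with its Wald
#' confidence interval on a log scale.
#'
#' @param object An `fh_logit` from [fit_logit_linear()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.fh_logit <- function(object, ...) {
  d <- glance(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$odds_ratio, y = "intervention")) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", color = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = sprintf("Conditional odds ratio (%.0f%% Wald CI)",
                  100 * object$conf_level),
      y = NULL,
      title = sprintf("Intervention effect: OR %.2f (%.2f-%.2f), p = %.2g",
                      d$odds_ratio, d$conf_low, d$conf_high, d$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
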