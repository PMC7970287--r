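# ggplot2 views of the result objects.

#' Forest plot of adjusted effect estimates
#'
#' @param object An `effect_estimates` tibble from [estimate_effects()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot effect_estimates
#' @export
autoplot.effect_estimates <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$outcome,
                                   colour = .data$comparison)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "Adjusted difference vs control (95% bootstrap CI)",
                  y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot age-adjusted marginal arm means
#'
#' @param means Tibble from [adjusted_means()].
#' @param outcome Optional axis label.
#' @return A ggplot.
#' @export
plot_adjusted_means <- function(means, outcome = NULL) {
  ggplot2::ggplot(means, ggplot2::aes(x = .data$arm, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::labs(x = NULL, y = outcome %||% "age-adjusted mean (95% CI)") +
    ggplot2::theme_minimal()
}

#' Plot fitted age-conditional reference moments
#'
#' Shows the control-arm mean and ±1 / ±4 SD envelopes over age for a
#' fitted standardiser.
#'
#' @param object An `age_standardizer`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot age_standardizer
#' @export
autoplot.age_standardizer <- function(object, ...) {
  ages <- seq(object$age_range[1], object$age_range[2], length.out = 200)
  df <- tibble(age = ages, mean = std_mean(object, ages),
               sd = std_sd(object, ages))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - 4 * .data$sd,
                                      ymax = .data$mean + 4 * .data$sd),
                         fill = "grey90") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::labs(x = "age (months)", y = object$outcome,
                  title = "control-arm age-conditional mean, ±1 and ±4 SD") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
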