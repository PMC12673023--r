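# ggplot2 methods for curves, subjects and cohorts.

#' Plot per-phase metric curves
#'
#' @param object an `aorta_curves` tibble (from [compute_subject()]).
#' @param metrics optional character vector restricting which metrics to show.
#' @param ... ignored.
#' @return A ggplot object (value vs cardiac phase, one facet per metric).
#' @export
autoplot.aorta_curves <- function(object, metrics = NULL, ...) {
  df <- object
  if (!is.null(metrics)) df <- dplyr::filter(df, .data$metric %in% metrics)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase, y = .data$value)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "cardiac phase (0 = end-diastole)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.aorta_curves
#' @export
autoplot.aorta_subject <- function(object, metrics = NULL, ...) {
  autoplot(object$curves, metrics = metrics, ...)
}

#' Boxplots of a cohort metric by group
#'
#' @param cohort a cohort tibble (see [simulate_cohort()]).
#' @param metric unquoted metric column.
#' @return A ggplot object.
#' @export
plot_cohort_metric <- function(cohort, metric) {
  ggplot2::ggplot(cohort, ggplot2::aes(x = .data$group, y = {{ metric }},
                                       fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.size = 0.8) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a regression result
#'
#' @param object an `aorta_regression`.
#' @param ... ignored.
#' @return A ggplot object (estimates with 95% CIs, univariate vs
#'   multivariate).
#' @export
autoplot.aorta_regression <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term,
                                   color = .data$model)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2, position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = "coefficient (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
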