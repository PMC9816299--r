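# ggplot2 visualizations for the main result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Kaplan-Meier plot for a dichotomization
#'
#' Step curves of the product-limit estimate for the low and high groups at
#' the optimized cutoff, annotated with the logrank p.
#'
#' @param object A `dichotomization` (from [optimize_cutoff()]).
#' @param time,event The survival outcome used for the fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.dichotomization <- function(object, time, event, ...) {
  assert_that(object$admissible, "no admissible cutoff to plot")
  km <- km_curve(time, event, object$group)
  base <- km |> group_by(.data$group) |>
    dplyr::reframe(time = c(0, .data$time), surv = c(1, .data$surv))
  ggplot2::ggplot(base, ggplot2::aes(x = .data$time, y = .data$surv,
                                     colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Overall survival (months)", y = "Survival probability",
                  colour = object$feature,
                  subtitle = sprintf("cutoff %.3g, logrank p = %.3g",
                                     object$cutoff, object$p)) +
    ggplot2::theme_minimal()
}

#' Marker overview plot
#'
#' Ranked -log10 p-values of evaluated radiogenomic markers, coloured by the
#' marker's pathway state.
#'
#' @param markers Evaluated marker tibble (from [evaluate_markers()]).
#' @param alpha Reference significance level drawn as a dashed line.
#' @return A ggplot object.
#' @export
plot_marker_ranking <- function(markers, alpha = 0.05) {
  assert_that(nrow(markers) > 0, "no markers to plot")
  df <- markers |> mutate(marker = factor(.data$marker_id,
                                          levels = rev(.data$marker_id)))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p), y = .data$marker,
                                   fill = .data$pathway_state)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = expression(-log[10]~p), y = NULL,
                  fill = "pathway state") +
    ggplot2::theme_minimal()
}

#' Feature-importance plot for a CV result
#'
#' Mean normalized importance (summing to 100 per model) of every feature,
#' faceted by classification model.
#'
#' @param object A `cv_result` (from [monte_carlo_cv()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cv_result <- function(object, ...) {
  df <- object$importance |>
    mutate(feature = stats::reorder(.data$feature, .data$importance))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance, y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "importance (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
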