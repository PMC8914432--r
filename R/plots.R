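#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted survival curve with its data
#'
#' Log-scaled surviving fraction against dose: observed points plus the
#' fitted RCR curve evaluated on a fine grid.
#'
#' @param object An `rcr_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.rcr_fit <- function(object, ...) {
  grid <- tibble::tibble(dose = seq(0, object$dose_range[2], length.out = 200))
  grid$sf <- rcr_survival(object$params, grid$dose)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$dose, y = .data$sf)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Dose (Gy)", y = "Surviving fraction",
                  title = if (is.null(object$quality)) NULL else object$quality)
}

#' Plot a TCP curve
#'
#' @param object A [tcp_curve()] result.
#' @param ... Unused.
#' @return A ggplot of TCP against total dose.
#' @exportS3Method ggplot2::autoplot
autoplot.tcp_curve <- function(object, ...) {
  axis <- attr(object, "dose_axis")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$total_dose, y = .data$tcp)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = if (identical(axis, "GyE")) "Total dose (GyE)" else "Total dose (Gy)",
      y = "Tumour control probability")
}

#' Plot panel-size accuracy profiles
#'
#' Mean and balanced cross-validated accuracy against panel size.
#'
#' @param object An [evaluate_panels()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.panel_evaluation <- function(object, ...) {
  long <- object |>
    dplyr::select("panel_size", "mean_accuracy", "balanced_accuracy") |>
    tidyr::pivot_longer(-"panel_size", names_to = "metric",
                        values_to = "accuracy")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$panel_size,
                                     y = .data$accuracy,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Panel size (genes)", y = "CV accuracy", colour = NULL)
}

#' Plot radiosensitivity cohorts along the SF3.5 axis
#'
#' @param object A [cluster_sf35()] result.
#' @param ... Unused.
#' @return A ggplot of SF3.5 values coloured by cohort.
#' @exportS3Method ggplot2::autoplot
autoplot.sensitivity_grouping <- function(object, ...) {
  ggplot2::ggplot(object$assignments,
                  ggplot2::aes(x = .data$sf35, y = .data$group,
                               colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "SF3.5", y = "Cohort", colour = NULL) +
    ggplot2::theme(legend.position = "none")
}
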