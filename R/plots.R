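# ggplot2 methods for the result classes.

#' Plot the steady-cycle waveforms
#'
#' Pressure traces (drive, tubing node, lung) and patient flow over one
#' breath period.
#'
#' @param object A `cycle_solution` or `transient_solution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cycle_solution <- function(object, ...) {
  wf <- object$waveforms
  long <- tidyr::pivot_longer(
    wf,
    cols = c("p_vent_cmH2O", "p_tube_cmH2O", "p_lung_cmH2O", "q_patient_Lps"),
    names_to = "channel", values_to = "value"
  )
  long$panel <- ifelse(long$channel == "q_patient_Lps",
                       "Flow (L/s)", "Pressure (cmH2O)")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value,
                                     colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cycle_solution
#' @exportS3Method ggplot2::autoplot
autoplot.transient_solution <- function(object, ...) {
  autoplot.cycle_solution(object, ...)
}

#' Plot a component characterisation fit
#'
#' Pressure-drop samples coloured by bi-square weight with the fitted
#' polynomial overlaid.
#'
#' @param object A `restrictor_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.restrictor_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(
    q_mean_Lps = seq(min(d$q_mean_Lps), max(d$q_mean_Lps), length.out = 200)
  )
  grid$dp_cmH2O <- object$k2 * grid$q_mean_Lps^2 +
    object$k1 * grid$q_mean_Lps + object$k0
  ggplot2::ggplot(d, ggplot2::aes(x = .data$q_mean_Lps, y = .data$dp_cmH2O)) +
    ggplot2::geom_point(ggplot2::aes(alpha = .data$weight)) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "Mean flow (L/s)", y = "Pressure drop (cmH2O)",
                  alpha = "weight",
                  title = sprintf("%s fit, R² = %.3f",
                                  object$model_kind, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot tidal volume against added restriction
#'
#' @param object A `vt_curve` from [vt_vs_restriction()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.vt_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r_restrictor,
                                       y = .data$vt_L)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Added inspiratory restriction (cmH2O/(L/s))",
                  y = "Tidal volume (L)") +
    ggplot2::theme_minimal()
}

#' Plot the validation report
#'
#' Measured versus predicted tidal volumes per validation case.
#'
#' @param object A `validation_report` from [run_validation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.validation_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$predicted_vt_L,
                                       y = .data$measured_vt_L,
                                       colour = .data$lung,
                                       shape = .data$restrictor)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = "Predicted tidal volume (L)",
                  y = "Measured tidal volume (L)",
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}
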