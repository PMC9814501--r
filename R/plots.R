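# ggplot2 methods for the package's result types.

#' Plot a delay-resolved ion trace
#'
#' @param trace A trace tibble (`delay_fs`, `yield`, `sem`).
#' @param label Optional title.
#' @return A ggplot.
#' @export
plot_ion_trace <- function(trace, label = attr(trace, "label")) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$delay_fs, y = .data$yield)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$yield - .data$sem,
                                      ymax = .data$yield + .data$sem),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pump-probe delay (fs)", y = "ion yield", title = label)
  p
}

#' @method autoplot delay_scan
#' @export
autoplot.delay_scan <- function(object, ...) {
  avg <- object |>
    dplyr::group_by(.data$label, .data$mz, .data$delay_fs) |>
    dplyr::summarise(sem = stats::sd(.data$yield) / sqrt(dplyr::n()),
                     yield = mean(.data$yield), .groups = "drop")
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$delay_fs, y = .data$yield)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$yield - .data$sem,
                                      ymax = .data$yield + .data$sem),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~label, scales = "free_y") +
    ggplot2::labs(x = "pump-probe delay (fs)", y = "scan-averaged yield")
}

#' @method autoplot kinetic_fit
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delay_fs)) +
    ggplot2::geom_pointrange(ggplot2::aes(y = .data$yield,
                                          ymin = .data$yield - .data$sem,
                                          ymax = .data$yield + .data$sem),
                             size = 0.2, colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#1b9e77",
                       linewidth = 0.8) +
    ggplot2::labs(x = "pump-probe delay (fs)", y = "ion yield",
                  title = sprintf("%s fit, residual rms %.3g",
                                  object$model, object$residual_rms))
}

#' @method autoplot shakeup_rates
#' @export
autoplot.shakeup_rates <- function(object, ...) {
  d <- dplyr::mutate(object,
                     photon_group = factor(.data$photon_group),
                     tau_plot = pmin(.data$tau_fs, 100))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$energy_ev, y = .data$tau_plot,
                                  colour = .data$photon_group)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$energy_ev, yend = 0)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$is_special), size = 3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "virtual orbital energy (eV)",
                  y = "characteristic shake-up time (fs)",
                  colour = "NIR photons", shape = "special state")
}

#' @method autoplot dm_trajectory
#' @export
autoplot.dm_trajectory <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::group_by(.data$time_fs, .data$orbital) |>
    dplyr::summarise(occupation = sum(.data$occupation), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_fs, y = .data$occupation,
                                  colour = factor(.data$orbital))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (fs)", y = "spin-summed occupation",
                  colour = "orbital", title = object$method)
}

#' @method autoplot depletion_curve
#' @export
autoplot.depletion_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$delay_fs, y = .data$depletion)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "pump-probe delay (fs)",
                  y = "NIR-induced depletion of the special state")
}
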