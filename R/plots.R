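#' Plot a simulated circuit trajectory
#'
#' Gate RNAP fluxes and reporter output over time, faceted by variable.
#'
#' @param object A `circuit_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.circuit_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"time",
                              names_to = "state", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~state, scales = "free_y") +
    ggplot2::labs(x = "Time (min)", y = "RPU flux / au",
                  title = "Circuit trajectory")
}

#' Plot a plate-reader series
#'
#' OD600 and raw fluorescence per well, colored by role.
#'
#' @param object A `platereader_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.platereader_series <- function(object, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(c("od", "fl"), names_to = "channel",
                        values_to = "value") |>
    dplyr::mutate(channel = dplyr::recode(.data$channel, od = "OD600",
                                          fl = "Fluorescence (au)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
                                     group = .data$well,
                                     colour = .data$role)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "Time (min)", y = NULL, colour = "Role")
}

#' Plot the fitted turn-on-rate trend
#'
#' The sigmoid curve over induction time, optionally with the fitted points.
#'
#' @param object A `sigmoid_trend_params`.
#' @param points Optional data frame with `induction_time`, `tau`.
#' @param xlim Induction-time range to draw (min).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sigmoid_trend_params <- function(object, points = NULL,
                                          xlim = c(0, 500), ...) {
  grid <- tibble(induction_time = seq(xlim[1L], xlim[2L], length.out = 200))
  grid$tau <- predict_tau(grid$induction_time, object)
  p <- ggplot2::ggplot(grid, ggplot2::aes(.data$induction_time, .data$tau)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Induction time (min)",
                  y = expression(tau[y]^{ON} ~ "(1/min)"))
  if (!is.null(points))
    p <- p + ggplot2::geom_point(data = as_tibble(points))
  p
}

#' Plot per-phase turn-on rates from a staged refit
#'
#' @param object A `staged_refit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.staged_refit <- function(object, ...) {
  ggplot2::ggplot(object$per_phase,
                  ggplot2::aes(.data$induction_time, .data$tau_y_on)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(linetype = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$phase), vjust = -0.8) +
    ggplot2::labs(x = "Induction time (min)",
                  y = expression(tau[y]^{ON} ~ "(1/min)"))
}
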