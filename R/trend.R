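#' Sigmoid trend parameters for the turn-on rate
#'
#' The four constants of the logistic model relating the gate turn-on rate
#' `tau_y_on` to the induction time `x` (min):
#' `tau(x) = L / (1 + exp(k * (x - x0))) + b` (falling orientation), so later
#' induction gives a smaller turn-on rate, bounded in `(b, L + b)`.
#'
#' @param L Amplitude (same units as `tau_y_on`, 1/min), `> 0`.
#' @param x0 Inflection induction time (min).
#' @param k Steepness (1/min), `> 0`.
#' @param b Baseline offset (1/min), `>= 0`.
#' @param orientation `"falling"` (default) or `"rising"`
#'   (`tau(x) = L / (1 + exp(-k (x - x0))) + b`), kept for sensitivity
#'   analysis.
#' @return An object of class `sigmoid_trend_params`.
#' @export
#' @examples
#' predict_tau(270, tau_trend_defaults())
sigmoid_trend_params <- function(L, x0, k, b,
                                 orientation = c("falling", "rising")) {
  orientation <- match.arg(orientation)
  check_scalar(L, "L", lower = 0, strict = TRUE)
  check_scalar(x0, "x0")
  check_scalar(k, "k", lower = 0, strict = TRUE)
  check_scalar(b, "b", lower = 0)
  structure(list(L = L, x0 = x0, k = k, b = b, orientation = orientation),
            class = "sigmoid_trend_params")
}

#' @export
print.sigmoid_trend_params <- function(x, ...) {
  cat(sprintf("<sigmoid_trend_params> (%s)\n", x$orientation))
  cat(sprintf("  L = %.8g  x0 = %.8g  k = %.8g  b = %.8g\n",
              x$L, x$x0, x$k, x$b))
  invisible(x)
}

#' Reference trend constants for the delay-circuit reporter gate
#'
#' The published least-squares constants of the turn-on-rate-versus-
#' induction-time sigmoid for the AraC-gate delay circuit characterization:
#' `L = 1.02423886e-1`, `x0 = 3.13060089e2`, `k = 1.80082383e-2`,
#' `b = 1.95602872e-2`.
#'
#' @return A [sigmoid_trend_params()] object.
#' @export
tau_trend_defaults <- function() {
  sigmoid_trend_params(L = 1.02423886e-1, x0 = 3.13060089e2,
                       k = 1.80082383e-2, b = 1.95602872e-2)
}

#' Predict the turn-on rate at an induction time
#'
#' @param x Induction time(s), min, `>= 0`; vectorized.
#' @param p A [sigmoid_trend_params()].
#' @return Predicted `tau_y_on` (1/min), strictly decreasing in `x` for the
#'   falling orientation and bounded in `(b, L + b)`.
#' @export
predict_tau <- function(x, p) {
  stopifnot(inherits(p, "sigmoid_trend_params"))
  if (any(x < 0)) abort("Induction time must be >= 0.")
  s <- if (p$orientation == "falling") 1 else -1
  p$L / (1 + exp(s * p$k * (x - p$x0))) + p$b
}

#' Fit the sigmoid trend to (induction time, turn-on rate) points
#'
#' Multi-start bounded Levenberg-Marquardt fit of the four-parameter logistic
#' to fitted per-phase turn-on rates, as in the Learn step.
#'
#' @param points Data frame with columns `induction_time` (min) and `tau`
#'   (1/min); at least 4 distinct induction times.
#' @param cfg A [fit_config()].
#' @param orientation Sigmoid orientation (see [sigmoid_trend_params()]).
#' @return A [sigmoid_trend_params()] with attributes `fit` (the underlying
#'   `fit_result`) and `x_range` (range of fitted induction times, used for
#'   the extrapolation guard).
#' @export
fit_sigmoid <- function(points, cfg = fit_config(),
                        orientation = c("falling", "rising")) {
  orientation <- match.arg(orientation)
  stopifnot(is.data.frame(points),
            all(c("induction_time", "tau") %in% names(points)))
  if (length(unique(points$induction_time)) < 4L)
    abort("Need at least 4 distinct induction times to fit 4 parameters.")
  x <- points$induction_time
  s <- if (orientation == "falling") 1 else -1
  model_fn <- function(p)
    p[["L"]] / (1 + exp(s * p[["k"]] * (x - p[["x0"]]))) + p[["b"]]
  fit <- multistart_fit(
    model_fn, points$tau,
    free = c("L", "x0", "k", "b"),
    bounds = list(L = c(1e-5, 10), x0 = c(1, 1e4),
                  k = c(1e-5, 1), b = c(1e-9, 1)),
    cfg = cfg
  )
  out <- sigmoid_trend_params(fit$estimates[["L"]], fit$estimates[["x0"]],
                              fit$estimates[["k"]], fit$estimates[["b"]],
                              orientation = orientation)
  attr(out, "fit") <- fit
  attr(out, "x_range") <- range(x)
  out
}

#' Predict a full trajectory for an untested induction time
#'
#' Composes the Learn step: predict the turn-on rate at induction time `x`
#' from the sigmoid trend, substitute it into the reporter stage, and
#' simulate the circuit with the second inducer added at `x`.  All other
#' parameters stay at their calibrated values.  Predictions beyond 1.5x the
#' largest fitted induction time carry an extrapolation warning (the Learn
#' step is interpolative).
#'
#' @param x Untested induction time (min).
#' @param trend A [sigmoid_trend_params()] (ideally from [fit_sigmoid()], so
#'   the fitted range is known).
#' @param topo A [circuit_topology()].
#' @param sched_template An [induction_schedule()] whose event for
#'   `variable_inducer` will be moved to time `x`.
#' @param variable_inducer Which inducer's addition time is varied
#'   (default `"ara"`).
#' @param solver A [solver_config()].
#' @return A `circuit_trajectory` tibble with attribute `tau_y_on` (the
#'   predicted rate used).
#' @export
predict_untested <- function(x, trend, topo, sched_template,
                             variable_inducer = "ara",
                             solver = solver_config()) {
  stopifnot(inherits(trend, "sigmoid_trend_params"),
            inherits(topo, "circuit_topology"),
            inherits(sched_template, "induction_schedule"))
  xr <- attr(trend, "x_range")
  if (!is.null(xr) && x > 1.5 * xr[2L])
    warn(sprintf("Induction time %g min is beyond 1.5x the fitted range (max %g min); extrapolation.",
                 x, xr[2L]))
  tau_hat <- predict_tau(x, trend)
  topo$reporter$tau_on <- tau_hat
  ev <- sched_template$events
  hit <- ev$inducer == variable_inducer
  if (!any(hit))
    abort(sprintf("Schedule template has no event for inducer '%s'.",
                  variable_inducer))
  ev$time[hit] <- x
  sched <- induction_schedule(ev, horizon = max(sched_template$horizon,
                                                x + 1))
  traj <- simulate_circuit(topo, sched, solver = solver)
  attr(traj, "tau_y_on") <- tau_hat
  traj
}
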