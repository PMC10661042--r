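#' Steady-state output of a repressing gate
#'
#' Hill repression in RPU flux:
#' `y = y_min + (y_max - y_min) * kappa^n / (kappa^n + x^n)`.
#' Strictly decreasing in `x`, with `y(0) = y_max` and `y -> y_min` as
#' `x -> Inf`.
#'
#' @param x Input RNAP flux (RPU), `>= 0`; vectorized.
#' @param p A [gate_params()] with `regulation == "repression"`.
#' @return Output RNAP flux (RPU), same length as `x`.
#' @export
#' @examples
#' p <- gate_params("r", "repression", y_min = 0.1, y_max = 2, kappa = 1, n = 2)
#' steady_state_repressor(c(0, 1, 10), p)
steady_state_repressor <- function(x, p) {
  stopifnot(inherits(p, "gate_params"))
  if (p$regulation != "repression")
    abort("`p` must be repression parameters; see `steady_state_activator()`.")
  check_flux(x)
  kn <- p$kappa^p$n
  p$y_min + (p$y_max - p$y_min) * kn / (kn + x^p$n)
}

#' Steady-state output of an activating gate
#'
#' Hill activation in RPU flux:
#' `y = y_min + (y_max - y_min) * x^n / (kappa^n + x^n)`.
#' Strictly increasing in `x`, with `y(0) = y_min` and `y -> y_max` as
#' `x -> Inf`.
#'
#' @inheritParams steady_state_repressor
#' @param p A [gate_params()] with `regulation == "activation"`.
#' @return Output RNAP flux (RPU).
#' @export
steady_state_activator <- function(x, p) {
  stopifnot(inherits(p, "gate_params"))
  if (p$regulation != "activation")
    abort("`p` must be activation parameters; see `steady_state_repressor()`.")
  check_flux(x)
  xn <- x^p$n
  p$y_min + (p$y_max - p$y_min) * xn / (p$kappa^p$n + xn)
}

# Dispatch on the regulation field.
steady_state_gate <- function(x, p) {
  if (p$regulation == "repression") steady_state_repressor(x, p)
  else steady_state_activator(x, p)
}

#' Steady-state output of a sensor gate
#'
#' Sensors are digital: output is `x_max` when the inducer is present
#' (`q = 1`) and `x_min` when absent (`q = 0`).
#'
#' @param q Inducer presence indicator, each element 0 or 1; vectorized.
#' @param s A [sensor_params()] object.
#' @return Output RNAP flux (RPU).
#' @export
sensor_output <- function(q, s) {
  stopifnot(inherits(s, "sensor_params"))
  if (!is.numeric(q) || !all(q %in% c(0, 1)))
    abort("`q` must contain only 0 (absent) or 1 (present).")
  ifelse(q == 1, s$x_max, s$x_min)
}

#' Whole-circuit steady-state fluxes
#'
#' Evaluates every gate's steady-state RNAP flux for a fixed inducer state by
#' propagating sensor outputs through the wiring in topological order.
#' Multiple inputs to a gate sum before the Hill function.
#'
#' @param topo A [circuit_topology()].
#' @param inducer_presence Named vector mapping each inducer to 0 or 1.
#' @return A tibble with columns `node`, `kind` (`"sensor"`/`"gate"`), and
#'   `flux` (RPU).
#' @export
#' @examples
#' circuit_steady_state(delay_circuit(), c(ara = 0, hsl = 1))
circuit_steady_state <- function(topo, inducer_presence) {
  stopifnot(inherits(topo, "circuit_topology"))
  needed <- unique(vapply(topo$sensors, `[[`, "", "inducer"))
  missing <- setdiff(needed, names(inducer_presence))
  if (length(missing))
    abort(sprintf("Missing inducer state for: %s.",
                  paste(missing, collapse = ", ")))
  flux <- c(
    vapply(topo$sensors, function(s)
      sensor_output(inducer_presence[[s$inducer]], s), numeric(1)),
    setNames(rep(NA_real_, length(topo$gates)), names(topo$gates))
  )
  inputs <- gate_inputs(topo)
  for (g in topo_order(topo)) {
    x <- sum_input_flux(flux[inputs[[g]]])
    flux[[g]] <- steady_state_gate(x, topo$gates[[g]])
  }
  tibble(
    node = names(flux),
    kind = ifelse(names(flux) %in% names(topo$sensors), "sensor", "gate"),
    flux = unname(flux)
  )
}

# Sum incoming RNAP fluxes; a gate with no declared inputs sees zero flux.
# Negative intermediates indicate a numerics error upstream and are reported
# above a small magnitude rather than silently clamped.
sum_input_flux <- function(x) {
  x <- sum(x)
  if (length(x) == 0L || is.na(x)) x <- 0
  if (x < 0) {
    if (x < -1e-9)
      abort(sprintf("Negative input flux (%.3e); numerics error upstream.", x))
    x <- 0
  }
  x
}

check_flux <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)))
    abort("Input flux must be finite and numeric.")
  if (any(x < 0))
    abort("Input flux must be >= 0.")
  invisible(x)
}
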