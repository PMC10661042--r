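#' Parameters of one transcriptional gate
#'
#' A gate is a transcriptional unit (a repressor or activator protein together
#' with the promoter it controls) treated as a logic element.  Its steady-state
#' response is a Hill function of the input RNAP flux, expressed in relative
#' promoter units (RPU); its dynamic response is a first-order relaxation
#' toward that steady state with separate turn-on and turn-off rates.
#'
#' @param name Gate identifier (single string).
#' @param regulation `"repression"` or `"activation"`.
#' @param y_min,y_max Minimal and maximal steady-state output RNAP flux (RPU);
#'   `y_min < y_max`, both `>= 0`.
#' @param kappa Hill affinity constant (RPU), `> 0`: the input flux at which the
#'   output is half-maximal.
#' @param n Hill cooperativity coefficient (dimensionless), `> 0`.
#' @param tau_on,tau_off First-order relaxation rates (1/min, `> 0`) used when
#'   the steady-state target lies above (`tau_on`) or below (`tau_off`) the
#'   current output.
#'
#' @return An object of class `gate_params` (a named list).
#' @seealso [steady_state_repressor()], [steady_state_activator()], [gate_rhs()]
#' @export
#' @examples
#' gate_params("notA", "repression",
#'             y_min = 0.02, y_max = 2.8, kappa = 0.9, n = 2.4)
gate_params <- function(name, regulation = c("repression", "activation"),
                        y_min, y_max, kappa, n,
                        tau_on = 0.03, tau_off = 0.02) {
  regulation <- match.arg(regulation)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  check_scalar(y_min, "y_min", lower = 0)
  check_scalar(y_max, "y_max", lower = 0)
  if (!(y_min < y_max)) abort("`y_min` must be strictly less than `y_max`.")
  check_scalar(kappa, "kappa", lower = 0, strict = TRUE)
  check_scalar(n, "n", lower = 0, strict = TRUE)
  check_scalar(tau_on, "tau_on", lower = 0, strict = TRUE)
  check_scalar(tau_off, "tau_off", lower = 0, strict = TRUE)
  structure(
    list(name = name, regulation = regulation,
         y_min = y_min, y_max = y_max, kappa = kappa, n = n,
         tau_on = tau_on, tau_off = tau_off),
    class = "gate_params"
  )
}

#' Parameters of an inducer sensor gate
#'
#' Sensor gates respond digitally to their small-molecule inducer: the output
#' RNAP flux is `x_max` when the inducer is present (`q = 1`) and `x_min` when
#' absent (`q = 0`); there is no dose-response curve.
#'
#' @param name Sensor identifier.
#' @param x_min,x_max Minimal and maximal output RNAP flux (RPU); `x_min >= 0`,
#'   `x_min < x_max`.
#' @param inducer Identifier of the small molecule sensed (e.g. `"ara"`,
#'   `"hsl"`).
#'
#' @return An object of class `sensor_params`.
#' @seealso [sensor_output()], [as_gate_params()]
#' @export
sensor_params <- function(name, x_min, x_max, inducer = name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(inducer), length(inducer) == 1L)
  check_scalar(x_min, "x_min", lower = 0)
  check_scalar(x_max, "x_max", lower = 0)
  if (!(x_min < x_max)) abort("`x_min` must be strictly less than `x_max`.")
  structure(
    list(name = name, x_min = x_min, x_max = x_max, inducer = inducer),
    class = "sensor_params"
  )
}

#' Reporter stage parameters
#'
#' The reporter (fluorescent protein) stage relaxes toward a steady state set
#' by the flux of the promoter controlling its expression, scaled into
#' arbitrary fluorescence units.
#'
#' @param tau_on,tau_off Relaxation rates (1/min, `> 0`).
#' @param rpu_to_au Conversion factor from RPU flux to per-cell fluorescence
#'   (au per RPU, `> 0`).
#'
#' @return An object of class `reporter_params`.
#' @export
reporter_params <- function(tau_on = 0.01, tau_off = 0.008, rpu_to_au = 1000) {
  check_scalar(tau_on, "tau_on", lower = 0, strict = TRUE)
  check_scalar(tau_off, "tau_off", lower = 0, strict = TRUE)
  check_scalar(rpu_to_au, "rpu_to_au", lower = 0, strict = TRUE)
  structure(
    list(tau_on = tau_on, tau_off = tau_off, rpu_to_au = rpu_to_au),
    class = "reporter_params"
  )
}

#' Promote a sensor gate to an internal gate
#'
#' A sensor used downstream of other gates (rather than reading an inducer)
#' needs a graded response curve.  This promotes `sensor_params` to
#' `gate_params` with a Hill response whose output range is the sensor's
#' `[x_min, x_max]`.
#'
#' @param s A [sensor_params()] object.
#' @param kappa,n Hill constants for the promoted gate.
#' @param regulation Response orientation of the promoted gate.
#' @inheritParams gate_params
#' @return A [gate_params()] object.
#' @export
as_gate_params <- function(s, kappa, n, regulation = "activation",
                           tau_on = 0.03, tau_off = 0.02) {
  stopifnot(inherits(s, "sensor_params"))
  gate_params(s$name, regulation,
              y_min = s$x_min, y_max = s$x_max, kappa = kappa, n = n,
              tau_on = tau_on, tau_off = tau_off)
}

#' Circuit wiring
#'
#' Assembles sensors, internal gates, directed edges, and the reporter stage
#' into a validated acyclic topology.  Every edge source must be a declared
#' sensor or gate, every target a declared gate; the `output_gate` feeds the
#' reporter.  Multiple inputs to one gate combine by summation of RNAP fluxes
#' before the Hill function is applied.
#'
#' @param sensors List of [sensor_params()].
#' @param gates List of [gate_params()].
#' @param edges A data frame with columns `from`, `to` (identifiers).
#' @param output_gate Name of the gate whose flux drives the reporter.
#' @param reporter A [reporter_params()] object.
#'
#' @return An object of class `circuit_topology`.
#' @seealso [circuit_steady_state()], [simulate_circuit()], [delay_circuit()]
#' @export
circuit_topology <- function(sensors, gates, edges, output_gate,
                             reporter = reporter_params()) {
  stopifnot(all(vapply(sensors, inherits, TRUE, "sensor_params")),
            all(vapply(gates, inherits, TRUE, "gate_params")),
            inherits(reporter, "reporter_params"),
            is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  sensor_names <- vapply(sensors, `[[`, "", "name")
  gate_names <- vapply(gates, `[[`, "", "name")
  if (anyDuplicated(c(sensor_names, gate_names)))
    abort("Sensor and gate names must be unique.")
  edges <- tibble(from = as.character(edges$from), to = as.character(edges$to))
  if (!all(edges$from %in% c(sensor_names, gate_names)))
    abort("Every edge source must be a declared sensor or gate.")
  if (!all(edges$to %in% gate_names))
    abort("Every edge target must be a declared gate.")
  if (!output_gate %in% gate_names)
    abort(sprintf("`output_gate` '%s' is not a declared gate.", output_gate))
  topo <- structure(
    list(sensors = setNames(sensors, sensor_names),
         gates = setNames(gates, gate_names),
         edges = edges, output_gate = output_gate, reporter = reporter),
    class = "circuit_topology"
  )
  topo_order(topo)  # errors on a cyclic wiring
  topo
}

#' @export
print.circuit_topology <- function(x, ...) {
  cat(sprintf("<circuit_topology> %d sensor(s), %d gate(s), %d edge(s)\n",
              length(x$sensors), length(x$gates), nrow(x$edges)))
  cat("  output gate:", x$output_gate, "\n")
  invisible(x)
}

# Topological order of gate evaluation (sensors have no inputs and are
# excluded).  Errors when the wiring graph has a cycle.
topo_order <- function(topo) {
  nodes <- c(names(topo$sensors), names(topo$gates))
  g <- igraph::graph_from_data_frame(topo$edges, directed = TRUE,
                                     vertices = nodes)
  if (!igraph::is_dag(g))
    abort("Circuit wiring contains a cycle; the topology must be acyclic.")
  ord <- names(igraph::topo_sort(g, mode = "out"))
  ord[ord %in% names(topo$gates)]
}

# Named list: gate -> character vector of its input node names.
gate_inputs <- function(topo) {
  split(topo$edges$from, factor(topo$edges$to, levels = names(topo$gates)))
}

#' Reference two-input delay circuit
#'
#' The default circuit fixture: a NOR-based AND stage.  Each inducer sensor
#' drives a NOT gate; the two NOT outputs sum into a final repressor, so the
#' output gate is high only when both arabinose and HSL are present.  Output
#' is produced with a delay set by the relaxation rates of the cascade.
#'
#' @param reporter Reporter stage; defaults mirror the plate-reader
#'   calibration used by [olc_preset()].
#' @return A [circuit_topology()].
#' @export
#' @examples
#' circ <- delay_circuit()
#' circuit_steady_state(circ, c(ara = 1, hsl = 1))
delay_circuit <- function(reporter = reporter_params(tau_on = 0.012,
                                                     tau_off = 0.008,
                                                     rpu_to_au = 4)) {
  circuit_topology(
    sensors = list(
      sensor_params("sens_ara", x_min = 0.01, x_max = 2.5, inducer = "ara"),
      sensor_params("sens_hsl", x_min = 0.025, x_max = 3.0, inducer = "hsl")
    ),
    gates = list(
      gate_params("notA", "repression", y_min = 0.02, y_max = 2.8,
                  kappa = 0.9, n = 4, tau_on = 0.03, tau_off = 0.02),
      gate_params("notB", "repression", y_min = 0.03, y_max = 2.4,
                  kappa = 0.8, n = 4, tau_on = 0.03, tau_off = 0.02),
      gate_params("norAB", "repression", y_min = 0.01, y_max = 2.6,
                  kappa = 0.85, n = 5, tau_on = 0.025, tau_off = 0.02)
    ),
    edges = data.frame(from = c("sens_ara", "sens_hsl", "notA", "notB"),
                       to = c("notA", "notB", "norAB", "norAB")),
    output_gate = "norAB",
    reporter = reporter
  )
}

check_scalar <- function(x, what, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number.", what))
  ok <- if (strict) x > lower else x >= lower
  if (!ok)
    abort(sprintf("`%s` must be %s %s.", what,
                  if (strict) ">" else ">=", format(lower)))
  invisible(x)
}
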