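#' Induction schedule
#'
#' Events switch one inducer's presence indicator at a given time.  Before any
#' event every inducer is absent (`q = 0`); events at `t = 0` are applied as
#' switches at the start of the simulation, so an induction-at-zero experiment
#' still starts from the uninduced state.
#'
#' @param events Data frame with columns `time` (min, `>= 0`), `inducer`
#'   (identifier), `q` (0 or 1).  May have zero rows.
#' @param horizon Simulation end time (min, `> 0`), at least the last event
#'   time.
#' @return An object of class `induction_schedule`.
#' @export
#' @examples
#' induction_schedule(
#'   data.frame(time = c(0, 180), inducer = c("hsl", "ara"), q = 1),
#'   horizon = 800
#' )
induction_schedule <- function(events = data.frame(time = numeric(),
                                                   inducer = character(),
                                                   q = numeric()),
                               horizon) {
  stopifnot(is.data.frame(events),
            all(c("time", "inducer", "q") %in% names(events)))
  check_scalar(horizon, "horizon", lower = 0, strict = TRUE)
  events <- tibble(time = as.numeric(events$time),
                   inducer = as.character(events$inducer),
                   q = as.numeric(events$q))
  if (any(events$time < 0)) abort("Event times must be >= 0.")
  if (!all(events$q %in% c(0, 1))) abort("Event `q` must be 0 or 1.")
  events <- dplyr::arrange(events, .data$time)
  if (anyDuplicated(events[c("time", "inducer")]))
    abort("At most one event per inducer per time point.")
  if (nrow(events) && max(events$time) > horizon)
    abort("`horizon` must be at least the last event time.")
  structure(list(events = events, horizon = horizon),
            class = "induction_schedule")
}

#' Solver configuration
#'
#' @param rtol,atol Relative and absolute tolerances of the adaptive embedded
#'   Runge-Kutta integrator.
#' @param max_step Maximum step size (min).
#' @param step Output grid spacing (min); the dense solution is reported on a
#'   uniform grid with this step.
#' @param tau_convention `"rate"` (default): relaxation parameters are
#'   first-order rate constants in 1/min, `dy/dt = tau * (y_ss - y)`.
#'   `"time_constant"`: parameters are time constants in min and the effective
#'   rate is `1/tau`.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(rtol = 1e-6, atol = 1e-9, max_step = 10, step = 1,
                          tau_convention = c("rate", "time_constant")) {
  tau_convention <- match.arg(tau_convention)
  structure(list(rtol = rtol, atol = atol, max_step = max_step, step = step,
                 tau_convention = tau_convention),
            class = "solver_config")
}

tau_rate <- function(tau, convention) {
  if (convention == "time_constant") 1 / tau else tau
}

#' Relaxation derivative of one gate
#'
#' First-order relaxation toward the current steady-state target:
#' `dy/dt = tau * (y_ss - y)`, with `tau = tau_on` when the target lies above
#' the current output and `tau_off` when below.
#'
#' @param y Current output RNAP flux (RPU, `>= 0`).
#' @param y_ss Steady-state target flux (RPU).
#' @param p A [gate_params()] object.
#' @param tau_convention See [solver_config()].
#' @return Derivative in RPU/min.
#' @export
gate_rhs <- function(y, y_ss, p, tau_convention = "rate") {
  stopifnot(inherits(p, "gate_params"))
  tau <- ifelse(y_ss > y,
                tau_rate(p$tau_on, tau_convention),
                tau_rate(p$tau_off, tau_convention))
  tau * (y_ss - y)
}

#' Relaxation derivative of the reporter
#'
#' The reporter relaxes toward `rpu_to_au * input_flux` with rate `tau_on`
#' when below the target and `tau_off` when above.
#'
#' @param yfp Current reporter output (au, `>= 0`).
#' @param input_flux RNAP flux of the promoter controlling the reporter (RPU).
#' @param r A [reporter_params()] object.
#' @inheritParams gate_rhs
#' @return Derivative in au/min.
#' @export
reporter_rhs <- function(yfp, input_flux, r, tau_convention = "rate") {
  stopifnot(inherits(r, "reporter_params"))
  target <- r$rpu_to_au * input_flux
  tau <- ifelse(target > yfp,
                tau_rate(r$tau_on, tau_convention),
                tau_rate(r$tau_off, tau_convention))
  tau * (target - yfp)
}

#' Simulate circuit dynamics under an induction schedule
#'
#' Integrates the per-gate relaxation ODEs and the reporter equation with an
#' adaptive embedded Runge-Kutta pair (Dormand-Prince 4(5) via
#' [deSolve::ode()]), piecewise between induction events.  State carries over
#' across events; only the digital sensor outputs switch.  The dense solution
#' is reported on a uniform output grid.
#'
#' @param topo A [circuit_topology()].
#' @param sched An [induction_schedule()].
#' @param init `"steady_state_at_t0"` (default): start from the steady state
#'   of the pre-event baseline (all inducers absent); `"all_zero"`: start all
#'   gates and the reporter at zero.
#' @param solver A [solver_config()].
#' @return A tibble of class `circuit_trajectory` with columns `time` (min),
#'   one column per gate (RPU flux), and `yfp` (au).
#' @export
#' @examples
#' sched <- induction_schedule(
#'   data.frame(time = c(0, 180), inducer = c("hsl", "ara"), q = 1), 600)
#' traj <- simulate_circuit(delay_circuit(), sched)
simulate_circuit <- function(topo, sched,
                             init = c("steady_state_at_t0", "all_zero"),
                             solver = solver_config()) {
  stopifnot(inherits(topo, "circuit_topology"),
            inherits(sched, "induction_schedule"),
            inherits(solver, "solver_config"))
  init <- match.arg(init)

  gate_names <- names(topo$gates)
  inducers <- vapply(topo$sensors, `[[`, "", "inducer")
  q <- setNames(rep(0, length(unique(inducers))), unique(inducers))

  state <- if (init == "all_zero") {
    setNames(rep(0, length(gate_names) + 1L), c(gate_names, "yfp"))
  } else {
    ss <- circuit_steady_state(topo, q)
    fl <- setNames(ss$flux, ss$node)[gate_names]
    c(fl, yfp = topo$reporter$rpu_to_au * fl[[topo$output_gate]])
  }

  inputs <- gate_inputs(topo)
  conv <- solver$tau_convention
  rhs <- function(t, y, parms) {
    sens <- vapply(topo$sensors, function(s)
      sensor_output(parms$q[[s$inducer]], s), numeric(1))
    node_val <- c(sens, y[gate_names])
    dy <- vapply(gate_names, function(g) {
      x <- sum_input_flux(node_val[inputs[[g]]])
      gate_rhs(y[[g]], steady_state_gate(x, topo$gates[[g]]),
               topo$gates[[g]], conv)
    }, numeric(1))
    dyfp <- reporter_rhs(y[["yfp"]], max(y[[topo$output_gate]], 0),
                         topo$reporter, conv)
    list(c(dy, dyfp))
  }

  ev <- sched$events
  breaks <- sort(unique(c(0, ev$time, sched$horizon)))
  breaks <- breaks[breaks <= sched$horizon]
  grid <- seq(0, sched$horizon, by = solver$step)
  if (tail(grid, 1L) < sched$horizon) grid <- c(grid, sched$horizon)

  out <- NULL
  for (i in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[i]
    t1 <- breaks[i + 1L]
    sw <- ev[ev$time == t0, ]
    if (nrow(sw)) q[sw$inducer] <- sw$q
    times <- sort(unique(c(t0, grid[grid > t0 & grid < t1], t1)))
    seg <- deSolve::ode(
      y = state, times = times, func = rhs, parms = list(q = q),
      method = "ode45", rtol = solver$rtol, atol = solver$atol,
      hmax = solver$max_step
    )
    if (attr(seg, "istate")[1L] < 0)
      abort("ODE integration failed; see deSolve diagnostics.")
    seg <- as.data.frame(seg)
    state <- setNames(as.numeric(seg[nrow(seg), -1L]), names(state))
    out <- if (is.null(out)) seg else rbind(out, seg[-1L, ])
  }

  out <- as_tibble(out)
  # tolerance-level negative undershoots are clamped; larger ones reported
  num <- out[, -1L]
  low <- min(as.matrix(num))
  if (low < -10 * solver$atol)
    warn(sprintf("Trajectory undershoot below -10*atol (%.3e).", low))
  out[, -1L] <- lapply(num, pmax, 0)
  names(out)[1L] <- "time"
  out <- out[out$time %in% grid, ]
  out <- dplyr::distinct(out, .data$time, .keep_all = TRUE)
  structure(out, class = c("circuit_trajectory", class(out)))
}

#' Time to reach a fraction of the final reporter level
#'
#' First (linearly interpolated) time at which the reporter output reaches
#' `fraction` of its final value.  Returns `NA` when the level is never
#' attained.
#'
#' @param traj A `circuit_trajectory` (or any data frame with `time` and
#'   `yfp` columns).
#' @param fraction Target fraction in (0, 1).
#' @return Time in min, or `NA_real_` if not reached.
#' @export
time_to_fraction <- function(traj, fraction) {
  stopifnot(is.data.frame(traj), all(c("time", "yfp") %in% names(traj)),
            is.numeric(fraction), length(fraction) == 1L,
            fraction > 0, fraction < 1)
  y <- traj$yfp
  tt <- traj$time
  target <- fraction * y[length(y)]
  if (target <= 0) {
    if (all(y <= 0)) return(NA_real_)
    return(tt[which(y > 0)[1L]])
  }
  i <- which(y >= target)[1L]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(tt[1L])
  # linear interpolation between the bracketing grid points
  tt[i - 1L] + (target - y[i - 1L]) / (y[i] - y[i - 1L]) * (tt[i] - tt[i - 1L])
}
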