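# Shared fixtures and independent oracles used across the suite.

rel_err <- function(est, truth) abs(est / truth - 1)

# A single pass-through topology: one sensor feeding one activating gate.
passthrough_circuit <- function(tau_on = 0.05, tau_off = 0.05,
                                rpu_to_au = 1000) {
  circuit_topology(
    sensors = list(sensor_params("sens", x_min = 0.01, x_max = 2.0,
                                 inducer = "ind")),
    gates = list(gate_params("g1", "activation", y_min = 0.05, y_max = 3.0,
                             kappa = 1.0, n = 2.0,
                             tau_on = tau_on, tau_off = tau_off)),
    edges = data.frame(from = "sens", to = "g1"),
    output_gate = "g1",
    reporter = reporter_params(tau_on = 0.02, tau_off = 0.02,
                               rpu_to_au = rpu_to_au)
  )
}

# Independent steady-state oracle: damped fixed-point iteration over all
# node fluxes, ignoring the wiring order entirely.
fixed_point_steady_state <- function(topo, inducer_presence,
                                     max_iter = 10000, tol = 1e-14) {
  nodes <- c(names(topo$sensors), names(topo$gates))
  flux <- setNames(rep(0.5, length(nodes)), nodes)
  for (s in topo$sensors)
    flux[[s$name]] <- if (inducer_presence[[s$inducer]] == 1) s$x_max else s$x_min
  inputs <- split(topo$edges$from, factor(topo$edges$to,
                                          levels = names(topo$gates)))
  for (it in seq_len(max_iter)) {
    new <- flux
    for (g in names(topo$gates)) {
      x <- sum(flux[inputs[[g]]])
      if (length(inputs[[g]]) == 0L) x <- 0
      p <- topo$gates[[g]]
      kn <- p$kappa^p$n
      new[[g]] <- if (p$regulation == "repression")
        p$y_min + (p$y_max - p$y_min) * kn / (kn + x^p$n)
      else
        p$y_min + (p$y_max - p$y_min) * x^p$n / (kn + x^p$n)
    }
    if (max(abs(new - flux)) < tol) return(new)
    flux <- new
  }
  flux
}

# Random acyclic circuit with n_gates gates; edges only point forward in a
# random node ordering, so the wiring is a DAG by construction.
random_acyclic_circuit <- function(n_gates, seed) {
  set.seed(seed)
  sensors <- list(sensor_params("s1", 0.01, runif(1, 1, 3), inducer = "i1"),
                  sensor_params("s2", 0.02, runif(1, 1, 3), inducer = "i2"))
  gates <- lapply(seq_len(n_gates), function(i) {
    gate_params(paste0("g", i),
                sample(c("repression", "activation"), 1L),
                y_min = runif(1, 0.01, 0.1), y_max = runif(1, 1, 4),
                kappa = runif(1, 0.3, 2), n = runif(1, 1, 4))
  })
  nodes <- c("s1", "s2", paste0("g", seq_len(n_gates)))
  edges <- do.call(rbind, lapply(seq_len(n_gates), function(i) {
    pool <- nodes[seq_len(i + 1L)]  # sensors + earlier gates only
    k <- sample(seq_len(min(2L, length(pool))), 1L)
    data.frame(from = sample(pool, k), to = paste0("g", i))
  }))
  circuit_topology(sensors, gates, edges, output_gate = paste0("g", n_gates))
}

# Normalized-trace builder for metric tests.
trace_tbl <- function(time, value) tibble::tibble(time = time, value = value)
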