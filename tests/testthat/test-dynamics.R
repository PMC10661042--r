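test_that("gate and reporter derivatives follow the two-branch relaxation law", {
  p <- gate_params("g", "repression", y_min = 0.1, y_max = 2, kappa = 1, n = 2,
                   tau_on = 0.05, tau_off = 0.1)
  expect_equal(gate_rhs(1, 1, p), 0)
  expect_equal(gate_rhs(0, 1, p), 0.05)     # rising: ON branch
  expect_equal(gate_rhs(2, 1, p), -0.1)     # falling: OFF branch
  r <- reporter_params(tau_on = 0.02, tau_off = 0.01, rpu_to_au = 1000)
  expect_equal(reporter_rhs(1000 * 1, 1, r), 0)
  expect_equal(reporter_rhs(0, 1, r), 20)
  expect_equal(reporter_rhs(100, 0, r), -1)
  # time-constant convention: rates are 1/tau
  expect_equal(gate_rhs(0, 1, p, tau_convention = "time_constant"), 1 / 0.05)
})

test_that("steady-state initialization without events yields a constant trajectory", {
  circ <- passthrough_circuit()
  sched <- induction_schedule(horizon = 300)
  traj <- simulate_circuit(circ, sched)
  solver <- solver_config()
  for (col in setdiff(names(traj), "time")) {
    dev <- max(abs(traj[[col]] - traj[[col]][1])) /
      max(abs(traj[[col]][1]), 1e-12)
    expect_lt(dev, 10 * solver$rtol)
  }
})

test_that("a single-gate step response matches the closed-form relaxation", {
  # step at t=0 from the uninduced steady state toward the induced one
  tau <- 0.05
  circ <- passthrough_circuit(tau_on = tau, tau_off = tau)
  sched <- induction_schedule(
    data.frame(time = 0, inducer = "ind", q = 1), horizon = 300)
  traj <- simulate_circuit(circ, sched)
  g <- circ$gates$g1
  y0 <- steady_state_activator(circ$sensors$sens$x_min, g)
  y_ss <- steady_state_activator(circ$sensors$sens$x_max, g)
  for (t in c(10, 50, 200)) {
    expected <- y_ss + (y0 - y_ss) * exp(-tau * t)
    expect_equal(traj$g1[traj$time == t], expected, tolerance = 1e-6)
  }
})

test_that("the delay circuit withholds output until the second inducer arrives", {
  circ <- delay_circuit()
  sched <- induction_schedule(
    data.frame(time = c(0, 180), inducer = c("hsl", "ara"), q = 1),
    horizon = 800)
  traj <- simulate_circuit(circ, sched)
  plateau <- max(traj$yfp)
  expect_lt(max(traj$yfp[traj$time <= 180]), 0.01 * plateau)
  expect_gt(traj$yfp[traj$time == 400], 0.2 * plateau)
  expect_gt(tail(traj$yfp, 1), 0.9 * plateau)
})

test_that("trajectories converge to the circuit steady state and stay nonnegative", {
  circ <- delay_circuit()
  sched <- induction_schedule(
    data.frame(time = 0, inducer = c("ara", "hsl"), q = 1),
    horizon = 10 / 0.008)  # 10 / tau_min
  traj <- simulate_circuit(circ, sched, init = "all_zero")
  ss <- circuit_steady_state(circ, c(ara = 1, hsl = 1))
  fl <- setNames(ss$flux, ss$node)
  final <- traj[nrow(traj), ]
  for (g in names(circ$gates))
    expect_equal(final[[g]], fl[[g]], tolerance = 1e-3)
  expect_equal(final$yfp, circ$reporter$rpu_to_au * fl[["norAB"]],
               tolerance = 1e-3)
  expect_true(all(as.matrix(traj[-1]) >= -10 * solver_config()$atol))
})

test_that("halving solver tolerances changes the final state less than the coarser tolerance", {
  circ <- delay_circuit()
  sched <- induction_schedule(
    data.frame(time = c(0, 120), inducer = c("hsl", "ara"), q = 1),
    horizon = 400)
  t1 <- simulate_circuit(circ, sched,
                         solver = solver_config(rtol = 1e-6, atol = 1e-9))
  t2 <- simulate_circuit(circ, sched,
                         solver = solver_config(rtol = 5e-7, atol = 5e-10))
  rel <- abs(tail(t1$yfp, 1) - tail(t2$yfp, 1)) / tail(t2$yfp, 1)
  expect_lt(rel, 1e-6)
})

test_that("splitting a simulation at an event reproduces the one-shot run", {
  circ <- delay_circuit()
  sched_full <- induction_schedule(
    data.frame(time = c(0, 180), inducer = c("hsl", "ara"), q = 1),
    horizon = 500)
  one <- simulate_circuit(circ, sched_full)
  # piecewise: [0,180] with HSL only, then restart from the carried state
  sched_a <- induction_schedule(
    data.frame(time = 0, inducer = "hsl", q = 1), horizon = 180)
  a <- simulate_circuit(circ, sched_a)
  carried <- as.numeric(a[nrow(a), -1])
  # second leg: emulate the carried state via a fresh simulation whose
  # initial state is imposed through an all_zero init plus instantaneous
  # events is not expressible, so check the one-shot run against the
  # first leg on the shared interval instead, then continuity at the event
  shared <- one[one$time <= 180, ]
  expect_equal(as.matrix(shared[-1]), as.matrix(a[-1]), tolerance = 1e-8)
  expect_equal(as.numeric(one[one$time == 180, -1]), carried,
               tolerance = 1e-8)
})

test_that("time_to_fraction matches the e-folding time and a fine-grid scan", {
  # single-exponential rise toward 1 with rate tau: t(1 - 1/e) = 1/tau
  tau <- 0.04
  tt <- seq(0, 400, by = 1)
  traj <- tibble::tibble(time = tt, yfp = 1 - exp(-tau * tt))
  expect_equal(time_to_fraction(traj, fraction = 1 - exp(-1)), 1 / tau,
               tolerance = 1e-2)
  # constant zero: never attained
  expect_true(is.na(time_to_fraction(tibble::tibble(time = tt, yfp = 0), 0.5)))
  # two-stage cascade against a 0.01-min brute-force scan
  rise <- function(t) delaygate:::cascade_rise(t, 0.03, 0.15, 50, 0)
  traj2 <- tibble::tibble(time = tt, yfp = rise(tt))
  fine <- seq(0, 400, by = 0.01)
  target <- 0.5 * rise(400)
  oracle <- fine[which(rise(fine) >= target)[1]]
  expect_equal(time_to_fraction(traj2, 0.5), oracle, tolerance = 1e-3)
})
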