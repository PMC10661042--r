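#' Logistic-with-lag bacterial growth model
#'
#' OD600 stays at `od0` through the lag phase, then follows a logistic curve
#' from `od0` toward the carrying capacity.  For `od0 << capacity` the early
#' post-lag segment is exponential with the given rate, so the doubling time
#' there is `ln(2) / rate`.
#'
#' @param od0 Initial OD600, `> 0`.
#' @param rate Exponential growth rate (1/min), `> 0`.
#' @param capacity Plateau OD600, `> od0`.
#' @param lag Lag duration (min), `>= 0`.
#' @return An object of class `growth_model`.
#' @export
growth_model <- function(od0 = 0.05, rate = 0.01, capacity = 0.5, lag = 60) {
  check_scalar(od0, "od0", lower = 0, strict = TRUE)
  check_scalar(rate, "rate", lower = 0, strict = TRUE)
  check_scalar(capacity, "capacity", lower = od0, strict = TRUE)
  check_scalar(lag, "lag", lower = 0)
  structure(list(od0 = od0, rate = rate, capacity = capacity, lag = lag),
            class = "growth_model")
}

# Noise-free growth curve; monotone non-decreasing, continuous at the lag.
growth_curve <- function(g, t) {
  stopifnot(inherits(g, "growth_model"))
  te <- pmax(t - g$lag, 0)
  e <- exp(g$rate * te)
  g$capacity * g$od0 * e / (g$capacity - g$od0 + g$od0 * e)
}

#' Replicate-noise and observation model
#'
#' Parameters of the synthetic observation model: per-point multiplicative
#' scatter on the cell-associated fluorescence, additive fluorescence noise,
#' additive OD noise, the media blank fluorescence level, and the seed that
#' makes every draw reproducible.
#'
#' @param fl_mult_cv Coefficient of variation of multiplicative fluorescence
#'   noise.
#' @param fl_add_sd Additive fluorescence noise SD (au).
#' @param od_add_sd Additive OD600 noise SD.
#' @param blank_level Media blank fluorescence (au).
#' @param seed Integer seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(fl_mult_cv = 0.05, fl_add_sd = 2, od_add_sd = 0.003,
                        blank_level = 50, seed = 1L) {
  for (v in c(fl_mult_cv, fl_add_sd, od_add_sd, blank_level))
    stopifnot(is.numeric(v), v >= 0)
  structure(list(fl_mult_cv = fl_mult_cv, fl_add_sd = fl_add_sd,
                 od_add_sd = od_add_sd, blank_level = blank_level,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Noise-free observation model
#'
#' @param ... Overrides passed to [noise_model()] (e.g. `seed`).
#' @return A [noise_model()] with all noise magnitudes zero.
#' @export
noise_off <- function(...) {
  noise_model(fl_mult_cv = 0, fl_add_sd = 0, od_add_sd = 0, ...)
}

#' Generate a synthetic OD600 growth trace
#'
#' @param g A [growth_model()].
#' @param grid Time grid (min), strictly increasing.
#' @param noise A [noise_model()]; only `od_add_sd` and `seed` are used.
#' @return A tibble with `time`, `value` (OD600).
#' @export
generate_growth <- function(g, grid = seq(0, 800, by = 10),
                            noise = noise_off()) {
  stopifnot(inherits(noise, "noise_model"), all(diff(grid) > 0))
  od <- growth_curve(g, grid)
  od <- withr_seed(noise$seed, od + rnorm(length(od), 0, noise$od_add_sd))
  tibble(time = grid, value = pmax(od, 0))
}

# Raw fluorescence observation: blank + OD-scaled per-cell signal with
# multiplicative and additive noise, quantized to whole au counts
# (plate-reader count resolution).
observe_fl <- function(od_true, percell, noise, quantize) {
  n <- length(od_true)
  mult <- 1 + rnorm(n, 0, noise$fl_mult_cv)
  f <- noise$blank_level + od_true * percell * mult +
    rnorm(n, 0, noise$fl_add_sd)
  if (quantize) f <- round(f)
  pmax(f, 0)
}

observe_od <- function(od_true, od_media, noise) {
  pmax(od_true + od_media + rnorm(length(od_true), 0, noise$od_add_sd), 0)
}

#' Generate a synthetic circuit plate-reader experiment
#'
#' Simulates the circuit under the given induction schedule to obtain the
#' per-cell reporter trajectory, then renders plate-reader observations:
#' fluorescence is `blank_level + OD * signal`, with multiplicative and
#' additive noise, quantized to whole au counts (the instrument's count
#' resolution); OD readings include the media blank offset.  Negative-control
#' wells carry the same strain without any induction; blank wells carry media
#' only.
#'
#' @param topo A [circuit_topology()].
#' @param sched An [induction_schedule()].
#' @param growth A [growth_model()].
#' @param noise A [noise_model()].
#' @param n_replicates Sample (and control) wells per condition, `>= 1`.
#' @param n_blanks Blank wells (default 3).
#' @param grid_step Sampling interval (min, default 10).
#' @param od_media OD600 of the media blank (default 0.04).
#' @param condition Free-form condition metadata (named list).
#' @param quantize Quantize fluorescence to whole counts (default `TRUE`).
#' @param solver A [solver_config()].
#' @return A [platereader_series()] with attribute `ground_truth`: the full
#'   generating configuration plus the noise-free per-cell trajectories,
#'   sufficient to recompute every expected metric with noise off.
#' @export
#' @examples
#' pre <- olc_preset(noise = noise_off())
#' ex <- do.call(generate_circuit_experiment, pre)
generate_circuit_experiment <- function(topo, sched, growth = growth_model(),
                                        noise = noise_model(),
                                        n_replicates = 5L, n_blanks = 3L,
                                        grid_step = 10, od_media = 0.04,
                                        condition = list(),
                                        quantize = TRUE,
                                        solver = solver_config()) {
  stopifnot(inherits(topo, "circuit_topology"),
            inherits(sched, "induction_schedule"),
            inherits(growth, "growth_model"),
            inherits(noise, "noise_model"),
            n_replicates >= 1L)
  grid <- seq(0, sched$horizon, by = grid_step)
  traj <- simulate_circuit(topo, sched, solver = solver)
  percell <- approx(traj$time, traj$yfp, xout = grid)$y
  sched0 <- induction_schedule(horizon = sched$horizon)
  traj0 <- simulate_circuit(topo, sched0, solver = solver)
  percell0 <- approx(traj0$time, traj0$yfp, xout = grid)$y
  od_true <- growth_curve(growth, grid)

  wells <- withr_seed(noise$seed, {
    make_wells(grid, od_true, list(sample = percell,
                                   negative_control = percell0),
               noise, n_replicates, n_blanks, od_media, quantize)
  })
  out <- platereader_series(wells$data, wells$map, condition = condition)
  attr(out, "ground_truth") <- list(
    topology = topo, schedule = sched, growth = growth, noise = noise,
    od_media = od_media, quantize = quantize,
    percell = tibble(time = grid, sample = percell,
                     negative_control = percell0),
    od_true = tibble(time = grid, value = od_true)
  )
  out
}

# Render wells for each role; called inside the seeded RNG scope.
make_wells <- function(grid, od_true, percell_by_role, noise,
                       n_replicates, n_blanks, od_media, quantize) {
  rows <- list()
  map <- list()
  for (role in names(percell_by_role)) {
    for (r in seq_len(n_replicates)) {
      well <- sprintf("%s%d", if (role == "sample") "S" else "C", r)
      rows[[length(rows) + 1L]] <- tibble(
        time = grid, well = well,
        od = observe_od(od_true, od_media, noise),
        fl = observe_fl(od_true, percell_by_role[[role]], noise, quantize)
      )
      map[[length(map) + 1L]] <- tibble(well = well, role = role)
    }
  }
  for (r in seq_len(n_blanks)) {
    well <- sprintf("B%d", r)
    f <- noise$blank_level + rnorm(length(grid), 0, noise$fl_add_sd)
    if (quantize) f <- round(f)
    rows[[length(rows) + 1L]] <- tibble(
      time = grid, well = well,
      od = pmax(od_media + rnorm(length(grid), 0, noise$od_add_sd), 0),
      fl = pmax(f, 0)
    )
    map[[length(map) + 1L]] <- tibble(well = well, role = "blank")
  }
  list(data = dplyr::bind_rows(rows), map = dplyr::bind_rows(map))
}

#' Optimal-lab-condition preset
#'
#' The committed calibration of the synthetic generator emulating the control
#' experiment: the reference delay circuit, both inducers added at `t = 0`,
#' default growth model, 10-min sampling over 800 min.  The reporter's
#' RPU-to-au scale is a calibration fixture chosen once so that, with noise
#' off, the detection-time rule fires at 180 min (the optimal detection
#' time); it is a calibration constant of the generator, not an estimate of
#' any measured quantity.
#'
#' @param noise A [noise_model()].
#' @param n_replicates Wells per role.
#' @return Named list of arguments for [generate_circuit_experiment()].
#' @export
olc_preset <- function(noise = noise_model(), n_replicates = 5L) {
  list(
    topo = delay_circuit(),
    sched = induction_schedule(
      data.frame(time = c(0, 0), inducer = c("ara", "hsl"), q = 1),
      horizon = 800),
    growth = growth_model(),
    noise = noise,
    n_replicates = n_replicates,
    condition = list(preset = "olc", temperature = 37, inducer_ratio = "1:1")
  )
}

#' Named condition presets
#'
#' Fixture multipliers emulating non-optimal conditions: temperature,
#' inducer ratio, and soil exposure scale the reporter amplitude, the
#' relaxation rates, and the replicate noise.  The magnitudes are fixtures
#' chosen to reproduce the direction of the observed condition effects
#' (weaker/slower signal away from the optimum), not measured values.
#'
#' @param temperature One of 30, 37, 42 (degrees C).
#' @param inducer_ratio One of `"1:100"`, `"1:10"`, `"1:1"`, `"10:1"`.
#' @param soil One of `"none"`, `"sterile"`, `"nonsterile"`.
#' @return A list of multipliers: `amplitude`, `tau_scale`, `noise_scale`.
#' @export
condition_preset <- function(temperature = 37,
                             inducer_ratio = c("1:1", "1:10", "1:100", "10:1"),
                             soil = c("none", "sterile", "nonsterile")) {
  inducer_ratio <- match.arg(inducer_ratio)
  soil <- match.arg(soil)
  temp <- c("30" = 0.5, "37" = 1, "42" = 0.05)[as.character(temperature)]
  if (is.na(temp)) abort("`temperature` must be one of 30, 37, 42.")
  ratio <- c("1:100" = 0.05, "1:10" = 0.3, "1:1" = 1, "10:1" = 1.8)[inducer_ratio]
  soil_amp <- c(none = 1, sterile = 0.8, nonsterile = 0.4)[soil]
  soil_noise <- c(none = 1, sterile = 1.5, nonsterile = 3)[soil]
  list(amplitude = unname(temp * ratio * soil_amp),
       tau_scale = unname(c("30" = 0.6, "37" = 1, "42" = 0.5)[as.character(temperature)]),
       noise_scale = unname(soil_noise))
}

#' Generate one ON/OFF characterization series
#'
#' `off_to_on`: per-cell signal rises from basal after induction at `t = 0`
#' following the two-stage cascade law.  `on_to_off`: signal decays
#' exponentially after a media exchange that removes the inducer.  Replicate
#' traces receive multiplicative and additive noise; the replicate mean is
#' returned.
#'
#' @param direction `"off_to_on"` or `"on_to_off"`.
#' @param truth Named list of generating parameters: `tau_y_on`, `tau_x_on`,
#'   `x_ss` (rise); `tau_y_off`, `y0`, `y_ss` (decay).
#' @param media_exchange_time Duration of the series (min, default 650, the
#'   media-exchange protocol length).
#' @param grid_step Sampling interval (min, default 10).
#' @param noise A [noise_model()]; `blank_level` is not used (the series is
#'   already normalized per-cell signal).
#' @param n_replicates Replicates averaged into the returned trace.
#' @return A tibble with `time`, `value`, and attribute `ground_truth`.
#' @export
generate_onoff_experiment <- function(direction = c("off_to_on", "on_to_off"),
                                      truth = list(), media_exchange_time = 650,
                                      grid_step = 10,
                                      noise = noise_off(),
                                      n_replicates = 5L) {
  direction <- match.arg(direction)
  grid <- seq(0, media_exchange_time, by = grid_step)
  defaults <- list(tau_y_on = 0.05, tau_x_on = 0.2, x_ss = 100,
                   tau_y_off = 0.01, y0 = 100, y_ss = 2)
  truth <- modifyList(defaults, truth)
  mean_curve <- if (direction == "off_to_on") {
    cascade_rise(grid, truth$tau_y_on, truth$tau_x_on, truth$x_ss, y0 = 0)
  } else {
    decay_curve(grid, truth$tau_y_off, truth$y0, truth$y_ss)
  }
  obs <- withr_seed(noise$seed, {
    reps <- replicate(n_replicates,
      mean_curve * (1 + rnorm(length(grid), 0, noise$fl_mult_cv)) +
        rnorm(length(grid), 0, noise$fl_add_sd))
    rowMeans(reps)
  })
  out <- tibble(time = grid, value = pmax(obs, 0))
  attr(out, "ground_truth") <- c(truth, list(direction = direction))
  out
}

#' Generate per-phase characterization datasets
#'
#' Builds a list of [phase_dataset()] objects sharing common `x_ss`,
#' `tau_x_on`, and `tau_y_off` but with a per-phase turn-on rate, emulating
#' the growth-phase characterization campaign.
#'
#' @param phases Character vector of phase labels.
#' @param induction_times Induction time per phase (min).
#' @param tau_y_on Turn-on rate per phase (1/min).
#' @param common Named list of the shared parameters (`tau_x_on`, `x_ss`,
#'   `tau_y_off`, `y_ss`).
#' @param noise A [noise_model()]; each phase uses `seed + phase index`.
#' @param n_replicates Replicates per trace.
#' @return List of [phase_dataset()] objects with ground truth attached.
#' @export
generate_phase_datasets <- function(phases, induction_times, tau_y_on,
                                    common = list(tau_x_on = 0.2, x_ss = 100,
                                                  tau_y_off = 0.01, y_ss = 2),
                                    noise = noise_off(),
                                    n_replicates = 5L) {
  stopifnot(length(phases) == length(induction_times),
            length(phases) == length(tau_y_on))
  purrr::map(seq_along(phases), function(i) {
    ns <- noise
    ns$seed <- noise$seed + i
    truth <- modifyList(common, list(tau_y_on = tau_y_on[[i]]))
    truth$y0 <- common$x_ss
    rise <- generate_onoff_experiment("off_to_on", truth, noise = ns,
                                      n_replicates = n_replicates)
    ns2 <- ns
    ns2$seed <- ns$seed + 1000L
    fall <- generate_onoff_experiment("on_to_off", truth, noise = ns2,
                                      n_replicates = n_replicates)
    out <- phase_dataset(phases[[i]], induction_times[[i]],
                         off_to_on = rise, on_to_off = fall)
    attr(out, "ground_truth") <- truth
    out
  })
}

#' Generate a synthetic lysis experiment
#'
#' OD600 follows the growth model until `induction_time + lysis_delay`, then
#' declines exponentially (cell lysis), and regrows from `rescue_at` onward
#' (escape mutants).  Negative-control wells keep growing; only OD is
#' rendered (the lysis assay measures no fluorescence), with the
#' fluorescence channel held at the blank level.
#'
#' @param lysis_delay Delay from induction to OD decline (min, default 240,
#'   the early-lag calibration).
#' @param rescue_at Time of regrowth onset (min, default 650);
#'   `induction_time + lysis_delay < rescue_at < horizon`.
#' @param g A [growth_model()].
#' @param noise A [noise_model()].
#' @param n_replicates Wells per role.
#' @param induction_time Time of the second-inducer addition (min).
#' @param decline_rate Exponential OD decline rate during lysis (1/min).
#' @param horizon End of the series (min).
#' @param grid_step Sampling interval (min).
#' @param od_media Media blank OD600.
#' @return A [platereader_series()] with attribute `ground_truth`.
#' @export
generate_lysis_experiment <- function(lysis_delay = 240, rescue_at = 650,
                                      g = growth_model(),
                                      noise = noise_model(),
                                      n_replicates = 5L,
                                      induction_time = 0,
                                      decline_rate = 0.004,
                                      horizon = 800, grid_step = 10,
                                      od_media = 0.04) {
  t_lys <- induction_time + lysis_delay
  if (!(t_lys < rescue_at && rescue_at < horizon))
    abort("Require induction_time + lysis_delay < rescue_at < horizon.")
  grid <- seq(0, horizon, by = grid_step)
  od_ctrl <- growth_curve(g, grid)
  od_lys <- growth_curve(g, t_lys)
  od_res <- od_lys * exp(-decline_rate * (rescue_at - t_lys))
  od_sample <- ifelse(
    grid <= t_lys, od_ctrl,
    ifelse(grid <= rescue_at,
           od_lys * exp(-decline_rate * (grid - t_lys)),
           pmin(g$capacity, od_res * exp(g$rate * (grid - rescue_at)))))

  wells <- withr_seed(noise$seed, {
    rows <- list(); map <- list()
    for (r in seq_len(n_replicates)) {
      rows[[length(rows) + 1L]] <- tibble(
        time = grid, well = sprintf("S%d", r),
        od = observe_od(od_sample, od_media, noise),
        fl = rep(noise$blank_level, length(grid)))
      map[[length(map) + 1L]] <- tibble(well = sprintf("S%d", r),
                                        role = "sample")
      rows[[length(rows) + 1L]] <- tibble(
        time = grid, well = sprintf("C%d", r),
        od = observe_od(od_ctrl, od_media, noise),
        fl = rep(noise$blank_level, length(grid)))
      map[[length(map) + 1L]] <- tibble(well = sprintf("C%d", r),
                                        role = "negative_control")
    }
    rows[[length(rows) + 1L]] <- tibble(
      time = grid, well = "B1",
      od = pmax(od_media + rnorm(length(grid), 0, noise$od_add_sd), 0),
      fl = rep(noise$blank_level, length(grid)))
    map[[length(map) + 1L]] <- tibble(well = "B1", role = "blank")
    list(data = dplyr::bind_rows(rows), map = dplyr::bind_rows(map))
  })
  out <- platereader_series(wells$data, wells$map,
                            condition = list(assay = "lysis",
                                             induction_time = induction_time))
  attr(out, "ground_truth") <- list(
    lysis_time = t_lys, rescue_time = rescue_at, growth = g, noise = noise,
    decline_rate = decline_rate, od_media = od_media,
    od_sample = tibble(time = grid, value = od_sample),
    od_control = tibble(time = grid, value = od_ctrl)
  )
  out
}

#' Generate (induction time, turn-on rate) trend points
#'
#' Draws turn-on rates from the sigmoid trend with optional multiplicative
#' noise, for round-trip tests of [fit_sigmoid()].
#'
#' @param trend A [sigmoid_trend_params()]; defaults to the published
#'   constants ([tau_trend_defaults()]).
#' @param induction_times At least 4 induction times (min).
#' @param noise_cv Multiplicative coefficient of variation (0 = noiseless).
#' @param seed Integer seed.
#' @return A tibble with `induction_time`, `tau`, and attribute
#'   `ground_truth` (the generating trend).
#' @export
generate_tau_trend_dataset <- function(trend = tau_trend_defaults(),
                                       induction_times = c(0, 180, 210, 240,
                                                           300, 360),
                                       noise_cv = 0, seed = 1L) {
  stopifnot(inherits(trend, "sigmoid_trend_params"),
            length(induction_times) >= 4L)
  tau <- predict_tau(induction_times, trend)
  tau <- withr_seed(seed,
                    tau * (1 + rnorm(length(tau), 0, noise_cv)))
  out <- tibble(induction_time = induction_times, tau = tau)
  attr(out, "ground_truth") <- trend
  out
}

#' Early-lag lysis preset
#'
#' The committed calibration of the lysis generator for early-lag induction:
#' induction at `t = 0`, OD decline from 240 min, rescue from 650 min.
#'
#' @param noise A [noise_model()].
#' @param n_replicates Wells per role.
#' @return Named list of arguments for [generate_lysis_experiment()].
#' @export
lysis_preset <- function(noise = noise_model(), n_replicates = 5L) {
  list(lysis_delay = 240, rescue_at = 650, g = growth_model(),
       noise = noise, n_replicates = n_replicates, induction_time = 0)
}
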