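#' Fitting configuration
#'
#' Controls the multi-start nonlinear least-squares machinery.  Starts are
#' drawn log-uniformly within the per-parameter bounds from a fixed seed, so
#' every fit is deterministic given `(data, config)`.
#'
#' @param n_starts Number of random starts (default 100).
#' @param seed Integer seed for the start draws.
#' @param bounds Named list of `c(low, high)` per free parameter, overriding
#'   the operation's defaults; bounds must be finite with `0 < low < high`.
#' @param loss `"relative"` (default): sum of squared relative errors, the
#'   normalized least-squares loss; `"absolute"`: plain residual sum of
#'   squares.
#' @param tol Convergence tolerance passed to the Levenberg-Marquardt
#'   optimizer.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_starts = 100L, seed = 1L, bounds = list(),
                       loss = c("relative", "absolute"), tol = 1e-10) {
  loss <- match.arg(loss)
  stopifnot(n_starts >= 1L, is.numeric(seed), length(seed) == 1L)
  for (b in bounds) {
    if (length(b) != 2L || !all(is.finite(b)) || b[1L] <= 0 || b[1L] >= b[2L])
      abort("Each bound must be finite with 0 < low < high.")
  }
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 bounds = bounds, loss = loss, tol = tol),
            class = "fit_config")
}

# Residual vector under the configured loss.  The relative loss divides by
# the observation, guarded against zeros at a small fraction of the data
# scale so basal points cannot dominate.
loss_residuals <- function(pred, obs, loss) {
  if (loss == "absolute") return(pred - obs)
  denom <- pmax(abs(obs), 1e-8 * max(abs(obs), 1e-300))
  (pred - obs) / denom
}

# Multi-start bounded Levenberg-Marquardt minimization.
#
# model_fn(pars) -> predicted vector; pars is a full named vector containing
# free and fixed parameters.  Returns a `fit_result`.
multistart_fit <- function(model_fn, obs, free, fixed = numeric(0),
                           bounds, cfg, flag_spread = 0.1) {
  stopifnot(inherits(cfg, "fit_config"), length(free) >= 1L)
  bounds <- modifyList(bounds, cfg$bounds[names(cfg$bounds) %in% free])
  missing_b <- setdiff(free, names(bounds))
  if (length(missing_b))
    abort(sprintf("No bounds for parameter(s): %s.",
                  paste(missing_b, collapse = ", ")))
  lo <- vapply(bounds[free], `[[`, 0, 1L)
  hi <- vapply(bounds[free], `[[`, 0, 2L)

  starts <- withr_seed(cfg$seed, {
    m <- matrix(runif(cfg$n_starts * length(free)), nrow = cfg$n_starts)
    sweep(sweep(m, 2L, log(hi / lo), `*`), 2L, log(lo), `+`) |> exp()
  })
  colnames(starts) <- free

  resid_fn <- function(p_free) {
    pars <- c(setNames(p_free, free), fixed)
    loss_residuals(model_fn(pars), obs, cfg$loss)
  }

  runs <- purrr::map(seq_len(cfg$n_starts), function(i) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[i, ], lower = lo, upper = hi, fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          ftol = cfg$tol, ptol = cfg$tol, maxiter = 500)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      list(chi2 = Inf, converged = FALSE, par = starts[i, ])
    } else {
      list(chi2 = fit$deviance, converged = fit$info %in% 1:4,
           par = setNames(coef(fit), free))
    }
  })

  chi2 <- vapply(runs, `[[`, 0, "chi2")
  conv <- vapply(runs, `[[`, TRUE, "converged")
  if (!any(conv))
    abort("No start converged; widen bounds or inspect the data.")
  ok <- which(conv)
  winner <- ok[which.min(chi2[ok])]
  best <- runs[[winner]]

  # unidentifiability: converged starts whose chi2 ties the winner but whose
  # estimates spread widely mean the data do not pin the parameter down
  tied <- ok[chi2[ok] <= best$chi2 + 1e-6 * (1 + best$chi2)]
  spread <- vapply(free, function(nm) {
    v <- vapply(runs[tied], function(r) r$par[[nm]], 0)
    if (length(v) < 2L) return(0)
    (max(v) - min(v)) / max(abs(mean(v)), 1e-300)
  }, 0)
  unident <- names(spread)[spread > flag_spread]

  estimates <- c(best$par, fixed)
  structure(
    list(
      estimates = estimates,
      fixed_mask = setNames(names(estimates) %in% names(fixed),
                            names(estimates)),
      chi2 = best$chi2,
      start_index = winner,
      unidentifiable = unident,
      all_starts = tibble(start = seq_len(cfg$n_starts), chi2 = chi2,
                          converged = conv),
      loss = cfg$loss
    ),
    class = "fit_result"
  )
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>\n")
  est <- x$estimates
  for (nm in names(est))
    cat(sprintf("  %-10s %12.6g%s\n", nm, est[[nm]],
                if (x$fixed_mask[[nm]]) " (fixed)" else ""))
  cat(sprintf("  chi2 = %.6g (start %d of %d, %d converged)\n",
              x$chi2, x$start_index, nrow(x$all_starts),
              sum(x$all_starts$converged)))
  if (length(x$unidentifiable))
    cat("  unidentifiable:", paste(x$unidentifiable, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.fit_result <- function(x, ...) {
  tibble(term = names(x$estimates),
         estimate = unname(x$estimates),
         fixed = unname(x$fixed_mask),
         unidentifiable = names(x$estimates) %in% x$unidentifiable)
}

#' @export
glance.fit_result <- function(x, ...) {
  tibble(chi2 = x$chi2, start_index = x$start_index,
         n_starts = nrow(x$all_starts),
         n_converged = sum(x$all_starts$converged),
         n_unidentifiable = length(x$unidentifiable))
}

default_flux_bounds <- function() c(1e-6, 100)
default_tau_bounds <- function() c(1e-4, 10)

#' Fit a Hill response function to dose-response data
#'
#' Multi-start bounded Levenberg-Marquardt fit of the four Hill parameters
#' `(y_min, y_max, kappa, n)` to measured (input flux, output flux) pairs,
#' minimizing the normalized (relative-error) least-squares loss.
#'
#' @param dose_response Data frame with columns `input` and `output`
#'   (RPU flux), at least 4 distinct input levels.
#' @param regulation `"repression"` or `"activation"`.
#' @param cfg A [fit_config()].
#' @return A `fit_result`; parameters that tie the best chi-squared across
#'   widely spread estimates are listed in `$unidentifiable`.
#' @export
fit_hill <- function(dose_response, regulation = c("repression", "activation"),
                     cfg = fit_config()) {
  regulation <- match.arg(regulation)
  stopifnot(is.data.frame(dose_response),
            all(c("input", "output") %in% names(dose_response)))
  if (length(unique(dose_response$input)) < 4L)
    abort("Need at least 4 distinct input levels to fit 4 parameters.")
  x <- dose_response$input
  model_fn <- function(p) {
    kn <- p[["kappa"]]^p[["n"]]
    frac <- if (regulation == "repression") kn / (kn + x^p[["n"]])
            else x^p[["n"]] / (kn + x^p[["n"]])
    p[["y_min"]] + (p[["y_max"]] - p[["y_min"]]) * frac
  }
  multistart_fit(
    model_fn, dose_response$output,
    free = c("y_min", "y_max", "kappa", "n"),
    bounds = list(y_min = default_flux_bounds(), y_max = default_flux_bounds(),
                  kappa = default_flux_bounds(), n = c(0.5, 8)),
    cfg = cfg
  )
}

# Sign of the series trend, zeroed when the total drift is negligible
# relative to the data scale (so exactly flat series trigger no warning).
trend_slope <- function(tt, y) {
  slope <- stats::coef(stats::lm(y ~ tt))[[2L]]
  drift <- slope * diff(range(tt))
  if (abs(drift) < 1e-8 * max(abs(y), 1e-300)) 0 else slope
}

# Closed-form first-order decay toward y_ss.
decay_curve <- function(t, tau_off, y0, y_ss) {
  y_ss + (y0 - y_ss) * exp(-tau_off * t)
}

#' Fit the turn-off rate to an ON-to-OFF decay series
#'
#' After input removal (media exchange) the reporter decays as
#' `y(t) = y_ss + (y0 - y_ss) * exp(-tau_off * t)`; this fits
#' `(tau_off, y0, y_ss)` by multi-start least squares.  Time is measured from
#' the start of the decay.
#'
#' @param on_to_off Data frame with columns `time` (min) and `value`
#'   (normalized fluorescence) after input removal.
#' @param cfg A [fit_config()].
#' @return A `fit_result` over `tau_off`, `y0`, `y_ss`.
#' @export
fit_tau_off <- function(on_to_off, cfg = fit_config()) {
  stopifnot(is.data.frame(on_to_off),
            all(c("time", "value") %in% names(on_to_off)))
  tt <- on_to_off$time - on_to_off$time[1L]
  y <- on_to_off$value
  if (trend_slope(tt, y) > 0)
    warn("Series trends upward; a decay fit may be inappropriate.")
  level_hi <- max(10 * max(abs(y)), 1)
  model_fn <- function(p) decay_curve(tt, p[["tau_off"]], p[["y0"]], p[["y_ss"]])
  multistart_fit(
    model_fn, y, free = c("tau_off", "y0", "y_ss"),
    bounds = list(tau_off = default_tau_bounds(),
                  y0 = c(1e-6, level_hi), y_ss = c(1e-6, level_hi)),
    cfg = cfg
  )
}

# Closed-form two-stage rise: sensor stage x(t) = x_ss * (1 - exp(-tau_x t))
# feeding dy/dt = tau_y * (x - y) from y(0) = y0.  The near-degenerate
# tau_x == tau_y case uses the analytic limit.
cascade_rise <- function(t, tau_y, tau_x, x_ss, y0) {
  d <- tau_y - tau_x
  if (abs(d) < 1e-9 * max(tau_y, tau_x)) {
    tau <- (tau_y + tau_x) / 2
    return(x_ss + (y0 - x_ss) * exp(-tau * t) - x_ss * tau * t * exp(-tau * t))
  }
  x_ss + (y0 - x_ss) * exp(-tau_y * t) -
    x_ss * tau_y * (exp(-tau_x * t) - exp(-tau_y * t)) / d
}

#' Fit turn-on kinetics to an OFF-to-ON rise series
#'
#' Fits the two-stage rise law (digital sensor stage turning on with rate
#' `tau_x_on`, feeding a reporter stage relaxing with rate `tau_y_on` toward
#' the plateau `x_ss`) to a post-induction time series.  Any subset of the
#' three parameters may be fixed, as in the staged refitting workflow.  The
#' initial level is taken from the first observation.  At a near-zero initial
#' level the two rates enter symmetrically, so when both are free the result
#' is reported under the convention `tau_x_on >= tau_y_on` (the sensor stage
#' is no slower than the reporter stage).
#'
#' @param off_to_on Data frame with columns `time` (min, from induction) and
#'   `value` (normalized fluorescence).
#' @param fixed Named numeric vector of parameters to hold fixed (subset of
#'   `tau_y_on`, `tau_x_on`, `x_ss`).
#' @param cfg A [fit_config()].
#' @return A `fit_result` over the free subset of
#'   `(tau_y_on, tau_x_on, x_ss)`.
#' @export
fit_tau_on <- function(off_to_on, fixed = numeric(0), cfg = fit_config()) {
  stopifnot(is.data.frame(off_to_on),
            all(c("time", "value") %in% names(off_to_on)))
  allp <- c("tau_y_on", "tau_x_on", "x_ss")
  if (length(fixed) && !all(names(fixed) %in% allp))
    abort("`fixed` names must be among tau_y_on, tau_x_on, x_ss.")
  free <- setdiff(allp, names(fixed))
  if (!length(free)) abort("At least one parameter must be free.")
  tt <- off_to_on$time - off_to_on$time[1L]
  y <- off_to_on$value
  y0 <- y[1L]
  if (trend_slope(tt, y) < 0)
    warn("Series trends downward; a rise fit may be inappropriate.")
  model_fn <- function(p)
    cascade_rise(tt, p[["tau_y_on"]], p[["tau_x_on"]], p[["x_ss"]], y0)
  fit <- multistart_fit(
    model_fn, y, free = free, fixed = fixed,
    bounds = list(tau_y_on = default_tau_bounds(),
                  tau_x_on = default_tau_bounds(),
                  x_ss = c(1e-6, max(10 * max(abs(y)), 1))),
    cfg = cfg
  )
  # canonical ordering where the model is rate-symmetric (y0 ~ 0, both free)
  both_free <- all(c("tau_y_on", "tau_x_on") %in% free)
  if (both_free && abs(y0) < 1e-6 * max(abs(y)) &&
      fit$estimates[["tau_x_on"]] < fit$estimates[["tau_y_on"]]) {
    tmp <- fit$estimates[["tau_x_on"]]
    fit$estimates[["tau_x_on"]] <- fit$estimates[["tau_y_on"]]
    fit$estimates[["tau_y_on"]] <- tmp
  }
  fit$y0 <- y0
  fit
}

#' One growth phase's characterization dataset
#'
#' @param phase Growth-phase label (e.g. `"EL"`, `"LL"`, ...).
#' @param induction_time Time (min) at which the phase's induction occurred.
#' @param off_to_on,on_to_off Data frames with columns `time`, `value`; at
#'   least one direction must be present.
#' @return An object of class `phase_dataset`.
#' @export
phase_dataset <- function(phase, induction_time, off_to_on = NULL,
                          on_to_off = NULL) {
  if (is.null(off_to_on) && is.null(on_to_off))
    abort("At least one experiment direction is required.")
  structure(list(phase = phase, induction_time = induction_time,
                 off_to_on = off_to_on, on_to_off = on_to_off),
            class = "phase_dataset")
}

#' Staged parameter-fixing refit across growth phases
#'
#' The staged workflow that isolates the growth-phase dependence of the gate
#' turn-on rate.  Stage 0 fits `tau_y_off` to each phase's ON-to-OFF decay
#' and fixes its cross-phase mean.  Each subsequent stage refits the rise
#' model to every phase, then fixes the next parameter in `order` at its
#' cross-phase mean from that stage.  The final stage refits with only
#' `tau_y_on` free, yielding one turn-on rate per phase.  Fitting each phase
#' separately with everything free (`order = character(0)`) reproduces the
#' unconstrained workflow, where parameter compensation spreads the estimates.
#'
#' @param datasets List of [phase_dataset()] objects (>= 1 phase).
#' @param order Fixing sequence; default `c("tau_y_off", "x_ss", "tau_x_on")`.
#'   An empty order fits all phases unconstrained.
#' @param cfg A [fit_config()].
#' @return An object of class `staged_refit`: a list with `per_phase` (tibble
#'   of phase, induction time, `tau_y_on`, chi2), `fixed` (the cross-phase
#'   fixed values), and `ledger` (per-iteration, per-phase estimates for
#'   audit).
#' @export
staged_refit <- function(datasets,
                         order = c("tau_y_off", "x_ss", "tau_x_on"),
                         cfg = fit_config()) {
  stopifnot(length(datasets) >= 1L,
            all(vapply(datasets, inherits, TRUE, "phase_dataset")))
  known <- c("tau_y_off", "x_ss", "tau_x_on")
  if (!all(order %in% known))
    abort(sprintf("`order` entries must be among: %s.",
                  paste(known, collapse = ", ")))
  phases <- vapply(datasets, `[[`, "", "phase")
  ledger <- list()
  fixed_common <- numeric(0)
  iter <- 0L

  record <- function(iter, fits, stage_label) {
    purrr::imap_dfr(fits, function(f, i) {
      tidy(f) |>
        dplyr::mutate(iteration = iter, stage = stage_label,
                      phase = phases[[as.integer(i)]], chi2 = f$chi2,
                      .before = 1L)
    })
  }

  # stage 0: turn-off rate from the decay experiments
  if ("tau_y_off" %in% order) {
    decay_fits <- purrr::imap(datasets, function(d, i) {
      if (is.null(d$on_to_off))
        abort(sprintf("Phase '%s' lacks the ON-to-OFF experiment required to fix tau_y_off.",
                      d$phase))
      fit_tau_off(d$on_to_off, cfg)
    })
    ledger[[length(ledger) + 1L]] <- record(iter, decay_fits, "fit tau_y_off")
    fixed_common["tau_y_off"] <-
      mean(vapply(decay_fits, function(f) f$estimates[["tau_off"]], 0))
    iter <- iter + 1L
  }

  rise_order <- setdiff(order, "tau_y_off")
  rise_fixed <- numeric(0)
  fit_phases <- function(fx) {
    purrr::imap(datasets, function(d, i) {
      if (is.null(d$off_to_on))
        abort(sprintf("Phase '%s' lacks the OFF-to-ON experiment.", d$phase))
      fit_tau_on(d$off_to_on, fixed = fx, cfg = cfg)
    })
  }

  fits <- fit_phases(rise_fixed)
  ledger[[length(ledger) + 1L]] <- record(iter, fits, "all free rise fit")
  for (par in rise_order) {
    fixed_common[par] <-
      mean(vapply(fits, function(f) f$estimates[[par]], 0))
    rise_fixed <- fixed_common[intersect(names(fixed_common),
                                         c("x_ss", "tau_x_on"))]
    iter <- iter + 1L
    fits <- fit_phases(rise_fixed)
    ledger[[length(ledger) + 1L]] <-
      record(iter, fits, sprintf("fix %s", par))
  }

  per_phase <- tibble(
    phase = phases,
    induction_time = vapply(datasets, `[[`, 0, "induction_time"),
    tau_y_on = vapply(fits, function(f) f$estimates[["tau_y_on"]], 0),
    tau_x_on = vapply(fits, function(f) f$estimates[["tau_x_on"]], 0),
    x_ss = vapply(fits, function(f) f$estimates[["x_ss"]], 0),
    chi2 = vapply(fits, `[[`, 0, "chi2")
  )
  structure(
    list(per_phase = per_phase, fixed = fixed_common,
         ledger = dplyr::bind_rows(ledger), final_fits = fits),
    class = "staged_refit"
  )
}

#' @export
print.staged_refit <- function(x, ...) {
  cat("<staged_refit>\n")
  if (length(x$fixed)) {
    cat("  fixed (cross-phase means):\n")
    for (nm in names(x$fixed))
      cat(sprintf("    %-10s %.6g\n", nm, x$fixed[[nm]]))
  }
  print(x$per_phase)
  invisible(x)
}

#' @export
tidy.staged_refit <- function(x, ...) x$per_phase

#' @export
glance.staged_refit <- function(x, ...) {
  tibble(n_phases = nrow(x$per_phase),
         n_iterations = length(unique(x$ledger$iteration)),
         total_chi2 = sum(x$per_phase$chi2))
}
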