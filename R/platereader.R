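#' Replicated plate-reader series
#'
#' Container for OD600 and fluorescence kinetics of one plate, in long form.
#' Each well carries a role: `sample` (induced circuit), `negative_control`
#' (same strain, not induced), or `blank` (media only).
#'
#' @param data Data frame with columns `time` (min), `well`, `od`, `fl`.
#'   Every well must cover the same strictly increasing time grid.
#' @param wellmap Data frame with columns `well`, `role` and optionally
#'   `condition`; `role` must be one of `sample`, `negative_control`, `blank`.
#' @param condition Optional free-form metadata (named list) describing the
#'   experimental condition (temperature, inducer ratio, induction phase...).
#'
#' @return An object of class `platereader_series`: a long tibble with the
#'   well map joined in and the condition stored as an attribute.
#' @export
platereader_series <- function(data, wellmap, condition = list()) {
  stopifnot(is.data.frame(data),
            all(c("time", "well", "od", "fl") %in% names(data)),
            is.data.frame(wellmap),
            all(c("well", "role") %in% names(wellmap)))
  roles <- c("sample", "negative_control", "blank")
  if (!all(wellmap$role %in% roles))
    abort(sprintf("Well roles must be one of: %s.", paste(roles, collapse = ", ")))
  data <- as_tibble(data)
  wellmap <- as_tibble(wellmap)
  if (!all(data$well %in% wellmap$well))
    abort("Every well in `data` must appear in `wellmap`.")
  grid <- sort(unique(data$time))
  if (any(diff(grid) <= 0)) abort("Time grid must be strictly increasing.")
  n_per_well <- table(data$well)
  if (length(unique(n_per_well)) != 1L || unique(n_per_well) != length(grid))
    abort("Every well must cover the same time grid.")
  out <- dplyr::left_join(data, wellmap, by = "well")
  out <- dplyr::arrange(out, .data$well, .data$time)
  structure(out, class = c("platereader_series", class(out)),
            condition = condition)
}

#' @export
print.platereader_series <- function(x, ...) {
  wells <- dplyr::distinct(as_tibble(x), .data$well, .data$role)
  cat(sprintf("<platereader_series> %d wells (%s), %d time points\n",
              nrow(wells),
              paste(sprintf("%d %s", table(wells$role)[unique(wells$role)],
                            unique(wells$role)), collapse = ", "),
              length(unique(x$time))))
  NextMethod()
}

series_role <- function(s, role) {
  out <- dplyr::filter(as_tibble(s), .data$role == !!role)
  if (!nrow(out)) abort(sprintf("Series has no well with role '%s'.", role))
  out
}

#' Blank- and OD-normalized fluorescence trace
#'
#' Per time point, the average blank reading is subtracted from the average
#' fluorescence of the chosen wells and the result divided by the average
#' blank-corrected OD600 of those wells:
#' `(F_bar - F_blank_bar) / (OD_bar - OD_blank_bar)`.
#' Replicates are averaged before the metric is formed.  Time points with a
#' nonpositive corrected OD are excluded with a warning.
#'
#' @param s A [platereader_series()].
#' @param role Which wells to normalize (`"sample"` or `"negative_control"`).
#' @param od_blank_correct Subtract the blank wells' OD before dividing
#'   (default `TRUE`); `FALSE` divides by the raw average OD.
#' @param per_well Also return one trace per well (replicate-level), each
#'   normalized against the average blank.
#' @return A tibble with columns `time` and `value` (au per OD600), plus
#'   `well` when `per_well = TRUE`.
#' @export
normalize_fluorescence <- function(s, role = "sample",
                                   od_blank_correct = TRUE,
                                   per_well = FALSE) {
  stopifnot(inherits(s, "platereader_series"))
  blank <- series_role(s, "blank") |>
    dplyr::summarise(fl_blank = mean(.data$fl), od_blank = mean(.data$od),
                     .by = "time")
  wells <- series_role(s, role)
  grp <- if (per_well) c("time", "well") else "time"
  out <- wells |>
    dplyr::summarise(fl = mean(.data$fl), od = mean(.data$od),
                     .by = dplyr::all_of(grp)) |>
    dplyr::left_join(blank, by = "time") |>
    dplyr::mutate(
      od_corr = if (od_blank_correct) .data$od - .data$od_blank else .data$od,
      value = (.data$fl - .data$fl_blank) / .data$od_corr
    )
  bad <- out$od_corr <= 0
  if (any(bad)) {
    warn(sprintf("%d time point(s) with nonpositive corrected OD excluded.",
                 sum(bad)))
    out <- out[!bad, ]
  }
  dplyr::select(out, dplyr::any_of(c("time", "well", "value")))
}

check_common_grid <- function(a, b) {
  stopifnot(is.data.frame(a), is.data.frame(b),
            all(c("time", "value") %in% names(a)),
            all(c("time", "value") %in% names(b)))
  if (nrow(a) != nrow(b) || !isTRUE(all.equal(a$time, b$time)))
    abort("Traces must share a common time grid.")
}

# First index i such that `hit[i..(i+debounce-1)]` are all TRUE, or NA.
first_sustained <- function(hit, debounce) {
  n <- length(hit)
  if (debounce < 1L) abort("`debounce` must be >= 1.")
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (hit[i]) run + 1L else 0L
    if (run >= debounce) return(i - debounce + 1L)
  }
  NA_integer_
}

#' Fluorescence detection time
#'
#' First grid time at which the sample's normalized fluorescence strictly
#' exceeds the negative control's and remains above it for `debounce`
#' consecutive grid points.  Times are reported at the grid point (the
#' measurement resolution), not interpolated.
#'
#' @param sample,control Normalized traces (tibbles with `time`, `value`) on
#'   a common grid, e.g. from [normalize_fluorescence()].
#' @param debounce Number of consecutive exceeding points required
#'   (default 2; `1` gives the literal single-point crossing rule).
#' @return Detection time in min, or `NA_real_` if never detected.
#' @export
detection_time <- function(sample, control, debounce = 2L) {
  check_common_grid(sample, control)
  i <- first_sustained(sample$value > control$value, debounce)
  if (is.na(i)) NA_real_ else sample$time[i]
}

#' Fluorescence fold change
#'
#' Ratio of the maximum normalized fluorescence of the sample to that of the
#' reference condition (whose own fold change is exactly 1).
#'
#' @param sample,reference Normalized traces (tibbles with `time`, `value`).
#' @return Dimensionless fold change.
#' @export
fold_change <- function(sample, reference) {
  stopifnot(nrow(sample) > 0, nrow(reference) > 0)
  mref <- max(reference$value)
  if (mref <= 0) abort("Reference trace maximum must be positive.")
  max(sample$value) / mref
}

#' Hourly accumulated fluorescence
#'
#' Partitions the trace from the detection time onward into consecutive
#' 60-min bins (left-closed, right-open; the last bin may be partial) and
#' sums the normalized values whose timestamps fall in each bin.  The bin
#' sums conserve the total over all points from detection.
#'
#' @param trace Normalized trace (tibble with `time`, `value`).
#' @param t_detect Detection time (min) within the grid; see
#'   [detection_time()].
#' @return A tibble with columns `hour` (1-based bin index), `t_start`,
#'   `t_end`, and `value` (bin sum); the total is `sum(out$value)`.
#' @export
accumulated_fluorescence <- function(trace, t_detect) {
  stopifnot(is.data.frame(trace), all(c("time", "value") %in% names(trace)))
  if (is.na(t_detect)) abort("`t_detect` is NA (signal never detected).")
  if (t_detect < min(trace$time) || t_detect > max(trace$time))
    abort("`t_detect` must lie within the time grid.")
  kept <- trace[trace$time >= t_detect, ]
  kept |>
    dplyr::mutate(hour = floor((.data$time - t_detect) / 60) + 1L) |>
    dplyr::summarise(
      t_start = t_detect + 60 * (.data$hour[1L] - 1L),
      t_end = t_detect + 60 * .data$hour[1L],
      value = sum(.data$value),
      .by = "hour"
    )
}

# First upward crossing of `level`, linearly interpolated; NA if never crossed.
first_crossing <- function(time, value, level) {
  above <- value >= level
  if (above[1L]) return(time[1L])
  i <- which(!above[-length(above)] & above[-1L])[1L]
  if (is.na(i)) return(NA_real_)
  time[i] + (level - value[i]) / (value[i + 1L] - value[i]) *
    (time[i + 1L] - time[i])
}

#' Doubling time from an OD600 trace
#'
#' Time for the (blank-corrected) OD600 to rise from 0.2 to 0.4, using
#' linearly interpolated first upward crossings of the two thresholds.
#'
#' @param od OD trace: tibble with `time`, `value`.
#' @param from,to OD thresholds (defaults 0.2 and 0.4).
#' @return Doubling time in min, or `NA_real_` when either threshold is never
#'   crossed.
#' @export
doubling_time <- function(od, from = 0.2, to = 0.4) {
  stopifnot(is.data.frame(od), all(c("time", "value") %in% names(od)))
  t1 <- first_crossing(od$time, od$value, from)
  t2 <- first_crossing(od$time, od$value, to)
  if (is.na(t1) || is.na(t2)) return(NA_real_)
  t2 - t1
}

#' Time of induced lysis
#'
#' First grid time from which the sample OD600 strictly decreases for
#' `debounce` consecutive steps while the negative control's does not.
#'
#' @param sample_od,control_od OD traces (tibbles with `time`, `value`) on a
#'   common grid.
#' @param debounce Consecutive decreasing steps required (default 2).
#' @return Lysis time in min, or `NA_real_` if no lysis is called.
#' @export
lysis_time <- function(sample_od, control_od, debounce = 2L) {
  check_common_grid(sample_od, control_od)
  ds <- diff(sample_od$value) < 0
  dc <- diff(control_od$value) < 0
  n <- length(ds)
  for (i in seq_len(n - debounce + 1L)) {
    win <- i:(i + debounce - 1L)
    if (all(ds[win]) && !all(dc[win])) return(sample_od$time[i])
  }
  NA_real_
}

#' Time of rescue from lysis
#'
#' First time at or after the lysis time from which the sample OD600
#' increases for `debounce` consecutive steps (regrowth of escape mutants).
#'
#' @param sample_od OD trace (tibble with `time`, `value`).
#' @param t_lysis Lysis time (min); see [lysis_time()].
#' @param debounce Consecutive increasing steps required (default 2).
#' @return Rescue time in min, or `NA_real_` if the OD never recovers.
#' @export
rescue_time <- function(sample_od, t_lysis, debounce = 2L) {
  stopifnot(is.data.frame(sample_od),
            all(c("time", "value") %in% names(sample_od)))
  if (is.na(t_lysis)) abort("`t_lysis` is NA (no lysis called).")
  post <- sample_od[sample_od$time >= t_lysis, ]
  du <- diff(post$value) > 0
  n <- length(du)
  if (n < debounce) return(NA_real_)
  for (i in seq_len(n - debounce + 1L)) {
    if (all(du[i:(i + debounce - 1L)])) return(post$time[i])
  }
  NA_real_
}

#' Growth-phase boundary configuration
#'
#' Phases are called from the fraction of the OD rise completed,
#' `f = (od - od_min) / (od_plateau - od_min)`, with configurable upper
#' boundaries per phase.  The defaults are a documented convention, not an
#' estimate of any particular strain's physiology.
#'
#' @param el,ll,ee,me,le Upper `f` boundary of the early-lag, late-lag,
#'   early-, mid-, and late-exponential phases; `f` above `le` is stationary.
#' @return Named numeric vector of boundaries.
#' @export
growth_phase_config <- function(el = 0.02, ll = 0.05, ee = 0.25, me = 0.6,
                                le = 0.9) {
  b <- c(EL = el, LL = ll, EE = ee, ME = me, LE = le)
  if (any(diff(b) <= 0)) abort("Phase boundaries must be strictly increasing.")
  b
}

#' Growth phase at a time point
#'
#' @param od OD trace (tibble with `time`, `value`, blank-corrected).
#' @param t Time (min), must be in the grid.
#' @param cfg Boundaries from [growth_phase_config()].
#' @return One of `"EL"`, `"LL"`, `"EE"`, `"ME"`, `"LE"`, `"S"`.
#' @export
growth_phase_at <- function(od, t, cfg = growth_phase_config()) {
  stopifnot(is.data.frame(od), all(c("time", "value") %in% names(od)))
  i <- match(t, od$time)
  if (is.na(i)) abort("`t` must be a grid time point.")
  f <- (od$value[i] - min(od$value)) / (max(od$value) - min(od$value))
  labels <- c(names(cfg), "S")
  labels[findInterval(f, cfg, left.open = TRUE) + 1L]
}

#' Two-sample Student's t-test on replicate metrics
#'
#' Convenience wrapper over [stats::t.test()] for comparing per-replicate
#' metric values between two conditions (two-sided; pooled variance by
#' default).
#'
#' @param a,b Numeric vectors of per-replicate values (`n >= 2` each).
#' @param var_equal Pooled-variance test (default `TRUE`); `FALSE` gives
#'   Welch's test.
#' @return A tibble with `statistic`, `p_value`, `df`, `mean_a`, `mean_b`.
#' @export
two_sample_t <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L)
    abort("Each group needs at least two replicates.")
  ht <- t.test(a, b, var.equal = var_equal)
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
         df = unname(ht$parameter), mean_a = mean(a), mean_b = mean(b))
}
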