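#' Read a plate-reader export
#'
#' Two delimited-text layouts are accepted (comma-separated, UTF-8, `.`
#' decimal, header row required; time always in minutes from experiment
#' start):
#'
#' * **wide**: first column `time`, then one `<well>_OD` and one `<well>_FL`
#'   column per well;
#' * **long**: columns `time`, `well`, `od`, `fl`.
#'
#' Well roles come from a well-map sidecar CSV with columns `well`, `role`
#' (and optionally `condition`).
#'
#' @param path Path to the plate-reader CSV.
#' @param wellmap Path to the well-map CSV.
#' @param layout `"wide"` or `"long"`.
#' @return A [platereader_series()].
#' @export
read_platereader <- function(path, wellmap, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  raw <- utils::read.csv(path, check.names = FALSE)
  map <- utils::read.csv(wellmap)
  if (!all(c("well", "role") %in% names(map)))
    abort("Well map must have columns `well` and `role`.")
  if (layout == "long") {
    need <- c("time", "well", "od", "fl")
    if (!all(need %in% names(raw)))
      abort("Long layout needs columns time, well, od, fl.")
    data <- as_tibble(raw[need])
  } else {
    if (names(raw)[1L] != "time")
      abort("Wide layout: first column must be `time`.")
    meas <- names(raw)[-1L]
    ok <- grepl("_(OD|FL)$", meas)
    if (!all(ok))
      abort(sprintf("Wide columns must end in _OD or _FL; offending: %s.",
                    paste(meas[!ok], collapse = ", ")))
    data <- tidyr::pivot_longer(as_tibble(raw), -"time",
                                names_to = c("well", ".value"),
                                names_pattern = "^(.*)_(OD|FL)$")
    names(data) <- tolower(names(data))
  }
  if (any(diff(sort(unique(data$time))) <= 0) ||
      is.unsorted(unique(data$time)))
    abort("Time grid must be strictly increasing.")
  for (role in c("blank")) {
    if (!role %in% map$role)
      abort(sprintf("Well map declares no '%s' well.", role))
  }
  platereader_series(data, map)
}

#' Write a plate-reader series
#'
#' @param s A [platereader_series()].
#' @param path Output CSV path.
#' @param wellmap Output well-map CSV path.
#' @param layout `"wide"` or `"long"` (see [read_platereader()]).
#' @return `path`, invisibly.
#' @export
write_platereader <- function(s, path, wellmap, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  stopifnot(inherits(s, "platereader_series"))
  tbl <- as_tibble(s)
  map <- dplyr::distinct(tbl, .data$well, .data$role)
  if (layout == "long") {
    out <- tbl[c("time", "well", "od", "fl")]
  } else {
    out <- tbl |>
      dplyr::select("time", "well", "od", "fl") |>
      tidyr::pivot_wider(names_from = "well",
                         values_from = c("od", "fl"),
                         names_glue = "{well}_{toupper(.value)}")
    # column order: each well's OD then FL
    wells <- unique(tbl$well)
    out <- out[c("time", as.vector(rbind(paste0(wells, "_OD"),
                                         paste0(wells, "_FL"))))]
  }
  utils::write.csv(out, path, row.names = FALSE)
  utils::write.csv(map, wellmap, row.names = FALSE)
  invisible(path)
}

topology_to_list <- function(topo) {
  list(
    sensors = purrr::map(unname(topo$sensors), unclass),
    gates = purrr::map(unname(topo$gates), unclass),
    edges = as.data.frame(topo$edges),
    output_gate = topo$output_gate,
    reporter = unclass(topo$reporter)
  )
}

#' Write / read a circuit topology document
#'
#' Topology and parameters are serialized as a JSON document with fields
#' `sensors[]`, `gates[]`, `edges[]`, `output_gate`, `reporter{}`; the
#' document is validated on load (field presence, types, invariants) by the
#' same constructors used in code.
#'
#' @param topo A [circuit_topology()].
#' @param path JSON file path.
#' @return `write_topology`: `path`, invisibly.  `read_topology`: a validated
#'   [circuit_topology()].
#' @export
write_topology <- function(topo, path) {
  stopifnot(inherits(topo, "circuit_topology"))
  jsonlite::write_json(topology_to_list(topo), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  need <- c("sensors", "gates", "edges", "output_gate", "reporter")
  missing <- setdiff(need, names(doc))
  if (length(missing))
    abort(sprintf("Topology document lacks field(s): %s.",
                  paste(missing, collapse = ", ")))
  circuit_topology(
    sensors = purrr::map(doc$sensors, function(s)
      sensor_params(s$name, s$x_min, s$x_max, s$inducer)),
    gates = purrr::map(doc$gates, function(g)
      gate_params(g$name, g$regulation, g$y_min, g$y_max, g$kappa, g$n,
                  g$tau_on, g$tau_off)),
    edges = dplyr::bind_rows(purrr::map(doc$edges, as_tibble)),
    output_gate = doc$output_gate,
    reporter = reporter_params(doc$reporter$tau_on, doc$reporter$tau_off,
                               doc$reporter$rpu_to_au)
  )
}

#' Write / read an induction schedule document
#'
#' @param sched An [induction_schedule()].
#' @param path JSON file path.
#' @return `write_schedule`: `path`, invisibly.  `read_schedule`: a validated
#'   [induction_schedule()].
#' @export
write_schedule <- function(sched, path) {
  stopifnot(inherits(sched, "induction_schedule"))
  jsonlite::write_json(list(events = as.data.frame(sched$events),
                            horizon = sched$horizon),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("events", "horizon") %in% names(doc)))
    abort("Schedule document needs `events` and `horizon`.")
  ev <- doc$events
  if (length(ev) == 0L || nrow(as.data.frame(ev)) == 0L)
    ev <- data.frame(time = numeric(), inducer = character(), q = numeric())
  induction_schedule(as.data.frame(ev), horizon = doc$horizon)
}

#' Write / read sigmoid trend parameters
#'
#' @param trend A [sigmoid_trend_params()].
#' @param path JSON file path.
#' @return `write_trend`: `path`, invisibly.  `read_trend`: a validated
#'   [sigmoid_trend_params()].
#' @export
write_trend <- function(trend, path) {
  stopifnot(inherits(trend, "sigmoid_trend_params"))
  jsonlite::write_json(unclass(trend), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_trend
#' @export
read_trend <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("L", "x0", "k", "b")
  if (!all(need %in% names(doc)))
    abort("Trend document needs fields L, x0, k, b.")
  sigmoid_trend_params(doc$L, doc$x0, doc$k, doc$b,
                       orientation = doc$orientation %||% "falling")
}

#' Write a trajectory as delimited text
#'
#' @param traj A `circuit_trajectory`.
#' @param path Output CSV path (`time`, one column per state).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Standard metric table for a circuit experiment
#'
#' Computes the plate-reader metrics (detection time, maximum normalized
#' fluorescence, total accumulated fluorescence from detection, doubling
#' time) for one series, in tidy form.
#'
#' @param s A [platereader_series()].
#' @param debounce Debounce window for the crossing rules.
#' @return A tibble with columns `metric`, `value`, `n` (wells used).
#' @export
analyze_platereader <- function(s, debounce = 2L) {
  stopifnot(inherits(s, "platereader_series"))
  samp <- normalize_fluorescence(s, "sample")
  ctrl <- normalize_fluorescence(s, "negative_control")
  n_sample <- length(unique(series_role(s, "sample")$well))
  det <- detection_time(samp, ctrl, debounce = debounce)
  acc <- if (is.na(det)) NA_real_
         else sum(accumulated_fluorescence(samp, det)$value)
  blank_od <- series_role(s, "blank") |>
    dplyr::summarise(v = mean(.data$od), .by = "time")
  od <- series_role(s, "sample") |>
    dplyr::summarise(value = mean(.data$od), .by = "time") |>
    dplyr::mutate(value = .data$value - blank_od$v)
  tibble(
    metric = c("detection_time", "max_normalized_fl",
               "accumulated_fl_total", "doubling_time"),
    value = c(det, max(samp$value), acc, doubling_time(od)),
    n = n_sample
  )
}
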