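make_series <- function(time, fl_sample, od_sample, fl_blank = 20,
                        od_blank = 0, fl_ctrl = NULL, od_ctrl = NULL) {
  wells <- list(
    tibble::tibble(time = time, well = "S1", od = od_sample + od_blank,
                   fl = fl_sample),
    tibble::tibble(time = time, well = "B1", od = rep(od_blank, length(time)),
                   fl = rep(fl_blank, length(time)))
  )
  map <- tibble::tibble(well = c("S1", "B1"), role = c("sample", "blank"))
  if (!is.null(fl_ctrl)) {
    wells <- c(wells, list(tibble::tibble(time = time, well = "C1",
                                          od = od_ctrl + od_blank,
                                          fl = fl_ctrl)))
    map <- dplyr::bind_rows(map,
                            tibble::tibble(well = "C1",
                                           role = "negative_control"))
  }
  platereader_series(dplyr::bind_rows(wells), map)
}

test_that("fluorescence normalization implements (F - blank) / OD", {
  tt <- seq(0, 50, by = 10)
  s <- make_series(tt, fl_sample = rep(100, 6), od_sample = rep(0.4, 6),
                   fl_blank = 20)
  out <- normalize_fluorescence(s)
  expect_equal(out$value, rep((100 - 20) / 0.4, 6))
  # fluorescence equal to blank everywhere gives a zero trace
  s0 <- make_series(tt, fl_sample = rep(20, 6), od_sample = rep(0.4, 6),
                    fl_blank = 20)
  expect_equal(normalize_fluorescence(s0)$value, rep(0, 6))
})

test_that("replicate averaging happens before normalization (spreadsheet oracle)", {
  tt <- c(0, 10, 20)
  data <- dplyr::bind_rows(
    tibble::tibble(time = tt, well = "S1", od = c(0.10, 0.20, 0.30),
                   fl = c(30, 60, 90)),
    tibble::tibble(time = tt, well = "S2", od = c(0.12, 0.22, 0.32),
                   fl = c(40, 70, 100)),
    tibble::tibble(time = tt, well = "B1", od = c(0.02, 0.02, 0.02),
                   fl = c(10, 12, 14)),
    tibble::tibble(time = tt, well = "B2", od = c(0.02, 0.02, 0.02),
                   fl = c(12, 14, 18))
  )
  map <- tibble::tibble(well = c("S1", "S2", "B1", "B2"),
                        role = c("sample", "sample", "blank", "blank"))
  s <- platereader_series(data, map)
  out <- normalize_fluorescence(s)
  # hand-computed means: F = (30+40)/2 etc., blank = (10+12)/2 etc.
  f_bar <- c(35, 65, 95); b_bar <- c(11, 13, 16)
  od_bar <- c(0.11, 0.21, 0.31) - 0.02
  expect_equal(out$value, (f_bar - b_bar) / od_bar, tolerance = 1e-12)
})

test_that("normalization is linear in the fluorescence scale", {
  tt <- seq(0, 90, by = 10)
  set.seed(11)
  fl <- 20 + cumsum(runif(10, 0, 30))
  s1 <- make_series(tt, fl_sample = fl, od_sample = runif(10, 0.1, 0.5),
                    fl_blank = 20)
  # scale all fluorescence (sample and blank) by c: trace scales by c
  tbl <- tibble::as_tibble(s1)
  tbl$fl <- tbl$fl * 3
  s3 <- platereader_series(tbl[c("time", "well", "od", "fl")],
                           dplyr::distinct(tbl, well, role))
  expect_equal(normalize_fluorescence(s3)$value,
               3 * normalize_fluorescence(s1)$value, tolerance = 1e-12)
})

test_that("detection time is the first sustained exceedance at grid resolution", {
  tt <- seq(0, 400, by = 10)
  ctrl <- trace_tbl(tt, rep(1, length(tt)))
  # never strictly exceeds itself
  expect_true(is.na(detection_time(ctrl, ctrl)))
  # crosses at the 180-min grid point and stays above
  samp <- trace_tbl(tt, ifelse(tt >= 180, 2, 0.5))
  expect_equal(detection_time(samp, ctrl), 180)
  # a single-point spike does not count under the default debounce
  spike <- trace_tbl(tt, ifelse(tt == 180, 2, 0.5))
  expect_true(is.na(detection_time(spike, ctrl)))
  expect_equal(detection_time(spike, ctrl, debounce = 1), 180)
  # adding a positive constant never delays detection
  for (c0 in c(0.1, 1, 5)) {
    shifted <- trace_tbl(tt, samp$value + c0)
    d <- detection_time(shifted, ctrl)
    expect_lte(d, detection_time(samp, ctrl))
  }
  expect_error(detection_time(samp, trace_tbl(tt + 5, ctrl$value)), "grid")
})

test_that("fold change is the ratio of trace maxima", {
  tt <- seq(0, 100, 10)
  a <- trace_tbl(tt, seq(0, 500, length.out = 11))
  b <- trace_tbl(tt, seq(0, 250, length.out = 11))
  expect_equal(fold_change(a, b), 2.0)
  expect_equal(fold_change(a, a), 1.0)
  set.seed(4)
  noisy <- trace_tbl(tt, runif(11, 0, 7))
  expect_equal(fold_change(noisy, b), max(noisy$value) / 250)
  expect_error(fold_change(a, trace_tbl(tt, rep(0, 11))), "positive")
})

test_that("hourly accumulation partitions and conserves the trace total", {
  tt <- seq(0, 800, by = 10)
  # constant value 10: first full bin sums six 10-min points
  const <- trace_tbl(tt, rep(10, length(tt)))
  acc <- accumulated_fluorescence(const, t_detect = 180)
  expect_equal(acc$value[1], 60)
  expect_equal(sum(acc$value), sum(const$value[const$time >= 180]))
  # ramp fixture against brute-force accumulation
  ramp <- trace_tbl(tt, pmax(tt - 100, 0) / 10)
  acc2 <- accumulated_fluorescence(ramp, t_detect = 120)
  brute <- sapply(split(ramp$value[ramp$time >= 120],
                        floor((ramp$time[ramp$time >= 120] - 120) / 60)), sum)
  expect_equal(acc2$value, unname(brute))
  expect_equal(sum(acc2$value), sum(ramp$value[ramp$time >= 120]))
  expect_error(accumulated_fluorescence(const, NA_real_), "NA")
})

test_that("doubling time recovers ln2/rate for exact exponentials", {
  tt <- seq(0, 300, by = 10)
  od <- trace_tbl(tt, 0.1 * 2^(tt / 30))
  expect_equal(doubling_time(od), 30, tolerance = 5e-3)
  # arbitrary-rate exponentials, 10-min sampling: < 0.5% error
  tt_long <- seq(0, 600, by = 10)
  for (rate in c(0.005, 0.01, 0.02)) {
    odr <- trace_tbl(tt_long, 0.05 * exp(rate * tt_long))
    expect_equal(doubling_time(odr), log(2) / rate, tolerance = 5e-3)
  }
  # capped below the upper threshold: not computable
  expect_true(is.na(doubling_time(trace_tbl(tt, pmin(0.1 * 2^(tt / 30), 0.35)))))
  # logistic fixture against a 0.01-min fine-grid oracle
  g <- growth_model(od0 = 0.05, rate = 0.01, capacity = 0.6, lag = 60)
  odl <- generate_growth(g, grid = tt)
  fine <- seq(0, 300, by = 0.01)
  odf <- delaygate:::growth_curve(g, fine)
  oracle <- fine[which(odf >= 0.4)[1]] - fine[which(odf >= 0.2)[1]]
  expect_equal(doubling_time(odl), oracle, tolerance = 1e-3)
})

test_that("lysis and rescue times follow the debounced OD-decline rules", {
  tt <- seq(0, 800, by = 10)
  growing <- trace_tbl(tt, 0.05 + 0.001 * tt)
  expect_true(is.na(lysis_time(growing, growing)))
  # sample declines from the 240-min grid point while the control grows
  samp <- trace_tbl(tt, ifelse(tt <= 240, 0.05 + 0.001 * tt,
                               0.29 * exp(-0.004 * (tt - 240))))
  expect_equal(lysis_time(samp, growing), 240)
  # V-shape with minimum at 650: rescue called at 650
  v <- trace_tbl(tt, ifelse(tt <= 650, 1 - 0.001 * tt,
                            0.35 + 0.002 * (tt - 650)))
  expect_equal(rescue_time(v, t_lysis = 240), 650)
  # monotone decline after lysis: no rescue
  dec <- trace_tbl(tt, 1 - 0.001 * tt)
  expect_true(is.na(rescue_time(dec, t_lysis = 240)))
  # increase from the first post-lysis point: that point's time
  up <- trace_tbl(tt, ifelse(tt < 300, 1 - 0.001 * tt,
                             0.7 + 0.002 * (tt - 300)))
  expect_equal(rescue_time(up, t_lysis = 300), 300)
})

test_that("growth phases are called from the fraction of the OD rise", {
  g <- growth_model(od0 = 0.05, rate = 0.01, capacity = 0.5, lag = 60)
  tt <- seq(0, 800, by = 10)
  od <- generate_growth(g, grid = tt)
  expect_equal(growth_phase_at(od, 0), "EL")
  expect_equal(growth_phase_at(od, 800), "S")
  # mid-rise points land in the exponential phases per the config table
  cfg <- growth_phase_config()
  f <- (od$value - min(od$value)) / (max(od$value) - min(od$value))
  t_ee <- od$time[which(f > cfg[["LL"]] & f <= cfg[["EE"]])[1]]
  expect_equal(growth_phase_at(od, t_ee), "EE")
  t_me <- od$time[which(f > cfg[["EE"]] & f <= cfg[["ME"]])[1]]
  expect_equal(growth_phase_at(od, t_me), "ME")
  expect_error(growth_phase_at(od, 805), "grid")
})

test_that("the two-sample t utility matches the pooled-variance formula", {
  a <- c(1, 2, 3); b <- c(1, 2, 3)
  same <- two_sample_t(a, b)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # textbook fixture: hand-computed pooled variance
  x <- c(5.1, 4.9, 6.0, 5.5); y <- c(4.0, 4.4, 3.9, 4.7)
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  got <- two_sample_t(x, y)
  expect_equal(got$statistic, t_hand, tolerance = 1e-12)
  # swapping groups negates t, p unchanged
  sw <- two_sample_t(y, x)
  expect_equal(sw$statistic, -got$statistic)
  expect_equal(sw$p_value, got$p_value)
  expect_error(two_sample_t(1, c(1, 2)), "two replicates")
})
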