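tiny_trial <- function(marker_cols, rate_marker = 100) {
  n <- length(marker_cols[[1]])
  markers <- tibble::tibble(time_s = (seq_len(n) - 1) / rate_marker)
  for (nm in names(marker_cols)) markers[[nm]] <- marker_cols[[nm]]
  n_imu <- max(2, n * 10)
  imu <- tibble::tibble(time_s = (seq_len(n_imu) - 1) / 1000,
                        `H.ACC.Z.L` = rep(0, n_imu))
  gait_trial(markers, imu, condition = "FW")
}

test_that("relative displacement is forward-signed foot minus pelvis centroid", {
  trial <- tiny_trial(list(
    `HEEL_L.X` = c(1.0, 2.0), `HEEL_L.Y` = c(0, 0), `HEEL_L.Z` = c(0, 0),
    `SACR.X` = c(0.5, 0.5), `SACR.Y` = c(0, 0), `SACR.Z` = c(0, 0),
    `PA.X` = c(0, 0), `PA.Y` = c(0, 0), `PA.Z` = c(0, 0),
    `PB.X` = c(1, 1), `PB.Y` = c(0, 0), `PB.Z` = c(0, 0)
  ))
  one <- relative_displacement(trial, "HEEL_L", "SACR")
  expect_equal(one$value, c(0.5, 1.5))

  centroid <- relative_displacement(trial, "PB", c("PA", "PB"))
  expect_equal(centroid$value, c(0.5, 0.5))

  same <- relative_displacement(trial, "SACR", "SACR")
  expect_equal(same$value, c(0, 0))

  expect_error(relative_displacement(trial, "NOPE", "SACR"), "NOPE")
})

test_that("kinematic detection maps extrema to IC/TC by condition", {
  disp <- sine_ts(1 / 1.2, duration = 8, rate = 100)
  params <- peak_params(min_separation = 0.5)
  fw <- detect_omc(disp, disp, condition = "FW", params = params)
  expect_true(all(diff(fw$time_s) > 0))
  ic <- fw$time_s[fw$kind == "IC"]
  tc <- fw$time_s[fw$kind == "TC"]
  expect_equal(diff(sort(ic)), rep(1.2, length(ic) - 1), tolerance = 0.02)
  # IC at maxima, TC at minima, alternating 0.6 s apart
  expect_equal(min(abs(outer(ic, tc, "-"))), 0.6, tolerance = 0.02)

  bw <- detect_omc(disp, disp, condition = "BW", params = params)
  # exact FW/BW label swap on the same trace
  expect_equal(bw$time_s, fw$time_s)
  expect_identical(bw$kind, ifelse(fw$kind == "IC", "TC", "IC"))

  expect_warning(
    empty <- detect_omc(timeseries(rep(1, 300), 100),
                        timeseries(rep(1, 300), 100) |>
                          (\(x) {x$value <- x$value + 1e-9 * seq_len(300); x})(),
                        condition = "FW", params = params),
    "No kinematic"
  )
  expect_equal(nrow(empty), 0)
})

test_that("forward-walking inertial rule finds IC at impact transients", {
  rate <- 1000
  t <- seq(0, 12 - 1 / rate, by = 1 / rate)
  impacts <- c(2.0, 3.1, 4.15, 5.3, 6.35, 7.4, 8.5, 9.6)
  acc <- rep(1, length(t))
  for (c0 in impacts) {
    w <- abs(t - c0) <= 0.3
    acc[w] <- acc[w] + 2 * exp(-abs(t[w] - c0) / 0.05) *
      cos(2 * pi * 8 * (t[w] - c0))
  }
  acc_ts <- filter_savgol(timeseries(acc, rate), 51)
  gy_ts <- filter_savgol(timeseries(-sin(2 * pi * t / 1.1), rate), 51)
  ev <- detect_imu_fw(acc_ts, gy_ts, peak_params(min_separation = 0.5))
  ic <- ev$time_s[ev$kind == "IC"]
  expect_length(ic, length(impacts))
  expect_lt(max(abs(ic - impacts)), 0.010)
  # TC at the sine minima of the gyroscope channel
  tc <- ev$time_s[ev$kind == "TC"]
  expected_tc <- 1.1 * (0:10) + 0.275
  expected_tc <- expected_tc[expected_tc < 12]
  expect_equal(tc, expected_tc, tolerance = 0.011)

  expect_warning(
    flat <- detect_imu_fw(timeseries(rep(0, 1000), rate) |>
                            (\(x) {x$value[1] <- 1e-12; x})(),
                          timeseries(rep(0, 1000), rate),
                          peak_params(min_separation = 0.5)),
    "No inertial"
  )
  expect_equal(nrow(flat), 0)
})

test_that("backward-walking run rule matches the hand-worked example", {
  # trace {0, 0, 0, -4}: mean -1, sample SD 2, threshold -3; the single
  # below-threshold sample is its own run and its minimum
  ts <- timeseries(c(0, 0, 0, -4), rate = 10)
  ev <- detect_imu_bw(ts, peak_params(min_separation = 0.05,
                                      min_run = 0, threshold_sd = 1))
  tc <- ev$time_s[ev$kind == "TC"]
  expect_equal(tc, ts$time_s[4])
})

test_that("run rule ignores channels that never cross the threshold", {
  # strictly positive, min above mean - 1 SD
  x <- rep(c(10, 10.1), 50)
  expect_warning(
    ev <- detect_imu_bw(timeseries(x, 100),
                        peak_params(min_separation = 0.01,
                                    min_prominence = 0)),
    "below-threshold"
  )
  expect_equal(sum(ev$kind == "TC"), 0)
  expect_error(detect_imu_bw(timeseries(rep(1, 50), 100)), "variance")
})

test_that("short below-threshold blips are rejected by min_run", {
  x <- rep(0, 400)
  x[100] <- -5            # single-sample excursion
  x[200:230] <- -5        # sustained dip
  ts <- timeseries(x, rate = 1000)
  ev <- detect_imu_bw(ts, peak_params(min_separation = 0.01,
                                      min_prominence = 0, min_run = 0.01))
  tc <- ev$time_s[ev$kind == "TC"]
  expect_length(tc, 1)
  expect_equal(tc, ts$time_s[200])  # first (earliest) minimum of the run
})

test_that("simulated backward trials put one TC dip per stride near truth", {
  sim <- simulate_trial(sim_config("BW", n_strides = 12, seed = 31))
  ev <- detect_events(sim$trial, "imu")
  for (s in c("L", "R")) {
    tc_true <- sort(sim$truth$time_s[sim$truth$kind == "TC" &
                                       sim$truth$side == s])
    tc_det <- sort(ev$time_s[ev$kind == "TC" & ev$side == s])
    expect_length(tc_det, length(tc_true))
    expect_lt(max(abs(tc_det - tc_true)), 0.020)
  }
})

test_that("detected events lie strictly inside the trimmed window", {
  sim <- simulate_trial(sim_config("FW", n_strides = 8, seed = 13))
  for (method in c("omc", "imu")) {
    ev <- detect_events(sim$trial, method)
    expect_true(all(ev$time_s > 1))
    expect_true(all(ev$time_s < sim$trial$duration - 1))
    # count per stream within 1 of the simulated stride count
    counts <- table(ev$kind, ev$side)
    expect_true(all(abs(counts - 8) <= 1))
  }
})

test_that("detection works identically through the file interface", {
  sim <- simulate_trial(sim_config("BW", n_strides = 6, seed = 17))
  mp <- withr::local_tempfile(fileext = ".csv")
  ip <- withr::local_tempfile(fileext = ".csv")
  write_trial(sim$trial, mp, ip)
  cfg <- list(walking_axis = "X", forward_sign = 1, condition = "BW",
              rates = list(marker = 100, imu = 1000))
  trial2 <- read_trial(mp, ip, cfg)
  ev1 <- detect_events(sim$trial, "omc")
  ev2 <- detect_events(trial2, "omc")
  expect_equal(ev1$time_s, ev2$time_s, tolerance = 1e-6)
  expect_identical(ev1$kind, ev2$kind)
})
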