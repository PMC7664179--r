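test_that("timeseries enforces its invariants", {
  expect_error(timeseries(c(1, NA, 2), rate = 10), "finite")
  expect_error(timeseries(1:5, rate = 0), "positive")
  ts <- timeseries(1:5, rate = 10, t0 = 0.5)
  expect_equal(ts$time_s, 0.5 + (0:4) / 10)
  expect_equal(ts_rate(ts), 10)
})

test_that("trim_edges drops exactly the requested edges and nothing else", {
  ts <- timeseries(seq_len(3000), rate = 100)
  tr <- trim_edges(ts)
  expect_equal(nrow(tr), 2800)
  expect_equal(ts_t0(tr), 1.0)
  # retained values are bit-exact
  expect_identical(tr$value, as.numeric(101:2900))
  expect_equal(ts_rate(tr), 100)

  expect_equal(trim_edges(ts, 0, 0)$value, ts$value)
  expect_error(trim_edges(timeseries(1:150, rate = 100)), "trim")
})

test_that("event tables round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")

  empty <- event_series(condition = "BW")
  write_events(empty, path)
  expect_equal(readLines(path), "time_s,kind,side,source")

  ev <- event_series(c(2.2, 1.1), kind = c("TC", "IC"), side = "L",
                     source = "OMC", check = FALSE)
  write_events(ev, path)
  lines <- readLines(path)
  expect_length(lines, 3)
  expect_match(lines[2], "^1.1,")  # sorted by time

  set.seed(11)
  times <- sort(runif(100, 1, 60)) + cumsum(rep(0.2, 100))
  big <- event_series(times, kind = rep(c("IC", "TC"), 50), side = "R",
                      source = "IMU", check = FALSE)
  write_events(big, path)
  back <- read_events(path)
  expect_equal(back$time_s, big$time_s, tolerance = 1e-6)
  expect_identical(back$kind, big$kind)
  expect_identical(back$side, big$side)
  expect_identical(back$source, big$source)
})

make_marker_file <- function(path, delim = ",", rate = 100, n = 20) {
  t <- (seq_len(n) - 1) / rate
  df <- data.frame(time_s = t, x = sin(t), y = cos(t), z = t * 0 + 1)
  names(df) <- c("time_s", "HEEL_L.X", "HEEL_L.Y", "HEEL_L.Z")
  utils::write.table(df, path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  df
}

make_imu_file <- function(path, rate = 1000, n = 200, jitter = 0) {
  t <- (seq_len(n) - 1) / rate
  if (jitter > 0) t[10] <- t[10] + jitter
  df <- data.frame(time_s = t, acc = rnorm(n))
  names(df) <- c("time_s", "H.ACC.Z.L")
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  df
}

test_that("read_trial parses both dialects and validates the grid", {
  cfg <- list(walking_axis = "X", forward_sign = 1, condition = "FW",
              rates = list(marker = 100, imu = 1000))
  mp <- withr::local_tempfile(fileext = ".csv")
  ip <- withr::local_tempfile(fileext = ".csv")

  make_marker_file(mp, delim = "\t")  # tab dialect auto-detected
  make_imu_file(ip)
  trial <- read_trial(mp, ip, cfg)
  expect_s3_class(trial, "gait_trial")
  expect_named(trial$markers,
               c("time_s", "HEEL_L.X", "HEEL_L.Y", "HEEL_L.Z"))
  expect_named(trial$imu, c("time_s", "H.ACC.Z.L"))
  expect_equal(trial$rate_marker, 100)

  # irregular time steps beyond tolerance are rejected
  make_imu_file(ip, jitter = 1e-4)
  expect_error(read_trial(mp, ip, cfg), "irregular")

  # declared rate disagreeing with the file grid is rejected
  make_imu_file(ip)
  cfg_bad <- cfg
  cfg_bad$rates$imu <- 500
  expect_error(read_trial(mp, ip, cfg_bad), "irregular|rate")

  # missing declared channel is an error
  cfg_chan <- cfg
  cfg_chan$channels <- list("HEEL_L.X", "T.ACC.Z.L")
  expect_error(read_trial(mp, ip, cfg_chan), "T.ACC.Z.L")
})

test_that("a simulated trial round-trips through the columnar files", {
  sim <- simulate_trial(sim_config("FW", n_strides = 4, seed = 3))
  mp <- withr::local_tempfile(fileext = ".csv")
  ip <- withr::local_tempfile(fileext = ".csv")
  write_trial(sim$trial, mp, ip)
  cfg <- list(walking_axis = "X", forward_sign = 1, condition = "FW",
              rates = list(marker = 100, imu = 1000))
  back <- read_trial(mp, ip, cfg)
  expect_equal(back$markers$`HEEL_L.X`, sim$trial$markers$`HEEL_L.X`,
               tolerance = 1e-6)
  expect_equal(back$imu$`T.ACC.Z.R`, sim$trial$imu$`T.ACC.Z.R`,
               tolerance = 1e-6)
  expect_equal(back$duration, sim$trial$duration)
})

test_that("trial config YAML round-trips", {
  cfg <- list(walking_axis = "Y", forward_sign = -1, condition = "BW",
              rates = list(marker = 100, imu = 1000),
              units = list(marker = "m", acc = "g", gyro = "deg/s"))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_trial_config(cfg, path)
  back <- read_trial_config(path)
  expect_equal(back$walking_axis, "Y")
  expect_equal(back$forward_sign, -1)
  expect_equal(back$rates$imu, 1000)
})

test_that("event series validation catches disorder and non-alternation", {
  expect_error(
    event_series(c(1, 1), kind = "IC", side = "L", source = "OMC"),
    "strictly increasing"
  )
  expect_warning(
    ev <- event_series(c(1, 1.5, 2), kind = c("IC", "IC", "TC"),
                       side = "L", source = "OMC"),
    "alternation"
  )
  viol <- alternation_violations(ev)
  expect_equal(nrow(viol), 1)
  expect_equal(viol$time_s, 1.5)
})
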