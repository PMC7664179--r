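#' Trial container and columnar interchange formats
#'
#' A `gait_trial` bundles one walking condition's synchronized streams:
#' a marker table (100 Hz by default) with columns `time_s` and
#' `<MARKER>.<X|Y|Z>` in meters, and an inertial table (1000 Hz by default)
#' with columns `<H|T>.<ACC|GY>.<X|Y|Z>.<L|R>` (heel/toe sensor,
#' accelerometer in g / gyroscope in deg/s, axis, side). Both streams are
#' assumed to start on the same trial clock at t = 0 (hardware-trigger
#' synchronization); no cross-correlation alignment is attempted and the
#' two rates are never merged onto one grid -- all between-stream
#' comparisons happen on event times in seconds.
#'
#' @param markers Tibble: `time_s` plus `<MARKER>.<axis>` columns (m).
#' @param imu Tibble: `time_s` plus IMU channel columns.
#' @param condition `"FW"` or `"BW"`.
#' @param walking_axis Lab axis (`"X"`, `"Y"` or `"Z"`) that is
#'   anterior-posterior.
#' @param forward_sign `+1` or `-1`: direction of forward progression along
#'   `walking_axis`.
#' @param rate_marker,rate_imu Sampling rates in Hz.
#' @param metadata Free-form named list (speed, participant id, seed, ...).
#' @return A `gait_trial` object.
#' @export
gait_trial <- function(markers, imu, condition = c("FW", "BW"),
                       walking_axis = "X", forward_sign = 1,
                       rate_marker = 100, rate_imu = 1000,
                       metadata = list()) {
  condition <- match.arg(condition)
  stopifnot(walking_axis %in% c("X", "Y", "Z"), forward_sign %in% c(-1, 1))
  check_stream(markers, rate_marker, "markers")
  check_stream(imu, rate_imu, "imu")
  if (abs(markers$time_s[1] - imu$time_s[1]) > 1e-9) {
    abort("Marker and IMU streams must share trial clock origin t = 0.")
  }
  duration <- nrow(imu) / rate_imu
  structure(
    list(
      markers = as_tibble(markers), imu = as_tibble(imu),
      condition = condition, walking_axis = walking_axis,
      forward_sign = forward_sign, rate_marker = rate_marker,
      rate_imu = rate_imu, duration = duration, metadata = metadata
    ),
    class = "gait_trial"
  )
}

check_stream <- function(df, rate, what) {
  if (!is.data.frame(df) || !"time_s" %in% names(df)) {
    abort(sprintf("`%s` must be a data frame with a `time_s` column.", what))
  }
  if (nrow(df) < 2) abort(sprintf("`%s` needs at least 2 samples.", what))
  steps <- diff(df$time_s)
  if (any(steps <= 0)) {
    abort(sprintf("`%s` time column must be strictly increasing.", what))
  }
  if (any(abs(steps - 1 / rate) > 1e-6)) {
    abort(sprintf(
      "`%s` time steps are irregular or disagree with the declared %g Hz rate.",
      what, rate
    ))
  }
  invisible(df)
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf(
    "<gait_trial> %s, %.2f s; %d markers @ %g Hz, %d IMU channels @ %g Hz\n",
    x$condition, x$duration,
    length(unique(sub("\\.[XYZ]$", "", setdiff(names(x$markers), "time_s")))),
    x$rate_marker, length(setdiff(names(x$imu), "time_s")), x$rate_imu
  ))
  invisible(x)
}

#' Extract one channel of a trial as a `gait_ts`
#'
#' @param trial A `gait_trial`.
#' @param channel Column name, e.g. `"H.ACC.Z.L"` or `"HEEL_L.X"`.
#' @param stream `"imu"` or `"markers"`; guessed from the channel name by
#'   default.
#' @return A `gait_ts`.
#' @export
trial_channel <- function(trial, channel, stream = NULL) {
  stopifnot(inherits(trial, "gait_trial"))
  stream <- stream %||%
    if (channel %in% names(trial$imu)) "imu" else "markers"
  df <- trial[[stream]]
  if (!channel %in% names(df)) {
    abort(sprintf("Channel `%s` not present in the %s stream.", channel, stream))
  }
  rate <- if (stream == "imu") trial$rate_imu else trial$rate_marker
  timeseries(df[[channel]], rate = rate, t0 = df$time_s[1], label = channel)
}

delim_of <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

read_stream_file <- function(path, rate, what) {
  df <- readr::read_delim(
    path, delim = delim_of(path), show_col_types = FALSE, progress = FALSE
  )
  if (names(df)[1] != "time_s") {
    abort(sprintf("First column of `%s` must be `time_s`.", path))
  }
  check_stream(df, rate, what)
  df
}

#' Read a trial from marker and IMU files
#'
#' Files are UTF-8 delimited text (comma or tab, auto-detected) with one
#' header line and a leading `time_s` column; marker columns are
#' `<MARKER>.<X|Y|Z>`, IMU columns `<H|T>.<ACC|GY>.<X|Y|Z>.<L|R>`. Rates,
#' walking axis, forward sign and condition come from the trial config
#' (see [read_trial_config()]); they are declared, never inferred, and a
#' file whose time grid disagrees with its declared rate is an error.
#'
#' @param marker_path,imu_path Paths to the two columnar files.
#' @param config Named list as returned by [read_trial_config()], with
#'   elements `walking_axis`, `forward_sign`, `condition`,
#'   `rates = list(marker, imu)` and optionally `channels` (declared channel
#'   names that must be present).
#' @return A `gait_trial`.
#' @export
read_trial <- function(marker_path, imu_path, config) {
  rates <- config$rates %||% list(marker = 100, imu = 1000)
  markers <- read_stream_file(marker_path, rates$marker, "markers")
  imu <- read_stream_file(imu_path, rates$imu, "imu")
  declared <- config$channels
  if (!is.null(declared)) {
    have <- c(names(markers), names(imu))
    missing <- setdiff(unlist(declared), have)
    if (length(missing) > 0) {
      abort(paste0("Declared channel(s) missing: ",
                   paste(missing, collapse = ", ")))
    }
  }
  gait_trial(
    markers, imu,
    condition = config$condition %||% "FW",
    walking_axis = config$walking_axis %||% "X",
    forward_sign = config$forward_sign %||% 1,
    rate_marker = rates$marker, rate_imu = rates$imu,
    metadata = config$metadata %||% list()
  )
}

#' Write a trial's marker and IMU streams to delimited files
#'
#' @param trial A `gait_trial`.
#' @param marker_path,imu_path Output paths (CSV).
#' @return `trial`, invisibly.
#' @export
write_trial <- function(trial, marker_path, imu_path) {
  stopifnot(inherits(trial, "gait_trial"))
  readr::write_csv(trial$markers, marker_path, progress = FALSE)
  readr::write_csv(trial$imu, imu_path, progress = FALSE)
  invisible(trial)
}

#' Read or write a trial configuration
#'
#' The config is a YAML file declaring `walking_axis`, `forward_sign`,
#' `condition`, `rates:` (`marker`, `imu`) and channel `units`. Units are
#' declarations for the reader's bookkeeping (meters, g, deg/s); nothing is
#' rescaled.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_trial_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$rates)) cfg$rates <- lapply(cfg$rates, as.numeric)
  if (!is.null(cfg$forward_sign)) cfg$forward_sign <- as.numeric(cfg$forward_sign)
  cfg
}

#' @rdname read_trial_config
#' @param config Named list to serialize.
#' @export
write_trial_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(config)
}

#' Write / read gait events as CSV
#'
#' The event table dialect has columns `time_s,kind,side,source`
#' (kind `IC`/`TC`, side `L`/`R`, source `OMC`/`IMU`/`TRUTH`). A
#' write-then-read round trip reproduces event times to better than 1e-6 s
#' and labels exactly.
#'
#' @param events An `event_series`.
#' @param path Output CSV path.
#' @return `events`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_series"))
  out <- as_tibble(events) |> dplyr::arrange(.data$time_s)
  readr::write_csv(out, path, progress = FALSE)
  invisible(events)
}

#' @rdname write_events
#' @param condition Condition label to attach (`"FW"`/`"BW"`).
#' @export
read_events <- function(path, condition = "FW") {
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      time_s = readr::col_double(), kind = readr::col_character(),
      side = readr::col_character(), source = readr::col_character()
    ),
    progress = FALSE
  )
  event_series(df$time_s, df$kind, df$side, df$source,
               condition = condition, check = FALSE)
}
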