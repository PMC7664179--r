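#' Foot displacement relative to the pelvis
#'
#' The kinematic (Zeni-style) detection signal: the anterior-posterior
#' position of a foot marker minus the centroid of the pelvis markers'
#' anterior-posterior positions, multiplied by the trial's forward sign so
#' that positive values always mean "foot ahead of the pelvis in the
#' direction of forward progression", whichever lab axis the treadmill
#' occupies.
#'
#' @param trial A `gait_trial`.
#' @param foot_marker Marker name, e.g. `"HEEL_L"`.
#' @param pelvis_markers Character vector of pelvis marker names
#'   (typically left/right anterior and posterior superior iliac spine);
#'   their centroid stands in for a model-based pelvis segment.
#' @return A `gait_ts` in meters at the marker rate.
#' @export
relative_displacement <- function(trial, foot_marker,
                                  pelvis_markers = c("ASIS_L", "ASIS_R",
                                                     "PSIS_L", "PSIS_R")) {
  stopifnot(inherits(trial, "gait_trial"), length(pelvis_markers) >= 1)
  axis <- trial$walking_axis
  col_of <- function(marker) {
    col <- paste0(marker, ".", axis)
    if (!col %in% names(trial$markers)) {
      abort(sprintf("Marker column `%s` not found.", col))
    }
    trial$markers[[col]]
  }
  foot <- col_of(foot_marker)
  pelvis <- rowMeans(do.call(cbind, lapply(pelvis_markers, col_of)))
  timeseries(
    trial$forward_sign * (foot - pelvis),
    rate = trial$rate_marker, t0 = trial$markers$time_s[1],
    label = paste0("disp.", foot_marker)
  )
}

empty_events <- function(condition) {
  event_series(condition = condition, check = FALSE)
}

detector_events <- function(times, kind, side, source, condition) {
  event_series(times, kind = kind, side = side, source = source,
               condition = condition, check = FALSE)
}

warn_if_empty <- function(times, what) {
  if (length(times) == 0) {
    warn(sprintf("No %s detected on a non-degenerate trace.", what))
  }
  times
}

#' Kinematic gait event detection (foot-pelvis displacement extrema)
#'
#' In forward walking the foot is farthest ahead of the pelvis at heel
#' strike and farthest behind at toe-off, so displacement maxima are
#' initial contacts (IC) and minima terminal contacts (TC). Backward
#' walking mirrors the geometry: the most backward foot position marks IC
#' and the most forward marks TC, i.e. the labels are exactly swapped.
#' Two displacement traces may be supplied so IC can come from the marker
#' on the part of the foot that strikes the ground and TC from the part
#' that leaves it last; passing the same trace twice gives single-marker
#' detection.
#'
#' @param displacement_ic,displacement_tc Preprocessed (low-pass +
#'   Savitzky-Golay) displacement `gait_ts` traces used for IC and TC.
#' @param condition `"FW"` or `"BW"`.
#' @param params [peak_params()].
#' @param side `"L"` or `"R"` label for emitted events.
#' @return An `event_series` with source `"OMC"`. Empty detection on a
#'   non-degenerate trace raises a warning, not an error.
#' @export
detect_omc <- function(displacement_ic, displacement_tc = displacement_ic,
                       condition = c("FW", "BW"), params = peak_params(),
                       side = "L") {
  condition <- match.arg(condition)
  ic_kind <- if (condition == "FW") "maxima" else "minima"
  tc_kind <- if (condition == "FW") "minima" else "maxima"
  degenerate <- sd(displacement_ic$value) == 0 && sd(displacement_tc$value) == 0
  ic <- find_extrema(displacement_ic, params, ic_kind)
  tc <- find_extrema(displacement_tc, params, tc_kind)
  if (!degenerate) {
    warn_if_empty(c(ic, tc), "kinematic events")
  }
  detector_events(
    c(ic, tc), kind = rep(c("IC", "TC"), c(length(ic), length(tc))),
    side = side, source = "OMC", condition = condition
  )
}

#' Inertial gait event detection, forward walking
#'
#' Heel-sensor rule for forward treadmill walking: maxima of the smoothed
#' vertical heel acceleration (impact transients) are initial contacts and
#' minima of the smoothed heel sagittal angular velocity are toe-offs.
#' The source sentence for this rule pairs "maxima and minima" with
#' "heel strikes and toes-off" across the two channels; this
#' implementation reads it distributively -- H.ACC.Z maxima give IC and
#' H.GY.Z minima give TC -- which is the only pairing consistent with
#' impact mechanics (acceleration spikes at contact, peak swing-onset
#' angular velocity at toe-off).
#'
#' @param h_acc_z Preprocessed + Savitzky-Golay-smoothed vertical heel
#'   acceleration (`gait_ts`, g).
#' @param h_gy_z Preprocessed + smoothed heel sagittal angular velocity
#'   (`gait_ts`, deg/s).
#' @inheritParams detect_omc
#' @return An `event_series` with source `"IMU"`, condition `"FW"`.
#' @export
detect_imu_fw <- function(h_acc_z, h_gy_z, params = peak_params(),
                          side = "L") {
  degenerate <- sd(h_acc_z$value) == 0 && sd(h_gy_z$value) == 0
  ic <- find_extrema(h_acc_z, params, "maxima")
  tc <- find_extrema(h_gy_z, params, "minima")
  if (!degenerate) warn_if_empty(c(ic, tc), "inertial FW events")
  detector_events(
    c(ic, tc), kind = rep(c("IC", "TC"), c(length(ic), length(tc))),
    side = side, source = "IMU", condition = "FW"
  )
}

# Maximal runs of TRUE in a logical vector, as (start, end) index pairs.
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Inertial gait event detection, backward walking
#'
#' Toe-sensor rule for backward treadmill walking. Initial contacts are
#' maxima of the vertical toe acceleration (toe-strike transients).
#' Terminal contacts use a run rule: with threshold
#' `theta = mean - threshold_sd * SD` computed over the whole trimmed,
#' filtered record (so the rule is invariant to constant offsets such as
#' gravity), every maximal contiguous run of samples below `theta` lasting
#' at least `min_run` yields exactly one TC -- the first local minimum
#' inside the run, or the run's (earliest) global minimum sample if the
#' run contains no interior local minimum.
#'
#' @param t_acc_z Preprocessed vertical toe acceleration (`gait_ts`, g).
#' @inheritParams detect_omc
#' @return An `event_series` with source `"IMU"`, condition `"BW"`.
#' @export
detect_imu_bw <- function(t_acc_z, params = peak_params(), side = "L") {
  x <- t_acc_z$value
  if (sd(x) == 0) abort("Zero-variance channel: the SD threshold is undefined.")
  ic <- find_extrema(t_acc_z, params, "maxima")
  theta <- mean(x) - params$threshold_sd * sd(x)
  runs <- logical_runs(x < theta)
  rate <- ts_rate(t_acc_z)
  min_len <- params$min_run * rate
  tc <- numeric()
  if (nrow(runs) > 0) {
    for (r in seq_len(nrow(runs))) {
      s <- runs[r, "start"]; e <- runs[r, "end"]
      if ((e - s + 1) < min_len) next
      seg <- x[s:e]
      local_min <- plateau_maxima(-seg)
      i <- if (length(local_min)) local_min[1] else which.min(seg)[1]
      tc <- c(tc, t_acc_z$time_s[s + i - 1L])
    }
  }
  if (length(tc) == 0) {
    warn("No below-threshold runs: zero TC events detected.")
  }
  detector_events(
    c(ic, tc), kind = rep(c("IC", "TC"), c(length(ic), length(tc))),
    side = side, source = "IMU", condition = "BW"
  )
}

#' Full detection pipeline on a trial
#'
#' Applies the standard preprocessing chain, trims the record edges, and
#' runs the requested detector for each side, returning one combined
#' event series. The chain is: kinematic displacement and accelerometer
#' channels through a first-order 10 Hz low-pass Butterworth; gyroscope
#' channels through a first-order 0.001--5 Hz band-pass; displacement and
#' the forward-walking heel channels additionally Savitzky-Golay smoothed
#' (order 3, 51-sample window); then 1 s trimmed from each end.
#'
#' For kinematic detection, initial contact uses the marker on the foot
#' region that strikes the ground first and terminal contact the region
#' that leaves last: heel-marker IC / toe-marker TC in forward walking,
#' reversed in backward walking. Set both templates to the same marker for
#' single-marker detection.
#'
#' @param trial A `gait_trial`.
#' @param method `"omc"` (marker kinematics) or `"imu"` (inertial).
#' @param sides Sides to process.
#' @param params [peak_params()]; by default separation is derived per
#'   channel from its dominant period.
#' @param zero_phase Zero-phase (forward-backward) Butterworth filtering;
#'   set `FALSE` for causal filtering sensitivity checks.
#' @param savgol_window Savitzky-Golay window length, samples.
#' @param heel_template,toe_template `sprintf` templates for foot marker
#'   names (`%s` = side letter).
#' @param pelvis_markers Pelvis marker names for the centroid reference.
#' @param trim_s Seconds trimmed from each record edge.
#' @return An `event_series` (source `"OMC"` or `"IMU"`).
#' @examples
#' sim <- simulate_trial(sim_config("FW", n_strides = 8, seed = 1))
#' ev <- detect_events(sim$trial, method = "omc")
#' @export
detect_events <- function(trial, method = c("omc", "imu"),
                          sides = c("L", "R"), params = peak_params(),
                          zero_phase = TRUE, savgol_window = 51,
                          heel_template = "HEEL_%s",
                          toe_template = "TOE_%s",
                          pelvis_markers = c("ASIS_L", "ASIS_R",
                                             "PSIS_L", "PSIS_R"),
                          trim_s = 1) {
  stopifnot(inherits(trial, "gait_trial"))
  method <- match.arg(method)
  condition <- trial$condition
  lowpass <- function(ts) {
    filter_butterworth(ts, 10, "low", order = 1, zero_phase = zero_phase)
  }
  bandpass <- function(ts) {
    filter_butterworth(ts, c(0.001, 5), "pass", order = 1,
                       zero_phase = zero_phase)
  }
  smooth <- function(ts) filter_savgol(ts, window = savgol_window)
  prep <- function(ts, chain) trim_edges(chain(ts), trim_s, trim_s)

  per_side <- lapply(sides, function(side) {
    if (method == "omc") {
      heel <- relative_displacement(trial, sprintf(heel_template, side),
                                    pelvis_markers)
      toe <- relative_displacement(trial, sprintf(toe_template, side),
                                   pelvis_markers)
      disp <- lapply(list(heel = heel, toe = toe), prep,
                     chain = function(ts) smooth(lowpass(ts)))
      strike_first <- if (condition == "FW") disp$heel else disp$toe
      leave_last <- if (condition == "FW") disp$toe else disp$heel
      detect_omc(strike_first, leave_last, condition = condition,
                 params = params, side = side)
    } else if (condition == "FW") {
      acc <- prep(trial_channel(trial, paste0("H.ACC.Z.", side)),
                  function(ts) smooth(lowpass(ts)))
      gy <- prep(trial_channel(trial, paste0("H.GY.Z.", side)),
                 function(ts) smooth(bandpass(ts)))
      detect_imu_fw(acc, gy, params = params, side = side)
    } else {
      acc <- prep(trial_channel(trial, paste0("T.ACC.Z.", side)), lowpass)
      detect_imu_bw(acc, params = params, side = side)
    }
  })
  combined <- dplyr::bind_rows(lapply(per_side, as_tibble))
  event_series(combined$time_s, combined$kind, combined$side,
               combined$source, condition = condition, check = FALSE)
}
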