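#' Construct a uniformly sampled channel
#'
#' A `gait_ts` is a tibble with columns `time_s` and `value` plus a stored
#' sampling rate and channel label. Sample `k` (1-based) has time
#' `t0 + (k - 1) / rate`; each sample owns the half-open interval
#' `[t, t + 1/rate)` and event times are the timestamp of the identified
#' sample.
#'
#' @param value Numeric vector of samples. Must be finite.
#' @param rate Sampling frequency in Hz (> 0).
#' @param t0 Time of the first sample in seconds on the shared trial clock.
#' @param label Channel identifier string.
#' @return A `gait_ts` tibble with columns `time_s`, `value`.
#' @examples
#' ts <- timeseries(sin(2 * pi * seq(0, 1, by = 0.01)), rate = 100)
#' ts_rate(ts)
#' @export
timeseries <- function(value, rate, t0 = 0, label = "channel") {
  if (!is.numeric(value) || length(value) == 0) {
    abort("`value` must be a non-empty numeric vector.")
  }
  if (!all(is.finite(value))) abort("All samples must be finite.")
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    abort("`rate` must be a single positive number (Hz).")
  }
  out <- tibble(
    time_s = t0 + (seq_along(value) - 1) / rate,
    value = as.numeric(value)
  )
  attr(out, "rate") <- as.numeric(rate)
  attr(out, "label") <- as.character(label)
  class(out) <- c("gait_ts", class(out))
  out
}

#' @rdname timeseries
#' @param ts A `gait_ts` object.
#' @export
ts_rate <- function(ts) attr(ts, "rate")

#' @rdname timeseries
#' @export
ts_t0 <- function(ts) ts$time_s[[1]]

#' @rdname timeseries
#' @export
ts_label <- function(ts) attr(ts, "label")

# Rebuild a gait_ts from an existing one with new samples/start time,
# preserving rate and label unless overridden.
ts_update <- function(ts, value = ts$value, t0 = ts_t0(ts),
                      rate = ts_rate(ts), label = ts_label(ts)) {
  timeseries(value, rate = rate, t0 = t0, label = label)
}

assert_gait_ts <- function(ts, arg = "ts") {
  if (!inherits(ts, "gait_ts")) {
    abort(sprintf("`%s` must be a `gait_ts` (see `timeseries()`).", arg))
  }
  invisible(ts)
}

#' Trim the first and last seconds of a channel
#'
#' Removes edge data (by default the first and last second of the record,
#' mirroring the treadmill-trial convention of discarding 0--1 s and 29--30 s
#' of a 30 s trial) before event detection, so filter edge transients and
#' gait initiation/termination never reach the detectors. Sample values in
#' the retained window are untouched; only the start time and length change.
#'
#' @param ts A `gait_ts` channel.
#' @param head_s Seconds to drop from the start.
#' @param tail_s Seconds to drop from the end.
#' @return The trimmed `gait_ts`.
#' @examples
#' ts <- timeseries(rnorm(3000), rate = 100)
#' trimmed <- trim_edges(ts)
#' nrow(trimmed)  # 2800
#' @export
trim_edges <- function(ts, head_s = 1, tail_s = 1) {
  assert_gait_ts(ts)
  if (head_s < 0 || tail_s < 0) abort("Trim lengths must be non-negative.")
  rate <- ts_rate(ts)
  duration <- nrow(ts) / rate
  if (head_s + tail_s >= duration) {
    abort(sprintf(
      "Cannot trim %.3f + %.3f s from a %.3f s record.",
      head_s, tail_s, duration
    ))
  }
  n_head <- as.integer(round(head_s * rate))
  n_tail <- as.integer(round(tail_s * rate))
  keep <- seq.int(n_head + 1L, nrow(ts) - n_tail)
  ts_update(ts, value = ts$value[keep], t0 = ts$time_s[keep[1]])
}

#' @export
print.gait_ts <- function(x, ...) {
  cat(sprintf(
    "<gait_ts> %s: %d samples @ %g Hz, t0 = %.4f s\n",
    ts_label(x), nrow(x), ts_rate(x), ts_t0(x)
  ))
  NextMethod()
}
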