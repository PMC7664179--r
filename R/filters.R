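#' Filter specification
#'
#' Declarative description of one preprocessing filter, expressible in a
#' trial config file. Three kinds are supported, mirroring the standard
#' treadmill-gait preprocessing chain: a low-pass Butterworth (kinematic
#' and accelerometer channels, default first order / 10 Hz), a band-pass
#' Butterworth (gyroscope channels, default first order / 0.001--5 Hz) and
#' a Savitzky-Golay polynomial smoother (default order 3, 51-sample
#' window).
#'
#' @param kind `"lowpass"`, `"bandpass"` or `"savgol"`.
#' @param order Filter order (Butterworth) or polynomial order
#'   (Savitzky-Golay).
#' @param cutoffs One or two cutoff frequencies in Hz (Butterworth only).
#' @param window Window length in samples (Savitzky-Golay only; odd,
#'   greater than `order`).
#' @param zero_phase Apply Butterworth filters forward-backward
#'   (zero phase). See [filter_butterworth()] for the trade-off.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(kind = c("lowpass", "bandpass", "savgol"),
                        order = if (kind == "savgol") 3L else 1L,
                        cutoffs = NULL, window = 51L, zero_phase = TRUE) {
  kind <- match.arg(kind)
  if (kind == "lowpass") cutoffs <- cutoffs %||% 10
  if (kind == "bandpass") cutoffs <- cutoffs %||% c(0.001, 5)
  if (kind %in% c("lowpass", "bandpass")) {
    n_want <- if (kind == "lowpass") 1L else 2L
    if (length(cutoffs) != n_want || any(cutoffs <= 0)) {
      abort(sprintf("`%s` needs %d positive cutoff(s).", kind, n_want))
    }
  } else {
    window <- as.integer(window)
    if (window %% 2L == 0L || window <= order) {
      abort("Savitzky-Golay window must be odd and greater than the polynomial order.")
    }
  }
  structure(
    list(kind = kind, order = as.integer(order), cutoffs = cutoffs,
         window = window, zero_phase = isTRUE(zero_phase)),
    class = "filter_spec"
  )
}

#' Apply a `filter_spec` to a channel
#'
#' @param ts A `gait_ts`.
#' @param spec A [filter_spec()].
#' @return Filtered `gait_ts` (same rate, start time and length).
#' @export
apply_filter <- function(ts, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  switch(spec$kind,
    lowpass = filter_butterworth(ts, spec$cutoffs, type = "low",
                                 order = spec$order,
                                 zero_phase = spec$zero_phase),
    bandpass = filter_butterworth(ts, spec$cutoffs, type = "pass",
                                  order = spec$order,
                                  zero_phase = spec$zero_phase),
    savgol = filter_savgol(ts, window = spec$window, polyorder = spec$order)
  )
}

# Steady-state-initialized IIR pass (the lfilter_zi idea): the filter is
# started in the state it would occupy after an infinitely long constant
# input equal to the first sample, so constant signals produce their exact
# steady-state output from sample one and edge transients are minimized.
# Implemented with stats::filter (C speed): MA part by one-sided
# convolution over a front-padded signal, AR part recursively with the
# steady-state output as initial values.
iir_pass <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  ord <- max(length(b), length(a)) - 1L
  x_pad <- c(rep(x[1], ord), x)
  v <- stats::filter(x_pad, b, method = "convolution", sides = 1)
  v <- v[!is.na(v)]
  dc <- sum(b) / sum(a)
  if (length(a) > 1) {
    y <- stats::filter(v, -a[-1], method = "recursive",
                       init = rep(x[1] * dc, length(a) - 1L))
  } else {
    y <- v
  }
  as.numeric(tail(y, length(x)))
}

#' Butterworth filtering of a channel
#'
#' Low-pass (unit DC gain) or band-pass (zero DC gain) Butterworth filter.
#' By default the filter is applied forward and backward (zero phase):
#' causal filtering would delay one detection method's events by the
#' filter's group delay and so bias every between-method agreement
#' statistic, whereas the forward-backward pass leaves symmetric features
#' in place. Note the double pass squares the magnitude response, so the
#' classic -3 dB point at the cutoff applies to `zero_phase = FALSE` only.
#' Each pass is initialized at the filter's steady state for the first
#' sample value, so a constant input yields its steady-state output
#' everywhere (in particular the band-pass maps constants to ~0 with no
#' multi-second start-up transient despite its very low 0.001 Hz edge).
#'
#' @param ts A `gait_ts`.
#' @param cutoffs Cutoff frequency in Hz (low-pass) or `c(low, high)`
#'   (band-pass). Must be strictly below the Nyquist frequency.
#' @param type `"low"` or `"pass"`.
#' @param order Butterworth order (per edge), default 1.
#' @param zero_phase Forward-backward application (default `TRUE`).
#' @return Filtered `gait_ts` with identical rate, `t0` and length.
#' @examples
#' ts <- timeseries(sin(2 * pi * 2 * seq(0, 5, by = 1e-3)), rate = 1000)
#' lp <- filter_butterworth(ts, 10, type = "low")
#' @export
filter_butterworth <- function(ts, cutoffs, type = c("low", "pass"),
                               order = 1, zero_phase = TRUE) {
  assert_gait_ts(ts)
  type <- match.arg(type)
  nyq <- ts_rate(ts) / 2
  if (any(cutoffs >= nyq)) {
    abort(sprintf("Cutoff(s) must be below the Nyquist frequency (%g Hz).", nyq))
  }
  if (any(cutoffs <= 0)) abort("Cutoff(s) must be positive.")
  ba <- signal::butter(order, sort(cutoffs) / nyq, type = type)
  y <- iir_pass(ba$b, ba$a, ts$value)
  if (zero_phase) y <- rev(iir_pass(ba$b, ba$a, rev(y)))
  if (!all(is.finite(y))) abort("Filter produced non-finite output.")
  ts_update(ts, value = y)
}

#' Savitzky-Golay smoothing of a channel
#'
#' Local least-squares polynomial smoother. Polynomials up to the chosen
#' order pass through unchanged (order 3 reproduces any cubic exactly),
#' which is why this smoother preserves peak locations and amplitudes far
#' better than a moving average at equal noise suppression.
#'
#' @param ts A `gait_ts`.
#' @param window Odd window length in samples, greater than `polyorder` and
#'   at most the record length.
#' @param polyorder Polynomial order (default 3).
#' @return Smoothed `gait_ts` with identical rate, `t0` and length.
#' @export
filter_savgol <- function(ts, window = 51, polyorder = 3) {
  assert_gait_ts(ts)
  window <- as.integer(window)
  if (window %% 2L == 0L) abort("`window` must be odd.")
  if (window <= polyorder) abort("`window` must exceed `polyorder`.")
  if (window > nrow(ts)) abort("`window` longer than the record.")
  y <- signal::sgolayfilt(ts$value, p = polyorder, n = window)
  ts_update(ts, value = as.numeric(y))
}
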