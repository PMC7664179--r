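#' Peak-picking parameters
#'
#' Gating parameters shared by all event detectors. Separation and
#' prominence suppress noise-induced extrema without merging genuine
#' strides; the threshold multiplier and minimum run length parameterize
#' the below-threshold run rule used for backward-walking terminal
#' contacts (see [detect_imu_bw()]).
#'
#' @param min_separation Minimum time between retained extrema, seconds.
#'   `NULL` lets detectors derive it as half the dominant stride period of
#'   the driving channel (autocorrelation estimate, see
#'   [dominant_period()]).
#' @param min_prominence Required topographic prominence as a fraction of
#'   the channel's robust amplitude (95th minus 5th percentile); in
#'   `[0, 1)`.
#' @param threshold_sd Multiplier k in the run-rule threshold
#'   `mean - k * SD` (default 1).
#' @param min_run Minimum duration of a below-threshold run, seconds
#'   (default 0.010 s, i.e. 10 samples at 1000 Hz, rejecting single-sample
#'   noise excursions).
#' @return A `peak_params` list.
#' @export
peak_params <- function(min_separation = NULL, min_prominence = 0.1,
                        threshold_sd = 1, min_run = 0.010) {
  if (!is.null(min_separation) && min_separation <= 0) {
    abort("`min_separation` must be positive.")
  }
  if (min_prominence < 0 || min_prominence >= 1) {
    abort("`min_prominence` must be in [0, 1).")
  }
  if (min_run < 0) abort("`min_run` must be non-negative.")
  structure(
    list(min_separation = min_separation, min_prominence = min_prominence,
         threshold_sd = threshold_sd, min_run = min_run),
    class = "peak_params"
  )
}

#' Dominant period of a quasi-periodic channel
#'
#' Autocorrelation estimate of the stride period: the earliest local
#' autocorrelation maximum within `[min_lag_s, max_lag_s]` that reaches at
#' least half the in-range global maximum (taking the earliest qualifying
#' lag avoids locking onto the two-stride harmonic, which under stride-time
#' jitter can narrowly exceed the one-stride peak). Used to derive
#' the default extrema separation (half a stride) so one gating default
#' works from the slowest backward to the fastest forward treadmill speed.
#'
#' @param ts A `gait_ts`.
#' @param min_lag_s,max_lag_s Search range in seconds.
#' @return Period in seconds, or `NA` if the channel is too short or
#'   aperiodic (non-positive peak autocorrelation).
#' @export
dominant_period <- function(ts, min_lag_s = 0.3, max_lag_s = 3) {
  assert_gait_ts(ts)
  rate <- ts_rate(ts)
  max_lag <- min(floor(max_lag_s * rate), nrow(ts) - 1L)
  min_lag <- ceiling(min_lag_s * rate)
  if (max_lag <= min_lag || sd(ts$value) == 0) return(NA_real_)
  a <- acf(ts$value, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  lags <- seq_along(a) - 1L
  in_range <- lags >= min_lag
  if (!any(in_range) || max(a[in_range]) <= 0) return(NA_real_)
  is_local_max <- c(FALSE, diff(sign(diff(a))) == -2, FALSE) & in_range
  if (!any(is_local_max)) {
    return(lags[in_range][which.max(a[in_range])] / rate)
  }
  cand <- which(is_local_max & a >= 0.5 * max(a[in_range]))
  if (!length(cand)) cand <- which(is_local_max)[which.max(a[is_local_max])]
  best <- cand[1]
  # octave correction: under stride-time jitter the two-stride lag can
  # edge out the one-stride lag; if a credible local max sits near half
  # the chosen lag, descend to it
  repeat {
    half <- which(is_local_max &
                    abs(lags - (best - 1) / 2) <= 0.15 * (best - 1) &
                    a >= 0.3 * a[best])
    if (!length(half)) break
    best <- half[which.max(a[half])]
  }
  lags[best] / rate
}

# Candidate local extrema of x (maxima), plateau-aware: equal-value runs
# are collapsed and a plateau peak is reported at its earliest sample.
plateau_maxima <- function(x) {
  r <- rle(x)
  k <- length(r$values)
  if (k < 3) return(integer())
  starts <- cumsum(c(1L, r$lengths[-k]))
  v <- r$values
  mid <- 2:(k - 1)
  pk <- mid[v[mid] > v[mid - 1] & v[mid] > v[mid + 1]]
  starts[pk]
}

# Topographic prominence of peaks at indices `idx` (heights x[idx]):
# on each side, walk to the nearest strictly higher sample (or the record
# end) and take the minimum in between; prominence is peak height minus
# the higher of the two side minima.
peak_prominence <- function(x, idx) {
  n <- length(x)
  vapply(idx, function(i) {
    h <- x[i]
    left_higher <- which(x[seq_len(i - 1)] > h)
    lo <- if (length(left_higher)) max(left_higher) + 1L else 1L
    left_min <- min(x[lo:i])
    right_higher <- which(x[(i + 1):n] > h)
    hi <- if (length(right_higher)) i + min(right_higher) - 1L else n
    right_min <- min(x[i:hi])
    h - max(left_min, right_min)
  }, numeric(1))
}

#' Find gated local extrema of a channel
#'
#' The shared peak engine behind every detector. Local extrema (plateaus
#' resolved to their earliest sample) are gated by topographic prominence
#' relative to the channel's robust amplitude, then thinned greedily by
#' descending prominence-gated height so that retained extrema are at
#' least `min_separation` apart; of two conflicting extrema the
#' taller wins, with ties broken toward the earlier sample.
#'
#' @param ts A `gait_ts` with at least 3 samples.
#' @param params A [peak_params()]; `min_separation = NULL` falls back to
#'   half the dominant period (or 0.25 s if the channel is aperiodic).
#' @param which `"maxima"` or `"minima"`.
#' @return Numeric vector of extremum times in seconds (possibly empty),
#'   sorted increasing.
#' @examples
#' t <- seq(0, 6, by = 0.01)
#' ts <- timeseries(sin(2 * pi * t / 1.2), rate = 100)
#' find_extrema(ts, peak_params(min_separation = 0.5), "maxima")
#' @export
find_extrema <- function(ts, params = peak_params(),
                         which = c("maxima", "minima")) {
  assert_gait_ts(ts)
  which <- match.arg(which)
  if (nrow(ts) < 3) abort("Need at least 3 samples.")
  x <- if (which == "maxima") ts$value else -ts$value
  idx <- plateau_maxima(x)
  if (length(idx) == 0) return(numeric())
  prom <- peak_prominence(x, idx)
  robust_amp <- diff(quantile(ts$value, c(0.05, 0.95), names = FALSE))
  keep <- prom >= params$min_prominence * robust_amp
  idx <- idx[keep]
  if (length(idx) == 0) return(numeric())
  min_sep <- params$min_separation %||% {
    period <- dominant_period(ts)
    if (is.na(period)) 0.25 else 0.5 * period
  }
  ord <- order(-x[idx], idx)
  accepted <- integer()
  rate <- ts_rate(ts)
  for (i in idx[ord]) {
    if (!length(accepted) ||
        all(abs(i - accepted) / rate >= min_sep)) {
      accepted <- c(accepted, i)
    }
  }
  sort(ts$time_s[accepted])
}
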