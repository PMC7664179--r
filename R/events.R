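#' Build an event series
#'
#' An `event_series` is a tibble of timestamped gait events with columns
#' `time_s`, `kind` (`IC` = initial contact, `TC` = terminal contact),
#' `side` (`L`/`R`) and `source` (`OMC`, `IMU` or `TRUTH`), sorted by time.
#' Within each (kind, side, source) stream times must be strictly
#' increasing; within a (side, source) stream IC and TC are expected to
#' alternate. Alternation violations are reported with a warning, never
#' silently repaired, since a missed or doubled detection is itself a
#' finding in method comparison.
#'
#' @param time_s Event times in seconds on the trial clock.
#' @param kind `"IC"` or `"TC"` (recycled).
#' @param side `"L"` or `"R"` (recycled).
#' @param source `"OMC"`, `"IMU"` or `"TRUTH"` (recycled).
#' @param condition `"FW"` (forward) or `"BW"` (backward walking).
#' @param check Check the alternation invariant and warn on violations.
#' @return An `event_series` tibble sorted by `time_s`.
#' @examples
#' event_series(c(1.0, 1.6, 2.2), kind = c("IC", "TC", "IC"),
#'              side = "L", source = "TRUTH", condition = "FW")
#' @export
event_series <- function(time_s = numeric(), kind = character(),
                         side = character(), source = character(),
                         condition = c("FW", "BW"), check = TRUE) {
  condition <- match.arg(condition)
  n <- length(time_s)
  ev <- tibble(
    time_s = as.numeric(time_s),
    kind = rep_len(as.character(kind), n),
    side = rep_len(as.character(side), n),
    source = rep_len(as.character(source), n)
  )
  if (n > 0) {
    stopifnot(all(ev$kind %in% c("IC", "TC")),
              all(ev$side %in% c("L", "R")),
              all(ev$source %in% c("OMC", "IMU", "TRUTH")))
    ev <- dplyr::arrange(ev, .data$time_s, .data$kind, .data$side)
    bad <- ev |>
      dplyr::group_by(.data$kind, .data$side, .data$source) |>
      dplyr::filter(dplyr::n() > 1, c(FALSE, diff(.data$time_s) <= 0)) |>
      dplyr::ungroup()
    if (nrow(bad) > 0) {
      abort("Event times must be strictly increasing within each (kind, side, source) stream.")
    }
  }
  attr(ev, "condition") <- condition
  class(ev) <- c("event_series", class(ev))
  if (check && n > 0) {
    viol <- alternation_violations(ev)
    if (nrow(viol) > 0) {
      warn(sprintf(
        "IC/TC alternation violated %d time(s); see `alternation_violations()`.",
        nrow(viol)
      ))
    }
  }
  ev
}

#' @rdname event_series
#' @param events An `event_series`.
#' @export
event_condition <- function(events) attr(events, "condition") %||% "FW"

#' Report IC/TC alternation violations
#'
#' Within each (side, source) stream of a valid gait event sequence, initial
#' and terminal contacts alternate. Returns one row per consecutive
#' same-kind event pair (the second event of the offending pair).
#'
#' @param events An `event_series`.
#' @return Tibble with columns `side`, `source`, `time_s`, `kind`.
#' @export
alternation_violations <- function(events) {
  events |>
    as_tibble() |>
    dplyr::group_by(.data$side, .data$source) |>
    dplyr::arrange(.data$time_s, .by_group = TRUE) |>
    dplyr::filter(c(FALSE, .data$kind[-1] == .data$kind[-dplyr::n()])) |>
    dplyr::ungroup() |>
    dplyr::select("side", "source", "time_s", "kind")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf(
    "<event_series> condition %s: %d events\n",
    event_condition(x), nrow(x)
  ))
  NextMethod()
}

#' Stride times from consecutive same-kind events
#'
#' Stride time is the interval between two consecutive gait events of the
#' same kind, same side and same source (e.g. successive left initial
#' contacts).
#'
#' @param events An `event_series` (or plain tibble with the same columns).
#' @param kind `"IC"` or `"TC"`.
#' @param side `"L"`, `"R"`, or `NULL` to keep all sides (computed per side).
#' @return Tibble with columns `side`, `source`, `t_start` (time of the
#'   first event of the pair) and `stride_s`. Streams with fewer than two
#'   events contribute no rows.
#' @examples
#' ev <- event_series(c(1.0, 2.2, 3.4), kind = "IC", side = "L",
#'                    source = "OMC", check = FALSE)
#' stride_times(ev, kind = "IC", side = "L")$stride_s  # 1.2 1.2
#' @export
stride_times <- function(events, kind = c("IC", "TC"), side = NULL) {
  kind <- match.arg(kind)
  ev <- as_tibble(events) |> dplyr::filter(.data$kind == !!kind)
  if (!is.null(side)) ev <- dplyr::filter(ev, .data$side == !!side)
  ev |>
    dplyr::group_by(.data$side, .data$source) |>
    dplyr::arrange(.data$time_s, .by_group = TRUE) |>
    dplyr::reframe(
      t_start = head(.data$time_s, -1),
      stride_s = diff(.data$time_s)
    )
}
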