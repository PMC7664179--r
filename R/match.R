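#' Pair two methods' events one-to-one
#'
#' Greedy nearest-neighbor matching of a test method's events (e.g. IMU)
#' against a reference method's (e.g. marker kinematics), restricted to
#' one event kind and side. Candidate pairs within the time tolerance are
#' accepted in order of increasing |time difference| (ties going to the
#' earlier test event), each event used at most once, and a pair is
#' rejected if it would cross an already-accepted pair, so the pairing is
#' order-preserving. Events left without a partner are counted rather
#' than dropped silently: an unmatched test event is a redundant
#' detection, an unmatched reference event an omission.
#'
#' The signed difference convention is `diff = t_test - t_ref` (positive =
#' test method late).
#'
#' @param ref,test `event_series` objects (or tibbles with the same
#'   columns).
#' @param kind `"IC"` or `"TC"`.
#' @param side `"L"`, `"R"`, or `NULL` to use all events of the kind.
#' @param tolerance_s Maximum |difference| for a valid pair, seconds.
#'   The default 0.1 s sits above the widest between-method limits of
#'   agreement reported for treadmill gait, so genuine pairs at realistic
#'   error scales are never dropped.
#' @return A `matched_pairs` tibble with columns `t_ref`, `t_test`,
#'   `diff_s`, sorted by `t_ref`, carrying attributes
#'   `n_unmatched_ref`, `n_unmatched_test`, `kind`, `tolerance_s`.
#' @examples
#' ref <- event_series(c(1, 2), kind = "IC", side = "L", source = "OMC",
#'                     check = FALSE)
#' test <- event_series(c(1.01, 1.5, 2.02), kind = "IC", side = "L",
#'                      source = "IMU", check = FALSE)
#' mp <- match_events(ref, test, kind = "IC", side = "L")
#' attr(mp, "n_unmatched_test")  # 1 redundant event
#' @export
match_events <- function(ref, test, kind = c("IC", "TC"), side = NULL,
                         tolerance_s = 0.1) {
  kind <- match.arg(kind)
  if (tolerance_s <= 0) abort("`tolerance_s` must be positive.")
  pick <- function(ev) {
    ev <- as_tibble(ev) |> dplyr::filter(.data$kind == !!kind)
    if (!is.null(side)) ev <- dplyr::filter(ev, .data$side == !!side)
    sort(ev$time_s)
  }
  tr <- pick(ref)
  tt <- pick(test)
  used_r <- rep(FALSE, length(tr))
  used_t <- rep(FALSE, length(tt))
  pairs_i <- integer()
  pairs_j <- integer()
  if (length(tr) > 0 && length(tt) > 0) {
    cand <- expand.grid(i = seq_along(tr), j = seq_along(tt))
    cand$d <- abs(tt[cand$j] - tr[cand$i])
    cand <- cand[cand$d <= tolerance_s, , drop = FALSE]
    cand <- cand[order(cand$d, tt[cand$j], tr[cand$i]), , drop = FALSE]
    for (row in seq_len(nrow(cand))) {
      i <- cand$i[row]; j <- cand$j[row]
      if (used_r[i] || used_t[j]) next
      crosses <- any((i - pairs_i) * (j - pairs_j) < 0)
      if (crosses) next
      used_r[i] <- TRUE
      used_t[j] <- TRUE
      pairs_i <- c(pairs_i, i)
      pairs_j <- c(pairs_j, j)
    }
  }
  ord <- order(pairs_i)
  out <- tibble(
    side = rep(side %||% NA_character_, length(pairs_i)),
    t_ref = tr[pairs_i[ord]],
    t_test = tt[pairs_j[ord]],
    diff_s = tt[pairs_j[ord]] - tr[pairs_i[ord]]
  )
  attr(out, "n_unmatched_ref") <- sum(!used_r)
  attr(out, "n_unmatched_test") <- sum(!used_t)
  attr(out, "kind") <- kind
  attr(out, "tolerance_s") <- tolerance_s
  class(out) <- c("matched_pairs", class(out))
  out
}

#' @rdname match_events
#' @param pairs A `matched_pairs` object.
#' @export
unmatched_counts <- function(pairs) {
  c(ref = attr(pairs, "n_unmatched_ref") %||% 0L,
    test = attr(pairs, "n_unmatched_test") %||% 0L)
}

# Concatenate matched_pairs objects (e.g. across sides), summing
# unmatched counts.
bind_pairs <- function(...) {
  pieces <- list(...)
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  out <- dplyr::bind_rows(lapply(pieces, as_tibble))
  attr(out, "n_unmatched_ref") <-
    sum(vapply(pieces, function(p) attr(p, "n_unmatched_ref") %||% 0L,
               numeric(1)))
  attr(out, "n_unmatched_test") <-
    sum(vapply(pieces, function(p) attr(p, "n_unmatched_test") %||% 0L,
               numeric(1)))
  attr(out, "kind") <- attr(pieces[[1]], "kind")
  attr(out, "tolerance_s") <- attr(pieces[[1]], "tolerance_s")
  class(out) <- c("matched_pairs", class(out))
  out
}
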