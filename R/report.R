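#' Full between-method agreement report
#'
#' Composes the agreement pipeline for one trial (or pooled battery of
#' trials): per event kind and side, events are paired with
#' [match_events()]; the pairs feed the mean absolute difference,
#' Bland-Altman bias and 95% limits of agreement; stride times derived
#' from consecutive matched events of each method feed the
#' absolute-agreement ICC, which is then classified into agreement
#' bands. Unmatched events (redundant detections / omissions) are
#' carried through as identification-error counts.
#'
#' Sides are matched separately (pairing never spans sides); set
#' `pool_sides = FALSE` to report each side on its own row instead of
#' pooling pairs across sides, since whether left and right strides
#' should be pooled is a study-design choice.
#'
#' @param ref,test `event_series` objects from the same trial clock
#'   (reference first, conventionally the kinematic method).
#' @param condition Condition label; defaults to the reference series'.
#' @param tolerance_s Matching tolerance, seconds (see [match_events()]).
#' @param pool_sides Pool pairs across sides (default `TRUE`).
#' @param icc_type `"agreement"` or `"consistency"` (see
#'   [icc_agreement()]).
#' @return An `agreement_report`: list with `table` (one row per kind
#'   [and side]: n pairs, MAD +/- SD, bias, limits of agreement, ICC with
#'   CI and class, unmatched counts), `pairs` (named list of
#'   `matched_pairs`), `condition`, `tolerance_s`.
#' @examples
#' sim <- simulate_trial(sim_config("FW", n_strides = 15, seed = 2))
#' rep <- agreement_report(detect_events(sim$trial, "omc"),
#'                         detect_events(sim$trial, "imu"))
#' tidy(rep)
#' @export
agreement_report <- function(ref, test, condition = NULL,
                             tolerance_s = 0.1, pool_sides = TRUE,
                             icc_type = "agreement") {
  condition <- condition %||% event_condition(ref)
  sides <- sort(unique(c(ref$side, test$side)))
  rows <- list()
  pairs_out <- list()
  for (kind in c("IC", "TC")) {
    by_side <- lapply(sides, function(s) {
      match_events(ref, test, kind = kind, side = s,
                   tolerance_s = tolerance_s)
    })
    groups <- if (pool_sides) {
      list(pooled = do.call(bind_pairs, by_side))
    } else {
      stats::setNames(by_side, sides)
    }
    for (g in names(groups)) {
      pairs <- groups[[g]]
      pairs_out[[paste(kind, g, sep = ".")]] <- pairs
      if (nrow(pairs) < 3) {
        warn(sprintf("Fewer than 3 %s pairs (%s); statistics skipped.",
                     kind, g))
        next
      }
      strides <- pairs |>
        as_tibble() |>
        dplyr::group_by(.data$side) |>
        dplyr::reframe(ref_s = diff(.data$t_ref),
                       test_s = diff(.data$t_test))
      mad <- mean_abs_difference(pairs)
      ba <- bland_altman(pairs)
      icc <- if (nrow(strides) >= 3) {
        icc_agreement(strides$ref_s, strides$test_s, type = icc_type)
      } else {
        warn(sprintf("Fewer than 3 %s strides (%s); ICC not computed.",
                     kind, g))
        tibble(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
               n = nrow(strides))
      }
      un <- unmatched_counts(pairs)
      names(icc) <- c("icc", "icc_ci_low", "icc_ci_high", "n_strides")
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble(
          condition = condition, kind = kind,
          side = if (pool_sides) "pooled" else g,
          n = mad$n, mad_ms = mad$mad_ms, mad_sd_ms = mad$sd_ms,
          bias_ms = ba$bias_ms, loa_low_ms = ba$loa_low_ms,
          loa_high_ms = ba$loa_high_ms
        ),
        icc,
        tibble(
          icc_class = if (is.na(icc$icc)) NA_character_ else
            classify_icc(icc$icc),
          n_unmatched_ref = un[["ref"]], n_unmatched_test = un[["test"]]
        )
      )
    }
  }
  structure(
    list(table = dplyr::bind_rows(rows), pairs = pairs_out,
         condition = condition, tolerance_s = tolerance_s),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> condition %s (tolerance %.0f ms)\n",
              x$condition, x$tolerance_s * 1000))
  print(x$table, ...)
  invisible(x)
}

#' Tidy an agreement report
#'
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @return The per-(kind, side) metrics tibble.
#' @export
tidy.agreement_report <- function(x, ...) x$table

#' One-row summary of an agreement report
#'
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @return One-row tibble: condition, total pairs, worst-case MAD and
#'   ICC across event kinds, total identification errors.
#' @export
glance.agreement_report <- function(x, ...) {
  tb <- x$table
  tibble(
    condition = x$condition,
    n_pairs = sum(tb$n),
    max_mad_ms = max(tb$mad_ms),
    min_icc = min(tb$icc),
    n_unmatched = sum(tb$n_unmatched_ref + tb$n_unmatched_test)
  )
}
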