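#' Run the full simulate -> detect -> agree battery
#'
#' End-to-end replica of a two-condition treadmill agreement study on
#' synthetic data: for each configuration, a trial is simulated, events
#' are detected with both the kinematic (reference) and inertial (test)
#' methods, pairs are pooled per condition across speeds and sides, and
#' one agreement report per (condition, event kind) is produced, plus
#' forward-vs-backward Mann-Whitney comparisons of the absolute
#' between-method differences (per event kind and pooled).
#'
#' The run is deterministic given `seed`: per-trial seeds are derived
#' from it, and the JSON summary written by [write_battery_json()]
#' contains no timestamps, so same-seed reruns are byte-identical.
#'
#' @param configs List of [sim_config()] objects; defaults to
#'   [regime_configs()] at the given `scale`.
#' @param seed Integer seed driving all randomness.
#' @param scale Stride-count scale for the default configs.
#' @param tolerance_s Event-matching tolerance, seconds.
#' @param out_dir If non-`NULL`, event CSVs and the JSON summary are
#'   written there.
#' @return A `gait_battery` object: list with `reports` (one
#'   `agreement_report` per condition), `comparisons` (Mann-Whitney
#'   FW-vs-BW tibble), `truth_check` (per-condition detector-vs-truth
#'   recall tibble), `meta` (seed, scale, config hash, package version).
#' @examples
#' bat <- run_battery(seed = 1, scale = 0.02)
#' tidy(bat)
#' @export
run_battery <- function(configs = NULL, seed = 1, scale = 0.05,
                        tolerance_s = 0.1, out_dir = NULL) {
  configs <- configs %||% regime_configs(scale = scale, seed = seed)
  runs <- lapply(configs, function(cfg) {
    sim <- simulate_trial(cfg)
    list(
      cfg = cfg, truth = sim$truth,
      omc = detect_events(sim$trial, "omc"),
      imu = detect_events(sim$trial, "imu")
    )
  })

  conditions <- unique(vapply(runs, function(r) r$cfg$condition,
                              character(1)))
  reports <- list()
  abs_diffs <- list()
  truth_rows <- list()
  for (cond in conditions) {
    in_cond <- Filter(function(r) r$cfg$condition == cond, runs)
    # pool events across the condition's speed trials on a common clock
    # by offsetting each trial to follow the previous one
    offset <- 0
    pooled_omc <- list()
    pooled_imu <- list()
    pooled_truth <- list()
    for (r in in_cond) {
      shift <- function(ev) {
        ev <- as_tibble(ev)
        ev$time_s <- ev$time_s + offset
        ev
      }
      pooled_omc[[length(pooled_omc) + 1L]] <- shift(r$omc)
      pooled_imu[[length(pooled_imu) + 1L]] <- shift(r$imu)
      pooled_truth[[length(pooled_truth) + 1L]] <- shift(r$truth)
      offset <- offset + ceiling(max(r$truth$time_s) + 5)
    }
    as_series <- function(lst) {
      tb <- dplyr::bind_rows(lst)
      event_series(tb$time_s, tb$kind, tb$side, tb$source,
                   condition = cond, check = FALSE)
    }
    omc <- as_series(pooled_omc)
    imu <- as_series(pooled_imu)
    truth <- as_series(pooled_truth)
    reports[[cond]] <- agreement_report(omc, imu, condition = cond,
                                        tolerance_s = tolerance_s)
    for (kind in c("IC", "TC")) {
      pairs <- reports[[cond]]$pairs[[paste0(kind, ".pooled")]]
      abs_diffs[[paste(cond, kind)]] <- abs(pairs$diff_s) * 1000
      for (method in c("OMC", "IMU")) {
        det <- if (method == "OMC") omc else imu
        mp <- do.call(bind_pairs, lapply(c("L", "R"), function(s) {
          match_events(truth, det, kind = kind, side = s,
                       tolerance_s = tolerance_s)
        }))
        un <- unmatched_counts(mp)
        truth_rows[[length(truth_rows) + 1L]] <- tibble(
          condition = cond, kind = kind, method = method,
          n_truth = nrow(mp) + un[["ref"]], n_matched = nrow(mp),
          n_missed = un[["ref"]], n_spurious = un[["test"]],
          max_abs_err_ms = if (nrow(mp)) max(abs(mp$diff_s)) * 1000 else NA_real_
        )
      }
    }
  }

  comparisons <- NULL
  if (all(c("FW", "BW") %in% conditions)) {
    cmp_row <- function(label, fw, bw) {
      mw <- mann_whitney_u(fw, bw)
      tibble(comparison = label, n_fw = length(fw), n_bw = length(bw),
             median_fw_ms = median(fw), median_bw_ms = median(bw),
             u = mw$u, p_value = mw$p_value, method = mw$method)
    }
    comparisons <- dplyr::bind_rows(
      cmp_row("IC", abs_diffs[["FW IC"]], abs_diffs[["BW IC"]]),
      cmp_row("TC", abs_diffs[["FW TC"]], abs_diffs[["BW TC"]]),
      cmp_row("pooled",
              c(abs_diffs[["FW IC"]], abs_diffs[["FW TC"]]),
              c(abs_diffs[["BW IC"]], abs_diffs[["BW TC"]]))
    )
  }

  bat <- structure(
    list(
      reports = reports,
      comparisons = comparisons,
      truth_check = dplyr::bind_rows(truth_rows),
      meta = list(
        seed = seed, scale = scale, n_trials = length(configs),
        tolerance_s = tolerance_s,
        config_hash = rlang::hash(lapply(configs, unclass)),
        package_version = as.character(utils::packageVersion("gaitmark"))
      )
    ),
    class = "gait_battery"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_battery_json(bat, file.path(out_dir, "battery_summary.json"))
  }
  bat
}

#' @export
print.gait_battery <- function(x, ...) {
  cat(sprintf("<gait_battery> seed %s, %d trials (hash %s)\n",
              x$meta$seed, x$meta$n_trials,
              substr(x$meta$config_hash, 1, 8)))
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a battery result
#'
#' @param x A `gait_battery`.
#' @param ... Unused.
#' @return Agreement table with one row per (condition, event kind).
#' @export
tidy.gait_battery <- function(x, ...) {
  dplyr::bind_rows(lapply(x$reports, tidy))
}

#' @rdname tidy.gait_battery
#' @export
glance.gait_battery <- function(x, ...) {
  tb <- tidy(x)
  tibble(
    n_trials = x$meta$n_trials,
    n_events = sum(tb$n) * 2 + sum(tb$n_unmatched_ref + tb$n_unmatched_test),
    n_unmatched = sum(tb$n_unmatched_ref + tb$n_unmatched_test),
    max_mad_ms = max(tb$mad_ms),
    min_icc = min(tb$icc),
    all_excellent = all(tb$icc_class == "excellent")
  )
}

#' Write a battery summary as JSON
#'
#' Deterministic machine-readable summary: the per-(condition, kind)
#' agreement table, the condition comparisons, the truth-recovery check
#' and run metadata (seed, scale, config hash, package version; no
#' timestamps, so identical runs produce identical bytes).
#'
#' @param battery A `gait_battery`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_battery_json <- function(battery, path) {
  jsonlite::write_json(
    list(
      meta = battery$meta,
      agreement = tidy(battery),
      comparisons = battery$comparisons,
      truth_check = battery$truth_check
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(path)
}
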