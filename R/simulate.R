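#' Simulation configuration
#'
#' Parameters of the synthetic treadmill-gait generator. Defaults follow
#' the walking regimes of healthy young adults on a treadmill: forward
#' walking at 1.34 m/s with ~1.05 s strides, backward walking at 0.54 m/s
#' with ~1.30 s strides, stance occupying 60% of the stride, and modest
#' sensor noise.
#'
#' @param condition `"FW"` or `"BW"`.
#' @param n_strides Strides simulated per side.
#' @param stride_time_mean,stride_time_sd Stride duration distribution,
#'   seconds; strides are drawn from a normal truncated at mean +/- 3 SD
#'   (the mean must exceed 3 SD). `NULL` picks the condition default
#'   (FW 1.05 +/- 0.03 s, BW 1.30 +/- 0.05 s).
#' @param duty_factor Stance fraction of the stride, in (0, 1).
#' @param speed Belt speed, m/s; `NULL` picks the condition default
#'   (FW 1.34, BW 0.54).
#' @param impact_amp Amplitude of the foot-contact acceleration transient,
#'   g.
#' @param impact_decay Transient decay time constant, seconds.
#' @param dip_depth Depth of the pre-terminal-contact dip in the vertical
#'   toe acceleration (backward walking rule), g.
#' @param noise_sd_marker Marker position noise SD, meters.
#' @param noise_sd_acc Accelerometer noise SD, g.
#' @param noise_sd_gyro Gyroscope noise SD, deg/s.
#' @param rate_marker,rate_imu Sampling rates, Hz.
#' @param sides Sides simulated.
#' @param seed Integer RNG seed (`NULL` = use the current RNG state).
#' @return A `sim_config` list.
#' @export
sim_config <- function(condition = c("FW", "BW"), n_strides = 50,
                       stride_time_mean = NULL, stride_time_sd = NULL,
                       duty_factor = 0.6, speed = NULL,
                       impact_amp = 2, impact_decay = 0.05,
                       dip_depth = 2, noise_sd_marker = 0.002,
                       noise_sd_acc = 0.05, noise_sd_gyro = 1,
                       rate_marker = 100, rate_imu = 1000,
                       sides = c("L", "R"), seed = NULL) {
  condition <- match.arg(condition)
  stride_time_mean <- stride_time_mean %||%
    if (condition == "FW") 1.05 else 1.30
  stride_time_sd <- stride_time_sd %||%
    if (condition == "FW") 0.03 else 0.05
  speed <- speed %||% if (condition == "FW") 1.34 else 0.54
  stopifnot(
    n_strides >= 1, stride_time_mean > 0, stride_time_sd >= 0,
    duty_factor > 0, duty_factor < 1, speed > 0,
    impact_amp >= 0, impact_decay > 0, dip_depth >= 0,
    noise_sd_marker >= 0, noise_sd_acc >= 0, noise_sd_gyro >= 0,
    rate_marker > 0, rate_imu > 0, all(sides %in% c("L", "R"))
  )
  if (stride_time_mean <= 3 * stride_time_sd) {
    abort("`stride_time_mean` must exceed 3 * `stride_time_sd`.")
  }
  structure(
    list(condition = condition, n_strides = as.integer(n_strides),
         stride_time_mean = stride_time_mean,
         stride_time_sd = stride_time_sd, duty_factor = duty_factor,
         speed = speed, impact_amp = impact_amp,
         impact_decay = impact_decay, dip_depth = dip_depth,
         noise_sd_marker = noise_sd_marker, noise_sd_acc = noise_sd_acc,
         noise_sd_gyro = noise_sd_gyro, rate_marker = rate_marker,
         rate_imu = rate_imu, sides = sides, seed = seed),
    class = "sim_config"
  )
}

# Normal draws truncated at mean +/- 3 sd (resampling).
rnorm_trunc3 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- abs(x - mean) > 3 * sd
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- abs(x - mean) > 3 * sd
  }
  x
}

# Foot-pelvis displacement as an alternating train of symmetric Gaussian
# lobes: +A at each initial contact, -A at each terminal contact (forward
# walking; sign-flipped for backward). The lobes are even about their
# event, so any zero-phase (symmetric-kernel) filter chain leaves each
# extremum exactly on its event -- the generator's timing contract. The
# lobe SD is a fixed quarter of the smaller inter-event gap, inside the
# range where a 51-sample smoother at 100 Hz provably does not displace
# the extremum, while keeping the trace quasi-sinusoidal.
displacement_trace <- function(t, ic, tc, amp, duty, stride_mean) {
  sig <- 0.25 * min(duty, 1 - duty) * stride_mean
  out <- numeric(length(t))
  lobe <- function(dt) exp(-dt^2 / (2 * sig^2))
  out <- out + add_transients(t, ic, lobe, 5 * sig)
  amp * (out - add_transients(t, tc, lobe, 5 * sig))
}

# Sum of transient shapes centered at `centers`, evaluated on `t`.
# Shapes are symmetric about their center so zero-phase filtering leaves
# the extremum at the true event time.
add_transients <- function(t, centers, fn, half_width) {
  out <- numeric(length(t))
  for (c0 in centers) {
    i <- which(t >= c0 - half_width & t <= c0 + half_width)
    if (length(i)) out[i] <- out[i] + fn(t[i] - c0)
  }
  out
}

#' Simulate a treadmill walking trial with ground-truth events
#'
#' Generates one trial of synchronized marker (default 100 Hz) and
#' inertial (default 1000 Hz) streams whose morphology matches what the
#' detectors assume, together with the exact event times used to build
#' the signals:
#'
#' * stride times are truncated-normal; initial contacts accumulate them
#'   exactly, and terminal contacts fall `duty_factor` into each stride;
#' * foot-pelvis anterior-posterior displacement is a quasi-periodic
#'   train of symmetric lobes, `+A` at each initial contact and `-A` at
#'   each terminal contact (sign-flipped for backward walking), so
#'   displacement extrema coincide exactly with the truth events and --
#'   because each lobe is even about its event -- stay there through any
#'   zero-phase filter chain;
#' * vertical heel acceleration carries a symmetric damped-cosine impact
#'   transient centered at each initial contact;
#' * heel sagittal angular velocity is a smooth stride-periodic waveform
#'   with its minimum at each terminal contact;
#' * vertical toe acceleration carries a positive transient at each
#'   initial contact and a smooth negative dip of depth `dip_depth`
#'   centered at each terminal contact, deep enough to cross the
#'   mean - 1 SD run-rule threshold every stride;
#' * independent Gaussian noise is added per channel.
#'
#' Left and right sides are simulated independently (with a small random
#' stagger); since every detector works per side on per-side channels,
#' interlimb phasing carries no information for the statistics computed
#' here. The record starts ~1.2 s before the first event and ends ~1.2 s
#' after the last so that trimming 1 s from each edge keeps every truth
#' event inside the analysis window while no phantom stride extremum
#' enters it.
#'
#' @param config A [sim_config()].
#' @return List with elements `trial` (a `gait_trial`) and `truth`
#'   (an `event_series` with source `"TRUTH"`). Deterministic given
#'   `config$seed`.
#' @examples
#' sim <- simulate_trial(sim_config("BW", n_strides = 10, seed = 7))
#' sim$truth
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config
  duty <- cfg$duty_factor

  per_side <- lapply(cfg$sides, function(side) {
    st <- rnorm_trunc3(cfg$n_strides, cfg$stride_time_mean,
                       cfg$stride_time_sd)
    # first IC sits clear of the 1 s trim line; small stagger between sides
    ic1 <- 1.3 + runif(1, 0, 0.1)
    ic <- ic1 + cumsum(c(0, st[-length(st)]))
    tc <- ic + duty * st
    list(side = side, stride = st, ic = ic, tc = tc)
  })
  names(per_side) <- cfg$sides

  last_tc <- max(vapply(per_side, function(s) max(s$tc), numeric(1)))
  duration <- ceiling((last_tc + 1.25) * 100) / 100

  t_m <- seq(0, duration - 1 / cfg$rate_marker, by = 1 / cfg$rate_marker)
  t_i <- seq(0, duration - 1 / cfg$rate_imu, by = 1 / cfg$rate_imu)

  amp_disp <- cfg$speed * duty * cfg$stride_time_mean / 2
  disp_sign <- if (cfg$condition == "FW") 1 else -1

  markers <- tibble(time_s = t_m)
  imu <- tibble(time_s = t_i)
  marker_noise <- function(n) rnorm(n, 0, cfg$noise_sd_marker)

  # static pelvis markers around the origin (centroid AP position 0)
  pelvis_xyz <- list(
    ASIS_L = c(0.08, 0.12, 0.95), ASIS_R = c(0.08, -0.12, 0.95),
    PSIS_L = c(-0.08, 0.10, 0.97), PSIS_R = c(-0.08, -0.10, 0.97)
  )
  for (m in names(pelvis_xyz)) {
    for (ax in 1:3) {
      markers[[paste0(m, ".", c("X", "Y", "Z")[ax])]] <-
        pelvis_xyz[[m]][ax] + marker_noise(length(t_m))
    }
  }

  for (s in per_side) {
    disp_m <- disp_sign * displacement_trace(
      t_m, s$ic, s$tc, amp_disp, duty, cfg$stride_time_mean
    )
    lat <- if (s$side == "L") 0.12 else -0.12
    for (marker in c("HEEL", "TOE")) {
      ap_off <- if (marker == "HEEL") -0.10 else 0.12
      name <- paste0(marker, "_", s$side)
      markers[[paste0(name, ".X")]] <- disp_m + ap_off +
        marker_noise(length(t_m))
      markers[[paste0(name, ".Y")]] <- lat + marker_noise(length(t_m))
      markers[[paste0(name, ".Z")]] <- 0.05 + marker_noise(length(t_m))
    }

    impact <- function(dt) {
      cfg$impact_amp * exp(-abs(dt) / cfg$impact_decay) *
        cos(2 * pi * 8 * dt)
    }
    h_acc <- 1 + add_transients(t_i, s$ic, impact, 6 * cfg$impact_decay) +
      rnorm(length(t_i), 0, cfg$noise_sd_acc)

    gy_bump <- function(dt) -100 * exp(-dt^2 / (2 * 0.08^2))
    h_gy <- add_transients(t_i, s$tc, gy_bump, 0.4) +
      rnorm(length(t_i), 0, cfg$noise_sd_gyro)

    toe_strike <- function(dt) {
      cfg$impact_amp * exp(-dt^2 / (2 * 0.03^2))
    }
    dip_w <- 0.06
    dip <- function(dt) -cfg$dip_depth * cos(pi * dt / (2 * dip_w))^2
    t_acc <- 1 + add_transients(t_i, s$ic, toe_strike, 0.12) +
      add_transients(t_i, s$tc, dip, dip_w) +
      rnorm(length(t_i), 0, cfg$noise_sd_acc)

    imu[[paste0("H.ACC.Z.", s$side)]] <- h_acc
    imu[[paste0("H.GY.Z.", s$side)]] <- h_gy
    imu[[paste0("T.ACC.Z.", s$side)]] <- t_acc
  }

  truth_tb <- dplyr::bind_rows(lapply(per_side, function(s) {
    tibble(
      time_s = c(s$ic, s$tc),
      kind = rep(c("IC", "TC"), each = cfg$n_strides),
      side = s$side
    )
  }))
  truth <- event_series(truth_tb$time_s, truth_tb$kind, truth_tb$side,
                        source = "TRUTH", condition = cfg$condition)

  trial <- gait_trial(
    markers, imu, condition = cfg$condition,
    walking_axis = "X", forward_sign = 1,
    rate_marker = cfg$rate_marker, rate_imu = cfg$rate_imu,
    metadata = list(speed = cfg$speed, seed = cfg$seed,
                    n_strides = cfg$n_strides,
                    stride_time_mean = cfg$stride_time_mean)
  )
  list(trial = trial, truth = truth)
}

#' Treadmill study regime configurations
#'
#' The simulated counterpart of a two-condition, three-speed treadmill
#' protocol (slow / comfortable / fast, self-selected): forward walking
#' around 1.34 m/s and backward walking around 0.54 m/s, with stride
#' counts apportioned so the full-scale battery carries ~1550 forward and
#' ~1321 backward strides in total across speeds and sides. Stride time
#' shrinks mildly with speed (`T = T_ref * sqrt(v_ref / v)`), a standard
#' walking scaling.
#'
#' @param scale Stride-count scale factor; `scale = 0.05` gives a
#'   desk-size battery of ~150 strides total.
#' @param seed Base seed; each config gets a distinct derived seed.
#' @return List of [sim_config()] objects (FW then BW, slow to fast).
#' @export
regime_configs <- function(scale = 1, seed = NULL) {
  regimes <- tibble(
    condition = rep(c("FW", "BW"), each = 3),
    speed = c(1.12, 1.34, 1.56, 0.42, 0.54, 0.66),
    ref_speed = rep(c(1.34, 0.54), each = 3),
    ref_stride = rep(c(1.05, 1.30), each = 3),
    total_strides = rep(c(1550, 1321), each = 3) / 3
  )
  purrr::pmap(regimes, function(condition, speed, ref_speed, ref_stride,
                                total_strides) {
    i <- which(regimes$speed == speed & regimes$condition == condition)
    sim_config(
      condition = condition,
      n_strides = max(3L, as.integer(round(total_strides * scale / 2))),
      stride_time_mean = ref_stride * sqrt(ref_speed / speed),
      speed = speed,
      seed = if (is.null(seed)) NULL else (seed + 101L * i) %% .Machine$integer.max
    )
  })
}
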