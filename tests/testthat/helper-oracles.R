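# Independent reference implementations used to check the package's
# algorithms. Deliberately written as plain loops / enumerations, sharing
# no code with the implementations they verify.

# Exhaustive scan peak finder: candidate local maxima by neighbor scan
# (plateaus -> earliest sample), prominence by explicit outward walks,
# then iterative tallest-first selection under the separation constraint.
oracle_extrema <- function(ts, min_separation, min_prominence,
                           which = "maxima") {
  x <- if (which == "maxima") ts$value else -ts$value
  n <- length(x)
  rate <- ts_rate(ts)
  cand <- integer()
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) cand <- c(cand, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(cand)) return(numeric())
  prom <- vapply(cand, function(i) {
    h <- x[i]
    lmin <- h
    j <- i - 1L
    while (j >= 1L && x[j] <= h) {
      lmin <- min(lmin, x[j])
      j <- j - 1L
    }
    rmin <- h
    j <- i + 1L
    while (j <= n && x[j] <= h) {
      rmin <- min(rmin, x[j])
      j <- j + 1L
    }
    h - max(lmin, rmin)
  }, numeric(1))
  amp <- as.numeric(diff(quantile(ts$value, c(0.05, 0.95))))
  cand <- cand[prom >= min_prominence * amp]
  if (!length(cand)) return(numeric())
  kept <- integer()
  remaining <- cand
  while (length(remaining)) {
    heights <- x[remaining]
    best <- remaining[order(-heights, remaining)][1]
    kept <- c(kept, best)
    remaining <- remaining[abs(remaining - best) / rate >= min_separation]
    remaining <- setdiff(remaining, best)
  }
  sort(ts$time_s[kept])
}

# ICC(2,1) via stats::aov mean squares assembled with the standard
# absolute-agreement formula.
oracle_icc_a1 <- function(a, b) {
  n <- length(a)
  k <- 2
  df <- data.frame(
    y = c(a, b),
    target = factor(rep(seq_len(n), 2)),
    rater = factor(rep(1:2, each = n))
  )
  tab <- summary(stats::aov(y ~ target + rater, data = df))[[1]]
  msr <- tab["target", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# All k-subsets of 1..n, built recursively (independent of utils::combn).
oracle_subsets <- function(n, k) {
  if (k == 0L) return(list(integer()))
  if (n < k) return(list())
  with_n <- lapply(oracle_subsets(n - 1L, k - 1L), function(s) c(s, n))
  c(with_n, oracle_subsets(n - 1L, k))
}

# Exact two-sided Mann-Whitney p by full enumeration over group
# assignments, with U counted directly from value comparisons
# (ties = half wins).
oracle_mw_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  nn <- length(pooled)
  u_of <- function(idx) {
    xs <- pooled[idx]
    ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * (nn - n1) / 2
  us <- vapply(oracle_subsets(nn, n1), u_of, numeric(1))
  list(u = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9))
}

# Random quasi-realistic test traces for the peak engine: smoothed noise,
# white noise, integer-quantized (plateau/tie-rich) and spiky variants.
random_trace <- function(n, rate = 100) {
  kind <- sample(c("smooth", "white", "quantized", "spiky"), 1)
  x <- switch(kind,
    smooth = as.numeric(stats::filter(rnorm(n), rep(1 / 7, 7),
                                      circular = TRUE)),
    white = rnorm(n),
    quantized = round(rnorm(n) * 2) / 2,
    spiky = {
      z <- rnorm(n) * 0.1
      hits <- sample(n, max(1, n %/% 25))
      z[hits] <- z[hits] + sample(c(-3, 3), length(hits), replace = TRUE)
      z
    }
  )
  timeseries(x, rate = rate)
}

# Small synthetic sine channel.
sine_ts <- function(freq, duration, rate, amp = 1, phase = 0) {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  timeseries(amp * sin(2 * pi * freq * t + phase), rate = rate)
}

# Fitted amplitude of a sinusoid at a known frequency (regression on the
# quadrature basis), robust to phase shifts.
fitted_amplitude <- function(ts, freq) {
  t <- ts$time_s
  fit <- stats::lm(ts$value ~ sin(2 * pi * freq * t) + cos(2 * pi * freq * t))
  sqrt(sum(coef(fit)[2:3]^2))
}

# Quick event-series builder for statistic tests.
mk_events <- function(times, kind = "IC", side = "L", source = "OMC") {
  event_series(times, kind = kind, side = side, source = source,
               check = FALSE)
}
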