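#' Mean absolute between-method difference
#'
#' Mean and sample SD of the absolute paired time differences, in
#' milliseconds.
#'
#' @param pairs A `matched_pairs` tibble (needs at least one pair).
#' @return One-row tibble: `mad_ms`, `sd_ms`, `n`.
#' @export
mean_abs_difference <- function(pairs) {
  d <- abs(pairs$diff_s) * 1000
  if (length(d) < 1) abort("Need at least one matched pair.")
  tibble(mad_ms = mean(d),
         sd_ms = if (length(d) > 1) sd(d) else 0,
         n = length(d))
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' Bias is the mean signed difference (`t_test - t_ref`); the limits of
#' agreement are `bias +/- 1.96 * SD(diff)`, bracketing ~95% of
#' between-method differences under normality. The plain single-level
#' formulation is used (strides treated as independent); no
#' repeated-measures correction is applied.
#'
#' @param pairs A `matched_pairs` tibble (needs at least two pairs).
#' @return One-row tibble: `bias_ms`, `loa_low_ms`, `loa_high_ms`, `n`.
#' @examples
#' p <- tibble::tibble(diff_s = c(0.001, 0.002, 0.003))
#' bland_altman(p)  # bias 2 ms, LoA 0.04 / 3.96 ms
#' @export
bland_altman <- function(pairs) {
  d <- pairs$diff_s * 1000
  if (length(d) < 2) abort("Need at least two matched pairs.")
  bias <- mean(d)
  s <- sd(d)
  tibble(bias_ms = bias,
         loa_low_ms = bias - 1.96 * s,
         loa_high_ms = bias + 1.96 * s,
         n = length(d))
}

#' Intraclass correlation for between-method agreement
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC --
#' ICC(2,1) in Shrout-Fleiss terms, ICC(A,1) in McGraw-Wong terms -- of a
#' paired table whose targets are strides and whose two raters are the
#' measurement methods. Absolute agreement is the appropriate form when
#' two methods measure the same physical quantity, because a constant
#' offset between methods must count against agreement; the consistency
#' form (which forgives constant offsets) is available via `type`.
#' The 95% confidence interval uses the McGraw-Wong variance-component F
#' quantiles. A table with zero residual and zero rater variance (perfect
#' agreement) returns ICC 1 with a degenerate unit interval.
#'
#' @param a,b Equal-length numeric vectors (n >= 3), paired by stride.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `icc`, `ci_low`, `ci_high`, `n`.
#' @export
icc_agreement <- function(a, b, type = c("agreement", "consistency"),
                          conf_level = 0.95) {
  type <- match.arg(type)
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  n <- length(a)
  if (n < 3) abort("Need at least 3 paired observations.")
  x <- cbind(a, b)
  if (all(x == x[1, 1])) abort("Zero total variance: ICC undefined.")
  k <- 2
  gm <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sst <- sum((x - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  alpha <- 1 - conf_level
  if (type == "consistency") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    if (mse <= 0) return(tibble(icc = 1, ci_low = 1, ci_high = 1, n = n))
    f_obs <- msr / mse
    df2 <- (n - 1) * (k - 1)
    fl <- f_obs / qf(1 - alpha / 2, n - 1, df2)
    fu <- f_obs * qf(1 - alpha / 2, df2, n - 1)
    return(tibble(icc = icc,
                  ci_low = (fl - 1) / (fl + k - 1),
                  ci_high = (fu - 1) / (fu + k - 1), n = n))
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  if (mse <= 0 && msc <= 0) {
    return(tibble(icc = 1, ci_low = 1, ci_high = 1, n = n))
  }
  fj <- msc / mse
  vn <- (n - 1) * (k - 1) *
    (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
  vd <- (n - 1) * k^2 * icc^2 * fj^2 +
    (n * (1 + (k - 1) * icc) - k * icc)^2
  v <- vn / vd
  f_u <- qf(1 - alpha / 2, n - 1, v)
  f_l <- qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f_u * mse) /
    (f_u * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_l * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_l * msr)
  tibble(icc = icc, ci_low = ci_low, ci_high = ci_high, n = n)
}

#' Classify an ICC into agreement bands
#'
#' Conventional interpretation bands: poor below 0.5, moderate 0.5--0.75,
#' good 0.75--0.9, excellent above 0.9. Boundary values belong to the
#' lower band (0.5 is moderate, 0.9 is good).
#'
#' @param icc Finite ICC value(s).
#' @return Character vector of labels.
#' @examples
#' classify_icc(c(0.45, 0.9, 0.986))
#' @export
classify_icc <- function(icc) {
  stopifnot(all(is.finite(icc)))
  dplyr::case_when(
    icc < 0.5 ~ "poor",
    icc <= 0.75 ~ "moderate",
    icc <= 0.9 ~ "good",
    TRUE ~ "excellent"
  )
}

# U statistic of x against y, counting ties as half wins.
u_statistic <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

#' Mann-Whitney U test
#'
#' Rank-based two-sample location test. For small samples
#' (`min(n1, n2) <= 8` and `n1 * n2 <= 64`) the two-sided p-value is
#' exact: all assignments of the pooled values to the two groups are
#' enumerated and the p-value is the fraction whose U deviates from the
#' null mean `n1 * n2 / 2` at least as much as observed, which remains
#' exact under ties. Larger samples use the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact Force exact enumeration on/off; default chooses by sample
#'   size as above.
#' @return One-row tibble: `u` (U of `x`), `p_value`, `n1`, `n2`,
#'   `method` (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0 || n2 == 0) abort("Both samples must be non-empty.")
  u_obs <- u_statistic(x, y)
  mu <- n1 * n2 / 2
  exact <- exact %||% (min(n1, n2) <= 8 && n1 * n2 <= 64)
  if (exact) {
    pooled <- c(x, y)
    r <- rank(pooled)
    combos <- combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "exact"
  } else {
    nn <- n1 + n2
    ties <- table(c(x, y))
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal"
  }
  tibble(u = u_obs, p_value = p, n1 = n1, n2 = n2, method = method)
}
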