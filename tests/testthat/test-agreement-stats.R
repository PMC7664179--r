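pairs_of <- function(diff_s) tibble::tibble(diff_s = diff_s)

test_that("mean absolute difference in milliseconds", {
  expect_equal(mean_abs_difference(pairs_of(c(-0.001, 0.001)))[1:2],
               tibble::tibble(mad_ms = 1, sd_ms = 0))
  expect_equal(mean_abs_difference(pairs_of(c(0, 0, 0)))$mad_ms, 0)
  res <- mean_abs_difference(pairs_of(c(0.010, 0.020, 0.030)))
  expect_equal(res$mad_ms, 20)
  expect_equal(res$sd_ms, 10)
  expect_error(mean_abs_difference(pairs_of(numeric())), "one matched")
})

test_that("Bland-Altman bias and limits of agreement", {
  res <- bland_altman(pairs_of(c(0.001, 0.002, 0.003)))
  expect_equal(res$bias_ms, 2)
  expect_equal(res$loa_low_ms, 2 - 1.96)
  expect_equal(res$loa_high_ms, 2 + 1.96)

  const <- bland_altman(pairs_of(rep(0.005, 10)))
  expect_equal(const$bias_ms, 5)
  expect_equal(const$loa_low_ms, 5)
  expect_equal(const$loa_high_ms, 5)

  sym <- bland_altman(pairs_of(c(-0.004, -0.001, 0.001, 0.004)))
  expect_equal(sym$bias_ms, 0)
  expect_equal(sym$loa_low_ms, -sym$loa_high_ms)

  expect_error(bland_altman(pairs_of(0.001)), "two")
})

test_that("limits of agreement span exactly 2 * 1.96 * SD", {
  set.seed(21)
  for (i in 1:10) {
    d <- rnorm(sample(5:50, 1), 0.002, 0.01)
    res <- bland_altman(pairs_of(d))
    expect_equal(res$loa_high_ms - res$loa_low_ms,
                 2 * 1.96 * sd(d * 1000))
  }
})

test_that("stride times difference consecutive same-kind events", {
  ev <- mk_events(c(1.0, 2.2, 3.4))
  expect_equal(stride_times(ev, "IC", "L")$stride_s, c(1.2, 1.2))
  expect_equal(stride_times(ev, "IC", "L")$t_start, c(1.0, 2.2))
  expect_equal(nrow(stride_times(mk_events(1.0), "IC", "L")), 0)
  expect_equal(stride_times(mk_events(c(1, 2, 3.5)), "IC", "L")$stride_s,
               c(1.0, 1.5))
  # streams are kept apart
  two <- event_series(c(1, 1.1, 2, 2.3), kind = "IC",
                      side = c("L", "R", "L", "R"), source = "OMC",
                      check = FALSE)
  st <- stride_times(two, "IC")
  expect_equal(st$stride_s[st$side == "L"], 1.0)
  expect_equal(st$stride_s[st$side == "R"], 1.2)
})

test_that("ICC(2,1) handles perfect, offset and degenerate tables", {
  a <- c(1.1, 1.3, 1.2, 1.4, 1.25)
  expect_equal(icc_agreement(a, a)$icc, 1.0)
  expect_error(icc_agreement(rep(1, 5), rep(1, 5)), "variance")
  expect_error(icc_agreement(a, a[-1]), "equal length")
  expect_error(icc_agreement(a[1:2], a[1:2]), "3")

  # a large constant offset destroys absolute agreement but not
  # consistency
  set.seed(3)
  x <- rnorm(40, 1.2, 0.03)
  y <- x + 10 * 0.03
  expect_lt(icc_agreement(x, y)$icc, 0.5)
  expect_gt(icc_agreement(x, y, type = "consistency")$icc, 0.99)
})

test_that("ICC matches the aov-based oracle on random small tables", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(3:20, 1)
    a <- rnorm(n, 1, 0.1)
    b <- a * runif(1, 0.5, 1.5) + rnorm(n, runif(1, -0.1, 0.1), 0.05)
    expect_equal(icc_agreement(a, b)$icc, oracle_icc_a1(a, b),
                 tolerance = 1e-10)
  }
})

test_that("ICC confidence interval matches an independent reference", {
  # table and reference values fixed from an independent
  # variance-component computation
  a <- c(1.129289, 1.211784, 1.158314, 1.067571, 1.002832, 1.094632,
         1.117246, 1.109946, 1.208576, 1.107931, 1.121306, 1.066710)
  b <- c(1.138073, 1.177050, 1.152899, 1.059704, 1.021735, 1.108805,
         1.144204, 1.133951, 1.195013, 1.170696, 1.118714, 1.087418)
  res <- icc_agreement(a, b)
  expect_equal(res$icc, 0.8917560895, tolerance = 1e-8)
  expect_equal(res$ci_low, 0.6792878867, tolerance = 1e-8)
  expect_equal(res$ci_high, 0.9672220145, tolerance = 1e-8)
})

test_that("ICC bands classify with lower-open boundaries", {
  expect_equal(classify_icc(0.45), "poor")
  expect_equal(classify_icc(0.5), "moderate")
  expect_equal(classify_icc(0.75), "moderate")
  expect_equal(classify_icc(0.9), "good")
  expect_equal(classify_icc(0.986), "excellent")
  # monotone non-decreasing in icc
  grid <- classify_icc(seq(-0.5, 1, by = 0.01))
  lev <- match(grid, c("poor", "moderate", "good", "excellent"))
  expect_true(all(diff(lev) >= 0))
})

test_that("Mann-Whitney exact mode reproduces enumeration results", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u, 0)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$method, "exact")

  # identical multisets: U = n^2 / 2 under half-win tie counting
  tie <- mann_whitney_u(c(1, 2), c(1, 2))
  expect_equal(tie$u, 2)

  # U_x + U_y = n1 * n2
  set.seed(8)
  for (i in 1:20) {
    x <- sample(1:8, sample(2:6, 1), replace = TRUE)
    y <- sample(1:8, sample(2:6, 1), replace = TRUE)
    expect_equal(mann_whitney_u(x, y)$u + mann_whitney_u(y, x)$u,
                 length(x) * length(y))
  }
  expect_error(mann_whitney_u(numeric(), 1:3), "non-empty")
})

test_that("exact p agrees with wilcox.test when ties are absent", {
  set.seed(15)
  for (i in 1:25) {
    x <- rnorm(sample(3:6, 1))
    y <- rnorm(sample(3:6, 1))
    ours <- mann_whitney_u(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$u, unname(ref$statistic))
  }
})

test_that("normal approximation matches wilcox.test with tie correction", {
  set.seed(30)
  x <- sample(1:40, 60, replace = TRUE)
  y <- sample(5:45, 70, replace = TRUE)
  ours <- mann_whitney_u(x, y)
  expect_equal(ours$method, "normal")
  ref <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  )
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("agreement_report composes matching and statistics", {
  ref <- event_series(rep(seq(1, 30, by = 1.1), each = 2) +
                        c(0, 0.66),
                      kind = c("IC", "TC"), side = "L", source = "OMC",
                      check = FALSE)
  # identical test series: perfect agreement
  test0 <- event_series(ref$time_s, ref$kind, ref$side, source = "IMU",
                        check = FALSE)
  rep0 <- agreement_report(ref, test0)
  tb <- tidy(rep0)
  expect_equal(tb$mad_ms, c(0, 0))
  expect_equal(tb$bias_ms, c(0, 0))
  expect_equal(tb$icc, c(1, 1))
  expect_equal(tb$icc_class, c("excellent", "excellent"))

  # constant 10 ms shift: MAD 10 +/- 0, LoA collapse onto the bias
  test1 <- event_series(ref$time_s + 0.010, ref$kind, ref$side,
                        source = "IMU", check = FALSE)
  tb1 <- tidy(agreement_report(ref, test1))
  expect_equal(tb1$mad_ms, c(10, 10))
  expect_equal(tb1$mad_sd_ms, c(0, 0))
  expect_equal(tb1$loa_low_ms, c(10, 10))
  expect_equal(tb1$loa_high_ms, c(10, 10))
  expect_equal(glance(rep0)$n_unmatched, 0)
})

test_that("report recovers injected Gaussian offsets at scale", {
  set.seed(77)
  n <- 120
  ic_ref <- cumsum(c(2, rnorm(n - 1, 1.1, 0.02)))
  ref <- event_series(ic_ref, "IC", "L", "OMC", check = FALSE)
  test <- event_series(ic_ref + rnorm(n, 0.005, 0.010), "IC", "L", "IMU",
                       check = FALSE)
  mp <- match_events(ref, test, "IC", "L")
  ba <- bland_altman(mp)
  expect_equal(ba$bias_ms, 5, tolerance = 2)
  expect_equal(ba$loa_low_ms, -14.6, tolerance = 4)
  expect_equal(ba$loa_high_ms, 24.6, tolerance = 4)
})
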