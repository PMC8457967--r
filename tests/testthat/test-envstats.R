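test_that("THI closed forms hold", {
  # the humidity factor vanishes at 1.8 T = 26, leaving 58 for any RH
  for (rh in c(0, 37, 55, 100)) {
    expect_equal(compute_thi(130 / 9, rh), 58)
  }
  # at saturation THI is the plain Fahrenheit conversion
  for (t in c(-5, 0, 14, 25, 35)) {
    expect_equal(compute_thi(t, 100), 1.8 * t + 32)
  }
  expect_equal(compute_thi(20, 60), 65.8)
  expect_error(compute_thi(20, 120), "rh_pct")
  expect_error(compute_thi(20, -3), "rh_pct")
})

test_that("period aggregation means readings inside clock-hour windows", {
  ts <- as.POSIXct("2020-01-05 06:00:00", tz = "UTC") + 60 * (0:59)
  readings <- tibble::tibble(timestamp = ts, nh3_ppm = 30, temp_c = 15,
                             rh_pct = 70)
  out <- aggregate_periods(readings)
  expect_equal(nrow(out), 1L)
  expect_equal(out$mean_nh3, 30)
  expect_equal(out$thi, compute_thi(15, 70))
  expect_true(out$complete)

  readings2 <- tibble::tibble(
    timestamp = as.POSIXct("2020-01-05 12:10:00", tz = "UTC") + c(0, 60, 120),
    nh3_ppm = c(10, 20, 30), temp_c = 14:16, rh_pct = c(65, 70, 75))
  out2 <- aggregate_periods(readings2)
  expect_equal(out2$mean_nh3, 20)
  expect_equal(out2$mean_temp, 15)
  expect_false(out2$complete)
  # mean-then-THI, not mean of per-reading THIs
  expect_equal(out2$thi, compute_thi(15, 70))
})

test_that("periods missing a required variable are dropped listwise", {
  ts6 <- as.POSIXct("2020-01-05 06:30:00", tz = "UTC")
  ts12 <- as.POSIXct("2020-01-05 12:30:00", tz = "UTC")
  readings <- tibble::tibble(
    timestamp = c(ts6, ts12),
    nh3_ppm = c(25, NA), temp_c = c(15, 16), rh_pct = c(70, 71))
  out <- aggregate_periods(readings)
  expect_equal(out$period, "06:00")
  # readings outside the requested period hours never appear
  odd <- tibble::tibble(timestamp = as.POSIXct("2020-01-05 09:30:00", tz = "UTC"),
                        nh3_ppm = 5, temp_c = 10, rh_pct = 60)
  expect_equal(nrow(aggregate_periods(odd)), 0L)
  expect_equal(nrow(aggregate_periods(readings[0, ])), 0L)
})

test_that("perfect concordance and discordance hit the tau bounds", {
  for (v in c("tau_a", "tau_b")) {
    expect_equal(kendall_tau(1:3, 1:3, v)$tau, 1)
    expect_equal(kendall_tau(1:3, 3:1, v)$tau, -1)
  }
})

test_that("tau_a equals the hand-counted concordance ratio", {
  kt <- kendall_tau(c(1, 2, 3, 4), c(1, 3, 2, 4), "tau_a")
  expect_equal(kt$tau, (5 - 1) / 6)
  expect_equal(kt$S, 4)
})

test_that("tau_a matches the O(n^2) double loop on random inputs", {
  double_loop_tau_a <- function(x, y) {
    n <- length(x)
    s <- 0
    for (i in 1:n) for (j in 1:n) s <- s + sign(x[i] - x[j]) * sign(y[i] - y[j])
    s / (n * (n - 1))
  }
  set.seed(55)
  for (i in 1:25) {
    n <- sample(3:60, 1)
    x <- sample(round(stats::rnorm(n, 0, 2), 1))  # rounding induces ties
    y <- round(stats::rnorm(n, 0, 2), 1)
    expect_equal(kendall_tau(x, y, "tau_a")$tau, double_loop_tau_a(x, y))
  }
})

test_that("tau_b agrees with the reference implementation, with and without ties", {
  set.seed(56)
  for (i in 1:20) {
    n <- sample(5:80, 1)
    x <- round(stats::rnorm(n), sample(0:1, 1))
    y <- round(stats::rnorm(n), sample(0:1, 1))
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendall_tau(x, y, "tau_b")$tau,
                 unname(stats::cor(x, y, method = "kendall")))
  }
})

test_that("tau is invariant under strictly increasing transforms", {
  set.seed(57)
  x <- stats::rnorm(30)
  y <- stats::rnorm(30)
  base <- kendall_tau(x, y)$tau
  expect_equal(kendall_tau(exp(x), y)$tau, base)
  expect_equal(kendall_tau(x, 3 * y + 2)$tau, base)
  expect_equal(kendall_tau(x, atan(y))$tau, base)
})

test_that("tau_a and tau_b coincide exactly on tie-free data", {
  set.seed(58)
  for (i in 1:10) {
    x <- stats::rnorm(25)
    y <- stats::rnorm(25)
    expect_equal(kendall_tau(x, y, "tau_a")$tau, kendall_tau(x, y, "tau_b")$tau)
  }
})

test_that("degenerate correlation inputs are rejected", {
  expect_error(kendall_tau(1:3, 1:4), "equal length")
  expect_error(kendall_tau(1, 1), "at least 2")
  expect_error(kendall_tau(c(2, 2, 2), 1:3, "tau_b"), "constant")
})

test_that("exact p-values match enumeration of rank arrangements", {
  # n = 3, tau = 1: only identity and reversal of 3! = 6 orders reach |tau| = 1
  kt <- kendall_tau(1:3, 1:3, "tau_a")
  expect_equal(as.numeric(kendall_pvalue(kt, "exact")), 2 / 6)
  # tie-free recurrence equals brute-force enumeration at n = 5
  set.seed(59)
  x <- stats::rnorm(5)
  y <- stats::rnorm(5)
  kt5 <- kendall_tau(x, y, "tau_a")
  perms <- chromaflock:::all_permutations(5L)
  s_obs <- abs(kt5$S)
  brute <- mean(apply(perms, 1, function(p)
    abs(chromaflock:::kendall_stats(x, y[p])$S) >= s_obs - 1e-9))
  expect_equal(as.numeric(kendall_pvalue(kt5, "exact")), brute)
  # tied data go through full enumeration for small n
  ktt <- kendall_tau(c(1, 1, 2, 3), c(1, 2, 2, 3))
  pt <- kendall_pvalue(ktt, "exact")
  expect_equal(attr(pt, "p_method"), "exact_enumeration")
  expect_gt(as.numeric(pt), 0)
})

test_that("normal-approximation p-values match the reference test under ties", {
  set.seed(60)
  for (i in 1:10) {
    n <- sample(15:60, 1)
    x <- round(stats::rnorm(n), 1)
    y <- round(x + stats::rnorm(n), 1)
    kt <- kendall_tau(x, y)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
    expect_equal(as.numeric(kt$p_value), ref$p.value, tolerance = 1e-8)
  }
  # null-centered tau has p near 1
  kt0 <- kendall_tau(1:100, rep(c(1, 2), 50))
  expect_gt(as.numeric(kt0$p_value), 0.5)
})

test_that("estimated tau tracks the Greiner relation for Gaussian copulas", {
  rho <- 0.6
  n <- 500
  target <- 2 / pi * asin(rho)
  set.seed(61)
  taus <- vapply(1:200, function(i) {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    kendall_tau(z1, z2, "tau_a")$tau
  }, numeric(1))
  se <- stats::sd(taus) / sqrt(length(taus))
  expect_lt(abs(mean(taus) - target), 3 * se + 1e-3)
})

test_that("period correlation pairs series by (date, period) and records n", {
  d <- chamber_period_data()
  expect_equal(nrow(d), 24L)
  res <- correlate_periods(d, "thi", "mean_nh3", variant = "tau_b")
  expect_equal(res$n, 24L)
  expect_equal(res$tau, unname(stats::cor(d$thi, d$mean_nh3, method = "kendall")))
  # identical variables correlate perfectly (tau_b; its tie correction makes
  # self-correlation exactly 1 even though the THI table contains a tie)
  expect_equal(correlate_periods(d, "thi", "thi", variant = "tau_b")$tau, 1)
  expect_equal(correlate_periods(d, "mean_nh3", "mean_nh3",
                                 variant = "tau_a")$tau, 1)
  # strictly monotone toy series: tau = 1 regardless of pairing order
  toy <- tibble::tibble(date = as.Date("2020-01-01") + 0:5,
                        period = "06:00", a = 1:6, b = (1:6)^2)
  expect_equal(correlate_periods(toy[sample(6), ], "a", "b")$tau, 1)
  expect_error(correlate_periods(toy[1, ], "a", "b"), "fewer than 2")
})

test_that("tidy and glance summarize correlation objects", {
  kt <- kendall_tau(1:5, c(2, 1, 4, 3, 5))
  td <- tidy(kt)
  expect_named(td, c("tau", "variant", "p_value", "p_method", "n"))
  gl <- glance(kt)
  expect_equal(gl$n, 5L)
})
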