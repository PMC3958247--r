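test_that("cross-covariance matches hand values and the O(N^2) oracle", {
  cv <- cross_covariance(c(1, 2, 3), max_lag_fraction = 1)
  expect_equal(unname(sapply(0:2, function(m) cv$values[cv$lags == m])),
               c(2, 0, -1), tolerance = 1e-12)

  # constant signal: all lags exactly zero after mean removal
  cvc <- cross_covariance(rep(7, 64), 0.5)
  expect_true(all(abs(cvc$values) < 1e-9))

  # random signals, N <= 512, vs the direct sum
  set.seed(101)
  for (n in c(8, 33, 100, 257, 512)) {
    x <- rnorm(n)
    cv <- cross_covariance(x, 0.5)
    want <- crosscov_oracle(x, max(cv$lags))
    got <- cv$values[cv$lags >= 0]
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-9)
  }
})

test_that("cross-covariance is symmetric and scale-covariant", {
  set.seed(102)
  x <- rnorm(200)
  cv <- cross_covariance(x, 0.8)
  expect_equal(cv$values, rev(cv$values), tolerance = 1e-12)
  # lag-0 dominates every lag
  expect_true(all(cv$values <= cv$values[cv$lags == 0] + 1e-9))
  # periodicity decision is invariant to amplitude scaling
  r1 <- detect_periodicity(cross_covariance(x, 0.5))
  r2 <- detect_periodicity(cross_covariance(1000 * x, 0.5))
  expect_identical(r1$is_periodic, r2$is_periodic)
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-9)
})

test_that("sinusoid covariance peaks at multiples of the period", {
  p <- 50
  x <- sin(2 * pi * (0:999) / p)
  cv <- cross_covariance(x, 0.5)
  pk <- find_local_peaks(cv, prominence = 0.25)
  expect_true(0 %in% pk$lag)
  # every positive-lag peak sits within 1 sample of a period multiple
  pos <- pk$lag[pk$lag > 0]
  expect_gt(length(pos), 2)
  expect_true(all(abs(pos / p - round(pos / p)) <= 1 / p))
  # the ratio between the top two peaks approaches 0 for many cycles
  r <- detect_periodicity(cv)
  expect_true(r$is_periodic)
  expect_lt(r$ratio, 0.2)
  expect_equal(r$period_estimate, p, tolerance = 1)
})

test_that("monotone decay yields a single lag-0 peak and no periodicity", {
  x <- exp(-(0:299) / 40)
  cv <- cross_covariance(x, 0.5)
  pk <- find_local_peaks(cv)
  expect_identical(nrow(pk), 1L)
  expect_identical(pk$lag, 0L)
  r <- detect_periodicity(cv)
  expect_false(r$is_periodic)
  expect_true(is.na(r$period_estimate))
})

test_that("white-noise covariance: lag-0 dominates, secondary peaks O(sqrt(N)) down", {
  set.seed(103)
  x <- rnorm(4096)
  cv <- cross_covariance(x, 0.5)
  pk0 <- find_local_peaks(cv, prominence = 0)   # all strict local maxima
  v0 <- pk0$value[pk0$lag == 0]
  second <- max(pk0$value[pk0$lag > 0])
  expect_lt(second / v0, 10 / sqrt(4096))
  # with the default prominence floor the decision is non-periodic
  expect_false(detect_periodicity(cv, 2)$is_periodic)
})

test_that("white noise is classified non-periodic in >= 99/100 seeds", {
  wrong <- sum(vapply(1:100, function(s) {
    set.seed(s)
    detect_periodicity(cross_covariance(rnorm(4096), 0.5), 2)$is_periodic
  }, TRUE))
  expect_lte(wrong, 1)
})

test_that("degenerate covariances are never declared periodic", {
  # all-zero second peak candidates (constant signal)
  r <- detect_periodicity(cross_covariance(rep(1, 100), 0.5))
  expect_false(r$is_periodic)
  expect_error(detect_periodicity(cross_covariance(rnorm(16), 0.5), epsilon = 0),
               class = "ft_param_error")
})

test_that("segment_and_connect recovers burst trains to within one window", {
  set.seed(104)
  fs <- 1000
  dur <- 40
  n <- dur * fs
  x <- rnorm(n, sd = 0.1)          # rest-phase noise floor (SNR 20 dB)
  truth <- logical(n)
  for (st in seq(0, dur - 2.5, by = 2.5)) {   # 1 s bursts every 2.5 s
    a <- round(st * fs) + 1
    b <- round((st + 1) * fs)
    x[a:b] <- rnorm(b - a + 1)
    truth[a:b] <- TRUE
  }
  acc <- gen_acceleration(dur, fs, "periodic", 2.5, Inf, seed = 104)$channel
  per <- detect_periodicity(cross_covariance(acc, 0.5), 2)
  expect_true(per$is_periodic)
  sc <- segment_and_connect(signal_channel(x, fs), acc, per)
  w <- round(0.125 * fs)
  expect_lt(abs(sc$map$connected_length - sum(truth)), w + 1)
  # map bookkeeping: disjoint sorted intervals, lengths add up
  iv <- sc$map$active_intervals
  expect_true(all(diff(as.vector(t(iv))) >= 0))
  expect_identical(sum(iv[, "end"] - iv[, "start"]), sc$map$connected_length)
  expect_identical(length(sc$signal$samples), sc$map$connected_length)
})

test_that("segmentation edge cases: fully active, all-zero, not periodic", {
  acc <- gen_acceleration(20, 250, "periodic", 2.5, Inf, seed = 7)$channel
  per <- detect_periodicity(cross_covariance(acc, 0.5), 2)
  set.seed(105)
  full <- signal_channel(rnorm(5000), 250)
  sc <- segment_and_connect(full, acc, per)
  expect_identical(sc$signal$samples, full$samples)
  expect_identical(nrow(sc$map$active_intervals), 1L)

  zero <- signal_channel(rep(0, 5000), 250)
  expect_error(segment_and_connect(zero, acc, per), class = "ft_input_error")

  nr <- detect_periodicity(cross_covariance(rep(1, 5000), 0.5))
  expect_error(segment_and_connect(full, acc, nr), class = "ft_input_error")
})
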