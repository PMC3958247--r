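test_that("rls_init validates its domain", {
  st <- rls_init(0.95, 0, 10000)
  expect_s3_class(st, "rls_state")
  expect_identical(st$count, 0L)
  expect_identical(st$t, 0)
  expect_silent(rls_init(1, 0, 1e6))   # pure least-squares mode
  expect_silent(rls_init(0, 0, 1e6))   # memoryless mode
  expect_error(rls_init(-0.1), class = "ft_param_error")
  expect_error(rls_init(1.01), class = "ft_param_error")
  expect_error(rls_init(0.95, 0, 0), class = "ft_param_error")
  expect_error(rls_init(0.95, 0, -5), class = "ft_param_error")
})

test_that("rls_update: zero innovation is a fixed point; time must increase", {
  st <- rls_init(0.9, phi0 = -0.3, p0 = 100)
  st2 <- rls_update(st, 2, -0.3 * 2)   # observation on the current model line
  expect_equal(st2$phi, -0.3, tolerance = 1e-14)
  expect_error(rls_update(st2, 2, 1), class = "ft_sequence_error")
  expect_error(rls_update(st2, 1.5, 1), class = "ft_sequence_error")
  expect_error(rls_update(st2, 3, NaN), class = "ft_input_error")
})

test_that("lambda = 0 reproduces the memoryless gain state p_t = t^-2", {
  st <- rls_init(0, 0, 1e4)
  for (t in c(1, 2.5, 7)) {
    st <- rls_update(st, t, 3 * t + 1)
    expect_equal(st$p, t^-2, tolerance = 1e-12)
    expect_equal(st$phi, (3 * t + 1) / t, tolerance = 1e-10)
  }
})

test_that("lambda = 1 recursion equals batch through-origin least squares", {
  st <- rls_init(1, 0, 1e6)
  st <- rls_update(st, 1, 2)
  st <- rls_update(st, 2, 4)
  expect_equal(st$phi, 2, tolerance = 1e-3)

  set.seed(401)
  for (i in 1:25) {
    n <- sample(5:100, 1)
    t <- sort(runif(n, 0.1, 50))
    t <- t[c(TRUE, diff(t) > 1e-6)]
    y <- -0.4 * t + rnorm(length(t), sd = 2)
    st <- rls_init(1, 0, 1e6)
    for (j in seq_along(t)) st <- rls_update(st, t[j], y[j])
    expect_equal(st$phi, batch_slope_oracle(t, y), tolerance = 1e-6)
  }
})

test_that("forgetting recursion converges on a noiseless ramp", {
  # f = -0.5 t + 100; de-meaned by the initial mean frequency (the model
  # intercept), the slope settles to -0.5 within 2% after 60 updates
  t <- 1:60
  f <- -0.5 * t + 100
  y <- f - 100                          # absorb the intercept
  st <- rls_init(0.95, 0, 10000)
  for (j in t) st <- rls_update(st, j, y[j])
  expect_equal(st$phi, -0.5, tolerance = 0.02)
})

test_that("smaller lambda reacts faster to a slope change", {
  t <- seq_len(200)
  y <- ifelse(t <= 100, -0.1 * t, -0.1 * 100 - 0.5 * (t - 100))
  err_after <- vapply(c(0.99, 0.95, 0.9), function(lam) {
    st <- rls_init(lam, 0, 1e4)
    for (j in t) st <- rls_update(st, j, y[j])
    abs(st$phi - (y[200] - y[199]))     # distance from the new local slope
  }, 0)
  expect_true(all(diff(err_after) < 0))
})

test_that("track_fatigue: levels start at zero and follow Eq-style evaluation", {
  mk_series <- function(vals, times = seq_along(vals), f0 = NULL) {
    s <- structure(list(times = times, values = vals,
                        f0 = if (is.null(f0)) mean(vals[1:min(5, length(vals))]) else f0,
                        window_length = 0.125, window_overlap = 0.063,
                        time_unit = "index", fs = 1000, taper = "hann"),
                   class = "mean_frequency_series")
    s
  }
  # constant series: no fatigue anywhere
  tr <- track_fatigue(mk_series(rep(80, 50)))
  expect_identical(tr$levels[1], 0)
  expect_true(all(abs(tr$levels) < 1e-9))

  # phi = -0.5 Hz/s at t = 10 s with f0 = 100 -> level -5%
  expect_equal(-0.5 * 10 / 100, -0.05)  # direct evaluation of the level formula
  ramp <- mk_series(100 - 0.5 * (1:200) * 0.1, times = (1:200) * 0.1, f0 = 100)
  tr2 <- track_fatigue(ramp)
  i10 <- which.min(abs(tr2$times - 10))
  expect_equal(tr2$levels[i10], -0.05, tolerance = 0.002)

  # a noiseless 20% decline ends within 1% of level -0.20
  n <- 966
  tt <- seq_len(n)
  dec <- mk_series(100 * (1 - 0.2 * tt / n), times = tt, f0 = 100)
  tr3 <- track_fatigue(dec)
  expect_equal(tr3$levels[n], -0.20, tolerance = 0.002)

  expect_error(track_fatigue(mk_series(rep(-5, 30), f0 = -5)),
               class = "ft_input_error")
})

test_that("fatigue level is invariant to rescaling the whole series", {
  g <- gen_semg(duration = 10, fs = 1000, f0 = 100, slope = -0.3,
                snr = 20, seed = 402)
  m <- mean_frequency_series(g$channel)
  m2 <- m
  m2$values <- 3 * m$values
  m2$f0 <- 3 * m$f0
  tr <- track_fatigue(m)
  tr2 <- track_fatigue(m2)
  expect_equal(tr$levels, tr2$levels, tolerance = 1e-9)
})

test_that("linearity F-test matches hand-computed sums of squares", {
  t <- 1:6
  y <- c(2.1, 3.9, 6.2, 8.1, 9.8, 12.3)
  ft <- linearity_ftest(t, y)
  # hand computation
  sxx <- sum((t - mean(t))^2)
  sxy <- sum((t - mean(t)) * (y - mean(y)))
  b <- sxy / sxx
  ssr <- b * sxy
  sse <- sum((y - mean(y))^2) - ssr
  f_hand <- ssr / (sse / 4)
  expect_equal(unname(ft$statistic), f_hand, tolerance = 1e-9)
  expect_equal(ft$p.value, stats::pf(f_hand, 1, 4, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(unname(ft$estimate["slope"]), b, tolerance = 1e-9)

  # perfect fit convention
  perfect <- linearity_ftest(1:5, 2 * (1:5))
  expect_identical(unname(perfect$statistic), Inf)
  expect_identical(perfect$p.value, 0)

  expect_error(linearity_ftest(1:2, 1:2), class = "ft_input_error")
  expect_error(linearity_ftest(rep(1, 5), rnorm(5)), class = "ft_input_error")
})

test_that("F-test rejects a genuine decline and keeps its size under the null", {
  g <- gen_semg(duration = 30, fs = 1000, f0 = 100, slope = -0.4,
                snr = 20, seed = 403)
  ft <- linearity_ftest(mean_frequency_series(g$channel))
  expect_lt(ft$p.value, 0.05)
  expect_lt(unname(ft$estimate["slope"]), 0)

  # quick null calibration (the full 2000-draw check lives in acceptance)
  set.seed(404)
  rej <- mean(vapply(1:200, function(i) {
    linearity_ftest(1:30, rnorm(30))$p.value < 0.05
  }, TRUE))
  expect_gt(rej, 0.005)
  expect_lt(rej, 0.12)
})
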