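test_that("psd_window: zero input, tone localization, Parseval", {
  zero <- psd_window(rep(0, 128), 1000)
  expect_true(all(zero$power == 0))
  expect_identical(zero$frequencies[1], 0)

  # 50 Hz tone, integer number of cycles, rectangular: peak exactly at 50
  x <- sin(2 * pi * 50 * (0:199) / 1000)
  sp <- psd_window(x, 1000, taper = "rectangular")
  expect_identical(sp$frequencies[which.max(sp$power)], 50)
  expect_true(all(sp$power >= 0))
  expect_true(all(diff(sp$frequencies) > 0))

  # one-sided PSD integrates (rectangle rule) to the mean square
  set.seed(201)
  y <- rnorm(512)
  sp2 <- psd_window(y, 250, taper = "rectangular")
  df <- diff(sp2$frequencies[1:2])
  expect_equal(sum(sp2$power) * df, mean(y^2), tolerance = 1e-6)

  expect_error(psd_window(rnorm(4), 100), class = "ft_input_error")
})

test_that("mean_frequency: point mass, flat spectrum, two-bin average", {
  grid <- seq(0, 125, by = 0.5)
  mass <- numeric(length(grid))
  mass[grid == 42.5] <- 3
  expect_equal(mean_frequency(structure(list(frequencies = grid, power = mass),
                                        class = "spectrum_estimate")), 42.5)

  flat <- structure(list(frequencies = seq(0, 80, by = 0.25),
                         power = rep(1, 321)), class = "spectrum_estimate")
  expect_equal(mean_frequency(flat), 40, tolerance = 0.25)  # within one bin

  two <- numeric(length(grid))
  two[grid %in% c(10, 30)] <- 5
  expect_equal(mean_frequency(structure(list(frequencies = grid, power = two),
                                        class = "spectrum_estimate")), 20)

  none <- structure(list(frequencies = grid, power = numeric(length(grid))),
                    class = "spectrum_estimate")
  expect_error(mean_frequency(none), class = "ft_input_error")
})

test_that("mean frequency is amplitude invariant and bounded by Nyquist", {
  set.seed(202)
  for (i in 1:20) {
    x <- rnorm(200)
    fs <- sample(c(250, 1000, 4000), 1)
    f1 <- mean_frequency(psd_window(x, fs))
    f2 <- mean_frequency(psd_window(1e3 * x, fs))
    expect_equal(f1, f2, tolerance = 1e-12)
    expect_gte(f1, 0)
    expect_lte(f1, fs / 2)
  }
})

test_that("series and per-window paths agree; rectangle vs trapezoid within a bin", {
  g <- gen_semg(duration = 2, fs = 1000, f0 = 100, slope = 0, snr = 20, seed = 203)
  mfs <- mean_frequency_series(g$channel, taper = "hann")
  wl <- round(0.125 * 1000)
  step <- round((0.125 - 0.063) * 1000)
  first <- mean_frequency(psd_window(g$channel$samples[1:wl], 1000, "hann"))
  expect_equal(mfs$values[1], first, tolerance = 1e-10)

  # rectangle-rule oracle for the centroid agrees to within one bin width
  sp <- psd_window(g$channel$samples[1:wl], 1000, "hann")
  rect <- sum(sp$frequencies * sp$power) / sum(sp$power)
  expect_lt(abs(rect - first), 1000 / wl)

  # timestamps: window centers, strictly increasing, step = length - overlap
  expect_equal(diff(mfs$times)[1], step / 1000, tolerance = 1e-12)
  expect_true(all(diff(mfs$times) > 0))
})

test_that("window count follows the integer-sample step rule", {
  # 1 s record, 0.125 s windows, 0.063 s overlap -> 0.062 s step -> 15 windows
  ch <- signal_channel(rnorm(1000), fs = 1000)
  mfs <- mean_frequency_series(ch)
  expect_identical(length(mfs$values), (1000L - 125L) %/% 62L + 1L)
  expect_identical(length(mfs$values), 15L)

  expect_error(mean_frequency_series(signal_channel(rnorm(100), 1000)),
               class = "ft_input_error")
})

test_that("stationary noise gives a flat centroid series around the target", {
  g <- gen_semg(duration = 30, fs = 1000, f0 = 100, slope = 0, snr = 20, seed = 204)
  mfs <- mean_frequency_series(g$channel)
  expect_equal(mean(mfs$values), 101.5, tolerance = 3)  # mixture centroid
  fit <- stats::coef(stats::lm(mfs$values ~ mfs$times))
  expect_lt(abs(fit[2]), 0.06)  # no drift beyond estimator noise
})

test_that("a linear centroid ramp is recovered by OLS on the series", {
  # slope steep enough that estimator noise (~0.013 Hz/s SD per 60 s run)
  # sits well inside the 5% band; averaged over a few seeds
  slopes <- vapply(301:305, function(s) {
    g <- gen_semg(duration = 60, fs = 1000, f0 = 130, slope = -0.5,
                  snr = 20, seed = s)
    m <- mean_frequency_series(g$channel)
    unname(stats::coef(stats::lm(m$values ~ m$times))[2])
  }, 0)
  expect_equal(mean(slopes), -0.5, tolerance = 0.05)
})

test_that("f0 reference averages the first K windows", {
  ch <- signal_channel(rnorm(2000) + sin(2 * pi * 50 * (0:1999) / 1000), 1000)
  m1 <- mean_frequency_series(ch, f0_windows = 1)
  m5 <- mean_frequency_series(ch, f0_windows = 5)
  expect_identical(m1$f0, m1$values[1])
  expect_equal(m5$f0, mean(m5$values[1:5]), tolerance = 1e-12)
})
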