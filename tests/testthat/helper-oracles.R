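# Independent oracles used across the suite. These deliberately use naive
# direct formulas (O(N^2) sums, closed forms, hand quadrature) so they
# share no code path with the package implementation.

# minimal Butterworth low-pass order, closed form
butter_order_oracle <- function(Wp, Ws, Rp, Rs) {
  ceiling(log10((10^(Rs / 10) - 1) / (10^(Rp / 10) - 1)) /
            (2 * log10(Ws / Wp)))
}

# digital filter magnitude (dB) at normalized frequency W (fraction of
# Nyquist), straight from the transfer-function definition
filter_gain_db <- function(coef, W) {
  z <- exp(1i * pi * W)
  num <- vapply(seq_along(coef$b), function(k) coef$b[k] * z^(-(k - 1)), 0i)
  den <- vapply(seq_along(coef$a), function(k) coef$a[k] * z^(-(k - 1)), 0i)
  20 * log10(Mod(sum(num) / sum(den)))
}

# Eq-style direct O(N^2) autocovariance sum, mean removed, biased
crosscov_oracle <- function(x, max_lag) {
  mu <- mean(x)
  vapply(0:max_lag, function(m) {
    n <- length(x)
    sum((x[(1 + m):n] - mu) * (x[1:(n - m)] - mu))
  }, 0)
}

# batch through-origin least-squares slope
batch_slope_oracle <- function(t, y) sum(t * y) / sum(t * t)

rms <- function(x) sqrt(mean(x^2))

# a pure tone channel
tone_channel <- function(freq, fs, duration, amp = 1) {
  n <- round(fs * duration)
  signal_channel(amp * sin(2 * pi * freq * (0:(n - 1)) / fs), fs,
                 label = sprintf("tone_%g", freq))
}
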