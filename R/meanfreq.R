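#' One-sided power spectral density of a window
#'
#' FFT periodogram of one analysis window: `PSD(f) = |FFT(f)|^2` on the
#' one-sided frequency grid `0 .. fs/2`, scaled so that the one-sided PSD
#' integrates (rectangle rule) to the mean square of the segment
#' (Parseval). A Hann taper (power-compensated) is applied by default to
#' control leakage in short windows; `"rectangular"` gives the raw
#' periodogram.
#'
#' @param segment Numeric vector (length >= 8).
#' @param fs Sampling rate in Hz.
#' @param taper `"hann"` (default) or `"rectangular"`.
#' @return A `spectrum_estimate` with `frequencies` (Hz, uniform grid from
#'   0) and non-negative `power` (V^2/Hz).
#' @export
psd_window <- function(segment, fs, taper = c("hann", "rectangular")) {
  taper <- match.arg(taper)
  x <- as.numeric(segment)
  n <- length(x)
  if (n < 8L) stop_input("psd_window: segment too short (%d < 8 samples)", n)
  if (!all(is.finite(x))) stop_input("psd_window: segment must be finite")
  w <- taper_vector(n, taper)
  X <- stats::fft(x * w)
  half <- n %/% 2L + 1L
  p <- abs(X[seq_len(half)])^2 / (n * fs * mean(w^2))
  scale <- rep(2, half)
  scale[1L] <- 1
  if (n %% 2L == 0L) scale[half] <- 1  # Nyquist bin present only for even n
  structure(
    list(frequencies = (seq_len(half) - 1L) * fs / n, power = p * scale),
    class = "spectrum_estimate"
  )
}

taper_vector <- function(n, taper) {
  switch(taper,
         hann = 0.5 - 0.5 * cos(2 * pi * seq.int(0L, n - 1L) / (n - 1L)),
         rectangular = rep(1, n))
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf("<spectrum_estimate> %d bins, 0..%.6g Hz\n",
              length(x$frequencies), max(x$frequencies)))
  invisible(x)
}

#' Spectral mean frequency (centroid)
#'
#' First spectral moment over zeroth moment,
#' \deqn{f_{mean} = \int \omega PSD(\omega) d\omega / \int PSD(\omega) d\omega,}
#' evaluated by trapezoidal quadrature on the discrete grid (DC bin
#' included). Invariant to amplitude scaling and always within
#' \[0, Nyquist\].
#'
#' @param spec A `spectrum_estimate`.
#' @return Mean frequency in Hz.
#' @export
mean_frequency <- function(spec) {
  stopifnot(inherits(spec, "spectrum_estimate"))
  f <- spec$frequencies
  p <- spec$power
  denom <- pracma::trapz(f, p)
  if (!is.finite(denom) || denom <= 0)
    stop_input("mean_frequency: spectrum has no power (undefined mean)")
  pracma::trapz(f, f * p) / denom
}

#' Moving-window mean-frequency trajectory
#'
#' Slides an analysis window along the signal (step = length - overlap,
#' rounded to integer samples; any final partial window is dropped) and
#' computes the spectral centroid of each window. The initial mean
#' frequency `f0` is the average of the first `f0_windows` values: a single
#' 0.125 s window gives a high-variance start, so a short average
#' stabilizes the reference that all fatigue levels are measured against
#' (`f0_windows = 1` restores the literal single-window definition).
#'
#' @param signal A [signal_channel()].
#' @param window_length,window_overlap Window settings in seconds.
#' @param taper Passed to [psd_window()].
#' @param f0_windows Windows averaged into `f0`.
#' @param time_unit `"seconds"` (timestamps at window centers) for
#'   continuous signals, or `"index"` (1, 2, ...) for connected signals
#'   whose concatenated time axis is no longer physical.
#' @return A `mean_frequency_series`: `times`, `values` (Hz), `f0`,
#'   and the window settings.
#' @export
mean_frequency_series <- function(signal, window_length = 0.125,
                                  window_overlap = 0.063,
                                  taper = c("hann", "rectangular"),
                                  f0_windows = 5L,
                                  time_unit = c("seconds", "index")) {
  taper <- match.arg(taper)
  time_unit <- match.arg(time_unit)
  stopifnot(inherits(signal, "signal_channel"))
  if (!(window_overlap > 0 && window_overlap < window_length))
    stop_param("mean_frequency_series: need 0 < window_overlap < window_length")
  fs <- signal$fs
  x <- signal$samples
  wl <- round(window_length * fs)
  step <- max(1L, round((window_length - window_overlap) * fs))
  if (length(x) < wl)
    stop_input("mean_frequency_series: signal shorter than one window (%d < %d samples)",
               length(x), wl)
  if (wl < 8L)
    stop_input("mean_frequency_series: window of %d samples is too short", wl)
  k <- (length(x) - wl) %/% step + 1L
  starts <- (seq_len(k) - 1L) * step
  wvec <- taper_vector(wl, taper)
  mat <- matrix(x[outer(seq_len(wl), starts, `+`)], nrow = wl) * wvec
  X <- stats::mvfft(mat)
  half <- wl %/% 2L + 1L
  p <- abs(X[seq_len(half), , drop = FALSE])^2
  freqs <- (seq_len(half) - 1L) * fs / wl
  # same one-sided doubling as psd_window, then trapezoid weights on the
  # uniform grid (any common scaling cancels in the centroid ratio)
  scale <- rep(2, half)
  scale[1L] <- 1
  if (wl %% 2L == 0L) scale[half] <- 1
  tw <- rep(1, half)
  tw[c(1L, half)] <- 0.5
  tw <- tw * scale
  denom <- colSums(p * tw)
  if (any(denom <= 0))
    stop_input("mean_frequency_series: window(s) with zero power; centroid undefined")
  vals <- colSums(p * (tw * freqs)) / denom
  times <- if (time_unit == "seconds") (starts + wl / 2) / fs else seq_len(k)
  structure(
    list(times = times, values = vals,
         f0 = mean(vals[seq_len(min(f0_windows, k))]),
         window_length = window_length, window_overlap = window_overlap,
         time_unit = time_unit, fs = fs, taper = taper),
    class = "mean_frequency_series"
  )
}

#' @export
print.mean_frequency_series <- function(x, ...) {
  cat(sprintf("<mean_frequency_series> %d windows (%s), f0 = %.2f Hz, last = %.2f Hz\n",
              length(x$values), x$time_unit, x$f0,
              x$values[length(x$values)]))
  invisible(x)
}

#' @rdname mean_frequency_series
#' @param series A `mean_frequency_series`.
#' @param path Output CSV path (columns `time`, `mean_frequency_hz`).
#' @export
write_mean_frequency <- function(series, path) {
  stopifnot(inherits(series, "mean_frequency_series"))
  utils::write.csv(data.frame(time = series$times,
                              mean_frequency_hz = series$values),
                   path, row.names = FALSE)
  invisible(path)
}
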