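#' Minimal-order Butterworth low-pass design
#'
#' Designs the lowest-order Butterworth low-pass filter whose magnitude
#' response has at most `Rp` dB of attenuation at the passband corner `Wp`
#' and at least `Rs` dB at the stopband corner `Ws`. Corners are normalized
#' frequencies (fractions of Nyquist, in (0, 1)). The minimal order follows
#' the classical inequality
#' \deqn{n = \lceil \log_{10}\{(10^{R_s/10}-1)/(10^{R_p/10}-1)\} /
#'       (2 \log_{10}(W_s/W_p)) \rceil}
#' with the natural cutoff `Wn` chosen so the passband spec is met exactly.
#'
#' @param Wp Passband corner, normalized (0 < Wp < Ws < 1).
#' @param Ws Stopband corner, normalized.
#' @param Rp Maximum passband ripple/attenuation in dB (> 0).
#' @param Rs Minimum stopband attenuation in dB (> Rp).
#' @return A `filter_spec`: the design parameters plus the realized order
#'   `n`, natural cutoff `Wn`, and the digital filter coefficients (`coef`,
#'   an `Arma` object from the signal package).
#' @examples
#' spec <- design_butterworth(0.1, 0.4, 3, 40)  # the sEMG pre-filter
#' spec$n
#' @export
design_butterworth <- function(Wp, Ws, Rp, Rs) {
  for (v in list(Wp, Ws, Rp, Rs))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_param("design_butterworth: all arguments must be finite scalars")
  if (!(Wp > 0 && Wp < Ws && Ws < 1))
    stop_param("design_butterworth: need 0 < Wp < Ws < 1 (low-pass)")
  if (Rp <= 0 || Rs <= 0)
    stop_param("design_butterworth: ripple/attenuation must be positive")
  if (Rp >= Rs)
    stop_param("design_butterworth: passband ripple must be below stopband attenuation")
  ord <- signal::buttord(Wp, Ws, Rp, Rs)
  structure(
    list(Wp = Wp, Ws = Ws, Rp = Rp, Rs = Rs,
         n = as.integer(ord$n), Wn = ord$Wc,
         coef = signal::butter(ord)),
    class = "filter_spec"
  )
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf(
    "<filter_spec> Butterworth low-pass, order %d, Wn = %.6g (Wp=%g Ws=%g Rp=%g dB Rs=%g dB)\n",
    x$n, x$Wn, x$Wp, x$Ws, x$Rp, x$Rs))
  invisible(x)
}

#' Apply a designed filter to a channel
#'
#' By default the filter is applied forward-backward (zero phase), which
#' suits offline segmentation; set `zero_phase = FALSE` for a causal pass.
#' Output has the same length and sampling rate as the input.
#'
#' @param channel A [signal_channel()].
#' @param spec A `filter_spec` from [design_butterworth()].
#' @param zero_phase Apply forward-backward (default) or causal filtering.
#' @return A filtered `signal_channel`.
#' @details Zero-phase filtering uses odd-reflection end padding sized to
#'   the slowest filter pole (~3 time constants), so low-cutoff designs do
#'   not ring at the record edges — essential for the near-DC acceleration
#'   filter, whose transients would otherwise masquerade as periodic
#'   movement in the covariance analysis.
#' @export
apply_filter <- function(channel, spec, zero_phase = TRUE) {
  stopifnot(inherits(channel, "signal_channel"), inherits(spec, "filter_spec"))
  x <- channel$samples
  n <- length(x)
  if (n <= 3L * spec$n)
    stop_input("apply_filter: signal too short for order-%d filter warm-up (%d samples)",
               spec$n, n)
  y <- if (zero_phase) {
    # anchor at the mean (exact DC passthrough) and continue the record by
    # odd reflection over ~10 time constants of the slowest pole, so the
    # zero-state transient of the forward-backward pass dies out in the
    # padding instead of ringing into the record
    rho <- max(abs(polyroot(rev(spec$coef$a))))
    pad <- min(n - 1L, max(3L * spec$n, ceiling(10 / max(1 - rho, 1e-6))))
    mu <- mean(x)
    xc <- x - mu
    xp <- c(2 * xc[1L] - xc[(pad + 1L):2L], xc,
            2 * xc[n] - xc[(n - 1L):(n - pad)])
    mu + signal::filtfilt(spec$coef, xp)[(pad + 1L):(pad + n)]
  } else {
    as.numeric(signal::filter(spec$coef, channel$samples))
  }
  channel_with(channel, y)
}

# Polyphase rational resampling of one channel onto a target rate.
# The ratio is taken from the actual fs values (reduced to lowest terms),
# never hard-coded.
resample_channel <- function(channel, fs_target) {
  stopifnot(inherits(channel, "signal_channel"))
  if (!is.numeric(fs_target) || fs_target <= 0)
    stop_param("resample_channel: fs_target must be positive")
  if (isTRUE(all.equal(channel$fs, fs_target))) return(channel)
  pq <- rationalize_ratio(fs_target, channel$fs)
  y <- signal::resample(channel$samples, pq[1L], pq[2L])
  channel_with(channel, y, fs = fs_target)
}

# p/q = a/b in lowest integer terms (fs values scaled to integers first)
rationalize_ratio <- function(a, b, max_scale = 1e6) {
  s <- 1
  while ((abs(a * s - round(a * s)) > 1e-9 || abs(b * s - round(b * s)) > 1e-9) &&
         s < max_scale) s <- s * 10
  p <- round(a * s); q <- round(b * s)
  g <- pracma::gcd(p, q)
  c(p / g, q / g)
}

#' Resample an sEMG / acceleration pair onto a common time base
#'
#' The higher-rate channel is resampled (polyphase, anti-aliased) onto the
#' lower rate; both channels are then truncated to the common overlapping
#' duration so their sample counts are equal and aligned at t = 0.
#'
#' @param semg,acc Two [signal_channel()] objects.
#' @return A list with elements `semg` and `acc`, equal length, equal fs.
#' @export
resample_to_common <- function(semg, acc) {
  stopifnot(inherits(semg, "signal_channel"), inherits(acc, "signal_channel"))
  fs <- min(semg$fs, acc$fs)
  semg <- resample_channel(semg, fs)
  acc <- resample_channel(acc, fs)
  n <- min(length(semg$samples), length(acc$samples))
  list(semg = channel_with(semg, semg$samples[seq_len(n)]),
       acc = channel_with(acc, acc$samples[seq_len(n)]))
}
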