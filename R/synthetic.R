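#' Synthetic sEMG with a prescribed mean-frequency decline
#'
#' Generates broadband noise whose spectral centroid follows
#' `f(t) = f0 + slope * t`, the linear decline that characterizes a
#' fatiguing muscle. Construction: white Gaussian noise is shaped, in
#' half-overlapping blocks joined with square-root-Hann crossfades, by a
#' sliding narrow band filter applied in the frequency domain — a
#' flat-top band of width `bandwidth` Hz with raised-cosine edges,
#' symmetric about `f(t)` — so the in-band spectral centroid equals
#' `f(t)` analytically and the expected power is constant. Broadband
#' measurement noise is then added at the given SNR. Fully seeded: the
#' same seed reproduces identical samples.
#'
#' @param duration Record length in seconds (the reference protocol uses
#'   1 min bouts).
#' @param fs Sampling rate in Hz.
#' @param f0 Initial spectral centroid in Hz.
#' @param slope Centroid drift in Hz/s (negative under fatigue).
#' @param snr Signal-to-noise ratio in dB (`Inf` = noiseless).
#' @param seed Integer seed (optional; uses the current RNG stream if NULL).
#' @param bandwidth Band-pass width in Hz.
#' @param label Channel label.
#' @return A list: `channel` (a [signal_channel()], units "V") and `truth`
#'   (f0, slope, snr, bandwidth, seed).
#' @export
gen_semg <- function(duration = 60, fs = 1000, f0 = 100, slope = -0.25,
                     snr = 20, seed = NULL, bandwidth = 40,
                     label = "semg") {
  if (f0 <= 0) stop_param("gen_semg: f0 must be positive")
  f_end <- f0 + slope * duration
  margin <- bandwidth / 2
  lo <- min(f0, f_end) - margin
  hi <- max(f0, f_end) + margin
  if (lo <= 0 || hi >= fs / 2)
    stop_param("gen_semg: centroid band [%.1f, %.1f] Hz leaves (0, Nyquist = %g)",
               lo, hi, fs / 2)
  n <- round(duration * fs)
  with_seed(seed, {
    blk <- 2L * (round(0.25 * fs) %/% 2L)  # even block length, ~0.25 s
    hop <- blk %/% 2L
    win <- sqrt(taper_vector(blk, "hann"))
    fgrid <- abs(seq.int(0L, blk - 1L) - blk * (seq.int(0L, blk - 1L) >= blk / 2)) * fs / blk
    roll <- min(margin / 2, 8)  # raised-cosine edge width, Hz
    sig <- numeric(n + blk)
    nblocks <- ceiling(n / hop) + 1L
    for (b in seq_len(nblocks)) {
      at <- (b - 1L) * hop
      tc <- (at + hop) / fs
      fc <- f0 + slope * min(max(tc, 0), duration)
      # flat-top band with raised-cosine edges, symmetric about fc
      d <- abs(fgrid - fc)
      mask <- as.numeric(d <= margin - roll) +
        ifelse(d > margin - roll & d < margin + roll,
               0.5 * (1 + cos(pi * (d - margin + roll) / (2 * roll))), 0)
      y <- Re(stats::fft(stats::fft(stats::rnorm(blk)) * mask, inverse = TRUE)) / blk
      sig[(at + 1L):(at + blk)] <- sig[(at + 1L):(at + blk)] + y * win
    }
    sig <- sig[seq_len(n)]
    sig <- sig / stats::sd(sig)
    if (is.finite(snr)) sig <- sig + stats::rnorm(n, sd = sqrt(10^(-snr / 10)))
    list(channel = signal_channel(sig, fs, label, "V"),
         truth = list(f0 = f0, slope = slope, snr = snr,
                      bandwidth = bandwidth, seed = seed))
  })
}

#' Synthetic acceleration traces
#'
#' Emulates the two movement paradigms: `"periodic"` gives a smooth
#' repetitive bending-stretching waveform (fundamental plus a weaker
#' second harmonic) with the given period; `"sustained"` gives a slow
#' posture drift (exponential settle plus a mild linear trend) with no
#' periodic component. Additive white noise at the given SNR.
#'
#' @param duration Record length in seconds.
#' @param fs Sampling rate in Hz (the reference accelerometer runs at
#'   296 Hz).
#' @param mode `"periodic"` or `"sustained"`.
#' @param period Movement period in seconds (periodic mode; the reference
#'   arm-curl protocol paces one lift every ~2.5 s). Must satisfy
#'   `0 < period < duration / 3` so several cycles are observed.
#' @param snr SNR in dB (`Inf` = noiseless).
#' @param seed Integer seed (optional).
#' @param amplitude Movement amplitude in g.
#' @param label Channel label.
#' @return A list: `channel` (units "g") and `truth` (mode, period, snr).
#' @export
gen_acceleration <- function(duration = 60, fs = 296,
                             mode = c("periodic", "sustained"),
                             period = 2.5, snr = 20, seed = NULL,
                             amplitude = 1, label = "acc") {
  mode <- match.arg(mode)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  if (mode == "periodic") {
    if (!(period > 0 && period < duration / 3))
      stop_param("gen_acceleration: periodic mode needs 0 < period < duration/3")
    base <- amplitude * (sin(2 * pi * t / period - pi / 2) +
                           0.3 * sin(4 * pi * t / period + 0.5))
  } else {
    base <- amplitude * (1 - exp(-t / (duration / 6))) +
      0.15 * amplitude * t / duration
  }
  with_seed(seed, {
    x <- base
    if (is.finite(snr))
      x <- x + stats::rnorm(n, sd = sqrt(stats::var(base) / 10^(snr / 10)))
    list(channel = signal_channel(x, fs, label, "g"),
         truth = list(mode = mode,
                      period = if (mode == "periodic") period else NA_real_,
                      snr = snr, seed = seed))
  })
}

#' Generate a coherent multi-muscle synthetic session
#'
#' Builds per-muscle sEMG plus tri-axial acceleration with known ground
#' truth, in the structure [run_pipeline()] consumes. The default roster
#' mirrors a three-muscle arm recording (biceps brachii, anterior deltoid,
#' triceps brachii) with distinct fatigue slopes. In periodic mode the
#' sEMG is gated to the contraction phase of each movement cycle (Tukey
#' envelope, duty cycle `duty`), so the true active intervals are known;
#' axis 1 of the accelerometer carries the movement and the other two
#' axes carry attenuated crosstalk plus noise.
#'
#' @param muscles List of per-muscle specs `list(label, f0, slope)`;
#'   defaults to the three-muscle roster with slopes -0.25, -0.05 and
#'   -0.20 Hz/s from f0 = 100 Hz.
#' @param duration Session length in seconds (1 min protocol).
#' @param fs_semg,fs_acc Sensor sampling rates in Hz (reference hardware:
#'   4000 and 296).
#' @param mode `"sustained"` (self-weight hold) or `"periodic"` (paced
#'   lifts).
#' @param period Movement period in seconds for periodic mode.
#' @param duty Active fraction of each movement cycle (periodic mode).
#' @param snr SNR in dB applied to both modalities.
#' @param seed Integer seed; fully determines the session.
#' @return A `synthetic_session`: `muscles` (pipeline-ready channel sets)
#'   and `ground_truth` (per-muscle f0/slope, movement mode and period,
#'   active intervals in seconds, snr, seed).
#' @export
gen_session <- function(muscles = list(
                          list(label = "biceps_brachii", f0 = 100, slope = -0.25),
                          list(label = "anterior_deltoid", f0 = 100, slope = -0.05),
                          list(label = "triceps_brachii", f0 = 100, slope = -0.20)),
                        duration = 60, fs_semg = 4000, fs_acc = 296,
                        mode = c("sustained", "periodic"), period = 2.5,
                        duty = 0.4, snr = 20, seed = 1L) {
  mode <- match.arg(mode)
  if (length(muscles) < 1L) stop_input("gen_session: need at least one muscle spec")
  with_seed(seed, {
    out <- vector("list", length(muscles))
    truth <- vector("list", length(muscles))
    active_s <- if (mode == "periodic")
      active_intervals_s(duration, period, duty) else NULL
    for (i in seq_along(muscles)) {
      sp <- muscles[[i]]
      lab <- if (!is.null(sp$label)) sp$label else sprintf("muscle_%d", i)
      g <- gen_semg(duration, fs_semg,
                    f0 = if (is.null(sp$f0)) 100 else sp$f0,
                    slope = if (is.null(sp$slope)) -0.25 else sp$slope,
                    snr = snr, label = paste0(lab, "_semg"))
      semg <- g$channel
      if (mode == "periodic")
        semg <- channel_with(semg, semg$samples *
                               burst_envelope(length(semg$samples),
                                              semg$fs, active_s))
      acc_main <- gen_acceleration(duration, fs_acc, mode, period, snr,
                                   label = paste0(lab, "_acc_x"))$channel
      cross <- vapply(c("y", "z"), function(ax) stats::runif(1, 0.05, 0.15), 0)
      acc_rest <- lapply(seq_along(cross), function(j)
        signal_channel(cross[j] * acc_main$samples +
                         stats::rnorm(length(acc_main$samples),
                                      sd = 0.05 * stats::sd(acc_main$samples)),
                       fs_acc, paste0(lab, "_acc_", c("y", "z")[j]), "g"))
      out[[i]] <- list(label = lab, semg = semg,
                       acc = c(list(acc_main), acc_rest))
      truth[[i]] <- list(label = lab, f0 = g$truth$f0,
                         slope = g$truth$slope)
    }
    names(out) <- vapply(out, `[[`, "", "label")
    structure(
      list(muscles = out,
           ground_truth = list(
             muscles = truth, mode = mode,
             period = if (mode == "periodic") period else NA_real_,
             active_intervals_s = active_s, duty = duty,
             snr = snr, seed = seed, duration = duration,
             fs_semg = fs_semg, fs_acc = fs_acc)),
      class = "synthetic_session")
  })
}

# ground-truth active intervals [start, end) in seconds, one per cycle
active_intervals_s <- function(duration, period, duty) {
  starts <- seq(0, duration - period, by = period)
  cbind(start = starts, end = starts + duty * period)
}

# Tukey-edged gate over the active intervals; activation and release ramps
# are brief (5% of burst length) as in paced lifting
burst_envelope <- function(n, fs, intervals_s) {
  env <- numeric(n)
  for (r in seq_len(nrow(intervals_s))) {
    a <- floor(intervals_s[r, 1L] * fs) + 1L
    b <- min(n, ceiling(intervals_s[r, 2L] * fs))
    if (b <= a) next
    m <- b - a + 1L
    tp <- max(2L, round(0.05 * m))
    w <- rep(1, m)
    ramp <- 0.5 * (1 - cos(pi * seq_len(tp) / tp))
    w[seq_len(tp)] <- ramp
    w[(m - tp + 1L):m] <- rev(ramp)
    env[a:b] <- w
  }
  env
}

#' @export
print.synthetic_session <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf("<synthetic_session> %d muscle(s), %s, %.0f s @ %g/%g Hz, SNR %g dB, seed %s\n",
              length(x$muscles), gt$mode, gt$duration, gt$fs_semg,
              gt$fs_acc, gt$snr, format(gt$seed)))
  invisible(x)
}

#' Write a synthetic session to disk
#'
#' One channel CSV per muscle (sEMG + three acceleration axes) in the
#' [read_channels()] format, plus a `ground_truth.json` sidecar.
#'
#' @param session A `synthetic_session`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "synthetic_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in session$muscles)
    write_channels(c(list(m$semg), m$acc),
                   file.path(dir, paste0(m$label, ".csv")))
  gt <- session$ground_truth
  gt$active_intervals_s <- if (!is.null(gt$active_intervals_s))
    apply(gt$active_intervals_s, 1L, as.list)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}
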