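#' Lagged autocovariance of an acceleration channel
#'
#' Computes the mean-removed, unnormalized lagged product sum
#' \deqn{\phi(m) = \sum_{n=0}^{N-|m|-1} (x(n+m)-\mu)(x(n)-\mu)}
#' for lags `|m| <= floor(max_lag_fraction * N)` (the biased estimate; no
#' 1/N scaling). For real signals the series is symmetric, and the lag-0
#' value dominates every other lag. Computed via FFT so long records stay
#' cheap; an O(N^2) direct sum gives identical values to ~1e-12 relative.
#'
#' @param acc A [signal_channel()] (or plain numeric vector).
#' @param max_lag_fraction Maximum lag as a fraction of the signal length,
#'   in (0, 1]; 0.5 caps the lag at 50% of the record, where the biased
#'   estimate is still well supported.
#' @return A `covariance_series`: two-sided `lags` (samples), `values`,
#'   sample count `n` and mean `mu`.
#' @export
cross_covariance <- function(acc, max_lag_fraction = 0.5) {
  x <- if (inherits(acc, "signal_channel")) acc$samples else as.numeric(acc)
  n <- length(x)
  if (n < 3L) stop_input("cross_covariance: need at least 3 samples")
  if (!(max_lag_fraction > 0 && max_lag_fraction <= 1))
    stop_param("cross_covariance: max_lag_fraction must be in (0, 1]")
  max_lag <- min(floor(max_lag_fraction * n), n - 1L)
  mu <- mean(x)
  xd <- x - mu
  # linear (not circular) autocovariance via zero-padded FFT
  m <- stats::nextn(2L * n)
  X <- stats::fft(c(xd, numeric(m - n)))
  ac <- Re(stats::fft(X * Conj(X), inverse = TRUE)) / m
  pos <- ac[seq_len(max_lag + 1L)]
  structure(
    list(lags = seq.int(-max_lag, max_lag),
         values = c(rev(pos[-1L]), pos),
         n = n, mu = mu),
    class = "covariance_series"
  )
}

#' @export
print.covariance_series <- function(x, ...) {
  cat(sprintf("<covariance_series> N = %d, lags -%d..%d, phi(0) = %.6g\n",
              x$n, max(x$lags), max(x$lags), covariance_at(x, 0L)))
  invisible(x)
}

# value(s) at non-negative lag(s)
covariance_at <- function(cov, lag) {
  cov$values[match(lag, cov$lags)]
}

#' Local peaks of a covariance series
#'
#' Finds local peaks over the non-negative lags. Lag 0 is always a peak;
#' interior lags qualify when they are strict local maxima whose
#' topographic prominence (height above the higher of the two flanking
#' valleys, valleys delimited by the nearest larger value on each side)
#' reaches `prominence` times the lag-0 value. A prominence — rather than
#' value — floor is essential: measurement noise riding on a slowly
#' decaying covariance creates shallow wiggles whose values are close to
#' the lag-0 value but whose prominence is negligible. Peaks are returned
#' sorted by value (descending), ties broken towards the smaller lag.
#'
#' @param cov A `covariance_series`.
#' @param prominence Peak prominence floor as a fraction of the lag-0
#'   value; 0 keeps every strict local maximum.
#' @return A data frame with columns `lag`, `value` and `prominence`.
#' @export
find_local_peaks <- function(cov, prominence = 0.25) {
  stopifnot(inherits(cov, "covariance_series"))
  keep <- cov$lags >= 0L
  v <- cov$values[keep]
  lag <- cov$lags[keep]
  L <- length(v)
  v0 <- v[1L]
  peaks_lag <- 0L
  peaks_val <- v[1L]
  peaks_prom <- v[1L] - min(v)
  if (L >= 3L) {
    i <- 2L:(L - 1L)
    cand <- i[v[i] > v[i - 1L] & v[i] > v[i + 1L]]
    if (length(cand)) {
      prom <- peak_prominences(v, cand)
      ok <- prom >= prominence * max(v0, 0)
      peaks_lag <- c(peaks_lag, lag[cand[ok]])
      peaks_val <- c(peaks_val, v[cand[ok]])
      peaks_prom <- c(peaks_prom, prom[ok])
    }
  }
  ord <- order(-peaks_val, peaks_lag)
  data.frame(lag = peaks_lag[ord], value = peaks_val[ord],
             prominence = peaks_prom[ord])
}

# Topographic prominence of v at the (strict local maximum) indices `cand`:
# on each side, the valley is the minimum between the peak and the nearest
# strictly larger sample (series end if none); prominence = peak value
# minus the higher valley. Nearest-larger indices via a monotonic stack,
# valley minima via a sparse range-min table: O(n log n) overall.
peak_prominences <- function(v, cand) {
  n <- length(v)
  nge_l <- nearest_greater(v)
  nge_r <- (n + 1L) - rev(nearest_greater(rev(v)))
  tab <- rmq_build(v)
  lo_l <- rmq_query(tab, pmax(nge_l[cand], 0L) + 1L, cand - 1L)
  lo_r <- rmq_query(tab, cand + 1L, pmin(nge_r[cand], n + 1L) - 1L)
  v[cand] - pmax(lo_l, lo_r)
}

# index of the nearest element strictly greater than v[j] to the left
# (0 when none)
nearest_greater <- function(v) {
  n <- length(v)
  out <- integer(n)
  stack <- integer(n)
  top <- 0L
  for (j in seq_len(n)) {
    while (top > 0L && v[stack[top]] <= v[j]) top <- top - 1L
    out[j] <- if (top > 0L) stack[top] else 0L
    top <- top + 1L
    stack[top] <- j
  }
  out
}

rmq_build <- function(v) {
  n <- length(v)
  tabs <- list(v)
  k <- 1L
  while (2L^k <= n) {
    prev <- tabs[[k]]
    span <- 2L^(k - 1L)
    tabs[[k + 1L]] <- pmin(prev[seq_len(n - 2L * span + 1L)],
                           prev[seq_len(n - 2L * span + 1L) + span])
    k <- k + 1L
  }
  tabs
}

# vectorized min(v[a..b]); a <= b required
rmq_query <- function(tabs, a, b) {
  len <- b - a + 1L
  k <- as.integer(floor(log2(len)))
  out <- numeric(length(a))
  for (kk in unique(k)) {
    i <- which(k == kk)
    span <- 2L^kk
    out[i] <- pmin(tabs[[kk + 1L]][a[i]], tabs[[kk + 1L]][b[i] - span + 1L])
  }
  out
}

#' Periodic-movement decision
#'
#' A movement is declared periodic when the two largest local covariance
#' peaks are of comparable size:
#' \deqn{(Max_1 - Max_2)/Max_2 < \epsilon}
#' A genuinely periodic acceleration trace repeats, so the covariance peak
#' at one period approaches the lag-0 peak and the ratio tends to 0; for a
#' sustained hold the lag-0 peak stands alone. Fewer than two qualifying
#' peaks, or a non-positive second peak, yield a non-periodic decision.
#' The decision is invariant to amplitude scaling of the signal.
#'
#' @param cov A `covariance_series`.
#' @param epsilon Decision threshold on the dimensionless ratio; the
#'   default 2 admits a second peak at least a third of the largest.
#' @param prominence Passed to [find_local_peaks()].
#' @return A `periodicity_result` with fields `is_periodic`, `max1`,
#'   `max2`, `ratio`, `threshold`, `period_estimate` (samples; `NA` when
#'   non-periodic) and the peak table.
#' @export
detect_periodicity <- function(cov, epsilon = 2, prominence = 0.25) {
  stopifnot(inherits(cov, "covariance_series"))
  if (epsilon <= 0) stop_param("detect_periodicity: epsilon must be positive")
  peaks <- find_local_peaks(cov, prominence)
  res <- list(is_periodic = FALSE, max1 = peaks$value[1L], max2 = NA_real_,
              ratio = NA_real_, threshold = epsilon,
              period_estimate = NA_integer_, peaks = peaks)
  if (nrow(peaks) >= 2L && peaks$value[2L] > 0) {
    res$max2 <- peaks$value[2L]
    res$ratio <- (res$max1 - res$max2) / res$max2
    if (res$ratio < epsilon) {
      res$is_periodic <- TRUE
      pos <- peaks[peaks$lag > 0L, , drop = FALSE]
      res$period_estimate <- pos$lag[1L]
    }
  }
  structure(res, class = "periodicity_result")
}

#' @export
print.periodicity_result <- function(x, ...) {
  if (x$is_periodic) {
    cat(sprintf("<periodicity_result> periodic (ratio %.3f < %.3f), period ~ %d samples\n",
                x$ratio, x$threshold, x$period_estimate))
  } else {
    cat(sprintf("<periodicity_result> non-periodic (ratio %s, threshold %.3f)\n",
                ifelse(is.na(x$ratio), "n/a", sprintf("%.3f", x$ratio)), x$threshold))
  }
  invisible(x)
}

#' Segment periodic sEMG and connect the active parts
#'
#' During contraction-recovery movement only the contraction phase carries
#' muscle activity; the recovery phase contributes noise that would bias
#' the spectral estimate. Active samples are located by centered
#' moving power (window `rms_window` seconds): the threshold is the
#' midpoint between the quietest-decile and loudest-decile mean power,
#' which places interval edges at the half-in/half-out point of the moving
#' window, i.e. at the true burst boundary. Signals with no rest phase
#' (loud/quiet power ratio below `k^2`) are treated as fully active.
#' Period breakpoints, anchored at the global acceleration extremum, are
#' recorded for audit.
#'
#' @param semg,acc Aligned equal-length [signal_channel()] objects.
#' @param result A periodic `periodicity_result` for `acc`.
#' @param rms_window Moving-power window in seconds.
#' @param k Homogeneity guard (see above); also the classical onset factor.
#' @return A list: `signal` (the connected active-sEMG channel) and `map`
#'   (a `segment_map` with `breakpoints`, `active_intervals` as 0-based
#'   half-open sample intervals, and `connected_length`).
#' @export
segment_and_connect <- function(semg, acc, result, rms_window = 0.125, k = 3) {
  stopifnot(inherits(semg, "signal_channel"), inherits(acc, "signal_channel"),
            inherits(result, "periodicity_result"))
  if (!result$is_periodic)
    stop_input("segment_and_connect: movement was not classified as periodic")
  n <- length(semg$samples)
  if (n != length(acc$samples))
    stop_input("segment_and_connect: sEMG and acceleration must be aligned (equal length)")
  P <- result$period_estimate
  w <- max(3L, round(rms_window * semg$fs))
  if (w %% 2L == 0L) w <- w + 1L
  # double moving average (~triangular kernel) steadies the short-window
  # power of band-limited noise, which has few independent samples per w
  pow <- moving_mean(moving_mean(semg$samples^2, w), w)
  if (max(pow) <= 0)
    stop_input("segment_and_connect: sEMG carries no activity (all zero)")
  qs <- stats::quantile(pow, c(0.1, 0.9), names = FALSE)
  p_low <- mean(pow[pow <= qs[1L]])
  p_high <- mean(pow[pow >= qs[2L]])
  active <- if (p_high < k^2 * max(p_low, .Machine$double.xmin)) {
    rep(TRUE, n)  # homogeneous activity: no rest phases to cut
  } else {
    # Midpoint-power threshold between the rest and contraction plateaus:
    # a centered window straddling a burst edge holds half burst power, so
    # the crossing falls on the edge itself. Plateau levels are class
    # medians (robust to the heavy-tailed fluctuation of short-window
    # power), iterated from a rough decile split.
    thr <- (qs[1L] + qs[2L]) / 2
    for (it in 1:3) {
      m_lo <- stats::median(pow[pow <= thr])
      m_hi <- stats::median(pow[pow > thr])
      if (!is.finite(m_hi)) break
      thr <- (m_lo + m_hi) / 2
    }
    a <- pow > thr
    a <- close_runs(a, FALSE, w)  # bridge sub-window dropouts inside bursts
    close_runs(a, TRUE, w)        # drop sub-window islands in rest phases
  }
  if (!any(active))
    stop_input("segment_and_connect: no interval exceeds the activity threshold")
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- cbind(start = starts[r$values] - 1L, end = ends[r$values])  # 0-based half-open
  anchor <- (which.max(abs(acc$samples - mean(acc$samples))) - 1L) %% P
  map <- structure(
    list(breakpoints = seq.int(anchor, n, by = P),
         active_intervals = iv,
         connected_length = sum(iv[, "end"] - iv[, "start"]),
         period = P),
    class = "segment_map"
  )
  connected <- channel_with(semg, semg$samples[active],
                            label = paste0(semg$label, " (connected)"))
  list(signal = connected, map = map)
}

#' @export
print.segment_map <- function(x, ...) {
  cat(sprintf("<segment_map> %d active interval(s), %d connected samples, period %d samples\n",
              nrow(x$active_intervals), x$connected_length, x$period))
  invisible(x)
}

# flip runs of `value` shorter than `minlen` (morphological close/open)
close_runs <- function(x, value, minlen) {
  r <- rle(x)
  r$values[r$values == value & r$lengths < minlen] <- !value
  inverse.rle(r)
}

# centered moving average with shrinking symmetric edges, via cumsum
moving_mean <- function(x, w) {
  n <- length(x)
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  h <- pmin(half, i - 1L, n - i)
  (cs[i + h + 1L] - cs[i - h]) / (2L * h + 1L)
}
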