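#' Centered moving-average smoother
#'
#' Used before differentiating fatigue levels (raw finite differences of a
#' noisy level series are unusable) and for display smoothing of computed
#' trajectories. The window must be odd; at the edges it shrinks
#' symmetrically. `window = 1` is the identity.
#'
#' @param series Numeric vector.
#' @param window Odd positive integer window length in samples.
#' @return Smoothed numeric vector, same length.
#' @export
smooth_series <- function(series, window) {
  x <- as.numeric(series)
  if (!is.numeric(window) || length(window) != 1L || window < 1 ||
      window %% 2 == 0)
    stop_param("smooth_series: window must be an odd positive integer")
  if (window == 1L || length(x) == 1L) return(x)
  moving_mean(x, as.integer(window))
}

#' Gradient-normalized fusion weights
#'
#' The contribution of each muscle to the overall fatigue level is
#' proportional to how fast its localized level is changing:
#' \deqn{\alpha_i = \|\nabla l_{fatigue,i}\| / \sum_j \|\nabla l_{fatigue,j}\|}
#' Gradients are finite differences of the smoothed level series. In the
#' default causal mode (the system is an online tracker) the weight at
#' step `t` uses only levels observed up to `t`: trailing moving-average
#' smoothing followed by a backward difference. `causal = FALSE` uses
#' centered smoothing and central differences over the whole record.
#' Where every gradient vanishes (including the first step) the weights
#' fall back to uniform `1/N_m`.
#'
#' @param trajectories List of [fatigue_trajectory()] objects on a common
#'   time grid.
#' @param smoothing_window Odd moving-average window (samples).
#' @param causal Per-step causal weights (default) or whole-record.
#' @return A `fusion_weights` object: a `T x N_m` matrix of non-negative
#'   weights, each row summing to 1.
#' @export
gradient_weights <- function(trajectories, smoothing_window = 9, causal = TRUE) {
  if (inherits(trajectories, "fatigue_trajectory"))
    trajectories <- list(trajectories)
  nm <- length(trajectories)
  if (nm < 1L) stop_input("gradient_weights: need at least one trajectory")
  stopifnot(all(vapply(trajectories, inherits, TRUE, "fatigue_trajectory")))
  times <- trajectories[[1L]]$times
  for (tr in trajectories)
    if (length(tr$times) != length(times) ||
        max(abs(tr$times - times)) > 1e-9)
      stop_input("gradient_weights: trajectories are not on a common time grid")
  if (smoothing_window < 1 || smoothing_window %% 2 == 0)
    stop_param("gradient_weights: smoothing_window must be odd and >= 1")
  grads <- vapply(trajectories, function(tr) {
    if (causal) {
      s <- trailing_mean(tr$levels, smoothing_window)
      c(0, diff(s))
    } else {
      s <- smooth_series(tr$levels, smoothing_window)
      central_diff(s)
    }
  }, numeric(length(times)))
  grads <- matrix(abs(grads), ncol = nm)
  rs <- rowSums(grads)
  w <- grads / ifelse(rs > 0, rs, 1)
  w[rs == 0, ] <- 1 / nm
  colnames(w) <- vapply(trajectories, `[[`, "", "muscle")
  structure(w, class = c("fusion_weights", class(w)))
}

trailing_mean <- function(x, w) {
  n <- length(x)
  cs <- cumsum(x)
  i <- seq_len(n)
  lo <- pmax(i - w, 0L)
  (cs[i] - c(0, cs)[lo + 1L]) / (i - lo)
}

central_diff <- function(x) {
  n <- length(x)
  if (n == 1L) return(0)
  g <- numeric(n)
  g[1L] <- x[2L] - x[1L]
  g[n] <- x[n] - x[n - 1L]
  if (n > 2L) g[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / 2
  g
}

#' Fuse localized fatigue levels at one time step
#'
#' Weighted average `L = sum_i alpha_i * l_i` with convex weights; the
#' result always lies between the smallest and largest localized level.
#'
#' @param levels Numeric vector of localized fatigue levels.
#' @param weights Numeric vector of weights (non-negative, summing to 1
#'   within 1e-9), e.g. one row of a `fusion_weights` matrix.
#' @return The overall fatigue level (dimensionless).
#' @export
fuse <- function(levels, weights) {
  levels <- as.numeric(levels)
  weights <- as.numeric(weights)
  if (length(levels) != length(weights))
    stop_input("fuse: levels and weights must have equal length")
  if (any(weights < -1e-12))
    stop_invariant("fuse: weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9)
    stop_invariant("fuse: weights must sum to 1 (got %.12g)", sum(weights))
  sum(levels * weights)
}

#' @export
print.fusion_weights <- function(x, ...) {
  cat(sprintf("<fusion_weights> %d step(s) x %d muscle(s); final: %s\n",
              nrow(x), ncol(x),
              paste(sprintf("%.3f", x[nrow(x), ]), collapse = " ")))
  invisible(x)
}
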