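#' Forgetting-factor recursive least squares for the mean-frequency slope
#'
#' During fatiguing work the sEMG mean frequency declines approximately
#' linearly with working time, `f_mean(t) = phi * t + intercept`. The slope
#' `phi` is tracked online by scalar recursive least squares with
#' exponential forgetting:
#' \deqn{\hat\phi_t = \hat\phi_{t-1} +
#'       \frac{p_{t-1} t}{\lambda + t^2 p_{t-1}}
#'       (y_t - \hat\phi_{t-1} t)}
#' \deqn{p_t = \frac{p_{t-1}}{\lambda + t^2 p_{t-1}}}
#' `lambda = 1` keeps all history (the recursion reproduces batch
#' through-origin least squares); `lambda = 0` uses only the current
#' sample, for which `p_t = t^-2` exactly. The recursion is a restricted
#' Kalman filter whose responsiveness to slope changes grows as `lambda`
#' decreases. `p0` must be large (default 10000) so the prior carries
#' negligible weight.
#'
#' @param lambda Forgetting factor in \[0, 1\].
#' @param phi0 Initial slope estimate (Hz per time unit).
#' @param p0 Initial gain state (> 0, "relatively large").
#' @return `rls_init()`: an `rls_state` with `phi`, `p`, `lambda`, last
#'   time `t` (0) and `count` (0).
#' @export
rls_init <- function(lambda = 0.95, phi0 = 0, p0 = 10000) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
    stop_param("rls_init: lambda must be a scalar in [0, 1]")
  if (!is.numeric(p0) || length(p0) != 1L || !is.finite(p0) || p0 <= 0)
    stop_param("rls_init: p0 must be positive (and relatively large)")
  if (!is.finite(phi0)) stop_param("rls_init: phi0 must be finite")
  structure(list(phi = phi0, p = p0, lambda = lambda, t = 0, count = 0L),
            class = "rls_state")
}

#' @rdname rls_init
#' @param state An `rls_state`.
#' @param t Observation time (strictly greater than the previous one).
#' @param f_mean_t Observed (possibly de-meaned) mean frequency at `t`.
#' @return `rls_update()`: the updated `rls_state`.
#' @export
rls_update <- function(state, t, f_mean_t) {
  stopifnot(inherits(state, "rls_state"))
  if (!is.finite(f_mean_t)) stop_input("rls_update: observation must be finite")
  if (!is.finite(t) || t <= state$t)
    stop_sequence("rls_update: time must increase (got t = %g after %g)", t, state$t)
  denom <- state$lambda + t^2 * state$p  # > 0 whenever p > 0, lambda >= 0
  gain <- state$p * t / denom
  state$phi <- state$phi + gain * (f_mean_t - state$phi * t)
  state$p <- state$p / denom
  if (state$p <= 0)
    stop_invariant("rls_update: gain state lost positivity (p = %g)", state$p)
  state$t <- t
  state$count <- state$count + 1L
  state
}

#' @export
print.rls_state <- function(x, ...) {
  cat(sprintf("<rls_state> phi = %.6g, p = %.6g, lambda = %g, %d update(s), t = %g\n",
              x$phi, x$p, x$lambda, x$count, x$t))
  invisible(x)
}

#' Localized fatigue trajectory container
#'
#' The localized fatigue level is the tracked relative decrease of the
#' mean frequency from its initial value:
#' `l_fatigue(t) = phi_hat(t) * t / f0` (dimensionless, negative under
#' fatigue, conventionally reported in percent). `l_fatigue(0) = 0`.
#'
#' @param muscle Muscle label.
#' @param times,levels,slopes Equal-length numeric vectors.
#' @param f0 Initial mean frequency (Hz), `NA` when unknown.
#' @param time_unit `"seconds"` or `"index"`.
#' @return A `fatigue_trajectory`.
#' @export
fatigue_trajectory <- function(muscle, times, levels, slopes,
                               f0 = NA_real_, time_unit = "seconds") {
  stopifnot(length(times) == length(levels), length(times) == length(slopes))
  if (!all(is.finite(levels))) stop_invariant("fatigue_trajectory: levels must be finite")
  structure(
    list(muscle = as.character(muscle)[1L], times = as.numeric(times),
         levels = as.numeric(levels), slopes = as.numeric(slopes),
         f0 = f0, time_unit = time_unit),
    class = "fatigue_trajectory"
  )
}

#' @export
print.fatigue_trajectory <- function(x, ...) {
  n <- length(x$levels)
  cat(sprintf("<fatigue_trajectory> %s: %d steps (%s), final slope %.4g, final level %.1f%%\n",
              x$muscle, n, x$time_unit, x$slopes[n], 100 * x$levels[n]))
  invisible(x)
}

#' Track the localized fatigue level of one muscle
#'
#' Runs the forgetting-factor recursion over a mean-frequency trajectory
#' and converts the tracked slope to a fatigue level. By default the
#' ordinate is de-meaned (`y_t = f_mean(t) - f0`) so the ~100 Hz spectral
#' baseline is absorbed as the model intercept and the through-origin
#' regressor sees only the decline; the level is then
#' `l(t) = phi_hat(t) * t / f0`, which starts at 0 for an unfatigued
#' muscle. `demean = FALSE` regresses the raw ordinate (the literal
#' through-origin form) for comparison.
#'
#' @param series A [mean_frequency_series()].
#' @param lambda,phi0,p0 RLS settings (see [rls_init()]).
#' @param demean De-mean the ordinate by `f0` (default TRUE).
#' @param muscle Label stored on the trajectory.
#' @return A [fatigue_trajectory()].
#' @export
track_fatigue <- function(series, lambda = 0.95, phi0 = 0, p0 = 10000,
                          demean = TRUE, muscle = "muscle") {
  stopifnot(inherits(series, "mean_frequency_series"))
  f0 <- series$f0
  if (!is.finite(f0) || f0 <= 0)
    stop_input("track_fatigue: initial mean frequency must be positive (got %g)", f0)
  n <- length(series$values)
  y <- if (demean) series$values - f0 else series$values
  state <- rls_init(lambda, phi0, p0)
  slopes <- numeric(n)
  for (i in seq_len(n)) {
    state <- rls_update(state, series$times[i], y[i])
    slopes[i] <- state$phi
  }
  levels <- slopes * series$times / f0
  levels[1L] <- 0  # the initial moment is the non-fatigued reference
  fatigue_trajectory(muscle, series$times, levels, slopes,
                     f0 = f0, time_unit = series$time_unit)
}

#' F-test of the linear mean-frequency model
#'
#' Verifies that working time predicts the mean frequency: simple linear
#' regression of `f_mean` on time, with the ANOVA F statistic
#' `F = MSR / MSE` on (1, n-2) degrees of freedom testing the null of zero
#' slope at the 5% level. A numerically perfect fit is reported as
#' `F = Inf`, `p = 0`.
#'
#' @param times,values Equal-length numeric vectors (n >= 3; times not all
#'   equal). A `mean_frequency_series` may be given as `times` instead.
#' @return An object of classes `linearity_ftest` and `htest` with the F
#'   statistic, degrees of freedom, p value, and slope/intercept estimates.
#' @export
linearity_ftest <- function(times, values = NULL) {
  if (inherits(times, "mean_frequency_series")) {
    values <- times$values
    times <- times$times
  }
  n <- length(times)
  if (n < 3L || n != length(values))
    stop_input("linearity_ftest: need n >= 3 paired observations")
  if (stats::var(times) == 0)
    stop_input("linearity_ftest: times must not all be equal")
  fit <- stats::lm(values ~ times)
  an <- suppressWarnings(stats::anova(fit))  # perfect fits handled below
  ss_res <- an[["Sum Sq"]][2L]
  ss_tot <- sum(an[["Sum Sq"]])
  if (ss_tot == 0 || ss_res <= 1e-12 * ss_tot) {
    f_stat <- Inf
    p_val <- 0
  } else {
    f_stat <- an[["F value"]][1L]
    p_val <- an[["Pr(>F)"]][1L]
  }
  co <- stats::coef(fit)
  structure(
    list(statistic = c(F = f_stat),
         parameter = c(df1 = 1, df2 = n - 2L),
         p.value = p_val,
         estimate = c(slope = unname(co[2L]), intercept = unname(co[1L])),
         n = n,
         method = "ANOVA F-test of the linear mean-frequency model (H0: slope = 0)",
         data.name = "mean frequency vs working time"),
    class = c("linearity_ftest", "htest")
  )
}
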