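#' Pipeline run configuration
#'
#' Collects every tunable of the fatigue-tracking pipeline with defaults
#' matching the reference sensor setup: sEMG low-pass corners Wp = 0.1,
#' Ws = 0.4 (fractions of Nyquist), acceleration corners 0.003 / 0.006,
#' both with 3 dB ripple and 40 dB attenuation; 0.125 s analysis windows
#' with 0.063 s overlap; forgetting factor lambda = 0.95 with initial slope
#' 0 and gain state p0 = 10000; periodicity threshold epsilon = 2 with the
#' covariance lag capped at 50% of the signal.
#'
#' @param semg_filter,acc_filter Named lists `list(Wp, Ws, Rp, Rs)` of
#'   normalized corner frequencies and dB specs per modality.
#' @param window_length,window_overlap Moving-window settings in seconds.
#' @param lambda Forgetting factor in \[0, 1\].
#' @param phi0,p0 Initial RLS slope estimate and gain state (p0 > 0).
#' @param epsilon Periodicity decision threshold on the normalized peak
#'   ratio (dimensionless).
#' @param max_lag_fraction Covariance maximum lag as a fraction of the
#'   signal length, in (0, 1\].
#' @param peak_prominence Topographic-prominence floor for covariance
#'   peaks, as a fraction of the lag-0 value (see [find_local_peaks()]).
#' @param activity_k Dynamic-range guard for sEMG activity segmentation:
#'   signals whose loud/quiet moving-power ratio is below `activity_k^2`
#'   are treated as fully active.
#' @param smoothing_window Moving-average window (samples, odd) used when
#'   differentiating fatigue levels for fusion weights.
#' @param f0_windows Number of initial windows averaged into the initial
#'   mean frequency f0 (1 reproduces the literal single-window definition).
#' @param taper Per-window taper for spectral estimation: `"hann"`
#'   (default) or `"rectangular"`.
#' @param zero_phase Apply filters forward-backward (default) or causally.
#' @param filter_first Filter before resampling (default) or after.
#' @param demean_regression Regress `f_mean - f0` on time (default), so the
#'   spectral baseline is absorbed as the model intercept; `FALSE` uses the
#'   literal through-origin form.
#' @param causal_weights Recompute fusion weights per time step from the
#'   trajectory seen so far (default); `FALSE` uses whole-record central
#'   gradients.
#' @param axis_select How to reduce tri-axial acceleration to one series:
#'   `"variance"` (axis with largest variance, default) or `"magnitude"`
#'   (Euclidean norm of the three axes).
#' @param fusion_weights Optional fixed fusion weights (non-negative,
#'   summing to 1); overrides gradient weighting when supplied.
#' @param seed Optional integer seed recorded in run reports.
#' @return A `run_config` object (a validated named list).
#' @export
run_config <- function(semg_filter = list(Wp = 0.1, Ws = 0.4, Rp = 3, Rs = 40),
                       acc_filter = list(Wp = 0.003, Ws = 0.006, Rp = 3, Rs = 40),
                       window_length = 0.125,
                       window_overlap = 0.063,
                       lambda = 0.95,
                       phi0 = 0,
                       p0 = 10000,
                       epsilon = 2,
                       max_lag_fraction = 0.5,
                       peak_prominence = 0.25,
                       activity_k = 3,
                       smoothing_window = 9,
                       f0_windows = 5,
                       taper = c("hann", "rectangular"),
                       zero_phase = TRUE,
                       filter_first = TRUE,
                       demean_regression = TRUE,
                       causal_weights = TRUE,
                       axis_select = c("variance", "magnitude"),
                       fusion_weights = NULL,
                       seed = NULL) {
  taper <- match.arg(taper)
  axis_select <- match.arg(axis_select)
  if (!(lambda >= 0 && lambda <= 1))
    stop_param("run_config: lambda must be in [0, 1]")
  if (!(window_overlap > 0 && window_overlap < window_length))
    stop_param("run_config: need 0 < window_overlap < window_length")
  if (!(max_lag_fraction > 0 && max_lag_fraction <= 1))
    stop_param("run_config: max_lag_fraction must be in (0, 1]")
  if (p0 <= 0) stop_param("run_config: p0 must be positive")
  if (epsilon <= 0) stop_param("run_config: epsilon must be positive")
  if (smoothing_window < 1 || smoothing_window %% 2 == 0)
    stop_param("run_config: smoothing_window must be odd and >= 1")
  if (f0_windows < 1) stop_param("run_config: f0_windows must be >= 1")
  if (!is.null(fusion_weights)) {
    if (any(fusion_weights < 0) || abs(sum(fusion_weights) - 1) > 1e-9)
      stop_param("run_config: fusion_weights must be non-negative and sum to 1")
  }
  structure(
    list(semg_filter = semg_filter, acc_filter = acc_filter,
         window_length = window_length, window_overlap = window_overlap,
         lambda = lambda, phi0 = phi0, p0 = p0, epsilon = epsilon,
         max_lag_fraction = max_lag_fraction,
         peak_prominence = peak_prominence, activity_k = activity_k,
         smoothing_window = as.integer(smoothing_window),
         f0_windows = as.integer(f0_windows), taper = taper,
         zero_phase = zero_phase, filter_first = filter_first,
         demean_regression = demean_regression,
         causal_weights = causal_weights, axis_select = axis_select,
         fusion_weights = fusion_weights, seed = seed),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path Path of a YAML file mirroring the `run_config()` arguments.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_input("read_run_config: no such file: %s", path)
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop_format("read_run_config: %s is not a YAML mapping", path)
  known <- names(formals(run_config))
  extra <- setdiff(names(vals), known)
  if (length(extra))
    stop_format("read_run_config: unknown fields: %s", paste(extra, collapse = ", "))
  do.call(run_config, vals)
}

#' @rdname run_config
#' @param config A `run_config` object.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
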