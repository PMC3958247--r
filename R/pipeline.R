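#' Run the full fatigue-tracking pipeline
#'
#' Executes the complete per-muscle chain and the final fusion:
#' \enumerate{
#'   \item design the Butterworth pre-filters and filter each channel;
#'   \item resample sEMG onto the acceleration rate (common length);
#'   \item decide periodic vs sustained movement from the acceleration
#'         autocovariance;
#'   \item for periodic movement, segment and concatenate the active sEMG
#'         (sustained movement skips this branch);
#'   \item compute the moving-window mean-frequency trajectory and its
#'         initial value f0;
#'   \item track the slope with forgetting-factor RLS and convert to the
#'         localized fatigue level;
#'   \item F-test the linear model as a per-muscle diagnostic;
#'   \item fuse localized levels with gradient-normalized weights.
#' }
#' Time is measured in seconds for sustained movement and in window index
#' for connected (segmented) signals. For fusion, trajectories are
#' truncated to the shortest and aligned by step index; the run report
#' records every decision.
#'
#' @param session A list of muscles; each muscle is a list with elements
#'   `label`, `semg` (a [signal_channel()]) and `acc` (a `signal_channel`
#'   or list of up to three axis channels). [gen_session()] produces this
#'   structure.
#' @param config A [run_config()].
#' @return A `fatigue_run`: `trajectories` (per-muscle
#'   [fatigue_trajectory()]), `overall` (an `overall_fatigue` with `times`,
#'   `levels`, `weights`), `report` (nested list, JSON-serializable) and
#'   the `config`.
#' @export
run_pipeline <- function(session, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (inherits(session, "synthetic_session")) session <- session$muscles
  if (!is.list(session) || length(session) < 1L)
    stop_input("run_pipeline: session must contain at least one muscle")
  semg_spec <- do.call(design_butterworth, config$semg_filter)
  acc_spec <- do.call(design_butterworth, config$acc_filter)

  trajectories <- list()
  muscle_reports <- list()
  for (i in seq_along(session)) {
    m <- session[[i]]
    label <- if (!is.null(m$label)) m$label else sprintf("muscle_%d", i)
    res <- tryCatch(
      process_muscle(m, label, semg_spec, acc_spec, config),
      fatiguetrack_error = function(e) {
        e$message <- sprintf("[%s] %s", label, conditionMessage(e))
        stop(e)
      })
    trajectories[[label]] <- res$trajectory
    muscle_reports[[label]] <- res$report
  }

  nmin <- min(vapply(trajectories, function(tr) length(tr$levels), 0L))
  units <- unique(vapply(trajectories, `[[`, "", "time_unit"))
  trunc <- lapply(trajectories, function(tr)
    fatigue_trajectory(tr$muscle, seq_len(nmin), tr$levels[seq_len(nmin)],
                       tr$slopes[seq_len(nmin)], tr$f0, "index"))
  weights <- if (!is.null(config$fusion_weights)) {
    if (length(config$fusion_weights) != length(trunc))
      stop_input("run_pipeline: fusion_weights length must equal muscle count")
    matrix(config$fusion_weights, nrow = nmin, ncol = length(trunc),
           byrow = TRUE, dimnames = list(NULL, names(trunc)))
  } else {
    gradient_weights(trunc, config$smoothing_window, config$causal_weights)
  }
  lv <- vapply(trunc, `[[`, numeric(nmin), "levels")
  lv <- matrix(lv, nrow = nmin)
  overall_levels <- rowSums(lv * weights)
  overall_times <- if (length(units) == 1L && units == "seconds")
    trajectories[[1L]]$times[seq_len(nmin)] else seq_len(nmin)
  overall <- structure(
    list(times = overall_times, levels = overall_levels, weights = weights),
    class = "overall_fatigue")

  report <- list(
    muscles = muscle_reports,
    overall = list(
      final_level = overall_levels[nmin],
      n_steps = nmin,
      time_unit = if (length(units) == 1L) units else "index",
      mixed_time_units = length(units) > 1L,
      weight_mode = if (!is.null(config$fusion_weights)) "fixed"
                    else if (config$causal_weights) "causal_gradient"
                    else "full_gradient"),
    settings = list(lambda = config$lambda, p0 = config$p0,
                    epsilon = config$epsilon,
                    window_length = config$window_length,
                    window_overlap = config$window_overlap,
                    seed = config$seed))
  structure(list(trajectories = trajectories, overall = overall,
                 report = report, config = config),
            class = "fatigue_run")
}

# one muscle through steps 1-7; returns trajectory + report entry
process_muscle <- function(m, label, semg_spec, acc_spec, config) {
  if (is.null(m$semg) || !inherits(m$semg, "signal_channel"))
    stop_input("muscle is missing its sEMG channel")
  acc_axes <- m$acc
  if (inherits(acc_axes, "signal_channel")) acc_axes <- list(acc_axes)
  if (is.null(acc_axes) || !length(acc_axes) ||
      !all(vapply(acc_axes, inherits, TRUE, "signal_channel")))
    stop_input("muscle is missing acceleration channel(s)")

  filt <- function(ch, spec) apply_filter(ch, spec, config$zero_phase)
  semg <- m$semg
  if (config$filter_first) {
    semg <- filt(semg, semg_spec)
    acc_axes <- lapply(acc_axes, filt, spec = acc_spec)
  }
  common <- resample_to_common(semg, acc_axes[[1L]])
  semg <- common$semg
  acc_axes <- c(list(common$acc),
                lapply(acc_axes[-1L], function(a) {
                  a <- resample_channel(a, common$acc$fs)
                  channel_with(a, a$samples[seq_len(length(semg$samples))])
                }))
  if (!config$filter_first) {
    semg <- filt(semg, semg_spec)
    acc_axes <- lapply(acc_axes, filt, spec = acc_spec)
  }
  acc <- select_acc_axis(acc_axes, config$axis_select)

  cov <- cross_covariance(acc, config$max_lag_fraction)
  per <- detect_periodicity(cov, config$epsilon, config$peak_prominence)

  seg <- NULL
  if (per$is_periodic) {
    sc <- segment_and_connect(semg, acc, per,
                              rms_window = config$window_length,
                              k = config$activity_k)
    semg <- sc$signal
    seg <- sc$map
    time_unit <- "index"
  } else {
    time_unit <- "seconds"
  }

  mfs <- mean_frequency_series(semg, config$window_length,
                               config$window_overlap, config$taper,
                               config$f0_windows, time_unit)
  traj <- track_fatigue(mfs, config$lambda, config$phi0, config$p0,
                        config$demean_regression, muscle = label)
  ft <- linearity_ftest(mfs)

  n <- length(traj$levels)
  list(trajectory = traj,
       report = list(
         label = label,
         periodic = per$is_periodic,
         peak_ratio = per$ratio,
         period_estimate = per$period_estimate,
         segmented = per$is_periodic,
         n_segments = if (is.null(seg)) 0L else nrow(seg$active_intervals),
         connected_length = if (is.null(seg)) NA_integer_ else seg$connected_length,
         f_mean_0 = mfs$f0,
         n_windows = length(mfs$values),
         final_slope = traj$slopes[n],
         final_level = traj$levels[n],
         ftest = list(F = unname(ft$statistic), p = ft$p.value,
                      slope = unname(ft$estimate["slope"]))))
}

select_acc_axis <- function(axes, how) {
  if (length(axes) == 1L) return(axes[[1L]])
  if (how == "magnitude") {
    mat <- vapply(axes, `[[`, numeric(length(axes[[1L]]$samples)), "samples")
    return(channel_with(axes[[1L]], sqrt(rowSums(mat^2)),
                        label = "acc_magnitude"))
  }
  vars <- vapply(axes, function(a) stats::var(a$samples), 0)
  axes[[which.max(vars)]]
}

#' @export
print.fatigue_run <- function(x, ...) {
  cat(sprintf("<fatigue_run> %d muscle(s), %d fused step(s)\n",
              length(x$trajectories), length(x$overall$levels)))
  for (r in x$report$muscles)
    cat(sprintf("  %-22s %-12s final level %6.1f%%  (F = %.1f, p = %.3g)\n",
                r$label, if (r$periodic) "periodic" else "sustained",
                100 * r$final_level, r$ftest$F, r$ftest$p))
  cat(sprintf("  overall final level: %.1f%%\n",
              100 * x$report$overall$final_level))
  invisible(x)
}

#' @export
print.overall_fatigue <- function(x, ...) {
  n <- length(x$levels)
  cat(sprintf("<overall_fatigue> %d step(s), final level %.1f%%\n",
              n, 100 * x$levels[n]))
  invisible(x)
}

#' Write the run report as JSON
#'
#' @param run A `fatigue_run` from [run_pipeline()].
#' @param path Output JSON path.
#' @export
write_run_report <- function(run, path) {
  stopifnot(inherits(run, "fatigue_run"))
  jsonlite::write_json(run$report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
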