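#' Read and write channel files
#'
#' Channel files are plain CSV with three metadata header rows followed by
#' one numeric column per channel:
#' ```
#' channel,biceps_brachii_semg,biceps_brachii_acc_x
#' units,V,g
#' fs,4000,296
#' 1.2e-05,0.013
#' ...
#' ```
#' Channels of unequal length are padded with empty fields; trailing blanks
#' are dropped on read. Samples are written with 17 significant digits so a
#' write/read/write cycle is lossless.
#'
#' @param path Path to the CSV file.
#' @return `read_channels()`: a named list of [signal_channel()] objects.
#' @export
read_channels <- function(path) {
  if (!file.exists(path)) stop_input("read_channels: no such file: %s", path)
  head <- readLines(path, n = 3L)
  if (length(head) < 3L)
    stop_format("read_channels: %s: missing metadata header (channel/units/fs rows)", path)
  rows <- strsplit(head, ",", fixed = TRUE)
  keys <- vapply(rows, `[[`, "", 1L)
  if (!identical(keys, c("channel", "units", "fs")))
    stop_format("read_channels: %s: header rows must be 'channel', 'units', 'fs'", path)
  labels <- rows[[1L]][-1L]
  units <- rows[[2L]][-1L]
  fs <- suppressWarnings(as.numeric(rows[[3L]][-1L]))
  if (length(labels) < 1L)
    stop_format("read_channels: %s: no channel columns", path)
  if (length(units) != length(labels) || length(fs) != length(labels) ||
      anyNA(fs))
    stop_format("read_channels: %s: units/fs metadata incomplete", path)
  dat <- utils::read.csv(path, skip = 3L, header = FALSE,
                         colClasses = "numeric",
                         col.names = labels, check.names = FALSE)
  out <- vector("list", length(labels))
  names(out) <- labels
  for (j in seq_along(labels)) {
    v <- dat[[j]]
    v <- v[seq_len(max(which(!is.na(v)), 0L))]
    if (length(v) == 0L)
      stop_format("read_channels: %s: channel '%s' has no samples", path, labels[j])
    out[[j]] <- signal_channel(v, fs[j], labels[j], units[j])
  }
  out
}

#' @param channels A (named) list of [signal_channel()] objects.
#' @rdname read_channels
#' @export
write_channels <- function(channels, path) {
  if (inherits(channels, "signal_channel")) channels <- list(channels)
  stopifnot(length(channels) >= 1L,
            all(vapply(channels, inherits, TRUE, "signal_channel")))
  labels <- vapply(channels, `[[`, "", "label")
  units <- vapply(channels, `[[`, "", "units")
  fs <- vapply(channels, `[[`, 0, "fs")
  nmax <- max(vapply(channels, function(ch) length(ch$samples), 0L))
  cols <- lapply(channels, function(ch) {
    v <- formatC(ch$samples, format = "g", digits = 17)
    c(v, rep("", nmax - length(v)))
  })
  lines <- c(
    paste(c("channel", labels), collapse = ","),
    paste(c("units", units), collapse = ","),
    paste(c("fs", formatC(fs, format = "g", digits = 17)), collapse = ","),
    do.call(paste, c(cols, sep = ","))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write fatigue trajectories to CSV
#'
#' Long-format CSV with columns `muscle`, `time`, `slope`, `level`; one row
#' per tracked time step per muscle.
#'
#' @param trajectories A list of `fatigue_trajectory` objects (or one).
#' @param path Output CSV path.
#' @export
write_trajectories <- function(trajectories, path) {
  if (inherits(trajectories, "fatigue_trajectory"))
    trajectories <- list(trajectories)
  stopifnot(all(vapply(trajectories, inherits, TRUE, "fatigue_trajectory")))
  df <- do.call(rbind, lapply(trajectories, function(tr) {
    data.frame(muscle = tr$muscle, time = tr$times,
               slope = tr$slopes, level = tr$levels)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @return `read_trajectories()`: a list of `fatigue_trajectory` objects.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop_input("read_trajectories: no such file: %s", path)
  df <- utils::read.csv(path)
  need <- c("muscle", "time", "slope", "level")
  if (!all(need %in% names(df)))
    stop_format("read_trajectories: %s: expected columns %s", path,
                paste(need, collapse = ", "))
  lapply(split(df, df$muscle), function(d)
    fatigue_trajectory(muscle = d$muscle[1L], times = d$time,
                       levels = d$level, slopes = d$slope))
}

#' Serialize a segment map for audit
#'
#' Active intervals are written as 0-based half-open `[start, end)` sample
#' indices, one row per interval.
#'
#' @param map A `segment_map` from [segment_and_connect()].
#' @param path Output CSV path.
#' @export
write_segment_map <- function(map, path) {
  stopifnot(inherits(map, "segment_map"))
  utils::write.csv(data.frame(start = map$active_intervals[, 1L],
                              end = map$active_intervals[, 2L]),
                   path, row.names = FALSE)
  invisible(path)
}
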