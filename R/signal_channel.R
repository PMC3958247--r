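#' Uniformly sampled signal channel
#'
#' The universal carrier for both sEMG and acceleration data: a real-valued
#' series with its sampling rate, a label (muscle + modality) and physical
#' units ("V" for sEMG, "g" for acceleration).
#'
#' @param samples Numeric vector of finite samples (length >= 1).
#' @param fs Sampling rate in Hz (> 0).
#' @param label Channel label, e.g. `"biceps_brachii_semg"`.
#' @param units Physical units of the samples, typically `"V"` or `"g"`.
#' @return An object of class `signal_channel`.
#' @examples
#' ch <- signal_channel(sin(2 * pi * 5 * (0:999) / 1000), fs = 1000,
#'                      label = "demo", units = "V")
#' channel_duration(ch)
#' @export
signal_channel <- function(samples, fs, label = "channel", units = "V") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L)
    stop_input("signal_channel: needs at least one sample")
  if (!all(is.finite(samples)))
    stop_input("signal_channel: samples must all be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_param("signal_channel: fs must be a single positive number")
  structure(
    list(samples = samples, fs = as.numeric(fs),
         label = as.character(label)[1L], units = as.character(units)[1L]),
    class = "signal_channel"
  )
}

#' @return `channel_duration()`: duration of the channel in seconds.
#' @rdname signal_channel
#' @param x A `signal_channel`.
#' @export
channel_duration <- function(x) {
  stopifnot(inherits(x, "signal_channel"))
  length(x$samples) / x$fs
}

#' @export
print.signal_channel <- function(x, ...) {
  cat(sprintf("<signal_channel> %s [%s]: %d samples @ %g Hz (%.3f s)\n",
              x$label, x$units, length(x$samples), x$fs,
              channel_duration(x)))
  invisible(x)
}

#' @export
length.signal_channel <- function(x) length(x$samples)

# internal: clone with new samples (and optionally fs / label suffix)
channel_with <- function(x, samples, fs = x$fs, label = x$label) {
  signal_channel(samples, fs, label, x$units)
}
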