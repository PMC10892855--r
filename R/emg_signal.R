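#' Construct a uniformly sampled EMG signal
#'
#' Container for a raw or filtered surface-EMG trace: a numeric amplitude
#' vector (arbitrary normalized units) plus its sampling rate in Hz.
#'
#' @param samples Numeric vector of finite amplitudes (non-empty).
#' @param sampling_rate Sampling rate in Hz (positive scalar).
#' @param channel_label Optional channel name, e.g. `"EDL"` or `"FDL"`.
#' @return An object of class `emg_signal` with fields `samples`,
#'   `sampling_rate` and `channel_label`.
#' @examples
#' sig <- emg_signal(sin(2 * pi * 50 * seq(0, 1, by = 1e-3)), 1000)
#' sig
#' @export
emg_signal <- function(samples, sampling_rate, channel_label = "EMG") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop_input("emg_signal: 'samples' must be non-empty")
  if (!all(is.finite(samples))) stop_input("emg_signal: all samples must be finite")
  if (!is_scalar_number(sampling_rate) || sampling_rate <= 0) {
    stop_config("emg_signal: 'sampling_rate' must be a positive number")
  }
  structure(
    list(samples = samples, sampling_rate = as.numeric(sampling_rate),
         channel_label = as.character(channel_label)),
    class = "emg_signal"
  )
}

#' @export
print.emg_signal <- function(x, ...) {
  dur <- length(x$samples) / x$sampling_rate
  cat(sprintf("<emg_signal> channel '%s': %d samples @ %g Hz (%.3f s)\n",
              x$channel_label, length(x$samples), x$sampling_rate, dur))
  cat(sprintf("  amplitude range [%.4g, %.4g], RMS %.4g\n",
              min(x$samples), max(x$samples), sqrt(mean(x$samples^2))))
  invisible(x)
}

#' @export
length.emg_signal <- function(x) length(x$samples)

#' @export
plot.emg_signal <- function(x, ...) {
  t <- (seq_along(x$samples) - 1) / x$sampling_rate
  plot(t, x$samples, type = "l", xlab = "time (s)",
       ylab = "amplitude (a.u.)", main = x$channel_label, ...)
  invisible(x)
}

#' Time axis of an EMG signal
#'
#' @param signal An [emg_signal()].
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
signal_times <- function(signal) {
  stopifnot(inherits(signal, "emg_signal"))
  (seq_along(signal$samples) - 1) / signal$sampling_rate
}

#' Construct an analysis window
#'
#' A fixed-length excerpt of an EMG trace on which the time-domain
#' features are computed.
#'
#' @param samples Numeric vector of at least 2 finite amplitudes.
#' @param start_time Start time of the window in seconds.
#' @return An object of class `analysis_window` with fields `samples`,
#'   `start_time` and `n` (the sample count).
#' @export
analysis_window <- function(samples, start_time = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop_input("analysis_window: need at least 2 samples")
  if (!all(is.finite(samples))) stop_input("analysis_window: all samples must be finite")
  structure(
    list(samples = samples, start_time = as.numeric(start_time),
         n = length(samples)),
    class = "analysis_window"
  )
}

#' @export
print.analysis_window <- function(x, ...) {
  cat(sprintf("<analysis_window> %d samples starting at %.4f s\n", x$n, x$start_time))
  invisible(x)
}
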