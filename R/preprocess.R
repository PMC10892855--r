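# Raw-EMG conditioning: Butterworth band-pass + 50 Hz notch, applied
# zero-phase (forward-backward), then segmentation into fixed windows.

#' Filter specification for EMG conditioning
#'
#' @param kind `"bandpass"` or `"notch"`.
#' @param low_hz,high_hz Band edges in Hz (band-pass only).
#' @param center_hz Notch center frequency in Hz (notch only).
#' @param order Butterworth order (per stage). Default 4 for the
#'   band-pass, 2 for the notch.
#' @param q_factor Notch quality factor; the stop band spans
#'   `center_hz / q_factor` Hz. Default 30 (about 1.7 Hz at 50 Hz).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("bandpass", "notch"),
                        low_hz = 10, high_hz = 2000,
                        center_hz = 50, order = NULL, q_factor = 30) {
  kind <- match.arg(kind)
  if (is.null(order)) order <- if (kind == "bandpass") 4L else 2L
  if (!is_scalar_number(order) || order < 1) stop_config("filter_spec: order must be >= 1")
  if (kind == "bandpass") {
    if (!(low_hz > 0 && low_hz < high_hz)) {
      stop_config("filter_spec: bandpass needs 0 < low_hz < high_hz")
    }
  } else {
    if (!(center_hz > 0)) stop_config("filter_spec: notch needs center_hz > 0")
    if (!(q_factor > 0)) stop_config("filter_spec: q_factor must be > 0")
  }
  structure(
    list(kind = kind, low_hz = low_hz, high_hz = high_hz,
         center_hz = center_hz, order = as.integer(order), q_factor = q_factor),
    class = "filter_spec"
  )
}

# Zero-phase Butterworth band-pass as a high-pass/low-pass cascade.
# Cascading keeps each stage numerically well-conditioned even when the
# low edge is a tiny fraction of Nyquist (10 Hz at 10 kHz).
bandpass_filter <- function(x, fs, low_hz, high_hz, order = 4L) {
  nyq <- fs / 2
  if (low_hz >= nyq) stop_config("bandpass: low edge ", low_hz, " Hz is at/above Nyquist (", nyq, " Hz)")
  if (high_hz >= nyq) {
    high_clipped <- 0.45 * fs
    warning(sprintf("bandpass: high edge %g Hz infeasible at fs = %g Hz; clipped to %g Hz",
                    high_hz, fs, high_clipped))
    high_hz <- high_clipped
  }
  hp <- signal::butter(order, low_hz / nyq, type = "high")
  lp <- signal::butter(order, high_hz / nyq, type = "low")
  signal::filtfilt(lp, signal::filtfilt(hp, x))
}

#' Band-pass filter an EMG signal
#'
#' Applies a zero-phase Butterworth band-pass (high-pass/low-pass
#' cascade, forward-backward filtering) reproducing the 10-2000 Hz
#' conditioning stage of the acquisition chain. When the upper edge is
#' infeasible at the signal's sampling rate it is clipped to
#' `0.45 * fs` with a warning.
#'
#' @param signal An [emg_signal()].
#' @param spec A band-pass [filter_spec()].
#' @return A filtered [emg_signal()] of identical length and rate.
#' @export
emg_bandpass <- function(signal, spec = filter_spec("bandpass")) {
  stopifnot(inherits(signal, "emg_signal"), inherits(spec, "filter_spec"))
  if (spec$kind != "bandpass") stop_config("emg_bandpass: spec kind must be 'bandpass'")
  y <- bandpass_filter(signal$samples, signal$sampling_rate,
                       spec$low_hz, spec$high_hz, spec$order)
  emg_signal(y, signal$sampling_rate, signal$channel_label)
}

#' Notch filter an EMG signal
#'
#' Removes power-line interference with a zero-phase Butterworth
#' band-stop of width `center_hz / q_factor` centred on the line
#' frequency (50 Hz by default).
#'
#' @inheritParams emg_bandpass
#' @param spec A notch [filter_spec()].
#' @return A filtered [emg_signal()] of identical length and rate.
#' @export
emg_notch <- function(signal, spec = filter_spec("notch")) {
  stopifnot(inherits(signal, "emg_signal"), inherits(spec, "filter_spec"))
  if (spec$kind != "notch") stop_config("emg_notch: spec kind must be 'notch'")
  nyq <- signal$sampling_rate / 2
  if (spec$center_hz >= nyq) {
    stop_config("notch: center ", spec$center_hz, " Hz is at/above Nyquist (", nyq, " Hz)")
  }
  bw <- spec$center_hz / spec$q_factor
  edges <- c(spec$center_hz - bw / 2, spec$center_hz + bw / 2) / nyq
  bs <- signal::butter(spec$order, edges, type = "stop")
  y <- signal::filtfilt(bs, signal$samples)
  emg_signal(y, signal$sampling_rate, signal$channel_label)
}

#' Segment a signal into fixed-length analysis windows
#'
#' Splits the trace into windows of `window_seconds` with the requested
#' fractional overlap; a trailing partial window is discarded. A window
#' longer than the signal yields an empty list (not an error).
#'
#' @param signal An [emg_signal()].
#' @param window_seconds Window length in seconds (default 0.2 s).
#' @param overlap_fraction Fractional overlap between consecutive
#'   windows, in `[0, 1)` (default 0.5).
#' @return List of [analysis_window()] objects with strictly increasing
#'   start times.
#' @examples
#' sig <- emg_signal(rnorm(10000), 10000)
#' length(segment_windows(sig, 0.2, 0))    # 5 windows
#' length(segment_windows(sig, 0.2, 0.5))  # 9 windows
#' @export
segment_windows <- function(signal, window_seconds = 0.2, overlap_fraction = 0.5) {
  stopifnot(inherits(signal, "emg_signal"))
  if (!(overlap_fraction >= 0 && overlap_fraction < 1)) {
    stop_config("segment_windows: overlap_fraction must lie in [0, 1)")
  }
  fs <- signal$sampling_rate
  n_win <- round(window_seconds * fs)
  if (n_win < 2) stop_config("segment_windows: window must span at least 2 samples")
  hop <- max(1L, round(n_win * (1 - overlap_fraction)))
  n <- length(signal$samples)
  if (n_win > n) return(list())
  starts <- seq(1L, n - n_win + 1L, by = hop)
  lapply(starts, function(s) {
    analysis_window(signal$samples[s:(s + n_win - 1L)], start_time = (s - 1L) / fs)
  })
}
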