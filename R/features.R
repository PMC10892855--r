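# Time-domain EMG features computed per analysis window, plus the
# affine normalization that maps each feature onto the fuzzy input
# range [0, 10].

window_samples <- function(window) {
  if (inherits(window, "analysis_window")) window$samples else as.numeric(window)
}

#' Root mean square of a window
#'
#' `sqrt(mean(x^2))` — the amplitude feature tied to constant-force,
#' non-fatiguing contraction under the amplitude-modulated Gaussian
#' model of surface EMG.
#'
#' @param window An [analysis_window()] or numeric vector.
#' @return Non-negative scalar.
#' @export
emg_rms <- function(window) {
  x <- window_samples(window)
  sqrt(mean(x^2))
}

#' Simple square integral of a window
#'
#' The energy feature `sum(x^2)`. A first-power variant (`sum(x)`), the
#' non-squared form occasionally seen in print, is available via
#' `definition = "first_power"` for comparison; the energy form is the
#' default because SSI is defined as the signal's energy.
#'
#' @inheritParams emg_rms
#' @param definition `"energy"` (default, sum of squares) or
#'   `"first_power"` (plain sum).
#' @return Scalar; non-negative under the energy definition.
#' @export
emg_ssi <- function(window, definition = c("energy", "first_power")) {
  definition <- match.arg(definition)
  x <- window_samples(window)
  if (definition == "energy") sum(x^2) else sum(x)
}

#' v-order amplitude estimator of a window
#'
#' `(mean(|x|^v))^(1/v)`, a force-related amplitude estimator that
#' generalizes RMS (`v = 2` recovers it exactly). Default `v = 3`.
#'
#' @inheritParams emg_rms
#' @param v Positive order.
#' @return Non-negative scalar with amplitude units.
#' @export
emg_vorder <- function(window, v = 3) {
  if (!is_scalar_number(v) || v <= 0) stop_config("emg_vorder: v must be > 0")
  x <- window_samples(window)
  mean(abs(x)^v)^(1 / v)
}

#' Log detector of a window
#'
#' `exp(mean(log(|x| + epsilon)))` — a geometric-mean-style amplitude
#' estimator. The small `epsilon` guards zero samples, for which the
#' raw logarithm is undefined.
#'
#' @inheritParams emg_rms
#' @param epsilon Small positive guard added to `|x|` (default 1e-12).
#' @return Non-negative scalar.
#' @export
emg_logdetect <- function(window, epsilon = 1e-12) {
  if (!is_scalar_number(epsilon) || epsilon <= 0) {
    stop_config("emg_logdetect: epsilon must be > 0")
  }
  x <- window_samples(window)
  exp(mean(log(abs(x) + epsilon)))
}

#' Extract the four time-domain features of a window
#'
#' @inheritParams emg_rms
#' @inheritParams emg_vorder
#' @inheritParams emg_logdetect
#' @return Named numeric vector `c(rms, ssi, vorder, logdetect)`.
#' @examples
#' extract_features(analysis_window(c(3, 4)))
#' @export
extract_features <- function(window, v = 3, epsilon = 1e-12) {
  c(rms = emg_rms(window),
    ssi = emg_ssi(window),
    vorder = emg_vorder(window, v),
    logdetect = emg_logdetect(window, epsilon))
}

feature_names <- c("rms", "ssi", "vorder", "logdetect")

#' Fit a per-feature normalization map from a calibration series
#'
#' Records the observed minimum and maximum of each feature over a
#' calibration recording; [normalize_features()] then maps new values
#' affinely onto the fuzzy input range (0 to 10 by default), clipping
#' values that fall outside the calibration range.
#'
#' @param feature_series Numeric matrix or data frame with one row per
#'   window and columns `rms`, `ssi`, `vorder`, `logdetect` (at least
#'   2 rows).
#' @param target Two-element target range, default `c(0, 10)`.
#' @return An object of class `normalization_map`: per-feature rows
#'   `y_min`, `y_max`, `yn_min`, `yn_max`.
#' @export
fit_normalization <- function(feature_series, target = c(0, 10)) {
  m <- as.matrix(as.data.frame(feature_series)[, feature_names, drop = FALSE])
  if (nrow(m) < 2L) {
    stop_config("fit_normalization: need at least 2 windows to calibrate")
  }
  if (target[2] <= target[1]) stop_config("fit_normalization: invalid target range")
  y_min <- apply(m, 2, min)
  y_max <- apply(m, 2, max)
  flat <- y_max <= y_min
  if (any(flat)) {
    stop_config("fit_normalization: constant feature series for: ",
                paste(feature_names[flat], collapse = ", "))
  }
  structure(
    data.frame(feature = feature_names, y_min = y_min, y_max = y_max,
               yn_min = target[1], yn_max = target[2], row.names = feature_names),
    class = c("normalization_map", "data.frame")
  )
}

#' Normalize a feature value onto the fuzzy input range
#'
#' Affine map sending `y_min -> yn_min` and `y_max -> yn_max`
#' (0 and 10 by default); values outside the calibration range are
#' clipped to the target range, because the fuzzy variable domains are
#' hard bounds.
#'
#' @param value Numeric value(s) of one feature.
#' @param map A [fit_normalization()] result.
#' @param feature Which feature's map entry to use.
#' @return Normalized value(s) in `[yn_min, yn_max]`.
#' @export
normalize_feature <- function(value, map, feature = feature_names) {
  feature <- match.arg(feature)
  e <- map[feature, ]
  if (e$y_max <= e$y_min) {
    stop_config("normalize_feature: degenerate range for feature '", feature, "'")
  }
  yn <- (e$yn_max - e$yn_min) * (value - e$y_min) / (e$y_max - e$y_min) + e$yn_min
  clip(yn, e$yn_min, e$yn_max)
}

#' Normalize a full feature vector
#'
#' @param features Named vector or one-row data frame with the four
#'   feature values.
#' @param map A [fit_normalization()] result.
#' @return Named numeric vector of the four normalized features.
#' @export
normalize_features <- function(features, map) {
  features <- unlist(features)[feature_names]
  vapply(feature_names, function(f) normalize_feature(features[[f]], map, f),
         numeric(1))
}
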