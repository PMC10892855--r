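#' Configuration for the synthetic EMG generator
#'
#' Describes an amplitude-modulated Gaussian surface-EMG model: a white
#' Gaussian carrier shaped by a band-pass filter to the EMG band, then
#' multiplied by a contraction envelope, with optional 50 Hz power-line
#' interference, slow baseline drift and a white noise floor.
#'
#' @param sampling_rate Sampling rate in Hz; must exceed twice the upper
#'   band edge. Default 10000 Hz.
#' @param duration Trace duration in seconds.
#' @param contraction_profile Either a single intensity in `[0, 1]` or a
#'   function of time (seconds) returning intensities in `[0, 1]`.
#' @param emg_band Two-element numeric `(low, high)` pass band in Hz of
#'   the shaping filter. Default `c(10, 2000)`.
#' @param powerline_amplitude Relative amplitude of the 50 Hz
#'   interference sinusoid (0 disables it).
#' @param baseline_drift_amplitude Relative amplitude of a slow (< 5 Hz)
#'   baseline drift component.
#' @param noise_floor Relative standard deviation of additive white
#'   measurement noise.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return An object of class `synth_config`.
#' @seealso [generate_emg()]
#' @export
synth_config <- function(sampling_rate = 10000, duration = 1,
                         contraction_profile = 0.5,
                         emg_band = c(10, 2000),
                         powerline_amplitude = 0,
                         baseline_drift_amplitude = 0,
                         noise_floor = 0,
                         seed = 1L) {
  if (!is_scalar_number(sampling_rate) || sampling_rate <= 0) {
    stop_config("synth_config: sampling_rate must be positive")
  }
  if (!is_scalar_number(duration) || duration <= 0) {
    stop_config("synth_config: duration must be positive")
  }
  if (length(emg_band) != 2L || !all(is.finite(emg_band)) ||
      emg_band[1] <= 0 || emg_band[1] >= emg_band[2]) {
    stop_config("synth_config: emg_band must satisfy 0 < low < high")
  }
  if (sampling_rate <= 2 * emg_band[2]) {
    stop_config("synth_config: sampling_rate must exceed 2 * emg_band high edge (",
                2 * emg_band[2], " Hz)")
  }
  if (is.numeric(contraction_profile)) {
    level <- contraction_profile[1]
    if (!is.finite(level) || level < 0 || level > 1) {
      stop_config("synth_config: constant contraction level must lie in [0, 1]")
    }
    contraction_profile <- local({
      lv <- level
      function(t) rep(lv, length(t))
    })
  }
  stopifnot(is.function(contraction_profile))
  structure(
    list(sampling_rate = sampling_rate, duration = duration,
         contraction_profile = contraction_profile,
         emg_band = as.numeric(emg_band),
         powerline_amplitude = powerline_amplitude,
         baseline_drift_amplitude = baseline_drift_amplitude,
         noise_floor = noise_floor, seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate a synthetic surface-EMG trace
#'
#' Synthesizes band-limited amplitude-modulated Gaussian EMG: white
#' Gaussian noise is shaped to the configured pass band with a
#' zero-phase Butterworth cascade, rescaled to unit RMS, and multiplied
#' by the contraction envelope so that the local signal amplitude tracks
#' contraction intensity. Power-line interference (50 Hz), sub-5 Hz
#' baseline drift and a white noise floor are then added per the config.
#'
#' @param config A [synth_config()].
#' @return An [emg_signal()] of length `round(sampling_rate * duration)`.
#' @examples
#' cfg <- synth_config(duration = 0.5, contraction_profile = 0.6, seed = 7)
#' sig <- generate_emg(cfg)
#' sig
#' @export
generate_emg <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$sampling_rate
  n <- round(fs * config$duration)
  t <- (seq_len(n) - 1) / fs
  env <- config$contraction_profile(t)
  if (length(env) != n) stop_config("contraction_profile must return one value per time point")
  if (any(!is.finite(env)) || any(env < 0) || any(env > 1)) {
    stop_config("contraction_profile values must lie in [0, 1]")
  }
  with_seed(config$seed, {
    carrier <- rnorm(n)
    carrier <- bandpass_filter(carrier, fs, config$emg_band[1], config$emg_band[2],
                               order = 4L)
    crms <- sqrt(mean(carrier^2))
    if (crms > 0) carrier <- carrier / crms
    x <- env * carrier
    if (config$powerline_amplitude != 0) {
      x <- x + config$powerline_amplitude * sin(2 * pi * 50 * t)
    }
    if (config$baseline_drift_amplitude != 0) {
      # slow drift: sum of two incommensurate sub-5 Hz sinusoids with
      # random phases, normalized to the requested amplitude
      ph <- stats::runif(2, 0, 2 * pi)
      drift <- sin(2 * pi * 0.3 * t + ph[1]) + 0.6 * sin(2 * pi * 1.1 * t + ph[2])
      x <- x + config$baseline_drift_amplitude * drift / 1.6
    }
    if (config$noise_floor != 0) {
      x <- x + config$noise_floor * rnorm(n)
    }
    emg_signal(x, fs, channel_label = "synthetic")
  })
}

#' Generate a motor-current trace from a torque profile
#'
#' Inverts the motor torque relation `T = Kt * I`: given a desired
#' resistive-torque profile and the motor torque constant, returns the
#' current the motor would draw, optionally with Gaussian sensor noise.
#'
#' @param torque_profile Either a numeric vector of torques (Nm), one per
#'   sample, or a function of time (seconds).
#' @param kt Motor torque constant in Nm/A (positive).
#' @param noise_sd Standard deviation of additive current noise in A.
#' @param seed Integer seed for the noise.
#' @param sampling_rate,duration Used only when `torque_profile` is a
#'   function, to build the time grid.
#' @return Numeric vector of currents in A.
#' @export
generate_current_trace <- function(torque_profile, kt, noise_sd = 0, seed = 1L,
                                   sampling_rate = 10000, duration = NULL) {
  if (!is_scalar_number(kt) || kt <= 0) stop_config("generate_current_trace: kt must be > 0")
  if (is.function(torque_profile)) {
    if (is.null(duration)) stop_config("duration required when torque_profile is a function")
    t <- (seq_len(round(sampling_rate * duration)) - 1) / sampling_rate
    torque <- torque_profile(t)
  } else {
    torque <- as.numeric(torque_profile)
  }
  current <- torque / kt
  if (noise_sd != 0) {
    current <- with_seed(seed, current + noise_sd * rnorm(length(current)))
  }
  current
}

#' Generate a per-iteration achieved range-of-motion sequence
#'
#' Models the slow recovery of joint range of motion over repeated
#' flexion/extension iterations: the achieved RoM grows by
#' `gain_per_iteration` degrees each iteration (optionally jittered) and
#' saturates at `ceiling`, which may never exceed the joint workspace
#' (130 degrees elbow flexion).
#'
#' @param initial_rom Starting RoM in degrees (`0 <= initial_rom <= ceiling`).
#' @param gain_per_iteration Mean RoM gain per iteration in degrees.
#' @param n_iterations Number of iterations to simulate.
#' @param ceiling Saturation RoM in degrees (at most the workspace limit).
#' @param seed Integer seed (used only when `jitter_sd > 0`).
#' @param jitter_sd Standard deviation of non-negative increment jitter in
#'   degrees; 0 (default) gives a deterministic linear ramp.
#' @param workspace_limit Joint workspace bound in degrees; default 130
#'   (elbow flexion).
#' @return Numeric vector of `n_iterations` monotonically non-decreasing
#'   RoM values, clipped at `ceiling`.
#' @examples
#' rom <- generate_rom_sequence(60, 1 / 50, 2500, ceiling = 130)
#' tail(rom, 1)  # 110 degrees after 2500 iterations
#' @export
generate_rom_sequence <- function(initial_rom, gain_per_iteration, n_iterations,
                                  ceiling = 130, seed = 1L, jitter_sd = 0,
                                  workspace_limit = 130) {
  if (ceiling > workspace_limit) {
    stop_config("generate_rom_sequence: ceiling exceeds the joint workspace (",
                workspace_limit, " degrees)")
  }
  if (initial_rom < 0 || initial_rom > ceiling) {
    stop_config("generate_rom_sequence: need 0 <= initial_rom <= ceiling")
  }
  n_iterations <- as.integer(n_iterations)
  stopifnot(n_iterations >= 1L)
  inc <- rep(gain_per_iteration, n_iterations)
  if (jitter_sd > 0) {
    inc <- with_seed(seed, pmax(0, inc + jitter_sd * rnorm(n_iterations)))
  }
  pmin(initial_rom + cumsum(inc), ceiling)
}
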