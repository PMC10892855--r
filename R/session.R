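# Closed-loop rehabilitation session simulator: iteration counting,
# pain-threshold-triggered stimulation selection, terminal automatic
# relax, and RoM-recovery accounting.

stimulation_modes <- c("pain_relief", "massage", "relax", "off")

#' Configure a rehabilitation session
#'
#' @param mode `"automatic"` (stimulation selected from the estimated
#'   pain) or `"manual"` (therapist-chosen mode applied throughout).
#' @param n_exercises Number of exercises in the session (default 6).
#' @param reps_per_exercise Repetitions of each exercise (default 5;
#'   6 x 5 gives the standard 30-iteration protocol).
#' @param pain_threshold Pain level (on the 0-10 scale) at or above
#'   which pain-relief stimulation is triggered in automatic mode.
#' @param manual_stimulation Stimulation mode applied in manual mode
#'   (one of `"pain_relief"`, `"massage"`, `"relax"`, `"off"`).
#' @param joint `"elbow"` or `"forearm"`; sets the workspace limit
#'   (130 deg flexion / 90 deg supination) unless overridden.
#' @param workspace_limit Joint workspace bound in degrees.
#' @param massage_fraction Automatic massage triggers when
#'   `pain >= massage_fraction * pain_threshold` (and below the
#'   threshold); default 0.5.
#' @param on_pain `"hold"` (default; stimulate then retry the same
#'   commanded angle) or `"abort"` (end the exercising phase early).
#' @param torque_aggregation Per-window torque statistic fed to the
#'   pain block: `"mean"` (default) or `"peak"` of `|T|`.
#' @param kt Motor torque constant in Nm/A used to convert the current
#'   trace to torque.
#' @param stimulator Inert stimulator metadata carried onto log records
#'   (pulse amplitude/rate/width are not simulated physics).
#' @return An object of class `session_config`.
#' @export
session_config <- function(mode = c("automatic", "manual"),
                           n_exercises = 6L, reps_per_exercise = 5L,
                           pain_threshold = 5,
                           manual_stimulation = NULL,
                           joint = c("elbow", "forearm"),
                           workspace_limit = NULL,
                           massage_fraction = 0.5,
                           on_pain = c("hold", "abort"),
                           torque_aggregation = c("mean", "peak"),
                           kt = 0.5,
                           stimulator = list(pulse_amplitude_v = 80,
                                             pulse_rate_hz = 100,
                                             pulse_width_us = 300)) {
  mode <- match.arg(mode)
  joint <- match.arg(joint)
  on_pain <- match.arg(on_pain)
  torque_aggregation <- match.arg(torque_aggregation)
  joint_limit <- c(elbow = 130, forearm = 90)[[joint]]
  if (is.null(workspace_limit)) workspace_limit <- joint_limit
  if (workspace_limit > joint_limit) {
    stop_config("session_config: workspace_limit exceeds the ", joint,
                " joint bound (", joint_limit, " degrees)")
  }
  n_exercises <- as.integer(n_exercises)
  reps_per_exercise <- as.integer(reps_per_exercise)
  if (n_exercises < 1L || reps_per_exercise < 1L) {
    stop_config("session_config: counts must be >= 1")
  }
  if (pain_threshold < 0 || pain_threshold > 10) {
    stop_config("session_config: pain_threshold must lie on the pain scale [0, 10]")
  }
  if (mode == "manual") {
    if (is.null(manual_stimulation) || !manual_stimulation %in% stimulation_modes) {
      stop_config("session_config: manual mode requires manual_stimulation, one of ",
                  paste(stimulation_modes, collapse = ", "))
    }
  }
  if (!is_scalar_number(kt) || kt <= 0) stop_config("session_config: kt must be > 0")
  structure(
    list(mode = mode, n_exercises = n_exercises,
         reps_per_exercise = reps_per_exercise,
         pain_threshold = pain_threshold,
         manual_stimulation = manual_stimulation, joint = joint,
         workspace_limit = workspace_limit,
         massage_fraction = massage_fraction, on_pain = on_pain,
         torque_aggregation = torque_aggregation, kt = kt,
         stimulator = stimulator),
    class = "session_config"
  )
}

#' Initialize session state
#'
#' @param config A [session_config()].
#' @param initial_best_rom Best RoM already achieved before the session,
#'   in degrees (default 0).
#' @return An object of class `session_state`.
#' @export
new_session_state <- function(config, initial_best_rom = 0) {
  structure(
    list(iteration = 0L, exercise_index = 1L, active_stimulation = "off",
         best_rom_achieved = initial_best_rom, phase = "exercising"),
    class = "session_state"
  )
}

#' Select the electrical-stimulation mode
#'
#' In manual mode the therapist's choice is returned unchanged. In
#' automatic mode: a finished session always gets `relax`; pain at or
#' above the threshold gets `pain_relief`; pain in the low band
#' (at least `massage_fraction` of the threshold) gets `massage`;
#' otherwise stimulation is `off`.
#'
#' @param pain_level Crisp pain estimate on `[0, 10]`.
#' @param threshold Pain-relief threshold.
#' @param phase Session phase (`"exercising"`, `"relaxing"`, `"done"`).
#' @param mode `"automatic"` or `"manual"`.
#' @param manual_choice Required stimulation mode when `mode = "manual"`.
#' @param massage_fraction Lower edge of the massage band as a fraction
#'   of the threshold (default 0.5).
#' @return One of `"pain_relief"`, `"massage"`, `"relax"`, `"off"`.
#' @export
select_stimulation <- function(pain_level, threshold, phase = "exercising",
                               mode = "automatic", manual_choice = NULL,
                               massage_fraction = 0.5) {
  stopifnot(phase %in% c("exercising", "relaxing", "done"),
            mode %in% c("automatic", "manual"))
  if (mode == "manual") {
    if (is.null(manual_choice) || !manual_choice %in% stimulation_modes) {
      stop_config("select_stimulation: manual mode requires a valid manual_choice")
    }
    return(manual_choice)
  }
  if (phase != "exercising") return("relax")
  if (pain_level >= threshold) return("pain_relief")
  if (pain_level >= massage_fraction * threshold) return("massage")
  "off"
}

#' Advance the session by one iteration
#'
#' Increments the iteration counter, updates the best achieved RoM,
#' selects the stimulation mode from the pain assessment, and emits one
#' log record. When the configured iteration count is reached the phase
#' moves to `"relaxing"` (the caller then emits the terminal relax
#' record and closes the session). Under the default `on_pain = "hold"`
#' policy a pain-relief activation flags the next commanded angle to be
#' held rather than advanced (stimulate-then-retry); `"abort"` ends the
#' exercising phase instead.
#'
#' @param state A [new_session_state()] result (phase must be
#'   `"exercising"`).
#' @param assessment A [assess_pain()] result for this iteration.
#' @param achieved_rom RoM achieved this iteration, in degrees.
#' @param config The [session_config()].
#' @param commanded_angle Commanded target angle for this iteration.
#' @return List with elements `state` (updated), `record` (one-row data
#'   frame) and `hold_next` (logical: repeat the commanded angle).
#' @export
session_step <- function(state, assessment, achieved_rom, config,
                         commanded_angle = achieved_rom) {
  stopifnot(inherits(state, "session_state"), inherits(config, "session_config"))
  if (state$phase != "exercising") {
    stop_input("session_step: cannot step a session in phase '", state$phase, "'")
  }
  if (achieved_rom > config$workspace_limit) {
    stop_input("session_step: achieved RoM ", achieved_rom,
               " exceeds the workspace limit (", config$workspace_limit, " degrees)")
  }
  state$iteration <- state$iteration + 1L
  state$exercise_index <- 1L + (state$iteration - 1L) %/% config$reps_per_exercise
  state$best_rom_achieved <- max(state$best_rom_achieved, achieved_rom)
  stim <- select_stimulation(assessment$pain_level, config$pain_threshold,
                             phase = "exercising", mode = config$mode,
                             manual_choice = config$manual_stimulation,
                             massage_fraction = config$massage_fraction)
  state$active_stimulation <- stim
  hold_next <- FALSE
  if (config$mode == "automatic" && stim == "pain_relief") {
    if (config$on_pain == "hold") hold_next <- TRUE else state$phase <- "relaxing"
  }
  total <- config$n_exercises * config$reps_per_exercise
  if (state$iteration >= total) state$phase <- "relaxing"
  record <- data.frame(
    iteration = state$iteration,
    timestamp = assessment$window_start_time,
    commanded_angle = commanded_angle,
    achieved_rom = achieved_rom,
    mean_abs_torque = NA_real_,
    contraction = assessment$muscle_contraction,
    pain_level = assessment$pain_level,
    active_stimulation = stim,
    phase = "exercising",
    stringsAsFactors = FALSE
  )
  list(state = state, record = record, hold_next = hold_next)
}

#' Run a full closed-loop rehabilitation session
#'
#' Deterministic composition of the whole pipeline, one analysis window
#' per iteration: the raw EMG is band-pass and notch filtered and
#' segmented; each iteration's window (the one spanning that
#' iteration's share of the trace) is reduced to the four time-domain
#' features, normalized, and pushed through the two-block fuzzy cascade
#' together with the window's aggregated torque magnitude and the
#' previously-attained RoM margin; the selected stimulation mode and
#' the updated state are logged. After the last iteration a terminal
#' automatic relax record closes the log.
#'
#' @param config A [session_config()].
#' @param emg An [emg_signal()] covering the session.
#' @param current Numeric motor-current trace in A, one value per EMG
#'   sample.
#' @param rom Numeric sequence of per-iteration achievable RoM values in
#'   degrees (at least one per iteration).
#' @param block1,block2 Fuzzy systems; defaults built on the fly.
#' @param normalization A [fit_normalization()] map; when `NULL`, the
#'   map is fitted on the session's own feature series (self-calibration).
#' @param window_seconds,overlap_fraction Segmentation parameters.
#' @param v,epsilon Feature parameters.
#' @param bandpass,notch Filter specs.
#' @param initial_best_rom Best RoM achieved before this session
#'   (degrees); also the baseline of the recovery percentage, when
#'   positive.
#' @return An object of class `session_log`: `records` (one row per
#'   iteration plus the terminal relax), `summary` (initial/final RoM,
#'   recovery percent, activation counts) and the `config`.
#' @export
run_session <- function(config, emg, current, rom,
                        block1 = build_block1(), block2 = build_block2(),
                        normalization = NULL,
                        window_seconds = 0.2, overlap_fraction = 0.5,
                        v = 3, epsilon = 1e-12,
                        bandpass = filter_spec("bandpass"),
                        notch = filter_spec("notch"),
                        initial_best_rom = 0) {
  stopifnot(inherits(config, "session_config"), inherits(emg, "emg_signal"))
  n_it <- config$n_exercises * config$reps_per_exercise
  if (length(current) != length(emg$samples)) {
    stop_input("run_session: current trace has ", length(current),
               " samples but the EMG has ", length(emg$samples))
  }
  if (length(rom) < n_it) {
    stop_input("run_session: RoM sequence has ", length(rom),
               " entries; the session needs ", n_it)
  }
  clean <- emg_notch(emg_bandpass(emg, bandpass), notch)
  windows <- segment_windows(clean, window_seconds, overlap_fraction)
  if (length(windows) < n_it) {
    stop_input("run_session: EMG yields ", length(windows),
               " analysis windows; the session needs ", n_it,
               " (trace too short by ",
               n_it - length(windows), " windows)")
  }
  feats <- t(vapply(windows, extract_features, numeric(4), v = v, epsilon = epsilon))
  if (is.null(normalization)) normalization <- fit_normalization(feats)
  fs <- clean$sampling_rate
  n_win <- round(window_seconds * fs)
  torque <- torque_from_current(current, config$kt)
  agg_fun <- if (config$torque_aggregation == "mean") mean else max

  state <- new_session_state(config, initial_best_rom)
  records <- vector("list", n_it + 1L)
  rom_ptr <- 1L
  for (i in seq_len(n_it)) {
    w_idx <- ceiling(i * length(windows) / n_it)
    win <- windows[[w_idx]]
    s0 <- round(win$start_time * fs) + 1L
    w_torque <- agg_fun(abs(torque[s0:(s0 + n_win - 1L)]))
    commanded <- min(rom[rom_ptr], config$workspace_limit)
    margin <- max(0, state$best_rom_achieved - commanded)
    norm_feats <- normalize_features(feats[w_idx, ], normalization)
    assessment <- assess_pain(norm_feats, w_torque, margin, block1, block2,
                              window_start_time = win$start_time)
    stepped <- session_step(state, assessment, achieved_rom = commanded,
                            config = config, commanded_angle = commanded)
    state <- stepped$state
    rec <- stepped$record
    rec$mean_abs_torque <- w_torque
    records[[i]] <- rec
    if (!stepped$hold_next) rom_ptr <- min(rom_ptr + 1L, length(rom))
    if (state$phase != "exercising" && i < n_it) {
      records <- records[seq_len(i + 1L)]
      break
    }
  }
  done <- Filter(Negate(is.null), records[-length(records)])
  n_done <- length(done)
  state$phase <- "done"
  state$active_stimulation <- "relax"
  terminal <- data.frame(
    iteration = n_done + 1L, timestamp = NA_real_,
    commanded_angle = NA_real_, achieved_rom = NA_real_,
    mean_abs_torque = NA_real_, contraction = NA_real_,
    pain_level = NA_real_, active_stimulation = "relax", phase = "done",
    stringsAsFactors = FALSE
  )
  records <- rbind(do.call(rbind, done), terminal)
  exercising <- records[records$phase == "exercising", ]
  initial_rom <- exercising$achieved_rom[1L]
  final_rom <- state$best_rom_achieved
  baseline <- if (initial_best_rom > 0) initial_best_rom else initial_rom
  summ <- list(
    iterations = n_done,
    initial_rom = initial_rom,
    final_rom = final_rom,
    rom_recovery_percent = if (baseline > 0) rom_recovery_percent(baseline, final_rom) else NA_real_,
    median_pain = median(exercising$pain_level),
    pain_relief_activations = sum(exercising$active_stimulation == "pain_relief"),
    massage_activations = sum(exercising$active_stimulation == "massage")
  )
  structure(list(records = records, summary = summ, config = config,
                 normalization = normalization, state = state),
            class = "session_log")
}

#' @export
print.session_log <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<session_log> %d iterations + terminal relax (%s mode, %s joint)\n",
              s$iterations, x$config$mode, x$config$joint))
  cat(sprintf("  RoM %g -> %g deg", s$initial_rom, s$final_rom))
  if (is.finite(s$rom_recovery_percent)) {
    cat(sprintf("  (recovery %.1f%%)", s$rom_recovery_percent))
  }
  cat("\n")
  cat(sprintf("  median pain %.2f; pain_relief x%d, massage x%d\n",
              s$median_pain, s$pain_relief_activations, s$massage_activations))
  invisible(x)
}

#' @export
summary.session_log <- function(object, ...) {
  print(object)
  print(utils::head(object$records, 5))
  invisible(object$summary)
}

#' Range-of-motion recovery percentage
#'
#' `100 * (final - initial) / initial`: the session-over-session RoM
#' improvement relative to the initial state (e.g. 60 deg at intake to
#' 110 deg after two weeks is an 83.3% recovery).
#'
#' @param initial_rom Initial RoM in degrees (> 0).
#' @param final_rom Final RoM in degrees.
#' @return Percentage.
#' @examples
#' rom_recovery_percent(60, 110)  # 83.33
#' @export
rom_recovery_percent <- function(initial_rom, final_rom) {
  if (!is_scalar_number(initial_rom) || initial_rom <= 0) {
    stop_input("rom_recovery_percent: initial_rom must be > 0")
  }
  100 * (final_rom - initial_rom) / initial_rom
}

#' Passive-torque reduction percentage
#'
#' `100 * (initial - final) / initial`: the drop in passive joint
#' torque over the course of rehabilitation.
#'
#' @param initial_torque Initial passive torque in Nm (> 0).
#' @param final_torque Final passive torque in Nm.
#' @return Percentage.
#' @examples
#' torque_reduction_percent(10, 7)  # 30
#' @export
torque_reduction_percent <- function(initial_torque, final_torque) {
  if (!is_scalar_number(initial_torque) || initial_torque <= 0) {
    stop_input("torque_reduction_percent: initial_torque must be > 0")
  }
  100 * (initial_torque - final_torque) / initial_torque
}
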