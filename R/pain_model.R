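# Two-block fuzzy pain cascade: Block 1 maps the four normalized EMG
# features to muscle contraction; Block 2 maps contraction, resistive
# torque and the previously-attained RoM margin to a pain level.

#' Estimate joint torque from motor current
#'
#' The passive torque produced by the motor is estimated from the
#' consumed current through the conventional motor relation
#' `T = Kt * I`, with `Kt` the torque constant from the motor's
#' manufacturer. Negative currents (direction reversal) give negative
#' torques; downstream pain estimation uses the magnitude.
#'
#' @param current Motor current in A (vectorized).
#' @param kt Torque constant in Nm/A (> 0).
#' @return Torque in Nm.
#' @examples
#' torque_from_current(3, kt = 0.5)  # 1.5 Nm
#' @export
torque_from_current <- function(current, kt) {
  if (!is_scalar_number(kt) || kt <= 0) {
    stop_config("torque_from_current: kt must be > 0")
  }
  kt * current
}

# Ordinal rule recipe: map each antecedent label to its index, form a
# weighted score of the normalized indices, divide by the positive
# weight mass and clip to [0, 1] (so negatively weighted inputs act as
# a pure discount and zero-evidence antecedents land on the lowest
# consequent), then bin uniformly onto the consequent labels with
# floor binning.
ordinal_consequent <- function(indices, maxima, weights, out_labels) {
  s <- sum(weights * indices / maxima) / sum(weights[weights > 0])
  frac <- clip(s, 0, 1)
  m <- length(out_labels)
  out_labels[[min(m, 1L + floor(frac * m))]]
}

#' Build the contraction-estimation fuzzy block (Block 1)
#'
#' Four inputs — the normalized time-domain features `rms`, `ssi`,
#' `vorder`, `logdetect`, each on `[0, 10]` with five Gaussian
#' membership functions (very_low, low, medium, high, very_high) — map
#' to a `muscle_contraction` output on `[0, 10]` with three membership
#' functions (low, medium, high). The complete default rule base
#' (5^4 = 625 rules) is generated from an ordinal recipe: the mean of
#' the four antecedent label indices is binned uniformly onto the three
#' output labels, so estimated contraction rises with every feature.
#'
#' @param grid_points Defuzzification grid resolution.
#' @return A [fuzzy_system()].
#' @export
build_block1 <- function(grid_points = 1001L) {
  in_labels <- c("very_low", "low", "medium", "high", "very_high")
  out_labels <- c("low", "medium", "high")
  inputs <- lapply(c("rms", "ssi", "vorder", "logdetect"), function(nm) {
    fuzzy_variable(nm, c(0, 10), in_labels)
  })
  output <- fuzzy_variable("muscle_contraction", c(0, 10), out_labels)
  combos <- expand.grid(rms = in_labels, ssi = in_labels, vorder = in_labels,
                        logdetect = in_labels, stringsAsFactors = FALSE)
  rules <- lapply(seq_len(nrow(combos)), function(i) {
    ante <- unlist(combos[i, ])
    idx <- match(ante, in_labels) - 1L
    fuzzy_rule(ante, ordinal_consequent(idx, rep(4L, 4), rep(1, 4), out_labels))
  })
  fuzzy_system(inputs, output, rules, grid_points)
}

#' Build the pain-evaluation fuzzy block (Block 2)
#'
#' Three inputs — muscle contraction on `[0, 10]` (3 MFs), resistive
#' torque on `[0, 65]` Nm (5 MFs; the elbow actuator's torque bound) and
#' the previously-attained RoM margin on `[0, 130]` degrees (4 MFs; the
#' elbow flexion workspace) — map to `pain_level` on `[0, 10]` with four
#' membership functions (none, low, moderate, severe). The RoM input is
#' the number of degrees by which the best previously achieved range of
#' motion exceeds the currently commanded angle (floored at 0): pain
#' rises with contraction and torque but is discounted when the current
#' target was already reached in the past, so rehabilitation can proceed
#' through pain across previously conquered territory. The complete
#' default rule base (3 x 5 x 4 = 60 rules) implements this with the
#' ordinal recipe: contraction and torque indices weighted +1, the
#' attained-margin index weighted -0.5, so the achievement discount
#' tempers mid-level pain evidence but can never fully override
#' maximal contraction-plus-torque evidence (a safety property).
#'
#' @param grid_points Defuzzification grid resolution.
#' @param torque_range Resistive-torque domain in Nm.
#' @param rom_range Attained-RoM-margin domain in degrees.
#' @return A [fuzzy_system()].
#' @export
build_block2 <- function(grid_points = 1001L, torque_range = c(0, 65),
                         rom_range = c(0, 130)) {
  c_labels <- c("low", "medium", "high")
  t_labels <- c("very_low", "low", "medium", "high", "very_high")
  r_labels <- c("none", "small", "large", "full")
  out_labels <- c("none", "low", "moderate", "severe")
  inputs <- list(
    fuzzy_variable("muscle_contraction", c(0, 10), c_labels),
    fuzzy_variable("resistive_torque", torque_range, t_labels),
    fuzzy_variable("rom_margin", rom_range, r_labels)
  )
  output <- fuzzy_variable("pain_level", c(0, 10), out_labels)
  combos <- expand.grid(muscle_contraction = c_labels, resistive_torque = t_labels,
                        rom_margin = r_labels, stringsAsFactors = FALSE)
  maxima <- c(2L, 4L, 3L)
  weights <- c(1, 1, -0.5)
  labelsets <- list(c_labels, t_labels, r_labels)
  rules <- lapply(seq_len(nrow(combos)), function(i) {
    ante <- unlist(combos[i, ])
    idx <- mapply(function(a, ls) match(a, ls) - 1L, ante, labelsets)
    fuzzy_rule(ante, ordinal_consequent(idx, maxima, weights, out_labels))
  })
  fuzzy_system(inputs, output, rules, grid_points)
}

#' Assess muscle contraction and pain for one analysis window
#'
#' Runs the two-block cascade: Block 1 turns the normalized feature
#' vector into a crisp muscle-contraction estimate; Block 2 combines
#' that estimate with the resistive-torque magnitude and the
#' previously-attained RoM margin into a crisp pain level.
#'
#' @param features Named vector of the four normalized features (each
#'   in `[0, 10]`), as returned by [normalize_features()].
#' @param torque Resistive torque in Nm (sign ignored).
#' @param rom_margin Degrees by which the best previously achieved RoM
#'   exceeds the commanded angle, floored at 0.
#' @param block1,block2 Fuzzy systems from [build_block1()] /
#'   [build_block2()].
#' @param window_start_time Timestamp carried onto the assessment.
#' @return An object of class `pain_assessment` with fields
#'   `muscle_contraction`, `pain_level` and `window_start_time`.
#' @export
assess_pain <- function(features, torque, rom_margin, block1, block2,
                        window_start_time = NA_real_) {
  contraction <- fuzzy_infer(block1, features[c("rms", "ssi", "vorder", "logdetect")])
  pain <- fuzzy_infer(block2, c(muscle_contraction = contraction,
                                resistive_torque = abs(torque),
                                rom_margin = max(0, rom_margin)))
  structure(
    list(muscle_contraction = contraction, pain_level = pain,
         window_start_time = window_start_time),
    class = "pain_assessment"
  )
}

#' @export
print.pain_assessment <- function(x, ...) {
  cat(sprintf("<pain_assessment> t=%.3f s  contraction=%.2f  pain=%.2f\n",
              x$window_start_time, x$muscle_contraction, x$pain_level))
  invisible(x)
}
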