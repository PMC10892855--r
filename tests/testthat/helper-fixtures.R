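# Shared fixtures and independent oracles, all built in code.

probe_signal <- function(freq, fs = 10000, duration = 2, amplitude = 1) {
  t <- seq(0, duration, by = 1 / fs)
  emg_signal(amplitude * sin(2 * pi * freq * t), fs, sprintf("probe_%gHz", freq))
}

# RMS with start-up/tail transients dropped (half a second each side)
trimmed_rms <- function(signal, trim_s = 0.5) {
  x <- signal$samples
  k <- round(trim_s * signal$sampling_rate)
  x <- x[(k + 1):(length(x) - k)]
  sqrt(mean(x^2))
}

# Naive one-pass loop oracles for the time-domain features, kept
# independent of the vectorized implementations.
oracle_rms <- function(x) {
  acc <- 0
  for (xi in x) acc <- acc + xi * xi
  sqrt(acc / length(x))
}
oracle_ssi <- function(x) {
  acc <- 0
  for (xi in x) acc <- acc + xi * xi
  acc
}
oracle_vorder <- function(x, v) {
  acc <- 0
  for (xi in x) acc <- acc + abs(xi)^v
  (acc / length(x))^(1 / v)
}
oracle_logdetect <- function(x, eps) {
  acc <- 0
  for (xi in x) acc <- acc + log(abs(xi) + eps)
  exp(acc / length(x))
}

# Independent center-of-area oracle: direct Gaussian formula, min/max
# Mamdani by explicit loops, rectangle-rule integration on a fine grid.
coa_oracle <- function(system, inputs, n_grid = 1e6) {
  gauss <- function(x, c, s) exp(-(x - c)^2 / (2 * s^2))
  out <- system$output
  x <- seq(out$range[1], out$range[2], length.out = n_grid)
  deg <- lapply(system$inputs, function(v) {
    xv <- min(max(inputs[[v$name]], v$range[1]), v$range[2])
    sapply(v$mfs, function(m) gauss(xv, m$center, m$sigma))
  })
  names(deg) <- names(system$inputs)
  agg <- numeric(n_grid)
  for (r in system$rules) {
    act <- min(mapply(function(vn, l) deg[[vn]][[l]], names(r$antecedent),
                      r$antecedent))
    mf <- out$mfs[[r$consequent]]
    agg <- pmax(agg, pmin(act, gauss(x, mf$center, mf$sigma)))
  }
  sum(agg * x) / sum(agg)
}

# Random small 2-input Mamdani system for engine cross-checks.
random_fuzzy_system <- function() {
  labs <- c("a", "b", "c")
  v1 <- fuzzy_variable("u", c(0, runif(1, 5, 20)), labs)
  v2 <- fuzzy_variable("w", c(0, runif(1, 5, 20)), labs)
  out <- fuzzy_variable("y", c(0, runif(1, 5, 20)), labs)
  rules <- list()
  for (l1 in labs) for (l2 in labs) {
    rules[[length(rules) + 1L]] <- fuzzy_rule(c(u = l1, w = l2), sample(labs, 1))
  }
  fuzzy_system(list(v1, v2), out, rules)
}

# Synthetic session inputs at a given constant contraction level, with
# a shared calibration map fitted on a low-to-high contraction ramp.
calibration_map <- function(seed = 99, duration = 3.5) {
  cal <- generate_emg(synth_config(duration = duration,
                                   contraction_profile = function(t) pmin(1, t / duration),
                                   powerline_amplitude = 0.1, noise_floor = 0.02,
                                   seed = seed))
  clean <- emg_notch(emg_bandpass(cal))
  fit_normalization(t(vapply(segment_windows(clean), extract_features, numeric(4))))
}

session_fixture <- function(level, seed, map, torque_nm = 20,
                            config = session_config(pain_threshold = 5),
                            block1 = build_block1(), block2 = build_block2()) {
  emg <- generate_emg(synth_config(duration = 3.5, contraction_profile = level,
                                   powerline_amplitude = 0.1, noise_floor = 0.02,
                                   seed = seed))
  current <- generate_current_trace(rep(torque_nm, length(emg$samples)), kt = config$kt)
  rom <- generate_rom_sequence(60, 0.2, 30, ceiling = 130)
  run_session(config, emg, current, rom, block1, block2, normalization = map)
}
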