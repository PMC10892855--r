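test_that("automatic stimulation selection follows the pain bands", {
  expect_equal(select_stimulation(9, 5, phase = "done"), "relax")
  expect_equal(select_stimulation(0, 5, phase = "relaxing"), "relax")
  expect_equal(select_stimulation(0, 5), "off")
  expect_equal(select_stimulation(2.4, 5), "off")
  expect_equal(select_stimulation(2.5, 5), "massage")
  expect_equal(select_stimulation(4.9, 5), "massage")
  expect_equal(select_stimulation(5, 5), "pain_relief")
  expect_equal(select_stimulation(10, 5), "pain_relief")
})

test_that("manual mode returns the therapist's choice regardless of pain", {
  expect_equal(select_stimulation(10, 5, mode = "manual", manual_choice = "massage"),
               "massage")
  expect_equal(select_stimulation(0, 5, mode = "manual", manual_choice = "relax"),
               "relax")
  expect_error(select_stimulation(5, 5, mode = "manual"),
               class = "empain_config_error")
  expect_error(session_config(mode = "manual"), class = "empain_config_error")
})

fake_assessment <- function(pain, contraction = 3, t = 0) {
  structure(list(muscle_contraction = contraction, pain_level = pain,
                 window_start_time = t), class = "pain_assessment")
}

test_that("stepping advances counters, tracks best RoM and flags holds", {
  cfg <- session_config(n_exercises = 2, reps_per_exercise = 2, pain_threshold = 5)
  st <- new_session_state(cfg)
  roms <- c(60, 64, 62, 66)
  best <- cummax(roms)
  for (i in 1:4) {
    out <- session_step(st, fake_assessment(1), roms[i], cfg)
    st <- out$state
    expect_equal(st$iteration, i)
    expect_equal(st$best_rom_achieved, best[i])
    expect_false(out$hold_next)
  }
  expect_equal(st$phase, "relaxing")
  expect_error(session_step(st, fake_assessment(1), 70, cfg),
               class = "empain_input_error")
})

test_that("pain at threshold triggers pain relief and a held command", {
  cfg <- session_config(n_exercises = 3, reps_per_exercise = 5, pain_threshold = 5)
  st <- new_session_state(cfg)
  out <- session_step(st, fake_assessment(6), 60, cfg)
  expect_equal(out$record$active_stimulation, "pain_relief")
  expect_true(out$hold_next)
  expect_equal(out$state$phase, "exercising")
  abort_cfg <- session_config(n_exercises = 3, reps_per_exercise = 5,
                              pain_threshold = 5, on_pain = "abort")
  out2 <- session_step(new_session_state(abort_cfg), fake_assessment(6), 60, abort_cfg)
  expect_equal(out2$state$phase, "relaxing")
})

test_that("achieved RoM beyond the workspace limit is refused", {
  cfg <- session_config()
  expect_error(session_step(new_session_state(cfg), fake_assessment(1), 140, cfg),
               class = "empain_input_error")
  expect_error(session_config(joint = "forearm", workspace_limit = 120),
               class = "empain_config_error")
})

test_that("a 6x5 session runs 30 iterations and ends with an automatic relax", {
  map <- calibration_map()
  log <- session_fixture(0.5, seed = 21, map = map)
  expect_equal(log$summary$iterations, 30L)
  expect_equal(nrow(log$records), 31L)
  last <- log$records[31, ]
  expect_equal(last$active_stimulation, "relax")
  expect_equal(last$phase, "done")
  expect_false(any(log$records$active_stimulation[1:30] == "relax"))
  expect_equal(log$state$phase, "done")
})

test_that("a quiet trace with zero torque draws no stimulation before the relax", {
  map <- calibration_map()
  cfg <- session_config(pain_threshold = 7)
  log <- session_fixture(0, seed = 22, map = map, torque_nm = 0, config = cfg)
  ex <- log$records[log$records$phase == "exercising", ]
  expect_true(all(ex$active_stimulation == "off"))
  expect_true(all(ex$pain_level < 7))
  expect_equal(tail(log$records$active_stimulation, 1), "relax")
})

test_that("best achieved RoM is the running max and respects the workspace", {
  map <- calibration_map()
  log <- session_fixture(0.3, seed = 23, map = map)
  ex <- log$records[log$records$phase == "exercising", ]
  expect_true(all(diff(cummax(ex$achieved_rom)) >= 0))
  expect_lte(log$state$best_rom_achieved, 130)
  expect_equal(log$state$best_rom_achieved, max(ex$achieved_rom))
})

test_that("sessions are deterministic end to end", {
  map <- calibration_map()
  a <- session_fixture(0.6, seed = 30, map = map)
  b <- session_fixture(0.6, seed = 30, map = map)
  expect_identical(a$records, b$records)
  expect_identical(a$summary, b$summary)
})

test_that("undersized traces are refused with the shortfall named", {
  map <- calibration_map()
  cfg <- session_config()
  emg <- generate_emg(synth_config(duration = 1, contraction_profile = 0.5, seed = 1))
  cur <- rep(0, length(emg$samples))
  rom <- generate_rom_sequence(60, 0.2, 30)
  expect_error(run_session(cfg, emg, cur, rom, normalization = map),
               "windows", class = "empain_input_error")
  emg2 <- generate_emg(synth_config(duration = 3.5, contraction_profile = 0.5, seed = 1))
  expect_error(run_session(cfg, emg2, rep(0, 10), rom, normalization = map),
               class = "empain_input_error")
  expect_error(run_session(cfg, emg2, rep(0, length(emg2$samples)), rom[1:10],
                           normalization = map),
               "RoM sequence", class = "empain_input_error")
})

test_that("recovery percentages match hand arithmetic", {
  expect_equal(rom_recovery_percent(60, 110), 100 * 50 / 60)
  expect_equal(rom_recovery_percent(60, 60), 0)
  expect_equal(rom_recovery_percent(60, 85), 100 * 25 / 60)
  expect_error(rom_recovery_percent(0, 100), class = "empain_input_error")
  expect_equal(torque_reduction_percent(10, 7), 30)
  expect_equal(torque_reduction_percent(10, 10), 0)
  expect_equal(torque_reduction_percent(8, 6), 25)
  expect_error(torque_reduction_percent(0, 1), class = "empain_input_error")
})
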