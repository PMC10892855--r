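test_that("torque follows the motor relation T = Kt * I", {
  expect_equal(torque_from_current(0, kt = 0.5), 0)
  expect_equal(torque_from_current(2, kt = 1), 2)
  expect_equal(torque_from_current(3, kt = 0.5), 1.5)
  expect_equal(torque_from_current(c(-2, 2), kt = 0.5), c(-1, 1))
  expect_error(torque_from_current(1, kt = 0), class = "empain_config_error")
  expect_error(torque_from_current(1, kt = -1), class = "empain_config_error")
})

test_that("block 1 has the published architecture: 4 inputs x 5 MFs -> 3-MF output", {
  b1 <- build_block1()
  expect_length(b1$inputs, 4L)
  expect_setequal(names(b1$inputs), c("rms", "ssi", "vorder", "logdetect"))
  for (v in b1$inputs) {
    expect_length(v$mfs, 5L)
    expect_equal(v$range, c(0, 10))
    expect_true(all(vapply(v$mfs, inherits, logical(1), "gaussian_mf")))
  }
  expect_equal(b1$output$name, "muscle_contraction")
  expect_length(b1$output$mfs, 3L)
  expect_length(b1$rules, 5L^4)
})

test_that("block 2 has the published architecture: 3/5/4-MF inputs -> 4-MF output", {
  b2 <- build_block2()
  counts <- vapply(b2$inputs, function(v) length(v$mfs), integer(1))
  expect_equal(unname(counts), c(3L, 5L, 4L))
  expect_equal(b2$inputs$resistive_torque$range, c(0, 65))
  expect_equal(b2$inputs$rom_margin$range, c(0, 130))
  expect_length(b2$output$mfs, 4L)
  expect_equal(names(b2$output$mfs), c("none", "low", "moderate", "severe"))
  expect_length(b2$rules, 3L * 5L * 4L)
})

test_that("block 1 output tracks the feature extremes", {
  b1 <- build_block1()
  lo <- fuzzy_infer(b1, c(rms = 0, ssi = 0, vorder = 0, logdetect = 0))
  hi <- fuzzy_infer(b1, c(rms = 10, ssi = 10, vorder = 10, logdetect = 10))
  expect_lt(lo, 10 / 3)
  expect_gt(hi, 20 / 3)
})

test_that("block 2 output spans quiet to painful conditions", {
  b2 <- build_block2()
  quiet <- fuzzy_infer(b2, c(muscle_contraction = 0, resistive_torque = 0,
                             rom_margin = 60))
  painful <- fuzzy_infer(b2, c(muscle_contraction = 10, resistive_torque = 65,
                               rom_margin = 0))
  expect_lt(quiet, 2.5)
  expect_gt(painful, 7.5)
})

test_that("pain rises with contraction and torque, falls with attained margin", {
  b2 <- build_block2()
  c_centers <- c(0, 5, 10)
  t_centers <- seq(0, 65, length.out = 5)
  r_centers <- seq(0, 130, length.out = 4)
  pain <- array(dim = c(3, 5, 4))
  for (i in 1:3) for (j in 1:5) for (k in 1:4) {
    pain[i, j, k] <- fuzzy_infer(b2, c(muscle_contraction = c_centers[i],
                                       resistive_torque = t_centers[j],
                                       rom_margin = r_centers[k]))
  }
  expect_true(all(apply(pain, c(2, 3), function(v) all(diff(v) >= -1e-9))))
  expect_true(all(apply(pain, c(1, 3), function(v) all(diff(v) >= -1e-9))))
  expect_true(all(apply(pain, c(1, 2), function(v) all(diff(v) <= 1e-9))))
})

test_that("assess_pain equals manual chaining of the two blocks and is deterministic", {
  b1 <- build_block1()
  b2 <- build_block2()
  feats <- c(rms = 7, ssi = 6, vorder = 8, logdetect = 5)
  a <- assess_pain(feats, torque = -12, rom_margin = 25, b1, b2,
                   window_start_time = 1.5)
  contraction <- fuzzy_infer(b1, feats)
  pain <- fuzzy_infer(b2, c(muscle_contraction = contraction,
                            resistive_torque = 12, rom_margin = 25))
  expect_identical(a$muscle_contraction, contraction)
  expect_identical(a$pain_level, pain)
  expect_identical(a$window_start_time, 1.5)
  b <- assess_pain(feats, torque = -12, rom_margin = 25, b1, b2, 1.5)
  expect_identical(a$pain_level, b$pain_level)
})

test_that("increasing torque never decreases assessed pain", {
  b1 <- build_block1()
  b2 <- build_block2()
  feats <- c(rms = 5, ssi = 5, vorder = 5, logdetect = 5)
  pains <- vapply(seq(0, 65, length.out = 8), function(tq) {
    assess_pain(feats, tq, rom_margin = 40, b1, b2)$pain_level
  }, numeric(1))
  expect_true(all(diff(pains) >= -1e-9))
})

test_that("crisp outputs stay within their declared ranges on random inputs", {
  b1 <- build_block1()
  b2 <- build_block2()
  set.seed(31)
  for (i in 1:40) {
    feats <- c(rms = runif(1, -2, 12), ssi = runif(1, -2, 12),
               vorder = runif(1, -2, 12), logdetect = runif(1, -2, 12))
    a <- assess_pain(feats, torque = runif(1, -80, 80),
                     rom_margin = runif(1, 0, 150), b1, b2)
    expect_gte(a$muscle_contraction, 0)
    expect_lte(a$muscle_contraction, 10)
    expect_gte(a$pain_level, 0)
    expect_lte(a$pain_level, 10)
  }
})
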