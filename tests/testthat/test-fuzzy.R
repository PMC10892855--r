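test_that("Gaussian membership has the contracted shape", {
  mf <- gaussian_mf("mid", center = 5, sigma = 2)
  expect_equal(membership(5, mf), 1)
  expect_equal(membership(7, mf), exp(-1 / 2))
  expect_equal(membership(3, mf), membership(7, mf))
  expect_lt(membership(5 + 20 * 2, mf), 1e-20)
  expect_error(gaussian_mf("bad", 0, sigma = 0), class = "empain_config_error")
})

test_that("fuzzify evaluates every label and clips into the range", {
  v <- fuzzy_variable("x", c(0, 10), c("low", "mid", "high"))
  d <- fuzzify(0, v)
  expect_named(d, c("low", "mid", "high"))
  expect_equal(unname(d["low"]), 1)
  expect_lt(d["high"], 0.02)
  expect_identical(fuzzify(25, v), fuzzify(10, v))
  expect_identical(fuzzify(-3, v), fuzzify(0, v))
  # degrees reproduce direct membership calls
  expect_equal(unname(d), vapply(v$mfs, function(m) membership(0, m), numeric(1)),
               ignore_attr = TRUE)
})

test_that("auto-layout spaces centers evenly with half-spacing sigma", {
  v <- fuzzy_variable("x", c(0, 12), c("a", "b", "c", "d"))
  centers <- vapply(v$mfs, function(m) m$center, numeric(1))
  sigmas <- vapply(v$mfs, function(m) m$sigma, numeric(1))
  expect_equal(unname(centers), c(0, 4, 8, 12))
  expect_equal(unname(sigmas), rep(2, 4))
})

test_that("single symmetric rule defuzzifies to its consequent center", {
  v <- fuzzy_variable("x", c(0, 10), c("lo", "hi"))
  out <- fuzzy_variable("y", c(0, 10), mfs = list(
    gaussian_mf("mid", 5, 1.5), gaussian_mf("edge", 9, 1.5)))
  sys <- fuzzy_system(list(v), out, list(fuzzy_rule(c(x = "lo"), "mid")))
  expect_equal(fuzzy_infer(sys, c(x = 0)), 5, tolerance = 1e-6)
})

test_that("inference matches the brute-force fine-grid oracle", {
  set.seed(123)
  for (i in 1:12) {
    sys <- random_fuzzy_system()
    for (j in 1:3) {
      ins <- c(u = runif(1, sys$inputs$u$range[1], sys$inputs$u$range[2]),
               w = runif(1, sys$inputs$w$range[1], sys$inputs$w$range[2]))
      expect_equal(fuzzy_infer(sys, ins), coa_oracle(sys, as.list(ins), 2e5),
                   tolerance = 1e-3)
    }
  }
})

test_that("crisp output stays within the output range and ignores rule order", {
  set.seed(77)
  sys <- random_fuzzy_system()
  perm <- sys
  perm$rules <- sys$rules[sample(length(sys$rules))]
  for (j in 1:10) {
    ins <- c(u = runif(1, -5, 30), w = runif(1, -5, 30))
    y <- fuzzy_infer(sys, ins)
    expect_gte(y, sys$output$range[1])
    expect_lte(y, sys$output$range[2])
    expect_identical(y, fuzzy_infer(perm, ins))
  }
})

test_that("doubling the defuzzification grid barely moves the shipped systems", {
  b1 <- build_block1(1001L)
  b1_fine <- build_block1(2001L)
  ins <- c(rms = 3.7, ssi = 6.1, vorder = 2.2, logdetect = 8.4)
  expect_equal(fuzzy_infer(b1, ins), fuzzy_infer(b1_fine, ins), tolerance = 1e-4)
  b2 <- build_block2(1001L)
  b2_fine <- build_block2(2001L)
  ins2 <- c(muscle_contraction = 6.5, resistive_torque = 22, rom_margin = 35)
  expect_equal(fuzzy_infer(b2, ins2), fuzzy_infer(b2_fine, ins2), tolerance = 1e-4)
})

test_that("a monotone rule base gives monotone output across the MF-center lattice", {
  labs <- c("lo", "mid", "hi")
  v1 <- fuzzy_variable("u", c(0, 10), labs)
  v2 <- fuzzy_variable("w", c(0, 10), labs)
  out <- fuzzy_variable("y", c(0, 10), labs)
  rules <- list()
  for (i in 1:3) for (j in 1:3) {
    rules[[length(rules) + 1L]] <- fuzzy_rule(
      c(u = labs[i], w = labs[j]), labs[max(i, j)])
  }
  sys <- fuzzy_system(list(v1, v2), out, rules)
  centers <- c(0, 5, 10)
  y <- outer(centers, centers, Vectorize(function(a, b) {
    fuzzy_infer(sys, c(u = a, w = b))
  }))
  expect_true(all(apply(y, 1, function(r) all(diff(r) >= -1e-9))))
  expect_true(all(apply(y, 2, function(r) all(diff(r) >= -1e-9))))
})

test_that("an identically-zero aggregate falls back to the range midpoint", {
  v <- fuzzy_variable("x", c(0, 1e6), mfs = list(
    gaussian_mf("near", 0, 1), gaussian_mf("near2", 10, 1)))
  out <- fuzzy_variable("y", c(0, 10), c("lo", "hi"))
  sys <- fuzzy_system(list(v), out, list(fuzzy_rule(c(x = "near"), "hi")))
  expect_warning(y <- fuzzy_infer(sys, c(x = 1e6)), "zero aggregate")
  expect_equal(y, 5)
})

test_that("system validation names the offending rule and input", {
  v <- fuzzy_variable("x", c(0, 10), c("lo", "hi"))
  out <- fuzzy_variable("y", c(0, 10), c("lo", "hi"))
  expect_error(fuzzy_system(list(v), out, list()), class = "empain_config_error")
  expect_error(
    fuzzy_system(list(v), out, list(fuzzy_rule(c(x = "oops"), "lo"))),
    "rule 1.*oops", class = "empain_config_error")
  expect_error(
    fuzzy_system(list(v), out, list(fuzzy_rule(c(z = "lo"), "lo"))),
    "unknown input variable 'z'", class = "empain_config_error")
  sys <- fuzzy_system(list(v), out, list(fuzzy_rule(c(x = "lo"), "lo")))
  expect_error(fuzzy_infer(sys, c(other = 1)), "missing",
               class = "empain_input_error")
})

test_that("predict() vectorizes inference over a data frame", {
  b2 <- build_block2()
  nd <- data.frame(muscle_contraction = c(0, 10), resistive_torque = c(0, 65),
                   rom_margin = c(60, 0))
  p <- predict(b2, nd)
  expect_length(p, 2L)
  expect_equal(p[1], fuzzy_infer(b2, unlist(nd[1, ])))
  expect_lt(p[1], p[2])
})
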